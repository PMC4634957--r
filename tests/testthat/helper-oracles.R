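# Independent brute-force oracles used to pin down expected values. These
# deliberately avoid the package's own code paths.

# Exhaustive homozygous-gene scan over a variant table and count matrix.
oracle_hom_genes <- function(variants, genotypes, individual) {
  hits <- character(0)
  for (i in seq_len(nrow(variants))) {
    g <- genotypes[variants$key[i], individual]
    if (!is.na(g) && g == 2) hits <- c(hits, variants$gene[i])
  }
  sort(unique(hits))
}

# Exhaustive compound-het scan with enumeration of parental-origin
# assignments for every heterozygous pair.
oracle_comp_het_genes <- function(variants, genotypes, individual, ped = NULL) {
  father <- mother <- NA
  if (!is.null(ped) && individual %in% ped$id) {
    father <- ped$father[ped$id == individual]
    mother <- ped$mother[ped$id == individual]
  }
  can_come_from <- function(parent, key) {
    if (is.na(parent) || !parent %in% colnames(genotypes)) return(TRUE)
    g <- genotypes[key, parent]
    is.na(g) || g >= 1
  }
  hits <- character(0)
  for (gene in unique(variants$gene)) {
    keys <- variants$key[variants$gene == gene]
    het <- keys[!is.na(genotypes[keys, individual]) &
                  genotypes[keys, individual] == 1]
    if (length(het) < 2) next
    ok <- FALSE
    for (a in het) for (b in het) {
      if (a >= b) next
      # enumerate the two trans assignments
      if ((can_come_from(father, a) && can_come_from(mother, b)) ||
          (can_come_from(father, b) && can_come_from(mother, a))) ok <- TRUE
    }
    if (ok) hits <- c(hits, gene)
  }
  sort(unique(hits))
}

# Two-sided Fisher p by explicit enumeration of all tables with the observed
# margins, probabilities from products of binomial coefficients.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- a + b + c + d
  denom <- choose(N, c1)
  support <- max(0, c1 - r2):min(c1, r1)
  probs <- vapply(support, function(x) {
    choose(r1, x) * choose(r2, c1 - x) / denom
  }, 0)
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Two-sided t-test p-value by numerical integration of the t density.
oracle_t_p <- function(t, df) {
  2 * stats::integrate(function(x) stats::dt(x, df), abs(t), Inf,
                       rel.tol = 1e-12)$value
}

# Hand reverse-complement (no Biostrings).
oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "")[[1]]),
        collapse = "")
}

# Small in-memory cohort for candidate-operation tests: random matrices with
# a trio pedigree whose child genotypes are consistent with transmission.
random_small_cohort <- function(seed, n_var = 12, n_genes = 4) {
  withr::with_seed(seed, {
    genes <- paste0("G", seq_len(n_genes))
    variants <- data.frame(
      chrom = "1", pos = seq_len(n_var) * 100,
      ref = sample(c("A", "C", "G", "T"), n_var, replace = TRUE),
      alt = "X", gene = sample(genes, n_var, replace = TRUE),
      func_class = "missense", known_id = NA_character_,
      cdna_pos = NA_character_, stringsAsFactors = FALSE
    )
    variants$alt <- vapply(variants$ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
    variants$key <- variant_key(variants$chrom, variants$pos,
                                variants$ref, variants$alt)
    ids <- c("FA", "MO", "CH", "S1", "S2", "U1", "U2", "U3")
    geno <- matrix(sample(c(0L, 1L, 2L, NA), n_var * length(ids),
                          replace = TRUE, prob = c(.45, .3, .15, .1)),
                   nrow = n_var, dimnames = list(variants$key, ids))
    ped <- data.frame(
      family = "F1",
      id = ids,
      father = c(NA, NA, "FA", "FA", "FA", NA, NA, NA),
      mother = c(NA, NA, "MO", "MO", "MO", NA, NA, NA),
      sex = c("M", "F", "F", "F", "M", "M", "F", "M"),
      affected = c("no", "no", "yes", "yes", "no", "no", "no", "no"),
      stringsAsFactors = FALSE
    )
    class(ped) <- c("pedigree", "data.frame")
    list(variants = variants, genotypes = geno, ped = ped)
  })
}

# Write a minimal VCF body with given records (list of character lines).
write_test_vcf <- function(lines, samples = c("S1", "S2", "S3")) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", samples), collapse = "\t")
  writeLines(c("##fileformat=VCFv4.2", header, lines), path)
  path
}
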