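# Synthetic cohorts with planted autosomal-recessive causal genotypes.
#
# The default design mirrors a six-exome discovery cohort: three affected
# offspring of consanguineous unions sharing homozygous causal alleles in one
# gene, an affected sib pair compound-heterozygous for two further alleles of
# the same gene, and one unaffected relative carrying a single causal allele.
# Distractor genes are engineered to pass the shared-homozygosity filter and
# fail the later exclusion stages; background polymorphism is drawn per
# individual with homozygote probability q^2 + F q (1 - q) for offspring of
# consanguineous unions (inbreeding coefficient F) and q^2 otherwise.

#' Simulation configuration
#'
#' @param seed Integer seed; fully determines every generated artifact.
#' @param n_genes Number of background genes.
#' @param mean_variants_per_gene Poisson mean; each gene gets 1 + Pois draws.
#' @param background_alt_freq Allele frequency q of background polymorphisms.
#' @param known_fraction Probability a background variant is in the known
#'   list (the role a dbSNP build plays upstream).
#' @param func_class_probs Named probabilities over the functional classes
#'   assigned to background variants.
#' @param causal_gene Symbol of the planted causal gene.
#' @param n_distractor_shared_hom Genes engineered to carry shared homozygous
#'   functional non-catalogued variants in the three consanguineous
#'   affecteds, but to fail the unaffected/sib-pair stages.
#' @param inbreeding_f Inbreeding coefficient F for offspring of
#'   consanguineous unions (default 1/16, second-cousin scale; a degree-d
#'   union maps to F = (1/2)^(d+1)).
#' @param biomarker List with `mean`, `sem`, `n` (each length 2: affected,
#'   unaffected) for the urinary biomarker emulation. Group SDs are
#'   `sem * sqrt(n)`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 150L,
                       mean_variants_per_gene = 3,
                       background_alt_freq = 0.10,
                       known_fraction = 0.95,
                       func_class_probs = c(missense = 0.25, nonsense = 0.03,
                                            splice_site = 0.07,
                                            synonymous = 0.45, other = 0.20),
                       causal_gene = "GENE0042",
                       n_distractor_shared_hom = 9L,
                       inbreeding_f = 1 / 16,
                       biomarker = list(mean = c(116.1, 35.9),
                                        sem = c(15.6, 4.6),
                                        n = c(15L, 13L))) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (background_alt_freq < 0 || background_alt_freq > 1 ||
      known_fraction < 0 || known_fraction > 1 ||
      inbreeding_f < 0 || inbreeding_f > 1) {
    stop("frequencies and F must lie in [0, 1]", call. = FALSE)
  }
  if (n_distractor_shared_hom >= n_genes) {
    stop("n_distractor_shared_hom must be smaller than n_genes", call. = FALSE)
  }
  if (!setequal(names(func_class_probs), FUNC_CLASSES) ||
      abs(sum(func_class_probs) - 1) > 1e-8) {
    stop("func_class_probs must cover the functional classes and sum to 1",
         call. = FALSE)
  }
  if (any(biomarker$sem < 0) || any(biomarker$n < 2L)) {
    stop("biomarker groups need sem >= 0 and n >= 2", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 mean_variants_per_gene = mean_variants_per_gene,
                 background_alt_freq = background_alt_freq,
                 known_fraction = known_fraction,
                 func_class_probs = func_class_probs[FUNC_CLASSES],
                 causal_gene = causal_gene,
                 n_distractor_shared_hom = as.integer(n_distractor_shared_hom),
                 inbreeding_f = inbreeding_f,
                 biomarker = biomarker),
            class = "sim_config")
}

# The fixed family designs (generated in a fixed order so seeds are portable).
# Consanguineous-union offspring are the individuals whose background
# homozygosity is inflated by F.
cohort_pedigree <- function() {
  ped <- data.frame(
    family = c(rep("A", 7), rep("B", 3), rep("C", 3), rep("D", 4)),
    id = c("A-IV-1", "A-IV-2", "A-V-2", "A-V-3", "A-V-4", "A-VI-1", "A-VI-2",
           "B-III-1", "B-III-2", "B-IV-3",
           "C-III-1", "C-III-2", "C-IV-3",
           "D-I-1", "D-I-2", "D-II-4", "D-II-5"),
    father = c(NA, NA, "A-IV-1", "A-IV-1", NA, "A-V-4", "A-V-4",
               NA, NA, "B-III-1",
               NA, NA, "C-III-1",
               NA, NA, "D-I-1", "D-I-1"),
    mother = c(NA, NA, "A-IV-2", "A-IV-2", NA, "A-V-2", "A-V-2",
               NA, NA, "B-III-2",
               NA, NA, "C-III-2",
               NA, NA, "D-I-2", "D-I-2"),
    sex = c("M", "F", "F", "F", "M", "F", "M",
            "M", "F", "F",
            "M", "F", "F",
            "M", "F", "F", "F"),
    affected = c("no", "no", "yes", "no", "no", "no", "no",
                 "no", "no", "yes",
                 "no", "no", "yes",
                 "no", "no", "yes", "yes"),
    stringsAsFactors = FALSE
  )
  attr(ped, "consanguinity") <- c(A = 5, B = 3, C = 3)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Individuals whose parents are consanguineous (background homozygosity
# inflated by F), and the roles used by the staged discovery analysis.
COHORT_ROLES <- list(
  inbred = c("A-V-2", "A-V-3", "B-IV-3", "C-IV-3"),
  consang_affected = c("A-V-2", "B-IV-3", "C-IV-3"),
  sib_pair = c("D-II-4", "D-II-5"),
  unaffected_exome = "A-V-3",
  exome_set = c("A-V-2", "B-IV-3", "C-IV-3", "D-II-4", "D-II-5", "A-V-3")
)

#' Generate a synthetic cohort
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort` with elements `variants`,
#'   `genotypes`, `ped`, `known`, `truth`, `config`. The truth record names
#'   the causal gene and variants, the planted per-individual genotypes and
#'   the distractor genes.
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  ped <- cohort_pedigree()
  ids <- ped$id
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  if (!config$causal_gene %in% genes) genes[1L] <- config$causal_gene
  distractors <- sample(setdiff(genes, config$causal_gene),
                        config$n_distractor_shared_hom)

  # Background variants: per-gene counts, positions laid out in 1-Mb blocks.
  # The causal gene carries exactly its planted alleles (its background is
  # left empty so the truth file stays exact under the filter contract).
  n_var <- 1L + stats::rpois(config$n_genes, config$mean_variants_per_gene)
  n_var[match(config$causal_gene, genes)] <- 0L
  gene_of <- rep(genes, n_var)
  chrom <- rep(as.character(rep_len(1:22, config$n_genes)), n_var)
  offset <- unlist(lapply(n_var, function(k) sort(sample.int(999000L, k))))
  pos <- rep(seq_len(config$n_genes) * 1000000L, n_var) + offset
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, length(pos), replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  func <- sample(names(config$func_class_probs), length(pos), replace = TRUE,
                 prob = config$func_class_probs)
  known <- stats::runif(length(pos)) < config$known_fraction
  variants <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                         gene = gene_of, func_class = func,
                         known_id = ifelse(known,
                                           sprintf("kv%06d", seq_along(pos)),
                                           NA_character_),
                         cdna_pos = NA_character_,
                         origin = "background",
                         stringsAsFactors = FALSE)

  # Background genotypes: HWE draws, homozygosity inflated by F for
  # offspring of consanguineous unions. Draws are independent across
  # pedigree members (no transmission model for the background).
  q <- config$background_alt_freq
  geno <- matrix(0L, nrow = nrow(variants), ncol = length(ids),
                 dimnames = list(NULL, ids))
  if (q > 0) {
    for (j in seq_along(ids)) {
      f <- if (ids[j] %in% COHORT_ROLES$inbred) config$inbreeding_f else 0
      p_hom <- q^2 + f * q * (1 - q)
      p_het <- 2 * q * (1 - q) * (1 - f)
      geno[, j] <- sample(c(0L, 1L, 2L), nrow(variants), replace = TRUE,
                          prob = c(1 - p_hom - p_het, p_het, p_hom))
    }
  }

  # Planted causal variants: two splice-site alleles homozygous in the
  # consanguineous affecteds, a missense/nonsense pair compound-het in the
  # sib pair (one allele per parent, hence trans).
  gi <- match(config$causal_gene, genes)
  causal_chrom <- as.character(rep_len(1:22, config$n_genes))[gi]
  causal_base <- gi * 1000000L
  plant <- function(posn, ref, alt, func, cdna, carriers) {
    row <- data.frame(chrom = causal_chrom, pos = posn, ref = ref, alt = alt,
                      gene = config$causal_gene, func_class = func,
                      known_id = NA_character_, cdna_pos = cdna,
                      origin = "causal", stringsAsFactors = FALSE)
    g <- stats::setNames(rep(0L, length(ids)), ids)
    g[names(carriers)] <- carriers
    list(row = row, g = g)
  }
  cv <- list(
    plant(causal_base + 999100L, "G", "C", "splice_site", "1461+1",
          c("A-IV-1" = 1L, "A-IV-2" = 1L, "A-V-2" = 2L, "A-V-3" = 1L,
            "A-VI-1" = 1L, "A-VI-2" = 1L)),
    plant(causal_base + 999200L, "G", "A", "splice_site", "940+1",
          c("B-III-1" = 1L, "B-III-2" = 1L, "B-IV-3" = 2L,
            "C-III-1" = 1L, "C-III-2" = 1L, "C-IV-3" = 2L)),
    plant(causal_base + 999300L, "G", "A", "missense", "664",
          c("D-I-1" = 1L, "D-II-4" = 1L, "D-II-5" = 1L)),
    plant(causal_base + 999400L, "C", "T", "nonsense", "1807",
          c("D-I-2" = 1L, "D-II-4" = 1L, "D-II-5" = 1L))
  )

  # Distractor genes: a functional, non-catalogued variant homozygous in all
  # three consanguineous affecteds. Every third distractor is also
  # homozygous in the unaffected relative (removed by the unaffected rule);
  # the rest carry nothing in the sib pair (removed by the extension rule).
  dv <- lapply(seq_along(distractors), function(k) {
    dgi <- match(distractors[k], genes)
    carriers <- c("A-V-2" = 2L, "B-IV-3" = 2L, "C-IV-3" = 2L)
    if (k %% 3L == 0L) carriers <- c(carriers, "A-V-3" = 2L)
    row <- data.frame(chrom = as.character(rep_len(1:22, config$n_genes))[dgi],
                      pos = dgi * 1000000L + 999500L,
                      ref = "C", alt = "A", gene = distractors[k],
                      func_class = "missense", known_id = NA_character_,
                      cdna_pos = NA_character_, origin = "distractor",
                      stringsAsFactors = FALSE)
    g <- stats::setNames(rep(0L, length(ids)), ids)
    g[names(carriers)] <- carriers
    list(row = row, g = g)
  })

  planted <- c(cv, dv)
  variants <- rbind(variants, do.call(rbind, lapply(planted, `[[`, "row")))
  geno <- rbind(geno, do.call(rbind, lapply(planted, `[[`, "g")))
  ord <- order(as.integer(variants$chrom), variants$pos, variants$ref, variants$alt)
  variants <- variants[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  variants$key <- variant_key(variants$chrom, variants$pos, variants$ref,
                              variants$alt)
  if (anyDuplicated(variants$key)) {
    # a background draw collided with a planted site; drop the background copy
    keep <- !(duplicated(variants$key) & variants$origin == "background")
    variants <- variants[keep, , drop = FALSE]
    geno <- geno[keep, , drop = FALSE]
  }
  rownames(variants) <- NULL
  rownames(geno) <- variants$key

  known_list <- variants[!is.na(variants$known_id),
                         c("chrom", "pos", "ref", "alt", "known_id", "key")]
  names(known_list)[5L] <- "id"
  rownames(known_list) <- NULL

  truth <- list(
    causal_gene = config$causal_gene,
    causal_variants = vapply(cv, function(v) variant_key(v$row$chrom, v$row$pos,
                                                         v$row$ref, v$row$alt), ""),
    planted_genotypes = lapply(planted, function(v)
      list(key = variant_key(v$row$chrom, v$row$pos, v$row$ref, v$row$alt),
           gene = v$row$gene, origin = v$row$origin,
           carriers = as.list(v$g[v$g > 0L]))),
    distractor_genes = sort(distractors),
    roles = COHORT_ROLES,
    n_variants = nrow(variants),
    n_functional = sum(variants$func_class %in% FUNCTIONAL_CLASSES),
    n_functional_unknown = sum(variants$func_class %in% FUNCTIONAL_CLASSES &
                                 is.na(variants$known_id))
  )

  cohort <- structure(list(variants = variants, genotypes = geno, ped = ped,
                           known = known_list, truth = truth, config = config),
                      class = "sim_cohort")
  check_truth_consistency(cohort)
  cohort
}

# Post-generation invariant: the emitted matrices agree with the truth file.
check_truth_consistency <- function(cohort) {
  for (pl in cohort$truth$planted_genotypes) {
    g <- cohort$genotypes[pl$key, ]
    carriers <- unlist(pl$carriers)
    expected <- stats::setNames(rep(0L, ncol(cohort$genotypes)),
                                colnames(cohort$genotypes))
    expected[names(carriers)] <- carriers
    if (!identical(as.integer(g), as.integer(expected[names(g)]))) {
      stop("truth-consistency check failed for ", pl$key, call. = FALSE)
    }
    if (pl$key %in% cohort$known$key) {
      stop("planted variant ", pl$key, " leaked into the known list",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Write a cohort's files (VCF, PED, known list, truth JSON)
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named list of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(vcf = file.path(dir, "cohort.vcf"),
                ped = file.path(dir, "cohort.ped"),
                known = file.path(dir, "known_variants.tsv"),
                truth = file.path(dir, "truth.json"))
  write_vcf(cohort$variants, cohort$genotypes, paths$vcf)
  write_ped(cohort$ped, paths$ped)
  write_known_variants(cohort$known, paths$known)
  jsonlite::write_json(cohort$truth, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths
}

#' Generate per-individual biomarker values
#'
#' Normal draws on the measurement scale for an affected and an unaffected
#' group; group SDs are reconstructed from the configured SEMs
#' (`sd = sem * sqrt(n)`).
#'
#' @param config A [sim_config()].
#' @return data.frame with columns `id`, `group`, `value`.
#' @export
generate_biomarker <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  b <- config$biomarker
  withr::with_seed(config$seed + 10007L, {
    sd <- b$sem * sqrt(b$n)
    data.frame(
      id = c(sprintf("case%02d", seq_len(b$n[1])),
             sprintf("ctrl%02d", seq_len(b$n[2]))),
      group = rep(c("affected", "unaffected"), b$n),
      value = c(stats::rnorm(b$n[1], b$mean[1], sd[1]),
                stats::rnorm(b$n[2], b$mean[2], sd[2])),
      stringsAsFactors = FALSE
    )
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort (seed %d): %d variants x %d individuals, causal gene %s, %d distractors\n",
              x$config$seed, nrow(x$variants), ncol(x$genotypes),
              x$truth$causal_gene, length(x$truth$distractor_genes)))
  invisible(x)
}
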