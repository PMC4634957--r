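# The discovery inference chain: functional filter -> known-variant
# exclusion -> per-individual autosomal-recessive candidate patterns ->
# cross-family intersection -> unaffected exclusion and extension to
# additional affecteds -> segregation check.
#
# Missingness policy: a missing genotype never qualifies an individual for a
# candidate pattern and never disqualifies a gene during unaffected
# exclusion (conservative both ways); strict mode treats missingness in
# unaffecteds as disqualifying.

#' Keep functional variants
#'
#' Retains non-synonymous (missense, nonsense) and splice-site variants,
#' preserving input order.
#'
#' @param variants Variant data.frame (see [read_vcf()]); `func_class` must
#'   be present for every record.
#' @return Filtered data.frame.
#' @export
filter_functional <- function(variants) {
  if (any(is.na(variants$func_class))) {
    stop("every variant needs a func_class before functional filtering",
         call. = FALSE)
  }
  variants[variants$func_class %in% FUNCTIONAL_CLASSES, , drop = FALSE]
}

#' Exclude catalogued variants
#'
#' Removes a variant only on a full (chrom, pos, ref, alt) key match against
#' the known list; a different alternate allele at a catalogued position is
#' retained.
#'
#' @param variants Variant data.frame.
#' @param known Known-variant data.frame ([read_known_variants()]) or a
#'   character vector of keys.
#' @return Filtered data.frame.
#' @export
filter_known <- function(variants, known) {
  keys <- if (is.character(known)) known else known$key
  variants[!variants$key %in% keys, , drop = FALSE]
}

check_individual <- function(genotypes, individual) {
  if (!individual %in% colnames(genotypes)) {
    stop("unknown individual id '", individual, "'", call. = FALSE)
  }
}

#' Genes with a homozygous variant in one individual
#'
#' @param variants Candidate variant data.frame (already filtered).
#' @param genotypes Alt-count matrix (rows = variant keys).
#' @param individual Sample id.
#' @return data.frame with columns `gene`, `variant` (one row per homozygous
#'   variant), sorted by gene then key. Missing genotypes never qualify.
#' @export
homozygous_candidate_genes <- function(variants, genotypes, individual) {
  check_individual(genotypes, individual)
  g <- genotypes[variants$key, individual]
  hom <- !is.na(g) & g == 2L
  out <- data.frame(gene = variants$gene[hom], variant = variants$key[hom],
                    stringsAsFactors = FALSE)
  out[order(out$gene, out$variant), , drop = FALSE]
}

# Can variants v1 and v2 (both het in `individual`) sit on different parental
# haplotypes? With both parents genotyped the pair must admit an assignment
# of the two variants to different parental origins; a parent that is absent
# from the matrix or has a missing call never rules an origin out.
trans_possible <- function(genotypes, individual, v1, v2, ped = NULL) {
  if (is.null(ped)) return(TRUE)
  row <- ped[ped$id == individual, , drop = FALSE]
  if (nrow(row) == 0L) return(TRUE)
  carrier_ok <- function(parent, v) {
    if (is.na(parent) || !parent %in% colnames(genotypes)) return(TRUE)
    g <- genotypes[v, parent]
    is.na(g) || g >= 1L
  }
  (carrier_ok(row$father, v1) && carrier_ok(row$mother, v2)) ||
    (carrier_ok(row$father, v2) && carrier_ok(row$mother, v1))
}

#' Genes with a possible trans compound-heterozygous pair in one individual
#'
#' A gene qualifies when the individual is heterozygous for two distinct
#' variants of that gene and the pair can be assigned to different parental
#' origins. Without parental genotypes a trans configuration is assumed; a
#' pair both of whose variants are carried by the same single parent and
#' absent from the other is cis-forced and disqualified.
#'
#' @inheritParams homozygous_candidate_genes
#' @param ped Optional `pedigree` used to resolve parental origin.
#' @return data.frame with columns `gene`, `variant1`, `variant2` (one row
#'   per qualifying pair), sorted.
#' @export
compound_het_candidate_genes <- function(variants, genotypes, individual,
                                         ped = NULL) {
  check_individual(genotypes, individual)
  g <- genotypes[variants$key, individual]
  het <- variants[!is.na(g) & g == 1L, , drop = FALSE]
  out <- data.frame(gene = character(0), variant1 = character(0),
                    variant2 = character(0), stringsAsFactors = FALSE)
  for (gene in unique(het$gene)) {
    keys <- sort(het$key[het$gene == gene])
    if (length(keys) < 2L) next
    for (a in seq_len(length(keys) - 1L)) {
      for (b in seq((a + 1L), length(keys))) {
        if (trans_possible(genotypes, individual, keys[a], keys[b], ped)) {
          out <- rbind(out, data.frame(gene = gene, variant1 = keys[a],
                                       variant2 = keys[b],
                                       stringsAsFactors = FALSE))
        }
      }
    }
  }
  out[order(out$gene, out$variant1, out$variant2), , drop = FALSE]
}

# Gene-level AR candidacy for one individual under a pattern rule.
candidate_gene_set <- function(variants, genotypes, individual, ped = NULL,
                               pattern = c("either", "hom", "compound_het")) {
  pattern <- match.arg(pattern)
  genes <- character(0)
  if (pattern %in% c("hom", "either")) {
    genes <- union(genes, homozygous_candidate_genes(variants, genotypes,
                                                     individual)$gene)
  }
  if (pattern %in% c("compound_het", "either")) {
    genes <- union(genes, compound_het_candidate_genes(variants, genotypes,
                                                       individual, ped)$gene)
  }
  sort(unique(genes))
}

#' Intersect per-individual candidate gene sets
#'
#' @param candidate_sets List of character vectors of gene symbols (one per
#'   required individual).
#' @return Sorted character vector: genes present in every set.
#' @export
shared_candidate_genes <- function(candidate_sets) {
  if (!length(candidate_sets)) stop("need at least one candidate set", call. = FALSE)
  sort(Reduce(intersect, candidate_sets))
}

#' Exclude candidates by unaffecteds and extend to additional affecteds
#'
#' Removes genes in which any unaffected individual carries a qualifying
#' biallelic genotype (homozygous or trans compound-het over the candidate
#' variants — mere heterozygous carriage never excludes a recessive gene),
#' then retains only genes that also satisfy an AR pattern in every
#' additional affected individual.
#'
#' @param genes Character vector of candidate genes.
#' @param variants Candidate variant data.frame (post filtering).
#' @param genotypes Alt-count matrix.
#' @param ped `pedigree`; unaffecteds default to its genotyped members with
#'   `affected == "no"`.
#' @param additional_affecteds Ids that must each show an AR pattern.
#' @param unaffected_ids Override for the unaffected set.
#' @param strict_missing When `TRUE`, a missing unaffected genotype at a
#'   candidate variant of a gene disqualifies that gene.
#' @return Sorted character vector of surviving genes.
#' @export
exclude_by_unaffected_and_extend <- function(genes, variants, genotypes, ped,
                                             additional_affecteds = character(0),
                                             unaffected_ids = NULL,
                                             strict_missing = FALSE) {
  if (is.null(unaffected_ids)) {
    unaffected_ids <- intersect(ped$id[ped$affected == "no"],
                                colnames(genotypes))
  }
  keep <- vapply(genes, function(gene) {
    gv <- variants[variants$gene == gene, , drop = FALSE]
    for (u in unaffected_ids) {
      biallelic <- length(candidate_gene_set(gv, genotypes, u, ped)) > 0L
      if (biallelic) return(FALSE)
      if (strict_missing && anyNA(genotypes[gv$key, u])) return(FALSE)
    }
    for (aff in additional_affecteds) {
      if (!length(candidate_gene_set(gv, genotypes, aff, ped))) return(FALSE)
    }
    TRUE
  }, TRUE)
  sort(genes[keep])
}

#' Run the staged candidate-gene discovery cascade
#'
#' Applies, in order: the functional filter, known-variant exclusion,
#' per-individual AR candidacy for the required individuals, gene-level
#' intersection, then unaffected exclusion and extension to additional
#' affecteds. Returns the final gene set with per-stage audit counts.
#'
#' @param variants Variant data.frame ([read_vcf()]).
#' @param genotypes Alt-count matrix.
#' @param ped `pedigree`.
#' @param known Known-variant list (data.frame or key vector).
#' @param required_individuals Ids whose candidate sets are intersected
#'   (the shared-homozygosity stage of the design).
#' @param additional_affecteds Ids that must each show an AR pattern for a
#'   gene to survive.
#' @param unaffected_ids Unaffected set for exclusion (default: genotyped
#'   unaffecteds of `ped`).
#' @param hom_only_for_consanguineous When `TRUE` (default) the required
#'   individuals contribute homozygous-pattern genes only, matching a
#'   shared-homozygosity design for consanguineous families; when `FALSE`
#'   compound-het patterns also count at that stage.
#' @param strict_missing See [exclude_by_unaffected_and_extend()].
#' @return An object of class `candidate_report`: list with `final_genes`,
#'   `shared_genes`, `per_individual` (named list of gene sets), `support`
#'   (data.frame of supporting genotype patterns for the final genes) and
#'   `audit` (named counts down the cascade).
#' @export
prioritize_cohort <- function(variants, genotypes, ped, known,
                              required_individuals,
                              additional_affecteds = character(0),
                              unaffected_ids = NULL,
                              hom_only_for_consanguineous = TRUE,
                              strict_missing = FALSE) {
  n_input <- nrow(variants)
  fun <- filter_functional(variants)
  surv <- filter_known(fun, known)
  pattern <- if (hom_only_for_consanguineous) "hom" else "either"
  per_individual <- stats::setNames(
    lapply(required_individuals, function(id)
      candidate_gene_set(surv, genotypes, id, ped, pattern = pattern)),
    required_individuals
  )
  shared <- shared_candidate_genes(per_individual)
  final <- exclude_by_unaffected_and_extend(
    shared, surv, genotypes, ped,
    additional_affecteds = additional_affecteds,
    unaffected_ids = unaffected_ids,
    strict_missing = strict_missing
  )

  support <- do.call(rbind, lapply(final, function(gene) {
    gv <- surv[surv$gene == gene, , drop = FALSE]
    ids <- unique(c(required_individuals, additional_affecteds))
    do.call(rbind, lapply(ids, function(id) {
      hom <- homozygous_candidate_genes(gv, genotypes, id)
      ch <- compound_het_candidate_genes(gv, genotypes, id, ped)
      pat <- if (nrow(hom)) "hom" else if (nrow(ch)) "compound_het" else "none"
      vars <- if (nrow(hom)) paste(hom$variant, collapse = ",")
              else if (nrow(ch)) paste(ch$variant1[1L], ch$variant2[1L], sep = ",")
              else ""
      data.frame(gene = gene, individual = id, pattern = pat,
                 variants = vars, stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(support)) {
    support <- data.frame(gene = character(0), individual = character(0),
                          pattern = character(0), variants = character(0),
                          stringsAsFactors = FALSE)
  }

  structure(list(
    final_genes = final,
    shared_genes = shared,
    per_individual = per_individual,
    support = support,
    audit = c(input_variants = n_input,
              functional_variants = nrow(fun),
              after_known_exclusion = nrow(surv),
              shared_genes = length(shared),
              final_genes = length(final))
  ), class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat("Candidate gene report\n")
  cat(sprintf("  variants: %d -> functional %d -> after known-variant exclusion %d\n",
              x$audit["input_variants"], x$audit["functional_variants"],
              x$audit["after_known_exclusion"]))
  cat(sprintf("  shared candidate genes: %d; after exclusion/extension: %d\n",
              x$audit["shared_genes"], x$audit["final_genes"]))
  if (length(x$final_genes)) {
    cat("  final:", paste(x$final_genes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Check co-segregation of causal variants in a pedigree
#'
#' Under the recessive model every affected must be biallelic for the causal
#' variants (homozygous for one, or heterozygous for two distinct ones), no
#' unaffected may be biallelic, and every genotyped parent of an affected
#' must carry at least one causal allele. Individuals with a missing causal
#' genotype are reported untestable, never as violations.
#'
#' @param ped `pedigree`.
#' @param genotypes Alt-count matrix.
#' @param causal_variants Character vector of variant keys (one gene's
#'   causal alleles as they segregate in the family under test).
#' @param family Optional family id; restricts the check to that family's
#'   members (different families of one cohort usually segregate different
#'   alleles of the causal gene).
#' @return An object of class `segregation_result` with `consistent`,
#'   `violations` (data.frame `individual`/`rule`/`observed`), `untestable`
#'   and `carrier_state` (per-individual causal-allele dose).
#' @export
check_segregation <- function(ped, genotypes, causal_variants, family = NULL) {
  if (!is.null(family)) {
    ped <- ped[ped$family %in% family, , drop = FALSE]
    if (!nrow(ped)) stop("family '", family, "' not in pedigree", call. = FALSE)
  }
  missing_keys <- setdiff(causal_variants, rownames(genotypes))
  if (length(missing_keys)) {
    stop("causal variants not in genotype matrix: ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  ids <- intersect(ped$id, colnames(genotypes))
  sub <- genotypes[causal_variants, ids, drop = FALSE]
  untestable <- ids[apply(sub, 2L, anyNA)]
  dose <- colSums(sub)
  biallelic <- apply(sub, 2L, function(g)
    !anyNA(g) && (any(g == 2L) || sum(g >= 1L) >= 2L))

  violations <- data.frame(individual = character(0), rule = character(0),
                           observed = character(0), stringsAsFactors = FALSE)
  add_violation <- function(id, rule, obs) {
    violations <<- rbind(violations,
                         data.frame(individual = id, rule = rule,
                                    observed = obs, stringsAsFactors = FALSE))
  }
  affected_ids <- ped$id[ped$affected == "yes"]
  for (id in setdiff(ids, untestable)) {
    aff <- ped$affected[ped$id == id]
    if (aff == "yes" && !biallelic[id]) {
      add_violation(id, "affected_not_biallelic",
                    sprintf("%d causal allele(s)", dose[id]))
    }
    if (aff == "no" && biallelic[id]) {
      add_violation(id, "unaffected_biallelic",
                    sprintf("%d causal allele(s)", dose[id]))
    }
  }
  for (id in intersect(affected_ids, ped$id)) {
    row <- ped[ped$id == id, ]
    for (parent in stats::na.omit(c(row$father, row$mother))) {
      if (!parent %in% ids || parent %in% untestable) next
      if (dose[parent] < 1L) {
        add_violation(parent, "parent_of_affected_not_carrier",
                      "0 causal alleles")
      }
    }
  }
  violations <- unique(violations)
  structure(list(consistent = nrow(violations) == 0L,
                 violations = violations,
                 untestable = untestable,
                 carrier_state = dose),
            class = "segregation_result")
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf("Segregation: %s (%d violation(s), %d untestable)\n",
              if (x$consistent) "consistent" else "INCONSISTENT",
              nrow(x$violations), length(x$untestable)))
  if (nrow(x$violations)) print(x$violations)
  invisible(x)
}
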