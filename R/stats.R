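# Cohort-level aggregates: per-patient biallelic classification, allele
# counts over explicit patient subsets, exact and summary-based tests, and
# clinical-feature proportions.

#' Load the packaged enteropathy patient table
#'
#' Transcription of the published per-patient table for the SLCO2A1
#' enteropathy cohort: 18 genetically confirmed patients with sex,
#' consanguinity, mutation genotype (two allele labels, `WT` for a
#' wild-type slot), ages, presenting symptoms, disease sites (subset of
#' S/D/J/I), laboratory values and surgery status. Patients 1-5 were
#' exome-sequenced, 6-16 found by Sanger screening of further enteropathy
#' patients, 17-18 by screening a Crohn's-disease cohort.
#'
#' @return data.frame, one row per patient.
#' @export
read_patient_table <- function() {
  path <- system.file("extdata", "ceas_patients.tsv", package = "exomeAR",
                      mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA")
}

#' Annotations of the seven recurrent SLCO2A1 mutations
#'
#' The mutation sites underlying the packaged patient table: hg19 position
#' on chromosome 3, exon, cDNA label, protein label and functional class,
#' plus control-cohort allele counts where the site was genotyped (`NA`
#' where it was not).
#'
#' @return data.frame, one row per mutation site.
#' @export
variant_annotations <- function() {
  data.frame(
    cdna = c("c.421G>T", "c.547G>A", "c.664G>A", "c.940+1G>A",
             "c.1372G>T", "c.1461+1G>C", "c.1807C>T"),
    chrom = "3",
    pos = c(133674014L, 133673888L, 133672567L, 133667736L,
            133664028L, 133663938L, 133654625L),
    exon = c("4", "4", "5", "intron 7", "10", "intron 10", "13"),
    protein = c("E141X", "G183R", "G222R", NA, "V458F", NA, "R603X"),
    func_class = c("nonsense", "missense", "missense", "splice_site",
                   "missense", "splice_site", "nonsense"),
    control_alt = c(NA, NA, 0L, 3L, NA, 0L, 0L),
    control_total = c(NA, NA, 1494L, 1494L, NA, 1494L, 1494L),
    stringsAsFactors = FALSE
  )
}

#' Classify a biallelic genotype from two allele labels
#'
#' @param allele1,allele2 Character vectors of mutation labels, `"WT"` for a
#'   wild-type slot.
#' @return Character vector over `{homozygous, compound_het, single_het,
#'   none}`.
#' @export
classify_genotype <- function(allele1, allele2) {
  if (length(allele1) != length(allele2)) {
    stop("allele vectors must have equal length", call. = FALSE)
  }
  bad <- is.na(allele1) | is.na(allele2) | !nzchar(allele1) | !nzchar(allele2)
  if (any(bad)) {
    stop("unparseable genotype at position ", which(bad)[1L], call. = FALSE)
  }
  ifelse(allele1 == "WT" & allele2 == "WT", "none",
  ifelse(allele1 == "WT" | allele2 == "WT", "single_het",
  ifelse(allele1 == allele2, "homozygous", "compound_het")))
}

#' Mutant allele count for one mutation over a patient subset
#'
#' Counts two alleles per homozygote and one per heterozygous carrier; the
#' denominator is two chromosomes per patient counted. The patient subset is
#' explicit because published allele-frequency columns are defined over
#' stated subcohorts.
#'
#' @param patients Patient table ([read_patient_table()]).
#' @param label Mutation label (cDNA name).
#' @param ids Patient ids to count (default: all rows).
#' @return data.frame row: `label`, `alt`, `total`, `frequency`.
#' @export
allele_counts <- function(patients, label, ids = patients$patient) {
  sub <- patients[patients$patient %in% ids, , drop = FALSE]
  alt <- sum(sub$allele1 == label) + sum(sub$allele2 == label)
  total <- 2L * nrow(sub)
  data.frame(label = label, alt = alt, total = total,
             frequency = if (total > 0L) alt / total else NA_real_,
             stringsAsFactors = FALSE)
}

#' Allele-count table over several mutations
#'
#' @inheritParams allele_counts
#' @param labels Mutation labels (default: the seven annotated sites).
#' @return data.frame, one row per label, mirroring a mutant-allele-frequency
#'   table column.
#' @export
allele_count_table <- function(patients, labels = variant_annotations()$cdna,
                               ids = patients$patient) {
  do.call(rbind, lapply(labels, function(l) allele_counts(patients, l, ids)))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by summing hypergeometric probabilities of all tables with
#' the observed margins that are no more probable than the observed table
#' (the convention of standard exact-test implementations); a doubling rule
#' is available. The odds ratio is the sample cross-product, with Haldane's
#' +0.5 correction (flagged) when a cell is zero.
#'
#' @param a,b,c,d Non-negative integer cell counts, rows = groups, columns =
#'   outcome: `matrix(c(a, c, b, d), 2, 2)` column-wise.
#' @param alternative_rule `"minlike"` (default) or `"doubling"`.
#' @return List with `p_value`, `odds_ratio`, `haldane` (logical flag).
#' @export
fisher_exact_2x2 <- function(a, b, c, d,
                             alternative_rule = c("minlike", "doubling")) {
  alternative_rule <- match.arg(alternative_rule)
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    stop("a margin of the 2x2 table is zero; the test is undefined",
         call. = FALSE)
  }
  m <- a + b          # first row total
  n <- c + d          # second row total
  k <- a + c          # first column total
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- switch(alternative_rule,
    minlike = sum(probs[probs <= p_obs * (1 + 1e-7)]),
    doubling = min(1, 2 * min(sum(probs[support <= a]),
                              sum(probs[support >= a])))
  )
  haldane <- any(cells == 0)
  or <- if (haldane) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    (a * d) / (b * c)
  }
  list(p_value = min(p, 1), odds_ratio = or, haldane = haldane)
}

#' Group summary (mean, SEM, n)
#' @param mean Group mean.
#' @param sem Standard error of the mean (> 0).
#' @param n Group size (>= 2).
#' @return List of class `group_summary`.
#' @export
group_summary <- function(mean, sem, n) {
  assert_scalar_number(mean, "mean")
  assert_scalar_number(sem, "sem")
  assert_scalar_number(n, "n")
  if (sem <= 0) stop("sem must be > 0", call. = FALSE)
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  structure(list(mean = mean, sem = sem, n = as.integer(n)),
            class = "group_summary")
}

#' Two-sample t test from group summaries
#'
#' Welch's unequal-variance form by default:
#' `t = (m1 - m2) / sqrt(sem1^2 + sem2^2)` with Welch-Satterthwaite degrees
#' of freedom on the squared SEMs. `pooled = TRUE` reproduces the classical
#' Student form (SDs reconstructed as `sem * sqrt(n)`).
#'
#' @param g1,g2 [group_summary()] objects (or lists with `mean`, `sem`, `n`).
#' @param pooled Use the pooled-variance Student form.
#' @return List with `t`, `df`, `p_value` (two-sided).
#' @export
welch_t_from_summary <- function(g1, g2, pooled = FALSE) {
  for (g in list(g1, g2)) {
    if (is.null(g$mean) || is.null(g$sem) || is.null(g$n) || g$sem <= 0) {
      stop("groups need mean, sem > 0 and n", call. = FALSE)
    }
  }
  if (pooled) {
    v1 <- (g1$sem * sqrt(g1$n))^2
    v2 <- (g2$sem * sqrt(g2$n))^2
    df <- g1$n + g2$n - 2
    sp2 <- ((g1$n - 1) * v1 + (g2$n - 1) * v2) / df
    t <- (g1$mean - g2$mean) / sqrt(sp2 * (1 / g1$n + 1 / g2$n))
  } else {
    s2 <- g1$sem^2 + g2$sem^2
    t <- (g1$mean - g2$mean) / sqrt(s2)
    df <- s2^2 / (g1$sem^4 / (g1$n - 1) + g2$sem^4 / (g2$n - 1))
  }
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Count and percentage of patients matching a predicate
#'
#' @param patients Patient table.
#' @param predicate Logical vector over rows, or a function of the table
#'   returning one.
#' @return List with `count`, `n`, `percent` (half-up to one decimal).
#' @export
feature_proportions <- function(patients, predicate) {
  if (!nrow(patients)) stop("empty patient list", call. = FALSE)
  sel <- if (is.function(predicate)) predicate(patients) else predicate
  stopifnot(is.logical(sel), length(sel) == nrow(patients))
  k <- sum(sel, na.rm = TRUE)
  list(count = k, n = nrow(patients),
       percent = round_half_up(100 * k / nrow(patients), 1))
}

#' Does a patient's disease-site string include a site?
#'
#' @param sites Character vector like `"S,D,I"` (subset of S, D, J, I).
#' @param site Single site code.
#' @return Logical vector.
#' @export
has_site <- function(sites, site) {
  if (!site %in% c("S", "D", "J", "I")) {
    stop("site must be one of S, D, J, I", call. = FALSE)
  }
  vapply(strsplit(sites, ",", fixed = TRUE),
         function(x) site %in% trimws(x), TRUE)
}
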