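# End-to-end orchestration: simulate -> prioritize -> segregate ->
# consequence -> stats, with TSV/JSON reports and a reproducibility
# manifest. All outputs are deterministic functions of the configuration, so
# a rerun on identical inputs is byte-identical.

#' Run the discovery workflow end to end
#'
#' @param out_dir Output directory (created if needed). Cohort inputs are
#'   written to / read from `out_dir/data`, reports to `out_dir`.
#' @param config A [sim_config()]; drives the simulate stage and the
#'   biomarker summary used by the stats stage.
#' @param stages Subset of `simulate`, `prioritize`, `segregate`,
#'   `consequence`, `stats`, run in that order. Later stages read the files
#'   the simulate stage writes, so they can also run against externally
#'   supplied files in `out_dir/data`.
#' @param hom_only_for_consanguineous,strict_missing Passed to
#'   [prioritize_cohort()].
#' @return Invisibly, a list with the stage results and the manifest. Any
#'   stage failure signals an error naming the stage.
#' @export
run_pipeline <- function(out_dir, config = sim_config(),
                         stages = c("simulate", "prioritize", "segregate",
                                    "consequence", "stats"),
                         hom_only_for_consanguineous = TRUE,
                         strict_missing = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  data_dir <- file.path(out_dir, "data")
  paths <- list(vcf = file.path(data_dir, "cohort.vcf"),
                ped = file.path(data_dir, "cohort.ped"),
                known = file.path(data_dir, "known_variants.tsv"),
                truth = file.path(data_dir, "truth.json"))
  results <- list()
  audit <- NULL

  in_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage %s: %s", stage, conditionMessage(e)), call. = FALSE)
    })
  }

  if ("simulate" %in% stages) {
    results$cohort <- in_stage("simulate", {
      cohort <- generate_cohort(config)
      write_cohort(cohort, data_dir)
      cohort
    })
  }

  need_inputs <- function(stage) {
    for (p in c(paths$vcf, paths$ped, paths$known)) {
      if (!file.exists(p)) {
        stop(sprintf("stage %s: required input %s is missing", stage, p),
             call. = FALSE)
      }
    }
  }

  if ("prioritize" %in% stages) {
    need_inputs("prioritize")
    results$report <- in_stage("prioritize", {
      vcf <- read_vcf(paths$vcf, strict_func = TRUE)
      ped <- read_ped(paths$ped)
      known <- read_known_variants(paths$known)
      report <- prioritize_cohort(
        vcf$variants, vcf$genotypes, ped, known,
        required_individuals = COHORT_ROLES$consang_affected,
        additional_affecteds = COHORT_ROLES$sib_pair,
        unaffected_ids = COHORT_ROLES$unaffected_exome,
        hom_only_for_consanguineous = hom_only_for_consanguineous,
        strict_missing = strict_missing
      )
      write_report_tsv(report$support, file.path(out_dir, "candidates.tsv"))
      jsonlite::write_json(as.list(report$audit),
                           file.path(out_dir, "audit.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      report
    })
    audit <- results$report$audit
  }

  if ("segregate" %in% stages) {
    need_inputs("segregate")
    results$segregation <- in_stage("segregate", {
      if (!file.exists(paths$truth)) {
        stop("truth file with causal variants is missing", call. = FALSE)
      }
      truth <- jsonlite::fromJSON(paths$truth)
      vcf <- read_vcf(paths$vcf)
      ped <- read_ped(paths$ped)
      # Each family is tested against the causal alleles its members carry.
      segs <- lapply(unique(ped$family), function(fam) {
        members <- intersect(ped$id[ped$family == fam], colnames(vcf$genotypes))
        sub <- vcf$genotypes[truth$causal_variants, members, drop = FALSE]
        fam_vars <- truth$causal_variants[rowSums(sub, na.rm = TRUE) > 0]
        if (!length(fam_vars)) return(NULL)
        seg <- check_segregation(ped, vcf$genotypes, fam_vars, family = fam)
        cbind(family = fam,
              data.frame(individual = names(seg$carrier_state),
                         causal_alleles = as.integer(seg$carrier_state),
                         affected = ped$affected[match(names(seg$carrier_state),
                                                       ped$id)],
                         consistent = seg$consistent,
                         stringsAsFactors = FALSE))
      })
      out <- do.call(rbind, segs)
      write_report_tsv(out, file.path(out_dir, "segregation.tsv"))
      out
    })
  }

  if ("consequence" %in% stages) {
    results$consequence <- in_stage("consequence", {
      cases <- list(
        exon_skip = generate_transcript_case(config$seed, event = "exon_skip"),
        intron_retention = generate_transcript_case(config$seed + 1L,
                                                    event = "insertion",
                                                    insert_len = 23L)
      )
      rows <- lapply(names(cases), function(nm) {
        cs <- cases[[nm]]
        cons <- name_consequence(coding_seq(cs$model),
                                 apply_splice_outcome(cs$model, cs$outcome))
        data.frame(case = nm, event = cs$outcome$kind,
                   category = cons$category, hgvs_p = cons$hgvs_p,
                   stringsAsFactors = FALSE)
      })
      tab <- do.call(rbind, rows)
      write_report_tsv(tab, file.path(out_dir, "consequence.tsv"))
      tab
    })
  }

  if ("stats" %in% stages) {
    results$stats <- in_stage("stats", {
      patients <- read_patient_table()
      alleles <- allele_count_table(patients, ids = 1:16)
      write_report_tsv(alleles, file.path(out_dir, "allele_counts.tsv"))
      props <- data.frame(
        feature = c("female", "stomach", "duodenum", "jejunum", "ileum"),
        count = NA_integer_, n = NA_integer_, percent = NA_real_,
        stringsAsFactors = FALSE
      )
      preds <- list(patients$sex == "F", has_site(patients$sites, "S"),
                    has_site(patients$sites, "D"), has_site(patients$sites, "J"),
                    has_site(patients$sites, "I"))
      for (i in seq_along(preds)) {
        fp <- feature_proportions(patients, preds[[i]])
        props$count[i] <- fp$count
        props$n[i] <- fp$n
        props$percent[i] <- fp$percent
      }
      write_report_tsv(props, file.path(out_dir, "feature_proportions.tsv"))
      b <- config$biomarker
      tt <- welch_t_from_summary(group_summary(b$mean[1], b$sem[1], b$n[1]),
                                 group_summary(b$mean[2], b$sem[2], b$n[2]))
      write_report_tsv(
        data.frame(statistic = c("t", "df", "p_value"),
                   value = sprintf("%.6g", c(tt$t, tt$df, tt$p_value)),
                   stringsAsFactors = FALSE),
        file.path(out_dir, "biomarker_test.tsv")
      )
      list(alleles = alleles, proportions = props, biomarker_test = tt)
    })
  }

  input_files <- Filter(file.exists, unlist(paths))
  manifest <- list(
    package = "exomeAR",
    version = as.character(utils::packageVersion("exomeAR")),
    stages = stages,
    seed = config$seed,
    config = unclass(config)[c("n_genes", "mean_variants_per_gene",
                               "background_alt_freq", "known_fraction",
                               "causal_gene", "n_distractor_shared_hom",
                               "inbreeding_f")],
    inputs = as.list(stats::setNames(tools::md5sum(input_files),
                                     basename(input_files))),
    audit = if (!is.null(audit)) as.list(audit) else NULL
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(results, list(manifest = manifest)))
}
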