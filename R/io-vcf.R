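# Reading and writing the documented VCF v4.2 subset.
#
# The dialect: columns CHROM POS ID REF ALT QUAL FILTER INFO FORMAT <samples>,
# INFO keys GENE (gene symbol), FUNC (functional class), KNOWN (known-variant
# id) and CDNA (HGVS c. position, e.g. 940+1) — all optional per record —
# and a FORMAT that contains GT. Genotypes are diploid; phase separators are
# accepted but phase is discarded at this layer (it is reconstructed from the
# pedigree during prioritization).

#' Read a variant call file
#'
#' Parses the VCF v4.2 subset used by the pipeline into a variant table and a
#' genotype matrix of per-sample alternate-allele counts. Multi-allelic
#' records are split into one variant per alternate allele, with genotype
#' allele indices remapped per split record; `./.` maps to `NA` (missing).
#'
#' @param path Path to an uncompressed VCF file.
#' @param strict_func When `TRUE`, records without a FUNC annotation are
#'   rejected rather than carried with an unknown class. Prioritization
#'   requires FUNC, so runs feeding that stage should use strict mode.
#' @return A list with elements:
#'   \describe{
#'     \item{variants}{data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'       `gene`, `func_class`, `known_id`, `cdna_pos`, `key`.}
#'     \item{genotypes}{integer matrix, variants (rows, named by key) by
#'       samples (columns); entries 0/1/2 or `NA` for missing.}
#'   }
#' @export
read_vcf <- function(path, strict_func = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcf@fix  # keep INFO (getFIX drops it)
  n_meta <- length(vcf@meta)
  body_line <- function(i) n_meta + 1L + i  # meta lines + #CHROM header + row

  gt_raw <- vcf@gt
  if (is.null(gt_raw) || ncol(gt_raw) < 2L) {
    stop(path, ": no sample genotype columns", call. = FALSE)
  }
  samples <- colnames(gt_raw)[-1L]
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix), dimnames = list(NULL, samples))

  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    chrom <- unname(fix[i, "CHROM"])
    pos <- suppressWarnings(as.integer(fix[i, "POS"]))
    ref <- unname(fix[i, "REF"])
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    if (is.na(pos) || pos < 1L) stop_format(path, body_line(i), "invalid POS")
    if (!length(alts) || any(alts == ref)) {
      stop_format(path, body_line(i), "ALT must differ from REF")
    }
    info <- parse_info(fix[i, "INFO"])
    func <- info[["FUNC"]] %||% NA_character_
    if (!is.na(func) && !func %in% FUNC_CLASSES) {
      stop_format(path, body_line(i), paste0("unknown FUNC value '", func, "'"))
    }
    if (strict_func && is.na(func)) {
      stop_format(path, body_line(i), "missing FUNC annotation (strict mode)")
    }

    # Parse diploid GT; count copies of each alt index after the split.
    counts <- matrix(NA_integer_, nrow = length(alts), ncol = length(samples))
    for (s in seq_along(samples)) {
      g <- gt[i, s]
      if (is.na(g)) next
      parts <- strsplit(g, "[/|]")[[1L]]
      if (length(parts) != 2L || !all(grepl("^(\\.|[0-9]+)$", parts))) {
        stop_format(path, body_line(i),
                    sprintf("malformed GT '%s' for sample %s", g, samples[s]))
      }
      if (any(parts == ".")) next  # half-calls treated as missing
      idx <- as.integer(parts)
      if (any(idx > length(alts))) {
        stop_format(path, body_line(i),
                    sprintf("GT allele index out of range in '%s'", g))
      }
      for (k in seq_along(alts)) counts[k, s] <- sum(idx == k)
    }

    id <- unname(fix[i, "ID"])
    out[[i]] <- list(
      variants = data.frame(
        chrom = chrom, pos = pos, ref = ref, alt = alts,
        gene = info[["GENE"]] %||% NA_character_,
        func_class = func,
        known_id = if (!is.null(info[["KNOWN"]])) info[["KNOWN"]]
                   else if (!is.na(id) && id != ".") id else NA_character_,
        cdna_pos = info[["CDNA"]] %||% NA_character_,
        stringsAsFactors = FALSE
      ),
      counts = counts,
      line = body_line(i)
    )
  }

  variants <- do.call(rbind, lapply(out, `[[`, "variants"))
  variants$key <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  dup <- duplicated(variants$key)
  if (any(dup)) {
    row_of <- rep(seq_along(out), vapply(out, function(o) nrow(o$variants), 1L))
    stop_format(path, out[[row_of[which(dup)[1L]]]]$line,
                paste0("duplicate variant ", variants$key[which(dup)[1L]]))
  }
  genotypes <- do.call(rbind, lapply(out, `[[`, "counts"))
  rownames(genotypes) <- variants$key
  colnames(genotypes) <- samples
  rownames(variants) <- NULL
  list(variants = variants, genotypes = genotypes)
}

parse_info <- function(x) {
  if (is.na(x) || x == "." || x == "") return(list())
  kv <- strsplit(strsplit(x, ";", fixed = TRUE)[[1L]], "=", fixed = TRUE)
  vals <- lapply(kv, function(p) if (length(p) == 2L) p[2L] else TRUE)
  names(vals) <- vapply(kv, `[[`, "", 1L)
  vals
}

VCF_META <- c(
  "##fileformat=VCFv4.2",
  "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol assigned upstream\">",
  "##INFO=<ID=FUNC,Number=1,Type=String,Description=\"Functional class: missense|nonsense|splice_site|synonymous|other\">",
  "##INFO=<ID=KNOWN,Number=1,Type=String,Description=\"Known-variant identifier\">",
  "##INFO=<ID=CDNA,Number=1,Type=String,Description=\"HGVS c. position, intron offsets as N+M/N-M\">",
  "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
)

#' Write a variant table and genotype matrix as canonical VCF
#'
#' Emits the package's canonical plain-text form: fixed meta header, one
#' bi-allelic record per variant, genotypes as `0/0`, `0/1`, `1/1` or `./.`.
#' `write_vcf(read_vcf(f))` is byte-identical for files already canonical.
#'
#' @param variants Variant data.frame as returned by [read_vcf()].
#' @param genotypes Matrix of alt-allele counts (rows = variant keys).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, genotypes, path) {
  stopifnot(nrow(variants) == nrow(genotypes))
  samples <- colnames(genotypes)
  info <- vapply(seq_len(nrow(variants)), function(i) {
    parts <- character(0)
    if (!is.na(variants$gene[i])) parts <- c(parts, paste0("GENE=", variants$gene[i]))
    if (!is.na(variants$func_class[i])) parts <- c(parts, paste0("FUNC=", variants$func_class[i]))
    if (!is.na(variants$known_id[i])) parts <- c(parts, paste0("KNOWN=", variants$known_id[i]))
    if (!is.na(variants$cdna_pos[i])) parts <- c(parts, paste0("CDNA=", variants$cdna_pos[i]))
    if (!length(parts)) "." else paste(parts, collapse = ";")
  }, "")
  gt_str <- matrix(c("0/0", "0/1", "1/1")[genotypes + 1L],
                   nrow = nrow(genotypes))
  gt_str[is.na(gt_str)] <- "./."
  body <- paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
                ".", ".", info, "GT",
                apply(gt_str, 1L, paste, collapse = "\t"),
                sep = "\t")
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", samples), collapse = "\t")
  writeLines(c(VCF_META, header, body), path)
  invisible(path)
}
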