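# Known-variant lists and TSV report writers.

#' Read a known-variant list
#'
#' Tab-separated catalogue of previously observed variants (the role dbSNP
#' plays in an exome filter): columns `chrom`, `pos`, `ref`, `alt`, `id`.
#' Membership is matched on the full (chrom, pos, ref, alt) key, never on
#' position alone.
#'
#' @param path Path to the TSV file (with header).
#' @return data.frame with a `key` column added.
#' @export
read_known_variants <- function(path) {
  kv <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "id")
  if (!all(need %in% names(kv))) {
    stop(path, ": known-variant list must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  kv$pos <- as.integer(kv$pos)
  kv$key <- variant_key(kv$chrom, kv$pos, kv$ref, kv$alt)
  kv
}

#' Write a known-variant list
#' @param known data.frame with columns `chrom`, `pos`, `ref`, `alt`, `id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_known_variants <- function(known, path) {
  utils::write.table(known[, c("chrom", "pos", "ref", "alt", "id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Fixed-column TSV report writer (deterministic byte output).
write_report_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
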