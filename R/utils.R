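# Internal helpers shared across modules.

#' Canonical variant key
#'
#' Builds the `chrom:pos:ref:alt` string used to index variants and the rows
#' of genotype matrices throughout the package.
#'
#' @param chrom Chromosome label.
#' @param pos 1-based genomic position.
#' @param ref Reference allele.
#' @param alt Alternate allele.
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# round() uses round-half-even; cohort percentages are reported half-up.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Format errors tied to a file location; line is the 1-based physical line.
stop_format <- function(path, line, msg) {
  stop(sprintf("%s: line %d: %s", path, line, msg), call. = FALSE)
}

FUNC_CLASSES <- c("missense", "nonsense", "splice_site", "synonymous", "other")
FUNCTIONAL_CLASSES <- c("missense", "nonsense", "splice_site")

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single non-missing number", name), call. = FALSE)
  }
}
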