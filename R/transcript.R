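# Transcript models: exon coordinates plus sequence, used to derive the
# protein-level consequence of splice events. Coordinates are 1-based
# inclusive within the supplied genomic span; CDS bounds are
# transcript-relative (1 = first spliced base, counting on the transcript
# strand).

#' Construct a transcript model
#'
#' @param gene Gene symbol.
#' @param strand `"+"` or `"-"`. For minus-strand genes exons are supplied in
#'   ascending genomic order and are spliced in reverse order after
#'   reverse-complementing.
#' @param exons data.frame (or 2-column matrix) of exon `start`/`end`
#'   coordinates, 1-based inclusive within `seq`.
#' @param cds_start,cds_end CDS bounds on the spliced transcript (1-based,
#'   inclusive; `cds_start` is the A of the ATG).
#' @param seq Genomic span sequence the exon coordinates index into.
#' @param require_frame When `TRUE` a CDS length that is not a multiple of 3
#'   is an error; when `FALSE` it only warns.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(gene, strand, exons, cds_start, cds_end, seq,
                             require_frame = TRUE) {
  if (is.matrix(exons)) exons <- data.frame(start = exons[, 1], end = exons[, 2])
  exons <- data.frame(start = as.integer(exons$start), end = as.integer(exons$end))
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  if (any(exons$start > exons$end)) stop("exon start > end", call. = FALSE)
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (nrow(exons) > 1L && any(exons$start[-1L] <= exons$end[-nrow(exons)])) {
    stop("overlapping exons", call. = FALSE)
  }
  if (max(exons$end) > nchar(seq)) {
    stop("exon coordinates exceed sequence length", call. = FALSE)
  }
  model <- structure(
    list(gene = gene, strand = strand, exons = exons,
         cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
         seq = toupper(seq)),
    class = "transcript_model"
  )
  tx <- spliced_seq(model)
  if (cds_start < 1L || cds_end > nchar(tx) || cds_end - cds_start + 1L < 3L) {
    stop("CDS bounds outside spliced transcript or shorter than one codon",
         call. = FALSE)
  }
  cds <- substr(tx, cds_start, cds_end)
  if (substr(cds, 1L, 3L) != "ATG") {
    stop("CDS does not begin with a start codon", call. = FALSE)
  }
  if (nchar(cds) %% 3L != 0L) {
    msg <- sprintf("CDS length %d is not a multiple of 3", nchar(cds))
    if (require_frame) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  model
}

#' Spliced transcript sequence
#' @param model A `transcript_model`.
#' @return Character scalar: exon sequences joined in transcript orientation.
#' @export
spliced_seq <- function(model) {
  pieces <- substring(model$seq, model$exons$start, model$exons$end)
  if (model$strand == "-") {
    pieces <- rev(vapply(pieces, revcomp, ""))
  }
  paste(pieces, collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Reference CDS of a transcript model
#' @param model A `transcript_model`.
#' @return Character scalar: spliced sequence from start codon to CDS end
#'   (terminal stop codon included when the model has one).
#' @export
cds_seq <- function(model) {
  substr(spliced_seq(model), model$cds_start, model$cds_end)
}

#' Open-ended reference coding sequence
#'
#' Spliced sequence from the start codon to the transcript 3' end — the
#' reference counterpart of [apply_splice_outcome()]'s mutant output, so the
#' pair feeds [name_consequence()] with a common 3' landmark.
#'
#' @param model A `transcript_model`.
#' @return Character scalar.
#' @export
coding_seq <- function(model) {
  substring(spliced_seq(model), model$cds_start)
}

# Exon spans on the spliced transcript (transcript orientation), as a
# data.frame with columns start/end; exon_index counts 5'->3' on the
# transcript strand.
transcript_exon_spans <- function(model) {
  lens <- model$exons$end - model$exons$start + 1L
  if (model$strand == "-") lens <- rev(lens)
  ends <- cumsum(lens)
  data.frame(exon = seq_along(lens), start = ends - lens + 1L, end = ends)
}

#' Read a transcript model from JSON
#'
#' Schema: object with fields `gene`, `strand`, `exons` (array of
#' `{start, end}` records or of `[start, end]` pairs), `cds_start`,
#' `cds_end`, `seq`.
#'
#' @param path Path to the JSON file.
#' @inheritParams transcript_model
#' @return A `transcript_model`.
#' @export
read_transcript <- function(path, require_frame = TRUE) {
  obj <- jsonlite::fromJSON(path)
  for (f in c("gene", "strand", "exons", "cds_start", "cds_end", "seq")) {
    if (is.null(obj[[f]])) stop(path, ": missing field '", f, "'", call. = FALSE)
  }
  transcript_model(obj$gene, obj$strand, obj$exons, obj$cds_start,
                   obj$cds_end, obj$seq, require_frame = require_frame)
}

#' Write a transcript model as JSON
#' @param model A `transcript_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcript <- function(model, path) {
  jsonlite::write_json(
    list(gene = model$gene, strand = model$strand, exons = model$exons,
         cds_start = model$cds_start, cds_end = model$cds_end,
         seq = model$seq),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("Transcript model %s (%s strand): %d exons, CDS %d..%d on %d-nt spliced transcript\n",
              x$gene, x$strand, nrow(x$exons), x$cds_start, x$cds_end,
              sum(x$exons$end - x$exons$start + 1L)))
  invisible(x)
}
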