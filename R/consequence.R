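# Protein-level consequences of coding and splice-site mutations.
#
# Splice events are applied to the spliced transcript, the coding sequence is
# re-read from the original start codon, and the reference and mutant
# translations are compared residue by residue. Frameshift names follow the
# fs*N convention in which N is the index of the new stop counting the first
# altered residue as 1 (a stop "after six amino acid residues" is fs*7).

#' Codon index of an exonic cDNA position
#'
#' Maps an HGVS c. position to the 1-based residue index of the codon it
#' falls in: `ceiling(pos / 3)`. Positions carrying an intron offset
#' (c.N+M / c.N-M) have no codon and are rejected.
#'
#' @param cdna_pos Integer position, or a string such as `"664"` or
#'   `"940+1"`.
#' @return Integer residue index.
#' @examples
#' cdna_codon_index(664)   # 222
#' cdna_codon_index(1807)  # 603
#' @export
cdna_codon_index <- function(cdna_pos) {
  p <- parse_cdna_position(cdna_pos)
  if (p$offset != 0L) {
    stop("intronic position c.", p$base, ifelse(p$offset > 0, "+", ""),
         p$offset, " has no codon index", call. = FALSE)
  }
  as.integer(ceiling(p$base / 3))
}

#' Parse an HGVS c. position
#'
#' @param x Integer or string; `"940+1"` parses to base 940, offset +1,
#'   `"1462-2"` to base 1462, offset -2. A leading `"c."` is accepted.
#' @return List with integer elements `base` and `offset`.
#' @export
parse_cdna_position <- function(x) {
  if (is.numeric(x)) {
    if (x < 1) stop("cDNA position must be >= 1", call. = FALSE)
    return(list(base = as.integer(x), offset = 0L))
  }
  s <- sub("^c\\.", "", as.character(x))
  m <- regmatches(s, regexec("^([0-9]+)([+-][0-9]+)?$", s))[[1L]]
  if (!length(m)) stop("cannot parse cDNA position '", x, "'", call. = FALSE)
  base <- as.integer(m[2L])
  if (base < 1L) stop("cDNA position must be >= 1", call. = FALSE)
  offset <- if (m[3L] == "") 0L else as.integer(m[3L])
  list(base = base, offset = offset)
}

#' Describe a splice outcome
#'
#' @param kind `"exon_skip"` or `"insertion"`.
#' @param exon_index For exon skips: the transcript-order exon to remove.
#' @param at For insertions: transcript position the sequence is inserted
#'   after (0 = before the first base).
#' @param seq For insertions: the inserted nucleotide sequence (non-empty).
#' @return An object of class `splice_outcome`.
#' @export
splice_outcome <- function(kind = c("exon_skip", "insertion"),
                           exon_index = NULL, at = NULL, seq = NULL) {
  kind <- match.arg(kind)
  if (kind == "exon_skip") {
    if (is.null(exon_index)) stop("exon_skip needs exon_index", call. = FALSE)
  } else {
    if (is.null(at) || is.null(seq) || !nzchar(seq)) {
      stop("insertion needs a position and a non-empty sequence", call. = FALSE)
    }
  }
  structure(list(kind = kind, exon_index = exon_index,
                 at = if (!is.null(at)) as.integer(at) else NULL,
                 seq = if (!is.null(seq)) toupper(seq) else NULL),
            class = "splice_outcome")
}

#' Apply a splice outcome to a transcript model
#'
#' Removes a whole exon from, or inserts a sequence into, the spliced
#' transcript, then re-reads the coding sequence from the original start
#' codon through the transcript end (open-ended, since a frameshift may run
#' past the reference stop).
#'
#' @param model A `transcript_model`.
#' @param outcome A `splice_outcome`.
#' @return Character scalar: the mutant coding sequence starting at the ATG.
#' @export
apply_splice_outcome <- function(model, outcome) {
  tx <- spliced_seq(model)
  if (outcome$kind == "exon_skip") {
    spans <- transcript_exon_spans(model)
    if (outcome$exon_index < 1L || outcome$exon_index > nrow(spans)) {
      stop("exon index out of range", call. = FALSE)
    }
    span <- spans[spans$exon == outcome$exon_index, ]
    if (span$start <= model$cds_start && model$cds_start <= span$end) {
      stop("skipping the exon containing the start codon is unsupported",
           call. = FALSE)
    }
    mut <- paste0(substr(tx, 1L, span$start - 1L),
                  substring(tx, span$end + 1L))
    new_start <- if (span$end < model$cds_start) {
      model$cds_start - (span$end - span$start + 1L)
    } else {
      model$cds_start
    }
  } else {
    at <- outcome$at
    if (at < 0L || at > nchar(tx)) stop("insertion point outside transcript", call. = FALSE)
    mut <- paste0(substr(tx, 1L, at), outcome$seq, substring(tx, at + 1L))
    new_start <- if (at < model$cds_start) {
      model$cds_start + nchar(outcome$seq)
    } else {
      model$cds_start
    }
  }
  substring(mut, new_start)
}

# Translate a coding sequence up to (not including) the first stop.
# Returns list(protein = chr vector of residues, stop_found = logical).
translate_coding <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(list(protein = character(0), stop_found = FALSE))
  aa <- suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(substr(seq, 1L, 3L * n)),
    if.fuzzy.codon = "X"
  )))
  res <- strsplit(aa, "")[[1L]]
  stop_at <- which(res == "*")
  if (length(stop_at)) {
    list(protein = res[seq_len(stop_at[1L] - 1L)], stop_found = TRUE)
  } else {
    list(protein = res, stop_found = FALSE)
  }
}

#' Name the protein consequence of a mutant coding sequence
#'
#' Translates the reference and mutant coding sequences with the standard
#' nuclear code (each from its ATG to its first stop), finds the first
#' divergent residue and classifies the change: identical protein
#' (`no_change`), substitution (`missense`), truncating stop gain
#' (`nonsense`), shifted reading frame with a downstream stop (`frameshift`,
#' with `stop_offset` counting the first altered residue as 1), or an
#' in-frame net length change (`inframe_deletion`; in-frame insertions are
#' reported under the same category with an `ins` HGVS suffix). A mutant
#' sequence with no stop codon before the sequence end is reported as
#' category `no_stop_found`, not as an error.
#'
#' The two sequences must start at the same ATG and end at the same
#' transcript landmark (both at the reference stop codon for plain CDS
#' comparisons, or both at the transcript 3' end for splice events, as
#' produced by [apply_splice_outcome()] and [coding_seq()]): for a single
#' contiguous edit their length difference is then exactly the net inserted
#' or deleted length, whose remainder mod 3 decides frameshift versus
#' in-frame.
#'
#' @param ref_coding Reference coding sequence from the ATG; must contain a
#'   stop codon (sequence beyond it is treated as untranslated tail).
#' @param mut_coding Mutant coding sequence from the ATG, cut at the same 3'
#'   landmark as `ref_coding`.
#' @return An object of class `protein_consequence` with fields `category`,
#'   `position`, `ref_aa`, `new_aa`, `stop_offset`, `hgvs_p`, `hgvs_p3`.
#' @export
name_consequence <- function(ref_coding, mut_coding) {
  ref <- translate_coding(ref_coding)
  if (!ref$stop_found) {
    stop("reference coding sequence has no stop codon", call. = FALSE)
  }
  mut <- translate_coding(mut_coding)
  p_ref <- ref$protein
  p_mut <- mut$protein

  if (!mut$stop_found) {
    i <- first_divergence(p_ref, p_mut)
    return(consequence_record("no_stop_found", i,
                              ref_aa = if (!is.na(i) && i <= length(p_ref)) p_ref[i] else NA,
                              new_aa = if (!is.na(i) && i <= length(p_mut)) p_mut[i] else NA))
  }
  if (identical(p_ref, p_mut)) {
    return(consequence_record("no_change"))
  }

  i <- first_divergence(p_ref, p_mut)
  d <- nchar(mut_coding) - nchar(ref_coding)
  frameshifted <- (d %% 3L) != 0L

  if (frameshifted) {
    if (length(p_mut) < i) {
      # the first altered codon is already a stop: a stop gain by convention
      return(consequence_record("nonsense", i, ref_aa = p_ref[i], new_aa = "*"))
    }
    return(consequence_record("frameshift", i, ref_aa = p_ref[i],
                              new_aa = p_mut[i],
                              stop_offset = length(p_mut) - i + 2L))
  }
  if (length(p_mut) < i) {
    # truncation with frame preserved (substitution to stop, or an in-frame
    # loss whose junction codon is a stop)
    return(consequence_record("nonsense", i, ref_aa = p_ref[i], new_aa = "*"))
  }
  if (d == 0L) {
    return(consequence_record("missense", i, ref_aa = p_ref[i], new_aa = p_mut[i]))
  }
  consequence_record("inframe_deletion", i, ref_aa = p_ref[i],
                     new_aa = p_mut[i], net = d)
}

first_divergence <- function(a, b) {
  n <- min(length(a), length(b))
  if (n > 0L) {
    diff <- which(a[seq_len(n)] != b[seq_len(n)])
    if (length(diff)) return(diff[1L])
  }
  if (length(a) == length(b)) return(NA_integer_)
  n + 1L
}

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Ter", X = "Xaa")

aa3 <- function(x) ifelse(is.na(x), NA_character_, unname(AA3[x]))

consequence_record <- function(category, position = NA_integer_,
                               ref_aa = NA_character_, new_aa = NA_character_,
                               stop_offset = NA_integer_, net = NA_integer_) {
  hgvs <- switch(
    category,
    no_change = "p.(=)",
    missense = sprintf("p.%s%d%s", ref_aa, position, new_aa),
    nonsense = sprintf("p.%s%dX", ref_aa, position),
    frameshift = sprintf("p.%s%d%sfs*%d", ref_aa, position, new_aa, stop_offset),
    inframe_deletion = sprintf("p.%s%d%s", ref_aa, position,
                               if (!is.na(net) && net > 0) "ins" else "del"),
    no_stop_found = "p.?"
  )
  hgvs3 <- switch(
    category,
    no_change = "p.(=)",
    missense = sprintf("p.%s%d%s", aa3(ref_aa), position, aa3(new_aa)),
    nonsense = sprintf("p.%s%dTer", aa3(ref_aa), position),
    frameshift = sprintf("p.%s%d%sfs*%d", aa3(ref_aa), position, aa3(new_aa),
                         stop_offset),
    inframe_deletion = sprintf("p.%s%d%s", aa3(ref_aa), position,
                               if (!is.na(net) && net > 0) "ins" else "del"),
    no_stop_found = "p.?"
  )
  structure(list(category = category, position = as.integer(position),
                 ref_aa = ref_aa, new_aa = new_aa,
                 stop_offset = as.integer(stop_offset),
                 hgvs_p = hgvs, hgvs_p3 = hgvs3),
            class = "protein_consequence")
}

#' Parse a single-letter HGVS p. name back to its components
#'
#' Round-trips the names emitted by [name_consequence()].
#'
#' @param s String such as `"p.R288Gfs*7"`, `"p.R603X"`, `"p.G222R"`.
#' @return List with `category`, `position`, `ref_aa`, `new_aa`,
#'   `stop_offset`.
#' @export
parse_hgvs_p <- function(s) {
  if (s == "p.(=)") return(list(category = "no_change", position = NA_integer_,
                                ref_aa = NA, new_aa = NA, stop_offset = NA_integer_))
  if (s == "p.?") return(list(category = "no_stop_found", position = NA_integer_,
                              ref_aa = NA, new_aa = NA, stop_offset = NA_integer_))
  m <- regmatches(s, regexec(
    "^p\\.([A-Z\\*])([0-9]+)(?:([A-Z\\*])fs\\*([0-9]+)|X|del|ins|([A-Z]))$",
    s))[[1L]]
  if (!length(m)) stop("cannot parse '", s, "'", call. = FALSE)
  pos <- as.integer(m[3L])
  if (m[4L] != "") {
    list(category = "frameshift", position = pos, ref_aa = m[2L],
         new_aa = m[4L], stop_offset = as.integer(m[5L]))
  } else if (grepl("X$", s)) {
    list(category = "nonsense", position = pos, ref_aa = m[2L], new_aa = "*",
         stop_offset = NA_integer_)
  } else if (grepl("(del|ins)$", s)) {
    list(category = "inframe_deletion", position = pos, ref_aa = m[2L],
         new_aa = NA, stop_offset = NA_integer_)
  } else {
    list(category = "missense", position = pos, ref_aa = m[2L],
         new_aa = m[6L], stop_offset = NA_integer_)
  }
}

#' @export
print.protein_consequence <- function(x, ...) {
  cat(sprintf("Protein consequence: %s (%s)\n", x$hgvs_p, x$category))
  invisible(x)
}

#' Name a coding substitution given a CDS and an HGVS c. change
#'
#' Convenience for substitution naming when the CDS is at hand:
#' applies `c.<pos><ref>><alt>` to the reference CDS and names the result.
#'
#' @param ref_cds Reference CDS (ATG through stop).
#' @param cdna_change String such as `"c.421G>T"`.
#' @return A `protein_consequence`.
#' @export
name_cdna_substitution <- function(ref_cds, cdna_change) {
  m <- regmatches(cdna_change,
                  regexec("^c\\.([0-9]+)([ACGT])>([ACGT])$", cdna_change))[[1L]]
  if (!length(m)) stop("cannot parse cDNA change '", cdna_change, "'", call. = FALSE)
  pos <- as.integer(m[2L])
  if (pos > nchar(ref_cds)) stop("position beyond CDS end", call. = FALSE)
  if (substr(ref_cds, pos, pos) != m[3L]) {
    stop("reference base at c.", pos, " is ", substr(ref_cds, pos, pos),
         ", not ", m[3L], call. = FALSE)
  }
  mut <- ref_cds
  substr(mut, pos, pos) <- m[4L]
  name_consequence(ref_cds, mut)
}
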