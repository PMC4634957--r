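# Random transcript cases for exercising the consequence module, with an
# embedded truth oracle (its own codon table, explicit loops) that stays
# independent of the Biostrings-backed implementation path.

SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
}

ORACLE_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

oracle_translate <- function(seq) {
  protein <- character(0)
  i <- 1L
  stop_found <- FALSE
  while (i + 2L <= nchar(seq)) {
    aa <- unname(ORACLE_CODE[substr(seq, i, i + 2L)])
    if (is.na(aa)) aa <- "X"
    if (aa == "*") {
      stop_found <- TRUE
      break
    }
    protein <- c(protein, aa)
    i <- i + 3L
  }
  list(protein = protein, stop_found = stop_found)
}

# Truth classification for generated cases; written against the same naming
# convention as the consequence module but with its own machinery. Both
# sequences run from the ATG to the transcript 3' end, so their length
# difference is the net indel size of the single splice edit.
oracle_consequence <- function(ref_coding, mut_coding) {
  pr <- oracle_translate(ref_coding)
  pm <- oracle_translate(mut_coding)
  if (!pm$stop_found) {
    return(list(category = "no_stop_found", position = NA_integer_,
                stop_offset = NA_integer_, hgvs_p = "p.?"))
  }
  a <- pr$protein
  b <- pm$protein
  if (length(a) == length(b) && all(a == b)) {
    return(list(category = "no_change", position = NA_integer_,
                stop_offset = NA_integer_, hgvs_p = "p.(=)"))
  }
  i <- 1L
  while (i <= length(a) && i <= length(b) && a[i] == b[i]) i <- i + 1L
  d <- nchar(mut_coding) - nchar(ref_coding)
  if (d %% 3L != 0L) {
    if (length(b) < i) {
      return(list(category = "nonsense", position = i,
                  stop_offset = NA_integer_,
                  hgvs_p = sprintf("p.%s%dX", a[i], i)))
    }
    off <- length(b) - i + 2L
    return(list(category = "frameshift", position = i, stop_offset = off,
                hgvs_p = sprintf("p.%s%d%sfs*%d", a[i], i, b[i], off)))
  }
  if (length(b) < i) {
    return(list(category = "nonsense", position = i, stop_offset = NA_integer_,
                hgvs_p = sprintf("p.%s%dX", a[i], i)))
  }
  if (d == 0L) {
    return(list(category = "missense", position = i, stop_offset = NA_integer_,
                hgvs_p = sprintf("p.%s%d%s", a[i], i, b[i])))
  }
  list(category = "inframe_deletion", position = i, stop_offset = NA_integer_,
       hgvs_p = sprintf("p.%s%d%s", a[i], i, if (d > 0) "ins" else "del"))
}

#' Generate a random transcript splice case with truth
#'
#' Builds a plus-strand multi-exon transcript (5' UTR and ATG in the first
#' exon, internal exons fully coding, stop codon and 3' UTR in the last
#' exon), applies either an internal exon skip or an insertion at an
#' exon-exon junction (emulating intron retention), and derives the truth
#' protein consequence with the embedded codon-by-codon oracle.
#'
#' @param seed Integer seed.
#' @param exon_count Number of exons (>= 4).
#' @param event `"exon_skip"` or `"insertion"` (default: random).
#' @param skip_exon Internal exon to skip (default: random internal exon).
#' @param insert_len Inserted length for insertion events (default: random
#'   in 1..30; 23 reproduces the motivating intron-retention case).
#' @return List with `model` ([transcript_model()]), `outcome`
#'   ([splice_outcome()]), `ref_cds` (ATG through stop), `ref_coding` and
#'   `mut_coding` (open-ended reference and oracle-derived mutant coding
#'   sequences) and `truth` (oracle consequence: `category`, `position`,
#'   `stop_offset`, `hgvs_p`).
#' @export
generate_transcript_case <- function(seed, exon_count = 8L,
                                     event = NULL, skip_exon = NULL,
                                     insert_len = NULL) {
  stopifnot(exon_count >= 4L)
  withr::with_seed(seed, {
    n_codons <- sample(80:300, 1L)
    cds <- paste0(
      "ATG",
      paste(sample(SENSE_CODONS, n_codons - 1L, replace = TRUE), collapse = ""),
      sample(c("TAA", "TAG", "TGA"), 1L)
    )
    u5 <- sample(10:60, 1L)
    u3 <- sample(10:60, 1L)
    bases <- c("A", "C", "G", "T")
    tx <- paste0(paste(sample(bases, u5, replace = TRUE), collapse = ""),
                 cds,
                 paste(sample(bases, u3, replace = TRUE), collapse = ""))
    cds_start <- u5 + 1L
    cds_end <- u5 + nchar(cds)

    # Breakpoints inside the CDS so internal exons are fully coding and the
    # last exon keeps >= 2 sense codons plus the stop.
    lo <- cds_start + 3L
    hi <- cds_end - 9L
    repeat {
      bp <- sort(sample(lo:hi, exon_count - 1L))
      if (all(diff(c(lo - 1L, bp)) >= 5L)) break
    }
    starts_t <- c(1L, bp + 1L)
    ends_t <- c(bp, nchar(tx))
    pieces <- substring(tx, starts_t, ends_t)

    intron_len <- sample(50:200, exon_count - 1L, replace = TRUE)
    introns <- vapply(intron_len, function(k)
      paste(sample(bases, k, replace = TRUE), collapse = ""), "")
    gseq <- pieces[1L]
    gstart <- integer(exon_count)
    gend <- integer(exon_count)
    gstart[1L] <- 1L
    gend[1L] <- nchar(pieces[1L])
    for (k in 2:exon_count) {
      gseq <- paste0(gseq, introns[k - 1L], pieces[k])
      gstart[k] <- gend[k - 1L] + intron_len[k - 1L] + 1L
      gend[k] <- gstart[k] + nchar(pieces[k]) - 1L
    }
    model <- transcript_model("SYNTX", "+",
                              data.frame(start = gstart, end = gend),
                              cds_start, cds_end, gseq)

    if (is.null(event)) event <- sample(c("exon_skip", "insertion"), 1L)
    if (event == "exon_skip") {
      k <- skip_exon %||% sample(2:(exon_count - 1L), 1L)
      if (k < 2L || k > exon_count - 1L) {
        stop("skip_exon must be an internal exon", call. = FALSE)
      }
      outcome <- splice_outcome("exon_skip", exon_index = k)
      mut_tx <- paste(pieces[-k], collapse = "")
    } else {
      len <- insert_len %||% sample(1:30, 1L)
      if (len < 1L) stop("insert_len must be >= 1", call. = FALSE)
      j <- sample(seq_len(exon_count - 1L), 1L)  # junction after exon j
      ins <- paste(sample(bases, len, replace = TRUE), collapse = "")
      outcome <- splice_outcome("insertion", at = ends_t[j], seq = ins)
      mut_tx <- paste0(substr(tx, 1L, ends_t[j]), ins,
                       substring(tx, ends_t[j] + 1L))
    }
    mut_coding <- substring(mut_tx, cds_start)
    ref_coding <- substring(tx, cds_start)
    list(model = model, outcome = outcome, ref_cds = cds,
         ref_coding = ref_coding, mut_coding = mut_coding,
         truth = oracle_consequence(ref_coding, mut_coding))
  })
}
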