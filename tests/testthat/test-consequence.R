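test_that("cdna codon arithmetic maps nucleotide positions to residues", {
  expect_equal(cdna_codon_index(1), 1L)
  expect_equal(cdna_codon_index(3), 1L)
  expect_equal(cdna_codon_index(4), 2L)
  expect_equal(cdna_codon_index("664"), 222L)
  expect_equal(cdna_codon_index("c.1807"), 603L)
  expect_error(cdna_codon_index("940+1"), "no codon index")
  expect_error(cdna_codon_index(0), ">= 1")
})

test_that("cdna positions parse with intron offsets", {
  expect_equal(parse_cdna_position("940+1"), list(base = 940L, offset = 1L))
  expect_equal(parse_cdna_position("c.1462-2"), list(base = 1462L, offset = -2L))
  expect_equal(parse_cdna_position(664), list(base = 664L, offset = 0L))
  expect_error(parse_cdna_position("abc"), "cannot parse")
})

test_that("splice outcomes do the expected length bookkeeping", {
  cs <- generate_transcript_case(31, exon_count = 6, event = "exon_skip",
                                 skip_exon = 3)
  spans <- exomeAR:::transcript_exon_spans(cs$model)
  skip_len <- spans$end[3] - spans$start[3] + 1
  ref_coding_len <- nchar(spliced_seq(cs$model)) - cs$model$cds_start + 1
  mut <- apply_splice_outcome(cs$model, cs$outcome)
  expect_equal(nchar(mut), ref_coding_len - skip_len)

  ins <- generate_transcript_case(32, exon_count = 6, event = "insertion",
                                  insert_len = 23)
  mut_ins <- apply_splice_outcome(ins$model, ins$outcome)
  expect_equal(nchar(mut_ins),
               nchar(spliced_seq(ins$model)) - ins$model$cds_start + 1 + 23)
  # 23 is not a multiple of 3: the frame downstream of the retention shifts
  # (a stop falling on the first altered codon would be the stop-gain case)
  expect_true(ins$truth$category %in% c("frameshift", "nonsense"))

  expect_error(apply_splice_outcome(cs$model,
                                    splice_outcome("exon_skip", exon_index = 1)),
               "start codon")
  expect_error(apply_splice_outcome(cs$model,
                                    splice_outcome("exon_skip", exon_index = 99)),
               "out of range")
})

test_that("substitutions are named from the codon change", {
  # toy CDS with GAA (Glu) at codon 141: c.421G>T creates a stop (p.E141X)
  cds <- paste0("ATG", strrep("GAA", 139), "GAATGGTTC", "TAA")
  expect_equal(substr(cds, 421, 423), "GAA")
  cons <- name_cdna_substitution(cds, "c.421G>T")
  expect_equal(cons$category, "nonsense")
  expect_equal(cons$position, 141L)
  expect_equal(cons$hgvs_p, "p.E141X")
  expect_equal(cons$hgvs_p3, "p.Glu141Ter")
  # missense at the same codon
  mis <- name_cdna_substitution(cds, "c.422A>T")
  expect_equal(mis$category, "missense")
  expect_equal(mis$hgvs_p, "p.E141V")
  expect_error(name_cdna_substitution(cds, "c.421A>T"), "reference base")
})

test_that("a one-base deletion frameshifts with the brute-force translation", {
  withr::with_seed(99, {
    codons <- sample(exomeAR:::SENSE_CODONS, 11, replace = TRUE)
    cds <- paste0("ATG", paste(codons, collapse = ""), "TAA")
  })
  # delete the first base of codon 5 (nucleotide 13)
  mut <- paste0(substr(cds, 1, 12), substring(cds, 14))
  cons <- name_consequence(cds, mut)
  truth <- exomeAR:::oracle_consequence(cds, mut)
  expect_equal(cons$category, truth$category)
  expect_equal(cons$hgvs_p, truth$hgvs_p)
  if (cons$category == "frameshift") {
    expect_gte(cons$stop_offset, 2L)
    expect_equal(cons$position, truth$position)
  }
})

test_that("identical sequences and degenerate cases are classified", {
  cds <- "ATGGCTGCTTAA"
  expect_equal(name_consequence(cds, cds)$category, "no_change")
  expect_equal(name_consequence(cds, "ATGGCTGCTGCA")$category, "no_stop_found")
  expect_error(name_consequence("ATGGCTGCT", cds), "no stop codon")
})

test_that("hgvs names round-trip to their components", {
  cases <- list(
    list(hgvs = "p.R288Gfs*7", category = "frameshift", position = 288L,
         stop_offset = 7L),
    list(hgvs = "p.I488Lfs*11", category = "frameshift", position = 488L,
         stop_offset = 11L),
    list(hgvs = "p.R603X", category = "nonsense", position = 603L),
    list(hgvs = "p.G222R", category = "missense", position = 222L),
    list(hgvs = "p.A17del", category = "inframe_deletion", position = 17L),
    list(hgvs = "p.(=)", category = "no_change")
  )
  for (cs in cases) {
    parsed <- parse_hgvs_p(cs$hgvs)
    expect_equal(parsed$category, cs$category, label = cs$hgvs)
    if (!is.null(cs$position)) expect_equal(parsed$position, cs$position)
    if (!is.null(cs$stop_offset)) expect_equal(parsed$stop_offset, cs$stop_offset)
  }
})

test_that("generated splice cases agree with the embedded truth oracle", {
  for (seed in 1:150) {
    cs <- generate_transcript_case(seed)
    mut <- apply_splice_outcome(cs$model, cs$outcome)
    expect_identical(mut, cs$mut_coding,
                     label = sprintf("mutant sequence, seed %d", seed))
    cons <- name_consequence(cs$ref_coding, mut)
    expect_equal(cons$category, cs$truth$category,
                 label = sprintf("category, seed %d", seed))
    expect_equal(cons$hgvs_p, cs$truth$hgvs_p,
                 label = sprintf("hgvs, seed %d", seed))
  }
})

test_that("frame arithmetic follows the skipped length mod 3", {
  hits <- 0
  for (seed in 200:320) {
    cs <- generate_transcript_case(seed, event = "exon_skip")
    spans <- exomeAR:::transcript_exon_spans(cs$model)
    k <- cs$outcome$exon_index
    skip_len <- spans$end[k] - spans$start[k] + 1
    cons <- name_consequence(cs$ref_coding,
                             apply_splice_outcome(cs$model, cs$outcome))
    if (skip_len %% 3 != 0) {
      # shifted frame: frameshift, or an immediate stop at the junction codon
      expect_true(cons$category %in% c("frameshift", "nonsense", "no_stop_found"),
                  label = sprintf("seed %d", seed))
      if (cons$category == "frameshift") hits <- hits + 1
    } else {
      expect_true(cons$category %in% c("inframe_deletion", "nonsense"),
                  label = sprintf("seed %d", seed))
    }
  }
  expect_gt(hits, 20)  # the dichotomy is actually exercised
})

test_that("translation agrees with the independent codon table", {
  withr::with_seed(42, {
    for (i in 1:20) {
      n <- sample(5:60, 1)
      cds <- paste0("ATG",
                    paste(sample(exomeAR:::SENSE_CODONS, n, replace = TRUE),
                          collapse = ""),
                    "TGA")
      impl <- exomeAR:::translate_coding(cds)
      orac <- exomeAR:::oracle_translate(cds)
      expect_identical(impl$protein, orac$protein)
      expect_identical(impl$stop_found, orac$stop_found)
    }
  })
})
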