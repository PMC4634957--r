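make_variants <- function(genes, func = "missense") {
  n <- length(genes)
  data.frame(chrom = "1", pos = seq_len(n) * 10, ref = "A", alt = "G",
             gene = genes, func_class = rep_len(func, n),
             known_id = NA_character_, cdna_pos = NA_character_,
             key = variant_key("1", seq_len(n) * 10, "A", "G"),
             stringsAsFactors = FALSE)
}

test_that("functional filter keeps exactly the non-synonymous and splice classes", {
  v <- make_variants(paste0("G", 1:5),
                     func = c("missense", "synonymous", "splice_site",
                              "other", "nonsense"))
  out <- filter_functional(v)
  expect_equal(out$gene, c("G1", "G3", "G5"))
  expect_equal(out$key, v$key[c(1, 3, 5)])  # order preserved
  expect_equal(nrow(filter_functional(v[0, ])), 0L)
  v$func_class[2] <- NA
  expect_error(filter_functional(v), "func_class")
})

test_that("known-variant exclusion matches on the full key, not position", {
  v <- make_variants(c("G1", "G2"))
  v$chrom <- "3"; v$pos <- c(133674014L, 133674014L)
  v$ref <- "G"; v$alt <- c("T", "A")
  v$key <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  # catalogued variant at the same position but a different change
  known <- data.frame(chrom = "3", pos = 133674014L, ref = "G", alt = "A",
                      id = "rs148547180", stringsAsFactors = FALSE)
  known$key <- variant_key(known$chrom, known$pos, known$ref, known$alt)
  out <- filter_known(v, known)
  expect_equal(out$key, "3:133674014:G:T")  # G>T retained, G>A removed
})

test_that("filter counts on synthetic cohorts equal the generator truth", {
  for (seed in c(4, 5)) {
    co <- generate_cohort(sim_config(seed = seed))
    fun <- filter_functional(co$variants)
    expect_equal(nrow(fun), co$truth$n_functional)
    surv <- filter_known(fun, co$known)
    expect_equal(nrow(surv), co$truth$n_functional_unknown)
  }
})

test_that("homozygous candidate scan equals the exhaustive oracle", {
  for (seed in 1:10) {
    sc <- random_small_cohort(seed, n_var = 20, n_genes = 5)
    for (id in colnames(sc$genotypes)) {
      got <- homozygous_candidate_genes(sc$variants, sc$genotypes, id)
      expect_equal(sort(unique(got$gene)),
                   oracle_hom_genes(sc$variants, sc$genotypes, id))
      # every reported variant is truly homozygous
      if (nrow(got)) {
        expect_true(all(sc$genotypes[got$variant, id] == 2L, na.rm = FALSE))
      }
    }
  }
  expect_error(homozygous_candidate_genes(make_variants("G1"),
                                          matrix(0L, 1, 1,
                                                 dimnames = list("k", "X")),
                                          "nobody"),
               "unknown individual")
})

test_that("an all-heterozygous individual yields no homozygous candidates", {
  v <- make_variants(c("G1", "G1", "G2"))
  g <- matrix(1L, nrow = 3, dimnames = list(v$key, "P1"))
  expect_equal(nrow(homozygous_candidate_genes(v, g, "P1")), 0L)
})

test_that("compound-het detection uses parental origin when available", {
  v <- make_variants(c("G1", "G1"))
  ped <- data.frame(family = "F", id = c("FA", "MO", "CH"),
                    father = c(NA, NA, "FA"), mother = c(NA, NA, "MO"),
                    sex = c("M", "F", "F"),
                    affected = c("no", "no", "yes"), stringsAsFactors = FALSE)
  mk <- function(fa, mo) {
    matrix(c(fa, mo, c(1L, 1L)), nrow = 2,
           dimnames = list(v$key, c("FA", "MO", "CH")))
  }
  # one variant from each parent: trans, qualifies
  trans <- compound_het_candidate_genes(v, mk(c(1L, 0L), c(0L, 1L)), "CH", ped)
  expect_equal(trans$gene, "G1")
  # both variants carried by one parent only: cis-forced, disqualified
  cis <- compound_het_candidate_genes(v, mk(c(1L, 1L), c(0L, 0L)), "CH", ped)
  expect_equal(nrow(cis), 0L)
  # without pedigree data a trans configuration is assumed
  no_ped <- compound_het_candidate_genes(v, mk(c(1L, 1L), c(0L, 0L)), "CH", NULL)
  expect_equal(no_ped$gene, "G1")
  # a missing parent never disqualifies (could have transmitted the allele)
  half <- compound_het_candidate_genes(v, mk(c(1L, 1L), c(NA, NA)), "CH", ped)
  expect_equal(half$gene, "G1")
  # but a parent genotyped reference at both variants forbids trans
  ruled_out <- compound_het_candidate_genes(v, mk(c(1L, NA), c(0L, 0L)), "CH", ped)
  expect_equal(nrow(ruled_out), 0L)
})

test_that("compound-het scan equals the phase-enumeration oracle on random matrices", {
  for (seed in 1:15) {
    sc <- random_small_cohort(seed, n_var = 18, n_genes = 4)
    for (id in c("CH", "S1", "U1")) {
      got <- compound_het_candidate_genes(sc$variants, sc$genotypes, id, sc$ped)
      expect_equal(sort(unique(got$gene)),
                   oracle_comp_het_genes(sc$variants, sc$genotypes, id, sc$ped),
                   label = sprintf("seed %d individual %s", seed, id))
    }
  }
})

test_that("shared candidate sets intersect at the gene level", {
  expect_equal(shared_candidate_genes(list(c("A", "B"), c("B", "C"))), "B")
  expect_equal(shared_candidate_genes(list(c("A", "B"), c("C"))), character(0))
  expect_equal(shared_candidate_genes(list(c("B", "A"))), c("A", "B"))
  expect_error(shared_candidate_genes(list()), "at least one")
})

test_that("unaffected exclusion removes biallelic genes but spares carriers", {
  v <- make_variants(c("G1", "G2", "G2"))
  ids <- c("AFF", "UN")
  ped <- data.frame(family = "F", id = ids, father = NA_character_,
                    mother = NA_character_, sex = "F",
                    affected = c("yes", "no"), stringsAsFactors = FALSE)
  g <- matrix(c(2L, 2L,   # G1: affected hom, unaffected hom -> excluded
                2L, 1L,   # G2 var1: unaffected merely het -> spared
                0L, 0L),
              nrow = 3, byrow = TRUE, dimnames = list(v$key, ids))
  out <- exclude_by_unaffected_and_extend(c("G1", "G2"), v, g, ped)
  expect_equal(out, "G2")
  # unaffected trans compound-het also excludes
  g2 <- matrix(c(2L, 0L, 2L, 1L, 0L, 1L), nrow = 3, byrow = TRUE,
               dimnames = list(v$key, ids))
  expect_equal(exclude_by_unaffected_and_extend(c("G1", "G2"), v, g2, ped),
               "G1")
  # no unaffecteds and no additional affecteds: identity
  expect_equal(exclude_by_unaffected_and_extend(c("G1", "G2"), v, g, ped,
                                                unaffected_ids = character(0)),
               c("G1", "G2"))
})

test_that("extension requires an AR pattern in every additional affected", {
  v <- make_variants(c("G1", "G2"))
  ids <- c("A1", "A2")
  ped <- data.frame(family = "F", id = ids, father = NA_character_,
                    mother = NA_character_, sex = "F",
                    affected = c("yes", "yes"), stringsAsFactors = FALSE)
  g <- matrix(c(2L, 2L,  # G1 biallelic in both
                2L, 1L), # G2 only het in A2
              nrow = 2, byrow = TRUE, dimnames = list(v$key, ids))
  out <- exclude_by_unaffected_and_extend(c("G1", "G2"), v, g, ped,
                                          additional_affecteds = ids)
  expect_equal(out, "G1")
})

test_that("strict missingness disqualifies genes untestable in unaffecteds", {
  v <- make_variants("G1")
  ids <- c("AFF", "UN")
  ped <- data.frame(family = "F", id = ids, father = NA_character_,
                    mother = NA_character_, sex = "F",
                    affected = c("yes", "no"), stringsAsFactors = FALSE)
  g <- matrix(c(2L, NA), nrow = 1, dimnames = list(v$key, ids))
  expect_equal(exclude_by_unaffected_and_extend("G1", v, g, ped), "G1")
  expect_equal(exclude_by_unaffected_and_extend("G1", v, g, ped,
                                                strict_missing = TRUE),
               character(0))
})

test_that("segregation check accepts the classic recessive family pattern", {
  co <- generate_cohort(sim_config(seed = 6))
  cv1 <- co$truth$causal_variants[1]
  seg <- check_segregation(co$ped, co$genotypes, cv1, family = "A")
  expect_true(seg$consistent)
  expect_equal(nrow(seg$violations), 0L)
  # parents, sibs and children are all heterozygous carriers
  hets <- c("A-IV-1", "A-IV-2", "A-V-3", "A-VI-1", "A-VI-2")
  expect_true(all(seg$carrier_state[hets] == 1L))
  expect_equal(unname(seg$carrier_state["A-V-2"]), 2L)

  # compound-het family: both sibs biallelic across the two alleles
  segD <- check_segregation(co$ped, co$genotypes,
                            co$truth$causal_variants[3:4], family = "D")
  expect_true(segD$consistent)
})

test_that("segregation flags exactly the perturbed individuals", {
  co <- generate_cohort(sim_config(seed = 10))
  cv1 <- co$truth$causal_variants[1]
  g <- co$genotypes
  # unaffected sib made homozygous -> violation
  g[cv1, "A-V-3"] <- 2L
  seg <- check_segregation(co$ped, g, cv1, family = "A")
  expect_false(seg$consistent)
  expect_equal(seg$violations$individual, "A-V-3")
  expect_equal(seg$violations$rule, "unaffected_biallelic")
  # proband demoted to het -> affected violation
  g <- co$genotypes
  g[cv1, "A-V-2"] <- 1L
  seg <- check_segregation(co$ped, g, cv1, family = "A")
  expect_setequal(seg$violations$individual, "A-V-2")
  # parent of an affected losing the allele -> carrier violation
  g <- co$genotypes
  g[cv1, "A-IV-1"] <- 0L
  seg <- check_segregation(co$ped, g, cv1, family = "A")
  expect_true("parent_of_affected_not_carrier" %in% seg$violations$rule)
  expect_true("A-IV-1" %in% seg$violations$individual)
  # missing genotype is untestable, not a violation
  g <- co$genotypes
  g[cv1, "A-VI-1"] <- NA
  seg <- check_segregation(co$ped, g, cv1, family = "A")
  expect_true(seg$consistent)
  expect_equal(seg$untestable, "A-VI-1")
})

test_that("the staged cascade is monotone and order-invariant", {
  co <- generate_cohort(sim_config(seed = 14))
  run <- function(variants, genotypes) {
    prioritize_cohort(variants, genotypes, co$ped, co$known,
                      required_individuals = c("A-V-2", "B-IV-3", "C-IV-3"),
                      additional_affecteds = c("D-II-4", "D-II-5"),
                      unaffected_ids = "A-V-3")
  }
  rep1 <- run(co$variants, co$genotypes)
  a <- rep1$audit
  expect_lte(a[["functional_variants"]], a[["input_variants"]])
  expect_lte(a[["after_known_exclusion"]], a[["functional_variants"]])
  expect_lte(a[["final_genes"]], a[["shared_genes"]])
  expect_true(all(rep1$final_genes %in% rep1$shared_genes))
  for (id in names(rep1$per_individual)) {
    expect_true(all(rep1$shared_genes %in% rep1$per_individual[[id]]))
  }
  # permuting the variant rows changes nothing
  perm <- withr::with_seed(1, sample(nrow(co$variants)))
  rep2 <- run(co$variants[perm, ], co$genotypes[perm, ])
  expect_identical(rep2$final_genes, rep1$final_genes)
  expect_identical(rep2$shared_genes, rep1$shared_genes)
  expect_identical(rep2$audit, rep1$audit)
})

test_that("the default study-design cohort recovers exactly the planted gene", {
  for (seed in 1:5) {
    co <- generate_cohort(sim_config(seed = seed))
    rep <- prioritize_cohort(co$variants, co$genotypes, co$ped, co$known,
                             required_individuals = co$truth$roles$consang_affected,
                             additional_affecteds = co$truth$roles$sib_pair,
                             unaffected_ids = co$truth$roles$unaffected_exome)
    expect_equal(length(rep$shared_genes),
                 1L + length(co$truth$distractor_genes))
    expect_identical(rep$final_genes, co$truth$causal_gene)
    # sensitivity control: cataloguing the causal alleles empties the result
    spiked <- c(co$known$key, co$truth$causal_variants)
    rep0 <- prioritize_cohort(co$variants, co$genotypes, co$ped, spiked,
                              required_individuals = co$truth$roles$consang_affected,
                              additional_affecteds = co$truth$roles$sib_pair,
                              unaffected_ids = co$truth$roles$unaffected_exome)
    expect_length(rep0$final_genes, 0L)
  }
})
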