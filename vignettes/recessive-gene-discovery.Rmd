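---
title: "Mapping a recessive disease gene from a handful of exomes"
author: "exomeAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recessive disease gene from a handful of exomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exomeAR)
```

## The inference model

`exomeAR` targets the situation in which a rare, clearly familial disorder
has been exome-sequenced in very few individuals and the disease model is
autosomal recessive. The causal genotype is then *biallelic*: homozygous
for one deleterious allele, or compound-heterozygous for two deleterious
alleles on different parental haplotypes (*trans*). Three observations make
a handful of exomes sufficient:

* **Consanguinity concentrates homozygosity.** An affected child of a
  degree-\(d\) consanguineous union is homozygous-by-descent over a
  substantial fraction of the genome; the causal variant of a recessive
  disorder is expected inside such a segment. Candidate genes for such a
  patient are those with at least one homozygous functional variant.
* **Affected sibs share the causal genotype.** A sib pair born to
  unrelated parents is expected to be compound-heterozygous for the same
  two alleles, one inherited from each parent.
* **Unaffected relatives bound the model.** No unaffected individual may
  carry a qualifying biallelic genotype in the causal gene, and carriers
  among parents are obligatory.

The staged cascade (functional filter, known-variant exclusion,
per-individual candidacy, gene-level intersection, unaffected exclusion and
extension to further affecteds) mirrors this logic; `prioritize_cohort()`
runs it with an audit trail of per-stage counts, which are non-increasing
by construction.

Two modelling choices deserve emphasis:

* **Gene-level intersection.** Different families may segregate different
  alleles of the same gene, so the intersection across families is taken
  over gene symbols, not variant keys.
* **Trans test for compound heterozygosity.** With both parents genotyped,
  a heterozygous pair qualifies only if the two variants can be assigned to
  different parental origins; a pair carried by one parent and absent from
  the other is *cis*-forced and disqualified. Without parental data the
  trans configuration is assumed (the permissive choice: phase cannot be
  resolved from a single unrelated genome). A parent with a missing call
  never rules an origin out.

**Missingness policy.** A missing genotype never *qualifies* an individual
for a candidate pattern and never *disqualifies* a gene during unaffected
exclusion — conservative in both directions, since a missing call carries
no evidence. `strict_missing = TRUE` switches the unaffected rule to treat
an untestable gene as disqualified, for analysts who prefer that only
positively cleared genes survive.

`hom_only_for_consanguineous` (default `TRUE`) restricts the intersected
stage to homozygous patterns, which is what a shared-homozygosity design
for consanguineous families prescribes; setting it `FALSE` also admits
compound-het patterns at that stage.

## The synthetic cohort and what it does (not) emulate

`generate_cohort()` reproduces the study conditions the pipeline assumes,
with a truth file, so that every downstream stage has an exact expected
answer. The fixed family designs are: three affected offspring of
consanguineous unions (families A, B, C; the B and C probands share one
causal allele, the A proband carries a second), an affected sib pair
compound-heterozygous for two further alleles (family D, one allele per
parent, hence trans by construction), and one unaffected sib in family A
carrying a single causal allele. Nine distractor genes are engineered to
pass the shared-homozygosity stage — a functional, non-catalogued variant
homozygous in all three consanguineous affecteds — and to fail later:
every third distractor is also homozygous in the unaffected (removed by the
unaffected rule), the rest carry nothing in the sib pair (removed by the
extension rule).

Defaults, chosen once as realistic study conditions:

| parameter | default | rationale |
|---|---|---|
| `n_genes` | 150 | enough genes for the filters to have work to do while keeping tests fast; scale is configurable, not calibrated, since genome-wide variant counts are not desk-reproducible |
| `mean_variants_per_gene` | 3 (Poisson, plus 1) | small-gene exome granularity |
| `background_alt_freq` | 0.10 | a common-polymorphism allele frequency |
| `known_fraction` | 0.95 | most common polymorphisms are catalogued; the remainder is what the known-variant filter cannot remove |
| class mix | missense .25, nonsense .03, splice_site .07, synonymous .45, other .20 | a typical exome functional-class spectrum |
| `inbreeding_f` | 1/16 | second-cousin scale; degree-\(d\) unions map to \(F = (1/2)^{d+1}\) |

Background genotypes are Hardy–Weinberg draws with homozygote probability
\(q^2 + Fq(1-q)\) for offspring of consanguineous unions and \(q^2\)
otherwise. What the generator deliberately does **not** emulate: linkage
disequilibrium and runs of homozygosity (consanguinity is a single
coefficient, not IBD segments); Mendelian transmission of *background*
variants (draws are independent across pedigree members; only planted
causal and distractor genotypes are transmission-consistent); read-level
error; and background variation inside the causal gene itself, which
carries exactly its planted alleles so the truth file stays exact. Passing
tests therefore demonstrate the correctness of the inference logic under
the recessive model, not robustness to artefacts real exome data would add
(population stratification, call errors, incidental rare benign variants
in the causal gene).

All randomness flows from one seeded generator and family designs are
produced in fixed order, so identical configurations give byte-identical
output files.

The biomarker module draws per-individual values from two normal
distributions on the measurement scale, with group SDs reconstructed from
the configured summaries as \(sd = sem\sqrt{n}\) (no distribution is
implied by a mean ± SEM summary; normality is the conventional choice).

## Consequence naming conventions

Splice events are applied to the spliced transcript and the coding
sequence is re-read from the original ATG. Classification compares the
reference and mutant coding sequences *cut at a common 3' landmark* (both
at the transcript end for splice events — `coding_seq()` and
`apply_splice_outcome()` produce this pair — or both at the reference stop
for plain CDS substitutions). For the single contiguous edits in scope,
the length difference of that pair is exactly the net inserted or deleted
length, and its remainder mod 3 decides frameshift versus in-frame. The
net change cannot be inferred from the translated proteins (their coding
lengths are always multiples of three), which is why the nucleotide-level
convention exists.

* `fs*N` counts the new stop with the first altered residue as 1: a
  premature stop "after six amino acid residues" is `fs*7`.
* A shifted frame whose *first* altered codon is already a stop is reported
  as `nonsense` (`p.<Ref><pos>X`), the standard nomenclature convention.
* Any in-frame net length change is reported under the single in-frame
  category, with `del`/`ins` HGVS suffixes distinguishing direction.
* A mutant sequence reaching the transcript end without a stop codon is
  the distinct category `no_stop_found`, not an error.
* Both single-letter (canonical in reports) and three-letter names are
  emitted. Only the standard nuclear code is supported; selenocysteine and
  non-ATG starts are not.
* Intron retention is modelled as a *provided* insertion (position and
  sequence); predicting cryptic splice sites from motifs is out of scope.

The generator's transcript cases embed a truth oracle with its own codon
table and explicit loops, independent of the Biostrings-backed
implementation path; the test suite checks equivalence on 1,000 random
cases (insertions and skips, both frame classes).

## Statistical conventions

* **Fisher's exact test** sums hypergeometric probabilities of all tables
  (fixed margins) no more probable than the observed one, with the
  customary \(1 + 10^{-7}\) slack on the comparison; a doubling rule is
  available by flag. The odds ratio is the sample cross-product, with
  Haldane's +0.5 correction (flagged) when a cell is zero. The test suite
  checks exact agreement with explicit enumeration on every 2×2 table with
  total ≤ 30.
* **Welch's t from summaries** is the default two-group comparison because
  the biomarker data arrive as mean ± SEM with visibly unequal SEMs;
  \(t = (m_1-m_2)/\sqrt{sem_1^2+sem_2^2}\) with Welch–Satterthwaite
  degrees of freedom on the squared SEMs. A pooled-variance option
  reproduces the classical Student form. P-values are validated against
  numerical integration of the t density to 1e-10 relative error.
  Summary-based recomputation is necessarily approximate when the original
  analysis used raw per-patient values that are not published.
* **Percentages** are rounded half-up to one decimal (base `round()`'s
  round-half-even would print 27.75 as 27.7; clinical tables round up).
* **Deterministic ordering.** Genes sort lexicographically, variants by
  (chrom, pos, ref, alt), so reports are order-invariant in their inputs.

## Degenerate inputs and numerical edges

Multi-allelic VCF records are split with genotype indices remapped;
half-missing calls (`./1`) are treated as missing; phase separators are
accepted and ignored (phase is reconstructed from the pedigree, not the
VCF). Duplicate variant keys, malformed genotypes and unknown functional
classes are rejected with the offending line number. Pedigrees are checked
for unresolved parents and ancestry cycles. Transcript models must begin
with ATG (error) and have CDS length a multiple of three (error by
default, warning with `require_frame = FALSE`). Skipping the exon that
contains the start codon is an unsupported-case error. A zero cell in a
2×2 table triggers the flagged Haldane correction; a zero margin is an
error.

## Problem sizes in the test suite

The suite exercises: 20 simulated cohorts (about 600 variants × 17
individuals each) for end-to-end recovery plus a known-list spike-in
control; 1,000 random transcript cases for consequence-oracle equivalence;
all 44,515 non-degenerate 2×2 tables with total ≤ 30 for the exact test;
1,000-seed Monte-Carlo runs for biomarker power and type-I behaviour; and
brute-force oracle scans on small random matrices for the candidate-gene
operations. These sizes were chosen to give the property-based checks real
coverage while keeping a full run inside a few minutes.

## Known limitations

* Dominant and X-linked models, runs-of-homozygosity mapping, and
  population-frequency resources beyond the supplied known list are out of
  scope.
* Gene assignment and functional class are taken from the input
  annotations (`GENE`/`FUNC`); the package does not annotate variants
  against transcripts.
* The trans test uses parental genotypes only; phasing from larger
  pedigrees or read backing is not attempted.
* Reproducing the published protein consequences of the real splice
  mutations (frameshifts from a whole-exon skip and a 23-bp intron
  retention) requires the real transcript sequence, which is not bundled;
  the synthetic transcript cases validate the machinery instead.
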