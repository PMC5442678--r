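---
title: "Methods: trio de novo filtration, burden testing and structural variant consensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio de novo filtration, burden testing and structural variant consensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denovoscreen)
```

# Scope and model

`denovoscreen` implements the computational core of a whole-genome-sequencing
trio study of rare disease (the motivating setting is idiopathic intellectual
disability): a child with a suspected de novo cause and two unaffected
parents, analyzed alongside a large affected cohort and a population control
cohort. Four analysis arms are covered:

1. **De novo small-variant filtration.** A child variant is called de novo
   when its alternate allele is absent from both parental genotypes at the
   same site. Candidates then pass a staged cascade: mapping quality
   strictly above 30 and depth between 10 and 100 inclusive
   (high confidence); maximum allele frequency across all annotation
   sources at or below 1% (rare); protein-altering consequence
   (functional); and at least one damaging prediction together with a
   conservation score at or above a floor (damaging). Four Mendelian
   screens (de novo heterozygous, homozygous recessive, compound
   heterozygous, hemizygous) classify the rare functional variants, and
   ACMG evidence codes are combined into a five-tier classification by the
   standard combining rules.
2. **Case/control burden.** A variant is a *possibly damaging SNV* (PDS)
   when it is simultaneously functional, rare and damaging-predicted — the
   same three predicates as the trio cascade. Burden is counted at the
   carrier level: an individual with any qualifying variant in a gene
   counts once. Candidate genes are tested with a two-sided Fisher exact
   test on the carrier 2×2 table; a gene-set bootstrap (1000 draws of six
   genes from the universe) asks whether the candidate set's mean/median
   burden could arise by random gene sampling; pathway enrichment uses the
   one-sided hypergeometric tail.
3. **CNV/SV consensus.** Same-type calls from multiple callers merge by
   single-linkage clustering at 50% reciprocal overlap; a consensus with
   two or more distinct callers is high confidence. Inheritance is decided
   by matching against parental call sets at the same threshold; no match
   in either parent means de novo. Breakpoint junctions are characterized
   by partitioning the contig into flanks and templated inserts (exact
   reference match, seed-and-extend) and measuring the junction
   microhomology as the maximal sequence shared by the two donor ends.
4. **Regulatory screen (DVPRR).** High-confidence de novo SNVs and CNVs are
   intersected with six non-coding annotation categories (TFBS, promoter,
   enhancer, 5'/3' UTR, ultrasensitive). A candidate-gene link is claimed
   through a listed gene's own promoter/UTR annotation or within a
   configurable flank of the gene body; for enhancers and ultrasensitive
   regions the link additionally requires variant and gene to share a
   topologically associating domain (TAD). SNVs in ncRNA genes are
   classified by context with precedence splice junction > exonic > UTR >
   intronic.

# Key parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `min_mapq` | 30 (exclusive) | phred | strict bound; reads below are ambiguous alignments |
| `min_depth`, `max_depth` | 10, 100 (inclusive) | reads | low depth is uninformative, very high depth flags collapsed repeats |
| `maf_threshold` | 0.01 | frequency | conventional rare-variant cutoff; absence from all sources counts as rare, since exclusion needs positive evidence of commonness |
| `min_tools` | 1 | tools | a single damaging call suffices, deliberately sensitive |
| `conservation_floor` | 2.0 | PhyloP-like score | "highly conserved" is not quantified in common usage; 2.0 ≈ p = 0.01 under neutrality and is configurable |
| `ro_threshold` | 0.5 | fraction | the standard reciprocal-overlap concordance rule for CNVs; single linkage, configurable |
| `trans_window` | 1000 | bp | breakend matching window for translocations |
| `flank_bp` | 10000 | bp | regulatory linkage flank; explicit and tunable because no canonical value exists |
| `set_size`, `reps` | 6, 1000 | — | the candidate-set size and replicate count of the motivating bootstrap design |
| `min_carriers` | 3 | carriers | below this, a 2×2 test is not meaningful and the gene is flagged instead |

# The synthetic-data generators

All inputs are generated, with truth tables, so every downstream stage is
testable without access to managed human data. The generators emulate:

* **Trios** — Hardy–Weinberg parental genotypes at a mixture of rare and
  common loci, Mendelian transmission (maternal-only on X for a male
  child), exactly `n_denovo` planted child-only variants, and symmetric
  single-allele genotype flips at a configurable error rate. Annotations
  (consequence, per-source frequencies, per-tool damaging calls,
  conservation) are written by the generator, not computed from sequence:
  the pipeline's logic starts downstream of annotation, exactly as it
  would with externally annotated VCFs.
* **Cohorts** — per-gene, per-individual carrier indicators; 2081 cases vs
  2535 controls by default, with carrier probability 0.002 per gene and
  0.02 in case-enriched genes. Counts are drawn per gene as binomials with
  carriers then sampled without replacement, which is distributionally
  identical to independent Bernoulli draws but scales to thousands of
  genes.
* **CNV call sets** — each planted event is emitted by a random caller
  subset (smaller subsets more likely, matching the observed low
  cross-algorithm concordance) with per-caller boundary jitter; inherited
  events also appear in one parent; each caller adds private Poisson
  false positives. Planted events are kept mutually disjoint so truth
  labels stay unambiguous.
* **Junctions** — a large deletion whose contig passes through templated
  inserts copied from other chromosomes (default 24 bp + 107 bp, the
  two-donor architecture), with a terminal microhomology planted by
  overwriting the distal donor; one guard base prevents the homology from
  extending by chance beyond its planted length.
* **Annotation** — TADs tiling each chromosome without gaps or overlap,
  promoters/UTRs anchored to gene models and carrying the gene id, a third
  of TFBS intervals nested inside promoters, random enhancer and
  ultrasensitive intervals, ncRNA models with exon structure, gene lists
  and GMT pathways.

What the generators do **not** emulate: read-level errors, realistic human
allele-frequency spectra, linkage disequilibrium, segmental duplications or
repeat-driven artifacts, caller-specific systematic biases, or annotation
noise. Passing tests therefore demonstrate correctness of the filtration
and testing logic under idealized inputs, not robustness to the failure
modes of real sequencing data.

# Numerical and design choices

* **Multi-source frequencies reduce by maximum** — a variant common in any
  database is excluded (conservative).
* **Compound-heterozygous phase** is inferred by parental exclusion only;
  sites carried by both parents are origin-ambiguous and are dropped from
  that model (and counted). No read-backed phasing is attempted.
* **Multi-allelic VCF records** are decomposed to bi-allelic rows on
  ingest; every predicate is allele-level.
* **Coordinates** are 0-based half-open internally; printed breakpoint
  pairs are treated as spans via `end − start`, which reproduces the
  published worked examples (a 243282457–243447771 deletion prints as
  ~165 kb; a 14-base homology span prints as 14).
* **Kilobase rounding** is half-up to the nearest integer.
* **Fisher test sidedness** is two-sided by default (one-sided available);
  the add-one estimator `(1 + #{null ≥ obs})/(1 + reps)` is used for
  bootstrap p-values to avoid p = 0 at finite replicates, and the
  bootstrap resamples over the *sorted* universe so results are invariant
  to input ordering.
* **Type-I calibration** of the burden scan is checked at a null carrier
  probability of 0.01 over 3000 genes: at much sparser counts the exact
  test's discreteness makes the rejection rate itself noisy, while at 0.01
  the test sits close to (and, being exact, slightly below) the nominal
  5% level. The power check uses the design's own settings (0.02 vs 0.002,
  2000/2500).
* **Insert-origin search** is exact-match seed-and-extend with a 15 bp
  minimum; shorter inserts are reported with unknown origin. Ambiguous
  multi-locus seeds are counted and the longest extension wins.
* **Degenerate inputs**: empty call sets, all-zero burden tables and empty
  funnels are returned as empty/zero structures, never errors; malformed
  VCF genotypes and call lines are skipped with counted warnings.

# Problem sizes

The packaged analysis uses one 10,000-site trio with 25 planted de novo
variants, 200-gene cohorts at 2081/2535 individuals, 20 planted CNVs
across four callers, and a 3×1 Mb (+0.5 Mb X) genome; the test suite uses
smaller variants of the same configurations (hundreds to thousands of
sites, tens of genes) chosen so each property is still identified. The
oracle-equivalence checks run the exhaustive references at the sizes where
exhaustion is exact: full-margin enumeration for Fisher (margins to 3000),
hypergeometric tails on universes ≤ 30, all-pairs transitive closure on
call sets ≤ 50, and brute-force suffix search on 200 simulated junctions.

# Known limitations

* Manual review steps of real studies (IGV curation, Sanger verification,
  pathway-tool triage) have no computational analogue here; only the
  algorithmic filters are implemented.
* ACMG combination covers pathogenic-side evidence codes; benign-side
  codes are out of scope for a de novo candidate screen.
* Enhancer–gene assignment is TAD co-membership plus distance only; no
  chromatin-contact or activity modelling.
* The burden model is marginal per gene: no covariates, relatedness or
  population-stratification adjustment (SKAT-style modelling is out of
  scope).
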