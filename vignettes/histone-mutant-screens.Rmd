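---
title: "Bar-seq fitness profiling and phenotype analytics for histone mutant screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bar-seq fitness profiling and phenotype analytics for histone mutant screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histscreen)
```

## The experiment this package models

Systematic histone mutant libraries replace each residue of yeast H2A and
H2B with alanine (and other substitutions, compound mutants and tail
deletions), each strain carrying a unique pair of TAG DNA barcodes. Two
complementary read-outs are analysed here:

1. **Pooled fitness (bar-seq).** The whole pool grows with and without a
   stressor (MMS, an alkylating agent, in the demonstration experiment). The
   TAG region of every strain is PCR-amplified with common primers, sample
   indices are introduced in a second PCR, and the mix is paired-end
   sequenced at roughly 95,000 read pairs per sample. A mutant whose barcode
   frequency drops in the treated arm relative to the control arm is
   stress-sensitive.
2. **Arrayed phenotyping.** Each strain is spotted individually on stress
   plates and its sensitivity graded 0 (none) to 4 (strongest) per
   condition, yielding an ordinal mutant-by-condition severity matrix, plus
   sectored-colony chromosome-loss assays and colony-colour silencing
   reporters at the telomere and the rDNA.

The package implements the full computational path for both read-outs, a
synthetic-data generator that emulates the sequencing experiment, and
structure mapping of phenotype residues onto the nucleosome with a
permutation test for spatial clustering.

## The simulator

`sim_config()` fixes the study conditions; `simulate_screen()` produces a
catalog, index set, ground truth, counts and (optionally) paired FASTQ.

The generative model, stage by stage:

* **Baseline pool.** Abundances are lognormal, then normalised to
  proportions. The default log-sd of 0.5 reflects a pool assembled by
  combining arrayed strains in roughly equal amounts — even deliberate
  equal-OD pooling leaves a few-fold spread — rather than the much wider
  spread of random-insertion libraries.
* **Fitness effects.** A `depleted_fraction` (default 0.1) of mutants gets a
  strictly negative log2 effect drawn from Normal(−2, 0.4) truncated below
  zero; everything else is exactly 0. The mean of −2 and the sd of 0.4 span
  observed log2 depletion ratios from about −1.2 (moderate) to below −3
  (severe), the range the screen's sensitive candidates occupy. Depletion
  acts once between the arms (treated proportions ∝ control × 2^effect,
  renormalised): the 2 h exposure plus outgrowth is abstracted into a single
  multiplier because no per-generation fitness model is identifiable from
  endpoint sequencing.
* **Counts.** Each sample is an independent multinomial draw of
  `read_pairs_per_sample` (default 95,000) from its arm's proportions, so
  column sums always equal the configured depth.
* **Reads.** Read 1 is `index (5 nt) + upstream flank + uptag (20 nt) +
  downstream flank`; read 2 carries the downtag between the same flanks,
  optionally reverse-complemented. Flanks are modelled on the yeast
  TAG-collection common primers; the 20-nt TAG length follows that same
  tradition (the library derives its barcodes from it). Substitution errors
  are applied uniformly per base (default 0.005, a typical Illumina
  substitution scale); indels, PCR jackpots, chimeras and quality-score
  structure are deliberately not modelled, and quality strings are constant
  Q40 — nothing downstream is quality-aware.
* **Indices.** Sample indices are drawn from the 256-word single
  parity-check code over {A,C,G,T}^5, which guarantees the required
  pairwise Hamming distance ≥ 2; TAG barcodes are redrawn until the whole
  up+down set sits at pairwise distance ≥ 3, the condition under which
  1-mismatch matching is provably unambiguous.

Everything is bit-reproducible under a fixed `seed`.

What passing tests on these simulations do **not** show: robustness to PCR
amplification bias, index hopping, adapter read-through, indels, or uneven
library quality — real data would add all of these, and the read-accounting
ledger is designed to make their impact visible rather than silently
absorbed.

## Demultiplexing and counting policies

* **Indices are matched exactly.** At pairwise distance 2 a single
  sequencing error can leave a read equidistant from two valid indices, so
  error correction cannot be licensed; correctness is preferred over yield.
* **Flanks are matched exactly**, and a read in which the upstream flank
  occurs twice is discarded as ambiguous.
* **TAG matching** allows at most one mismatch, and only when the catalog's
  tag set has minimum pairwise distance ≥ 3 (checked, not assumed). The
  implementation precomputes the 1-neighbourhood of every tag; disjointness
  of these balls under the distance gate makes matching a single hash
  lookup.
* **Read 2** is checked for pairing but not cross-validated: the counted
  TAG rides on read 1 by default (a layout flag flips this), and no pair
  reconciliation protocol is described for the original analysis.
* Every read pair lands in exactly one count-matrix cell or one unassigned
  counter (`bad_index`, `bad_flank`, `unknown_tag`, `ambiguous_tag`); the
  conservation identity is asserted after every run.

## Depletion statistics

For each replicate's treated/control pair, with per-mutant counts $t, c$ and
assigned library sizes $T, C$:

* `log2_ratio` $= \log_2\frac{(t+0.5)/T}{(c+0.5)/C}$. The pseudocount of
  0.5 keeps ratios finite at $t = 0$ without materially moving the ranking;
  library sizes are *assigned* totals so unassigned reads cannot distort
  proportions.
* `depletion_test` is a two-sided exact test on the table
  $[[t, T-t], [c, C-c]]$, computed by hypergeometric enumeration (the sum of
  probabilities of all same-margin tables no more likely than the observed
  one, the `fisher.test` convention, with its standard $1 + 10^{-7}$
  discreteness guard). The original analysis names no test; an exact count
  test is assumption-free at these depths and is deliberately kept behind
  its own operation boundary so it can be swapped.
* `adjust_fdr_bh` / `adjust_fwer_holm` delegate to `stats::p.adjust`. Both
  are reported; only P and q gate the call, because the printed rule names
  only those two.
* `classify_sensitive` applies the printed rule with **strict**
  inequalities: log2 ratio < −1 AND P < 0.01 AND q < 0.01. A mutant at
  exactly −1 is not sensitive, however significant.
* `replicate_concordance` reports the Pearson correlation of log2 ratios
  and the overlap of candidate sets; downstream consumers use the
  **intersection** across replicates, mirroring the screen's use of
  overlapping candidates. Replicates are analysed independently, never
  pooled.

Under the global null the exact test is conservative (its discreteness
pushes the attained level below nominal); the test suite verifies that the
fraction of mutants with P < 0.01 stays at or below 0.02 across 50
simulated experiments and that the triple rule makes no call at all in at
least 45 of them. Under the default effect model the
intersection-of-replicates candidate set recovers ≥ 90% of truly depleted
mutants with essentially no false discoveries (both quantities are
recomputed by `scripts/acceptance.R`).

## Phenotype-matrix analytics

Severities are integers 0–4 (0 extends the screen's 1–4 scale so matrix
algebra is total; it encodes "no phenotype", never missingness).

* `residue_severity`: per (histone, residue, condition), the **maximum**
  severity over all mutants touching the residue — a residue with one
  grade-2 and one grade-3 mutant displays grade 3. Deletion alleles
  annotate every residue in their range; compound substitutions every
  listed position.
* `count_phenotype_classes`: the number of distinct stress classes (DNA
  damage, microtubule, temperature, other) with any phenotype; counts 1–4
  carry the display labels I–IV, and class-0 mutants are excluded from
  I–IV summaries.
* `fraction_with_phenotype`, `subset_relation`: exact counting and Venn
  logic for statements like "the UV-sensitive set is a subset of the
  MMS-sensitive set".
* `conservation_compare`: group means ± SEM by class count with two-sided
  Mann–Whitney tests (a rank test avoids normality assumptions on
  conservation scores; the scores themselves, e.g. ConSurf output, are
  consumed, never computed).
* `chromosome_loss_rate` = half-sectored / total colonies (the
  first-division loss estimator of the sectoring assay), and
  `call_unstable` flags a strain only when its rate exceeds wild type by
  **strictly more than** fourfold — 4.0 exactly is not a call.
* `call_silencing` classifies reporter scores (higher = more expression =
  less silencing): LTS/ITS at the telomere, LRS only at the rDNA — an
  "increased rDNA silencing" category is not defined by the screen's
  vocabulary, so the rDNA call space is deliberately {WT, LRS}. Scores are
  numeric inputs; digitising colony colour is out of scope.

### Synthetic reconstructions

The screen's arrayed datasets are not available in machine-readable form,
so `synthetic_phenotype_screen()`, `synthetic_chromosome_loss()` and
`synthetic_silencing_scores()` build deterministic, clearly-labelled
**synthetic stand-ins** whose composition is fixed a priori to the screen's
reported marginal summaries (150 of 570 mutants with a phenotype; 109
HU-sensitive mutants over 76 residues; UV and CPT subsets of MMS; more than
60% of phenotype mutants in ≥ 2 classes; 31 H2A and 17 H2B unstable
alleles among 592). The analytics then genuinely recompute those summaries
from the constructed tables. These objects validate the machinery at
realistic scale; they carry no information about which *specific* residues
the real screen identified.

## Structure mapping

`parse_structure` reads Cα coordinates from a PDB file (the nucleosome
crystal structure, with its two copies of each histone) through
`bio3d::read.pdb`, resolving alternate locations to the highest-occupancy
record, first-listed on ties. `map_annotations` joins residue severities to
coordinates with the two-tier display banding (severities 1–2 vs 3–4) and
reports annotated residues absent from the structure instead of dropping
them silently.

`spatial_clustering_test` formalises "these residues cluster on the
structure": the statistic is the mean pairwise Cα distance of the query
set, with the distance between two residues taken as the **minimum over
symmetric chain copies** (which copy a figure colours is unknowable, and
the minimum is invariant to that choice). The null redraws same-size sets
with the query's exact per-histone composition, so histone-specific
geometry cannot masquerade as clustering. P values use the add-one
permutation formula $(1 + \#\{\text{null} \le \text{obs}\})/(1 + n)$ —
never exactly zero, always within $[1/(n+1), 1]$ — and an `exact = TRUE`
mode enumerates every composition-matched set on small structures, which
the tests compare against an independent enumeration.

```{r cluster-demo}
co <- synthetic_structure(n_per_histone = 20, seed = 3)
spatial_clustering_test(data.frame(histone = "H2A", residue = 1:4),
                        co, n_permutations = 2000, seed = 9)
```

## Numerical and design choices

| Parameter | Default | Why |
|---|---|---|
| `tag_length` | 20 nt | yeast deletion-collection TAG convention |
| index length / distance | 5 nt, ≥ 2 | the experiment's index design rule |
| tag distance gate | ≥ 3 | disjoint 1-mismatch balls ⇒ unambiguous matching |
| `read_pairs_per_sample` | 95,000 | the experiment's per-sample depth |
| `depleted_fraction` | 0.1 | ~10% of the pool MMS-sensitive |
| `effect_log2_mean`, `sd` | −2, 0.4 | moderate (−1.5) to severe (< −3) depletion range |
| `abundance_lognormal_sd` | 0.5 | equal-amount pooling of an arrayed collection |
| `seq_error_rate` | 0.005 | typical Illumina substitution scale |
| pseudocount | 0.5 | finite log2 at zero counts, ranking preserved |
| thresholds | −1 / 0.01 / 0.01 | the printed calling rule, strict |
| `fold_cut` | 4 | "more than fourfold", strict |

Degenerate inputs are handled explicitly rather than coerced: a 0/0 log2
ratio at zero pseudocount returns a flagged `NA`; a zero library size, an
all-treated design, a wild-type rate of zero, or a query residue without
coordinates are hard errors naming the offender.

Problem sizes in the test suite are the package's own choices, balancing
coverage against runtime: full study scale (570 mutants × 95,000 pairs ×
4 samples) for the round-trip and recovery checks, 50 simulated experiments
for null calibration, exhaustive enumeration up to margins of 30 for the
exact test, and 200 draws for permutation-test calibration.

## Known limitations

* The simulator's error model is substitution-only; it cannot probe
  robustness to indels or to index hopping between samples.
* The exact test treats reads as independent draws; PCR duplicates violate
  this in real data and would anti-conservatively sharpen P values.
* The intersection-of-replicates rule controls false discoveries at the
  cost of sensitivity for effects near the −1 boundary; mutants with true
  effects between −1 and about −1.2 are intrinsically hard to call under
  the printed thresholds.
* The synthetic phenotype reconstructions reproduce marginal counts, not
  the identity of real phenotype residues; conclusions about specific
  residues require the original data.
* Structure mapping consumes whatever chain-to-histone map it is given; it
  does not validate that a PDB entry actually is a nucleosome.
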