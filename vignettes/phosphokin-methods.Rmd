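---
title: "Methods: from phosphopeptide intensities to kinase activities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from phosphopeptide intensities to kinase activities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphokin)
```

This vignette documents the statistical model behind each stage of the
pipeline, the assumptions it makes, the parameters that matter, and the
design choices taken where the problem was genuinely open. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## The quantification model

The input is a peptide-level table: one log2 intensity per peptide ion per
run, where a run is one (condition, timepoint, replicate) sample.

**Site groups.** Peptides are aggregated by the *set* of phosphorylated
sites they carry on a protein — set equality, not overlap, so `{S15}` and
`{S15, T20}` are distinct analysis units. Within a run, intensities of
peptides sharing a site group are summed on the linear scale and
re-logged. Summation (rather than averaging or a model fit) was chosen
because it preserves total signal and is invariant to how the instrument
happened to split one site group across peptide ions; it is a documented
assumption, since "quantified together" admits several operators.

**Normalization.** Equal median normalization shifts each run additively
on the log2 scale so all run medians equal the grand median (the median of
run medians). Any common target yields the same fold changes — additive
constants cancel in treated-minus-control differences — so the target
choice is cosmetic. The post-condition (all run medians equal, to 1e-9)
and idempotence are tested. One caveat is worth knowing: median
normalization assumes most sites are unregulated. When a noticeable
fraction of sites shifts in one direction, part of that shift is absorbed
into the run median and subtracted again, biasing per-site fold changes
toward zero. The kinase statistic below is location-invariant per
contrast, so downstream inference is immune; absolute per-site fold
changes are not, and the synthetic studies measure planted effects
relative to the null-site background for exactly this reason.

**Differential tests.** Each stimulated (ligand, timepoint) is compared
with its time-matched unstimulated control: log2FC is the difference of
mean log2 intensities, and p values come from a two-sided two-sample
t test. Welch's unequal-variance form is the default — a robust choice at
n = 2–3 where variance pooling assumptions are hard to check — with the
pooled-variance (classical Student) form behind `var_equal = TRUE`. Two
degenerate regimes are handled explicitly:

* *one side entirely missing*: log2FC is ±infinity and p is undefined
  (these records are excluded from BH and can never win the collapse);
* *zero variance on both sides*: p = 1 when the means agree, otherwise the
  Welch statistic is computed with a variance floor of 1e-8 — at n = 2 a
  literal t test is undefined, and the floor keeps an extreme, honest
  p value rather than dropping the site.

Benjamini–Hochberg correction is applied within each contrast separately
(the tests are run "per timepoint"; pooling across contrasts would let a
strongly-regulated contrast alter another's threshold).

**Collapse to one fold change per site.** A single site can carry several
(FC, p) records — one per site group containing it. Records with infinite
fold changes are discarded; among the rest the lowest p value wins, with
deterministic tie-breaks (larger |FC|, then lexicographic group key).
Note that a compound (multiply-phosphorylated) record can legitimately win
a site's collapse with a larger fold change than the site's own
single-site record: under an independent-occupancy model a doubly-phospho
peptide's log2 fold change is the *sum* of its sites' occupancy changes,
and the simulator reproduces that behaviour.

## Cross-species site transfer

Kinase–substrate annotations are richest in human coordinates, while the
measurements may be mouse. Positions are transferred through a global
(Needleman–Wunsch) alignment of each ortholog pair, computed by a
three-state affine-gap (Gotoh) dynamic program written in C++:

* scoring: BLOSUM62, gap open −10, gap extend −0.5, a gap of length L
  scoring `open + (L − 1) · extend`. The original analysis used an
  aligner's unnamed defaults; this standard protein scheme is substituted
  and exposed in the configuration, so mapped positions may differ from
  the original at edge cases.
* tie-breaks: fixed preference diagonal → up (gap in target) → left,
  applied both when choosing a cell's best predecessor state and at the
  final cell, making the traceback fully deterministic.
* a site maps to the target coordinate of its alignment column, or is
  dropped (with a logged count) when that column holds a target gap.
  Duplicate target sites after mapping are resolved by the same lowest-p
  collapse rule.

Sites landing on a target residue outside the source's phospho-acceptor
class (S/T interchangeable; Y only with Y) are retained but flagged
`residue_conserved = FALSE`; `drop_nonconserved = TRUE` removes them. The
default retains them to avoid silently shrinking substrate sets — the
conservative choice when annotations and alignments are both imperfect.

Correctness is anchored two ways: alignment scores are checked against an
exhaustive enumeration of all alignments for short sequences, and against
an independent aligner (`Biostrings::pairwiseAlignment`) under the same
scheme; position transfer is checked against the simulator's recorded
ground-truth maps.

## The kinase activity statistic

For one contrast, let the collapsed finite fold changes of all n measured
sites have mean u and sample standard deviation s (the *background*). A
kinase with m ≥ 2 measured substrate sites whose fold changes average M
gets

  z = (M − u) / (s / √m),  p = 2 · (1 − Φ(|z|)).

Choices embedded here, each with its rationale and an escape hatch:

* **Background = all sites in the contrast**, including the kinase's own
  substrates ("the overall distribution"). The alternative
  (`exclude_substrates_from_background = TRUE`) matters only when a
  substrate set is a large fraction of the table. A consequence of the
  inclusive background: the z of a hypothetical kinase whose substrates
  are the entire table is exactly 0, and null z variance is slightly
  deflated (≈ 1 − m/n), visible only when m approaches n.
* **Standard error from the background sd**, the standard
  kinase-set-enrichment form; `se_mode = "substrate"` switches to the
  substrate-set sd. The phrase "in terms of standard error" admits both
  readings; the background form is the default because it remains defined
  and stable at m = 2.
* **Substrate floor m ≥ 2**: kinases below it are omitted, never
  zero-filled — an absent estimate is not evidence of inactivity.
* **Raw p at α = 0.05** drives the `significant` flag, matching an
  unadjusted z-test cutoff; a BH-adjusted column is emitted alongside for
  users who prefer controlling the kinase-level FDR.
* **Multiply-phosphorylated site groups** contribute once per site group
  to a kinase, even when several of their positions are annotated
  substrates, to avoid double counting one measurement.

The statistic is invariant to shifting all fold changes by a constant or
scaling them by c > 0 (both cancel between M − u and s), strictly
increasing in the substrate fold changes, and calibrated under the null —
the suite verifies the significant fraction and a Kolmogorov–Smirnov check
of z against the standard normal. For each pair of ligands sharing a
timepoint the fit also reports per-kinase z differences, the
differentially-regulated-kinase display.

## Network assembly and enrichment

Proteins with at least one site passing BH-adjusted p < 0.05 in at least
one timepoint of a ligand form the core node set. Edges with combined
interaction score strictly greater than 0.4 connect them; isolated core
proteins remain as nodes because they still carry phosphorylation states.
Up to ten expansion nodes are added, ranked once by the summed
above-threshold edge score linking each candidate to the current node set
(ties lexicographic) — a deterministic re-specification of an external
service's "functionally related" ranking, and a documented deviation from
it. Each node carries one state per timepoint: the signed log2FC of its
largest-|FC| significant site, or absent.

Enrichment uses the hypergeometric upper tail P(X ≥ k) with BH correction
and an FDR < 0.05 filter. The universe defaults to proteins with at least
one quantified phosphosite — the detected background, which is the
appropriate reference for detection-biased omics — with the full
annotation universe available by argument. Redundant terms are pruned
greedily by ascending FDR, dropping any term whose Jaccard similarity of
overlap-gene sets with a kept term reaches 0.5; Jaccard is a stated
substitution for the unnamed metric of the original tooling.

## The synthetic-data generator

The generator emulates the statistical structure of a two-ligand
(fibrin, iC3b), two-timepoint (1 h, 3 h) stimulation design with
time-matched unstimulated controls and n = 2–3 biological replicates:

* baseline site log2 abundances ~ Normal(25, 1.5); replicate noise
  ~ Normal(0, `noise_sd`), default 0.3 log2 units;
* planted kinases shift their substrate sites' means by `delta`
  (default ±1.5 log2 units) in stimulated conditions;
* per-run additive offsets (default Normal(0, 0.5)) make normalization
  nontrivial, and are recoverable exactly on constructed inputs;
* a fraction of proteins emit a doubly-phosphorylated peptide (site-group
  semantics), some site groups appear as two peptide ions (aggregation
  semantics), and measurements drop out independently with probability
  0.1 (exercising the infinite-FC path);
* orthologs arise by per-position substitutions (rate 0.05) and
  single-residue indels (rate 0.02) with the exact edit script and
  position map recorded; longer gaps arise from adjacent indels, which
  keeps the ground-truth bookkeeping exact;
* interaction edges score kinase co-substrate pairs high
  (uniform 0.5–0.95) over a sparse random background, and one term per
  kinase module plus random terms feed the enrichment stage.

One master seed drives everything; stage-level child seeds are derived by
fixed offsets so stages are independently reproducible. The intensity
distribution of real data is unknown — the normal-on-log2 model is an
assumption, and a flag emits linear-scale intensities to exercise the log
transform path.

What the generator does *not* emulate: peptide detectability and
abundance-dependent missingness, retention-time and spectral artefacts,
correlated (batch-structured) noise, shared peptides between proteins,
and real substrate-annotation error. Passing recovery tests therefore
shows the inference chain is correct and calibrated under its stated
model, not that the model captures every property of real spectra.

## Study sizes and reference checks

The verification studies run at sizes chosen to give stable empirical
rates on a single CPU: the alignment oracle on hundreds of random short
pairs (where exhaustive enumeration is exact), transfer recovery over 40
mutated pairs (~7,000 sites), null calibration over 200 simulated studies
of 170 proteins × 3 sites with 50 kinases × 10 substrates, planted-kinase
recovery over 100 studies of 100 proteins with 5 active among 50 kinases,
and end-to-end sensitivity/false-discovery over replicate pipeline runs.
Expected behaviours: null significant fraction near 0.05 within binomial
error, z passing a KS check against N(0, 1) at the 1% level for m ≥ 10,
planted kinases occupying the top |z| ranks, and sensitivity ≥ 0.9 with
false discovery proportion ≤ 0.1 at the default settings.

One property of the default demo deserves a note: with |delta| = 1.5,
noise 0.3 and n = 3, *site-level* BH selection at FDR 0.05 is marginal by
design (raw p of a true site is a few 1e-3, competing against ~200 mostly
null tests), so the demo's changed-protein sets — and hence its networks —
are small, while *kinase-level* inference, which aggregates m substrates,
recovers the planted kinases with high sensitivity. That contrast between
per-site and set-level power is the practical argument for substrate-set
statistics, and the demo reproduces it.

## Known limitations

* Protein inference from shared peptides, intensity imputation and
  spectral-level processing are out of scope; the pipeline starts from a
  quantified peptide table.
* Ortholog *pairs* are an input; the package does not detect orthologs or
  convert identifier namespaces.
* The kinase statistic assumes substrate fold changes are exchangeable
  draws from the background under the null; strongly correlated substrate
  sites (shared peptides, complex co-regulation) would make z
  anticonservative.
* The alignment scoring scheme is a stated substitute for the original
  tool's defaults; site transfers can differ at gap boundaries.
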