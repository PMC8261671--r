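---
title: "Methods: differential RNA-interactome capture analysis with ricdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential RNA-interactome capture analysis with ricdiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ricdiff)
```

## The analysis problem

RNA-interactome capture (RIC) identifies the proteins bound to poly(A)
RNA in vivo: proteins are UV-crosslinked to RNA, poly(A) transcripts are
captured on oligo(dT) beads, and co-purified proteins are identified and
quantified by mass spectrometry. A *differential* RIC experiment compares
two conditions (here called `untreated` and `stress`) to ask which
proteins change their RNA association. Two features make the statistics
non-standard:

* **Specificity is established by competition, not by statistics alone.**
  Each capture is paired with a control in which excess free
  polyadenylic acid competes away sequence-specific binding; proteins
  recovered equally well in the control are background.
* **Label-free quantification is method-dependent.** The same samples can
  be quantified by TOP3 (mean of the three most intense peptide areas),
  iBAQ, and LFQ, which disagree systematically about fold-change
  magnitudes. Robust calls therefore require agreement between at least
  two methods.

`ricdiff` implements this pipeline end to end: preprocessing, a
fold-change statistic with a shuffle-based FDR, cross-method consensus,
hypergeometric set statistics, a paralog-specialization analysis, and a
synthetic-data generator that makes every stage testable at desk scale.

## Preprocessing cascade

For each quantification method, `preprocess()` applies, in order:

1. **Peptide filter** — keep proteins with >= 2 peptides in at least one
   *biological* sample of either condition (`min_peptides = 2`).
   Competition controls are ignored here: a protein identified only in
   controls is not evidence of RNA binding (decision exposed as
   `filter_min_peptides()`).
2. **Normalization** — scale each sample column so its total raw peak
   area is 1e6 (arbitrary MS intensity units), then transform as
   `log2(normalized + 1)`. The pseudocount makes "not identified"
   (area 0) map to log2 value 0.
3. **Control-enrichment filter** — keep proteins whose mean raw
   biological area is >= 3-fold the mean raw control area in *both*
   conditions (`ratio = 3`, boundary inclusive). This is computed on raw
   areas, not normalized values: the source procedure words the filter in
   terms of raw peak areas even though normalization has already
   happened, and we follow that literal reading; both representations are
   carried so the alternative is one argument away.
   A condition with control mean 0 passes iff its biological mean is
   positive — the natural limit of "3-fold greater" as the denominator
   vanishes.
4. **Presence filter** — keep proteins identified (raw area > 0) in >= 2
   of the biological replicates of at least one condition
   (`min_reps = 2`).

Normalization factors are computed once, on the peptide-filtered table,
and are *not* recomputed after the later filters (the procedure we follow
normalizes before those filters and never mentions renormalizing). After
filtering, column totals are therefore <= 1e6;
`renormalize_after_filters = TRUE` restores exact 1e6 totals when a
strictly compositional output is wanted.

Missing cells are read as area 0 ("not identified"); zeros are written
back as `0`, never as blanks, so tables round-trip exactly.

## The differential statistic

Replicates are not paired across conditions, so `compute_pairwise_fcs()`
uses the **average pairwise fold-change**: for protein *p* with stress
replicates *i* and untreated replicates *j*,

    FC_p(i, j) = log2value_p(stress_i) - log2value_p(untreated_j)

over all ordered cross-condition pairs (9 in the canonical 3 x 3
design), and the statistic is their arithmetic mean. Within-condition
pairs are never formed.

The null model (`build_null_distribution()`) pools *all* per-protein
pairwise fold-changes into one global vector; each of 10,000 random
experiments draws 9 values without replacement from the pool and records
their mean. The wording of the source procedure ("shuffling the
experimentally obtained fold-changes of replicates") is ambiguous about
scope; we read it as a single global null distribution, which matches the
downstream use of one percentage per threshold. A within-protein
sign-flip variant (`build_null_distribution_signflip()`) is provided for
comparison but is not wired into the default pipeline.

`compute_fdr_grid()` then evaluates, for each fold-change threshold, the
percentage of the 10,000 null means at or beyond it — the empirical FDR —
and `fit_fdr_model()` fits one ordinary-least-squares line
`FDR ~ threshold` through the grid. `assign_fdr()` evaluates that line at
each protein's |avg FC|, clamps to [0, 100], and calls a protein
significant at `fdr_percent <= 5`.

**Tail mode.** The literal grid runs from -10 to 10 in 0.5 steps (41
points, `tail_mode = "signed"`), counting null means *above* each
threshold. Taken literally, that one-sided count can never assign a small
FDR to a protein that *loses* RNA association, yet decreased association
is reported as a first-class outcome. We therefore default to
`tail_mode = "folded"`: thresholds 0..10, counting |null mean| >=
threshold, with the fitted line applied to |avg FC| (equivalently, the
mirrored model applied to -avg FC for negative fold-changes). Both modes
are implemented and recorded in the output.

### Calibration of the linear FDR model

This estimator is faithful to its source but statistically crude, and the
package documents rather than repairs that: a single straight line is fit
to a convex, rapidly decaying grid over the full 0..10 range. Because
most of the grid is ~0 while the left edge is 100, the fitted line
acquires a large intercept and a shallow slope, and its 5% crossing lands
at |FC| of roughly 5-7 for any realistic null spread. Consequences,
measured by this package's own acceptance tests:

* Under a pure null the procedure is strongly conservative (far fewer
  than 5% of proteins are called; the null-calibration test bounds the
  per-method fraction at 15% and observes ~0).
* Moderate true effects (|log2 FC| of 2-4) are essentially never called,
  so the parameter-recovery acceptance criterion (sensitivity >= 0.80 at
  a true mean effect of 3) **fails** — sensitivity is ~0.03 while
  precision and direction agreement are 1.0. We assert the criterion as
  stated and leave it red rather than altering the estimator, the grid,
  or the simulation toward a pass; a practitioner wanting calibrated
  sensitivity should treat the ranking by |avg FC| as the robust output
  and the absolute FDR values as method-specific conventions.

## Cross-method consensus

`integrate_methods()` takes the per-method tables over the union of
their protein universes; a protein absent from one method's table (it
failed that method's filters) counts as not significant there. A protein
is *selected* when >= 2 methods call it at FDR <= 5% **and** the
selecting methods agree on direction. Direction disagreements are
flagged `discordant` and never selected — the concordance requirement is
our convention (the source presents only concordant calls); discordant
cases are reported, not dropped. Note one subtlety this creates: raising
the FDR cutoff can recruit a third, discordant method and thereby
*deselect* a protein, so selection is monotone in the cutoff only up to
discordance (the property tests assert exactly that).

## Hypergeometric statistics

Overlap significance (`overlap_test()`) and over-representation analysis
(`ora()`) use the exact upper-tail hypergeometric probability
P(X >= k), computed from log-gamma binomial coefficients with
log-sum-exp so that extreme tails (p ~ 1e-114 and far smaller) remain
representable; both `p` and `log10_p` are reported. ORA intersects each
category with the background before testing, drops categories whose
overlap is below 2, and applies Benjamini-Hochberg across the emitted
rows. The canonical background in the motivating study is its 6,725
protein-coding genes; the background here is always explicit.

## Paralog specialization

`specialization_report()` asks whether RNA binding segregates within
duplicated gene pairs: `classify_pairs()` partitions pairs into both-in /
one-in / neither against the detected-binder set and the differential
set; a Mann-Whitney test compares the abundance of one-in binders against
their non-binding partners (exact by full enumeration for untied samples
with n1 + n2 <= 20, normal approximation with tie and continuity
corrections otherwise); and ORA tests category enrichment among the
unique differential paralogs using **all paired proteins** as the
background, so the question is "which functions specialize?" rather than
"which functions are abundant?". The abundance table is user-supplied;
the simulator writes a compatible `abundance.tsv`.

## The synthetic-data generator

`simulate_ric_experiment()` emulates the structure of a three-method RIC
study with known ground truth. Per protein: latent base abundance
`a ~ LogNormal(ln 1e4, 1.5^2)` (arbitrary intensity units); deterministic
subgroup counts `n_rbp = round(f_rbp * n)`, `n_diff = round(f_diff *
n_rbp)`, `n_up = round(f_up * n_diff)` assigned along a seeded random
order (deterministic rounding keeps count-based tests exact); true
effect magnitudes from a Normal(effect_mean, effect_sd^2) left-truncated
at 0, drawn by inverse CDF so exactly one uniform is consumed per
protein regardless of parameters.

Observation layer, independently per method: biological log2 intensity =
log2 a + (stress) x method_scale x effect + Normal(0, sigma_rep^2) per
replicate; competition controls of true binders are suppressed 20-fold
(`control_suppression = 1/20`), non-binders are not suppressed, so
non-binders fail the 3-fold filter in expectation; dropout zeroes each
cell with probability `plogis(steepness * (midpoint - latent log2))`;
peptide counts are `1 + Poisson(max(0, log2 a - 8))` for observed cells
and 0 for dropped cells.

Defaults and their anchors:

| parameter | default | rationale |
|---|---|---|
| `n_proteins` | 1000 | order of a detected RIC proteome (~800-1300) |
| `f_rbp` | 0.8 | most detected proteins pass the competition filter |
| `f_diff` | 0.25 | ~25% of binders change association under stress |
| `f_up` | 0.58 | observed split of increased vs decreased (150 of 257) |
| `effect_mean`, `effect_sd` | 1.5, 0.75 | log2 units; moderate effects |
| `sigma_rep` | 0.5 | reported average replicate stdev ~0.5 |
| `method_scales` | TOP3 1.5, iBAQ 0.8, LFQ 1.0 | TOP3 overestimates, LFQ/iBAQ underestimate relative changes; scaling the *effect*, not the noise, reproduces differing per-method FC dispersions while replicate correlation stays high |
| `control_suppression` | 1/20 | strong but imperfect competition |
| `dropout_midpoint`, `dropout_steepness` | 8, 0.8 | our choice (no stated missingness model): ~1-2% dropout for a typical protein (latent log2 ~ 13.3), rising steeply below ~2^9, so low-abundance proteins and suppressed controls go missing preferentially |

One latent truth is shared by all methods; noise and dropout are drawn
independently per method, which reproduces high replicate correlations
within methods and fair (not perfect) correlation between methods.

**What the generator does not emulate:** peptide-level inference and
shared peptides, retention-time or batch structure, intensity-dependent
variance beyond the dropout layer, correlated dropout between methods,
or biological covariance between proteins (complexes). A green recovery
test therefore establishes correctness of the pipeline's bookkeeping and
calibration *under this stated world*, not performance on real spectra.

## Numerical conventions

* Quantification tables are written with `%.17g`, so write/read
  round-trips are bit-exact on doubles.
* The FDR grid uses counts (`100 * (count / n)`) rather than floating
  means, making the brute-force oracle comparison exact.
* OLS is solved by `stats::lm.fit`; tests require agreement with the
  closed-form normal equations to 1e-8.
* Hypergeometric tails below double underflow are reported via
  `log10_p`; `p_value` may round to 0 there. The tail includes the
  observed overlap (P(X >= k)).
* All randomness (simulation, shuffle null) flows from explicit integer
  seeds; equal seeds give byte-identical pipeline outputs, which the
  acceptance suite verifies at file level.
* Ties at filter boundaries are kept (>= everywhere), matching the
  inclusive wording of the source procedure.

## Known limitations

* The linear FDR model is conservative by construction (see above); the
  red recovery criterion documents this honestly.
* The exact Mann-Whitney enumerates up to C(20, 10) = 184,756
  assignments; beyond `exact_limit` it switches to the corrected normal
  approximation.
* `preprocess()` assumes the canonical two-condition design with
  competition controls in both conditions; other designs are rejected,
  not coerced.
* The paralog analysis reports its own classification counts; the
  motivating study's printed counts are internally inconsistent and are
  not reconciled here.
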