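---
title: "bruwave: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bruwave: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bruwave)
```

This vignette is the package's account of its science: the kinetic model
behind the simulator, the quantification and classification rules, the
wave-front detector, the parameters that matter, and the places where the
design was genuinely open and a choice had to be made. It states no
empirical result that the test suite does not itself compute.

## 1. The kinetic model of pulse-labeled nascent transcription

Experiments of this kind pulse cells with bromouridine for 30 minutes,
either at a starved steady state or in consecutive windows tiling the first
two hours after stimulation, and sequence the RNA made during each pulse.
The minimal generative model that reproduces the characteristic coverage
shapes (TSS-anchored wedges after induction, 5′-cleared profiles after
repression) has three ingredients:

* **Initiation** is an inhomogeneous Poisson process at the TSS with
  piecewise-constant rate $I(t)$ (initiations/min). The starved baseline
  rate is assumed to have held for all $t < 0$; named patterns
  (`sustained_up`, `transient_down`, `reversal`, …) are step schedules on
  top of it.
* **Elongation** is deterministic motion through a position-dependent,
  piecewise-constant speed field $v(x)$ (kb/min). The travel time is
  $\tau(x) = \int_0^x dx' / v(x')$, strictly increasing and piecewise
  linear; its inverse is the wave-front position at elapsed time $t$.
* **Labeling** marks a position $x$ iff some polymerase transcribes $x$
  while label is present. For a window $(w_0, w_1)$ the expected labeled
  signal at $x$ is
  $$E(x) = \int_{w_0 - \tau(x)}^{w_1 - \tau(x)} I(t)\, dt,$$
  evaluated in closed form at bin centers (default bin: 1000 bp). Reads
  are independent Poisson draws with mean `read_depth * E(x)` per bin
  (`noise = "none"` returns the rounded expectation for closed-form
  checks).

Deliberately *not* modeled: promoter-proximal pausing and release,
termination and read-through, RNA degradation, and splicing. Labeled signal
persists within its window regardless of where the polymerase later goes —
matching the fact that the assay captures labeled RNA, not polymerase
positions. Label availability equals the window exactly (no uptake lag).
Two consequences worth knowing: (i) transient patterns produce *mixtures*
in the windows flanking a rate change, because RNA labeled minutes before
the change still counts; (ii) fronts in this model are sharp, whereas real
fronts are blurred by initiation-timing and rate heterogeneity — recovery
results here are therefore upper bounds on what identical settings achieve
on real data.

Determinism: one master seed; each gene draws from a substream derived by a
stable integer hash of its id, so changing cohort composition never
perturbs other genes, and identical scenarios are byte-identical across
runs.

## 2. Quantification: TSS-proximal windowed RPKM

Productive initiation is measured as RPKM over the first 30 kb downstream
of the TSS (the whole gene when shorter than 30 kb; a gene of exactly 30 kb
is treated as capped — the boundary had to land somewhere and this makes it
testable). Counting is strand-matched; bins partially overlapping the
interval contribute proportionally to the overlap fraction, so results
converge as bins shrink. A gene is *expressed* if RPKM strictly exceeds
0.5 in any window, starved included. Quantification intervals shorter than
300 bp are skipped with a warning: the upstream method computes RPKM "over
300 bp" units and the intended role of that figure is ambiguous, so it is
implemented as a minimum-interval filter rather than silently guessed to
mean something else.

**Library size and composition bias.** RPKM divides by the per-window
library size. In a genome-scale library this is nearly constant across
windows because responding genes are a negligible mass fraction. A small
simulated cohort violates that: its own responders dominate the totals, and
on a balanced 8-pattern cohort the per-window totals rise ~1.5-fold after
stimulation, deflating every log2 fold change by ~0.6 — enough to push
3-fold effects under the twofold threshold. Scenarios therefore accept a
fixed `library_size` (the shipped worlds use $10^6$), modeling equal
sequencing depth of a transcriptome in which the simulated cohort is a
small subset. The default (`NULL`) still uses cohort totals, which is the
right choice when the cohort *is* the library.

## 3. Response classification

Fold changes are $\log_2((\mathrm{RPKM}_w + \varepsilon) /
(\mathrm{RPKM}_{starved} + \varepsilon))$ with $\varepsilon = 0.1$ RPKM.
The upstream procedure cites prior work without a formula; a fixed small
symmetric pseudocount keeps ratios finite at zero and keeps the twofold
threshold meaningful near the 0.5 expressed floor. Calls are insensitive to
twofold variation of $\varepsilon$ for genes expressed at baseline (a
regression property in the suite).

Thresholds are strict (>2-fold, i.e. |fc| > 1 in log2). The taxonomy:

* **induced** — some window above +1, none below −1;
* **repressed** — mirror image, *and* starved RPKM > 0.5 (loss of signal
  is only interpretable against a detectable baseline; the upstream text
  implies but does not state the same 0.5 cutoff — implemented with 0.5);
* **reversal** — both thresholds crossed, order recorded as a sub-flag
  (`up_down` / `down_up`);
* **onset** — first crossing window;
* **sustained** — every window from onset on stays beyond threshold;
  **transient** — otherwise (the "returned within twofold" case);
* **delayed** — onset after window 1; reported as pattern `delayed` with
  the sustained/transient distinction kept in a `subpattern` column, since
  the delayed and sustained/transient axes are defined independently and
  their cross-product is not.

Counting: reversal genes contribute to both direction totals by default
(`count_reversal_both = TRUE`), mirroring heat maps that show the reversal
panel under both directions; a switch restores exclusive counting. Heat-map
export orders genes by direction, pattern, onset ascending, then descending
max |fc|, with gene-id as the final deterministic tie-break.

## 4. Wave-front detection and elongation rates

Only responders strictly longer than 200 kb enter the cohort (induced =
advancing mode, repressed = retreating; reversal genes are excluded because
their wave changes direction mid-course). Upstream work called fronts by
eye at ~10-kb granularity; `bruwave` replaces that with an explicit
detector, with `--round-to 10000` available for comparability.

The advancing detector: (1) smooth the binned profile with a centered
moving average (`w = 5` bins); (2) plateau level = median of the smoothed
first quartile of the covered region; threshold = `max(noise_floor, beta *
plateau)` with `beta = 0.25`; (3) walk from the TSS through the
above-threshold run, bridging up to `gap_tol = 2` below-threshold bins;
undetectable if fewer than `min_run = 5` signal bins; (4) **refinement**:
extend from the run's end along *raw* bins above `noise_floor` (same gap
bridging) to the signal's zero-crossing.

Step (4) is a considered deviation from a pure threshold rule, and the one
place the detector's definition was genuinely open. An induction wedge
tapers linearly to zero at the true front, so a 0.25-plateau crossing sits
$\beta \times 30\,\mathrm{min} \times v$ (15 kb at 2 kb/min) short of it —
systematically, even on noiseless data. Displacements between windows are
unaffected (the offset cancels), but absolute fronts would never match the
closed form. The two-level rule keeps the robust threshold anchor *and*
recovers the zero-crossing exactly on clean data; under Poisson noise the
extension stops at the first `gap_tol`-run of empty bins, a small
front-proximal bias that again cancels in displacements.

The retreating detector is literally the advancing detector applied to the
reversed profile (boundary = gene length − reversed front), which makes
advancing/retreating symmetry structural rather than approximate. A still
fully-covered gene yields boundary 0 with flag `full`; a fully cleared one
is `undetectable` — flagged, never fabricated.

Displacements are taken between consecutive stimulated windows 1→2, 2→3,
3→4 (intervals 30–60, 60–90, 90–120 min) and divided by the 30-min window;
the starved→window-1 interval is excluded by default because wave positions
in the first window are dominated by initiation-timing variability (a
config flag can include it). An undetectable window voids both adjacent
intervals. Negative displacements (detector jitter) are flagged and
excluded from cohort statistics but reported. Note the two modes measure
slightly different instants of the same wave — the advancing edge sits at
$\tau^{-1}(w_1 - t_{on})$, the clearing boundary at $\tau^{-1}(w_0 -
t_{off})$ — which is also how the simulator's truth manifest defines
per-window fronts; interval displacements agree for both.

Cohort statistics report per-interval n, mean/SD/median rate and median
displacement, plus paired two-sided tests between consecutive intervals and
between the first and last interval, on genes present in both. The default
is the Wilcoxon signed-rank (exact for n ≤ 25 without ties or zero
differences): with n ≈ 21 and unknown rate distributions a rank test is the
defensible default, and the upstream study does not name its test; a paired
t-test is available (`test = "ttest"`). When more candidates than needed
exist, `top_n` keeps the strongest responders by max |fc| to mimic a
fixed-size cohort; the default is all eligible genes.

## 5. Numerical choices and degenerate inputs

* Travel time and its inverse are exact piecewise-linear interpolations on
  segment knots; the round trip is tested to $10^{-9}$ min.
* `expected_coverage` integrates the initiation step function in closed
  form at bin centers; the suite bounds its deviation from a discrete-event
  oracle (initiation grid 0.01 min) at 1% of the profile maximum.
* All thresholds (0.5 RPKM, twofold, 200 kb) are strict inequalities;
  boundary cases are pinned by unit tests.
* Zero or all-zero profiles are `undetectable`, not errors; empty gene
  lists run to completion with a warning; zero library sizes and negative
  depths are errors.
* TSVs put the header on a `#`-prefixed first line and are written in
  binary mode so reruns are byte-identical; doubles use 15 significant
  digits.

## 6. What the simulator does and does not establish

The generator emulates: a starved steady state held since $t = -\infty$;
step changes in initiation at stated onset times in both directions
(3-fold by default — comfortably beyond the twofold threshold, as expected
for a strong stimulus); position-dependent elongation with rates around
the 1.4–2 kb/min scale reported for human Pol II, including accelerating
fields; 30-min windows at starved and 0–30/30–60/60–90/90–120 min; Poisson
sampling at depths giving ≥ 50 reads per kb of plateau (read_depth 1–2 at
the default initiation rates).

It does not emulate: initiation burstiness or timing jitter, pausing,
termination, RNA processing or decay, mappability structure, or antisense
background. A green recovery test therefore establishes that the analysis
logic is correct under the stated model — not that identical settings reach
the same accuracy on real libraries, where front blur and background will
cost resolution. The shipped default scenario illustrates this honestly:
at read depth 1, transient repression — whose first-window fold change is
structurally damped toward the twofold threshold by label persistence (a
mixture of pre- and post-shut-off initiation) — is only partially
recovered, while every other class is recovered fully.

## 7. Known limitations

* Overlapping same-strand genes are counted for every overlapping gene and
  flagged, with no disambiguation — the upstream method is silent.
* Fronts are quantized to the analysis bin (default 1 kb); genes whose
  length is not a bin multiple carry a sub-bin boundary offset in
  retreating mode.
* The wave-front stage assumes one wave per gene per direction; reversal
  genes are out of scope.
* Whether per-interval cohort means should average the same fixed gene set
  in every interval or whichever genes are detectable per interval is
  unspecified upstream; `bruwave` averages detectable genes per interval
  and reports n per interval so the distinction is visible.
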