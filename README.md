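# bruwave

Transcription dynamics from pulse-labeled nascent RNA coverage.

## The problem

Bulk RNA-seq measures steady-state RNA, which lags the transcriptional
events that produce it. Pulse-labeling nascent RNA (bromouridine labeling
followed by capture and sequencing, "Bru-seq") instead snapshots what RNA
polymerase II synthesized during a defined 30-minute window. Tiling such
windows across the first two hours of a stimulus — here, serum stimulation
of starved fibroblasts as the canonical response paradigm — exposes three
things that steady-state data cannot:

1. **Productive initiation per gene per window.** Reads within the first
   30 kb downstream of the TSS (the whole gene, if shorter) reflect
   initiation during the pulse rather than full-gene output, because at
   typical elongation rates (~1.4–2 kb/min) a polymerase traverses 30 kb
   within one 30-min pulse. `bruwave` computes this as windowed RPKM:

   `RPKM = reads / (interval_kb) / (library_size / 10^6)`

2. **Temporal response classes.** With `fc_w = log2((RPKM_w + ε) /
   (RPKM_starved + ε))` per stimulated window, a gene whose |fc| exceeds
   log2(2) in any window is a responder: *induced* or *repressed*
   (repression requires starved RPKM > 0.5), *sustained* (stays beyond
   threshold from onset on), *transient* (returns within twofold),
   *delayed* (onset after the first window), or *reversal* (crosses both
   thresholds).

3. **Elongation rates from transcription waves.** In genes longer than
   200 kb, induction launches a wave of polymerases whose leading edge
   advances between windows; repression leaves a retreating wave (a growing
   5′ cleared region). The displacement of the wave front between
   consecutive windows, divided by the 30-min window duration, estimates
   the elongation rate `v = Δx / 30 min` per interval — revealing, for
   example, that polymerases accelerate along long gene bodies.

Because such studies rarely ship reusable code, and their raw data is often
unavailable, `bruwave` pairs the analysis stages with a kinetic simulator:
point polymerases initiating as a piecewise-constant-rate process, moving
deterministically through a position-dependent speed field, with Poisson
read sampling. Every stage is validated against the simulator's ground
truth and against independent brute-force oracles.

## Worked example

The shipped default scenario is a compact serum-response world: three genes
for each of the eight temporal initiation patterns (12-kb genes, 3-fold
effects) plus three long silent genes switched on at t = 0 and three long
active genes shut off at t = 0 (300 kb, 2 initiations/min, 2 kb/min).

```r
library(bruwave)
sim <- simulate_cohort(default_scenario(seed = 1), "simdir")
res <- run_pipeline(list(genes = sim$genes, samples = sim$samples,
                         out_dir = "outdir"))
res$counts
#>   direction   pattern n
#> 1   induced sustained 6
#> 2   induced transient 3
#> 3   induced   delayed 3
#> 4 repressed sustained 6
#> 5 repressed transient 1
#> 6 repressed   delayed 3
#> 7   induced  reversal 3
#> 8 repressed  reversal 3
res$wavefront$stats$advancing$per_interval
#>   interval n mean_rate sd_rate median_displacement_kb median_rate
#> 1    30-60 3      2.01  0.0192                     60           2
#> 2    60-90 3      1.99  0.0192                     60           2
#> 3   90-120 3      2.02  0.0385                     60           2
```

Reading this: the classifier recovers the simulated taxonomy (sustained
rows include the three long wave genes per direction; reversal genes count
toward both direction totals). Note `repressed transient n = 1` against 3
simulated: transient repression is the intrinsically hardest class — RNA
labeled just before shut-off still contributes to the first stimulated
window, leaving the observed fold change hovering at the twofold threshold
at this read depth. The wave-front stage recovers the simulated elongation
rate (2 kb/min) in every interval, with 60-kb median displacements per
30-min window, for both advancing (induced) and retreating (repressed)
waves.

## Command line

```sh
bruwave simulate  --config inst/extdata/default_scenario.json --out simdir [--seed N] [--no-noise]
bruwave quantify  --genes genes.bed --samples samples.tsv --cap 30000 --out matrix.tsv
bruwave classify  --matrix matrix.tsv --pseudocount 0.1 --fold 2 --out clsdir
bruwave wavefront --samples samples.tsv --genes genes.bed --calls clsdir/calls.tsv \
                  --min-length 200000 --beta 0.25 --bin 1000 --out wfdir
bruwave run       --config run_config.json
```

(`inst/cli/bruwave` is an Rscript shim over `bruwave::bruwave_main()`; exit
codes: 0 success, 2 validation failure, 3 stage failure.)

Formats: BED6 annotation; per-window per-strand bedGraph coverage (0-based,
half-open); TSV sample sheet `window / plus / minus / library_size`; all
tabular outputs are TSVs whose header line starts with `#`.

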