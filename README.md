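# g1commit

Single-cell analysis of the G1 competition between terminal-differentiation
commitment and cell-cycle entry, built around adipogenesis as the model
system.

## The problem

During adipogenesis, each preadipocyte tracked live with two reporters —
endogenous citrine-tagged PPARG (the master adipogenic transcription
factor) and an APC/C-degron cell-cycle reporter — faces a race in every G1
phase. Either nuclear PPARG reaches a threshold level $\theta$ that
triggers a bistable, self-amplifying switch, committing the cell
irreversibly to the adipocyte fate and simultaneously locking it out of the
cell cycle, or the cell enters S phase first, which suppresses PPARG
accumulation until the next G1. Adipogenic stimulation slowly tilts the
race by lengthening G1 over successive cycles and steepening the G1 PPARG
accumulation rate; mitogens tilt it the other way. The balance determines
how many terminally differentiated cells a progenitor pool produces and how
many progenitors it keeps in reserve.

`g1commit` provides:

* a stochastic generator of dual-reporter single-cell time courses
  (96 h sampled every 12 min) with complete ground truth, embodying the
  G1-competition model, including perturbation presets (p21 / cyclin D1
  knockdown, p21 overexpression, MEK inhibition, low serum, rosiglitazone);
* the trace-QC filters used on live-imaging data;
* mitosis detection and G1 / S-G2-M segmentation from the APC/C reporter;
* endpoint two-component Gaussian-mixture classification and
  commitment-threshold estimation: the smallest 48-h PPARG cut predicting
  final fate with false positive rate $FP/(FP+TN) \le 5\%$;
* crossing-time detection with persistence filtering and optional
  slope-break (kink) refinement;
* threshold-aligned ensembles, per-time Pearson correlation profiles with a
  scrambled-alignment control, level binning, mitosis-to-threshold gap
  statistics, first-versus-second G1 comparisons, and a three-way fate
  census (differentiated/post-mitotic, undifferentiated/proliferating,
  undifferentiated/quiescent);
* first-order exponential half-life fitting for cycloheximide-chase decay
  series;
* a mitogen x adipogen stimulus-grid census of progenitor versus
  differentiated cell numbers with an iso-progenitor contour.

## Worked example

```r
library(g1commit)

cfg <- sim_config(n_cells = 500, seed = 1)
sim <- simulate_population(cfg)
sim
#> <sim_population> 500 cells x 481 samples; fates: differentiated_postmitotic=218,
#>   undiff_proliferating=224, undiff_quiescent=58

qc     <- filter_traces(sim$traces)
events <- compute_events(qc$traces)

mix <- fit_endpoint_mixture(sim$endpoint$pparg_end)
mix
#> <mixture_model> low: N(316.7, 132.3) w=0.57 | high: N(1975.0, 118.6) w=0.43

labels <- classify_endpoint(sim$endpoint$pparg_end, mix)
ref <- subset(qc$traces, time_h == 48)
thr <- estimate_threshold(ref$pparg_au[order(ref$cell_id)], labels,
                          mixture = mix)
thr
#> <threshold_result> threshold 401.47 a.u. at 48 h (method fpr_scan); FPR 0.0490 (max 0.05)

crossings <- gate_crossings(
  detect_crossings(qc$traces, thr$threshold_au, refine_kink = TRUE),
  sim$endpoint$cell_id, labels)
census(crossings, events, traces = qc$traces,
       threshold_au = thr$threshold_au)
#> <fate_census> differentiated_postmitotic=214, undiff_proliferating=228,
#>   undiff_quiescent=58

g <- mitosis_to_threshold_gaps(crossings, events)
mean(g$gaps$gap_h); median(g$gaps$gap_h)
#> 4.5
#> 4.2
```

Reading the output: the endpoint PPARG distribution is bimodal (modes near
317 and 1975 a.u.); the 48-h level that predicts final fate with under 5%
false positives is ~401 a.u.; the fate census recovered from the traces
alone (214 / 228 / 58) matches the generator's ground truth (218 / 224 /
58); and committed cells reach the threshold on average ~4.5 h after their
final mitosis — always in G1 except for a small negative tail of cells that
crossed while their last S/G2/M was still completing.

`run_all(cfg, out_dir)` executes the whole chain (simulate, QC, events,
mixture/threshold/crossings, aligned analyses, census), writes every
intermediate as CSV plus a content-hash manifest, and is byte-reproducible
from the configuration. A thin command-line wrapper lives at
`inst/scripts/g1pipeline.R`. The methods vignette
(`vignettes/g1-competition.Rmd`) documents the generative model, all
numerics, and the design decisions.

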