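# viewdecode

Time-resolved population decoding of view-invariant object representations
in inferotemporal (IT) cortex, with a synthetic spike-train generator for
end-to-end validation.

## What it does

Single IT neurons respond selectively to visual objects; whether that
selectivity survives a rotation of the object — and whether the anterior
(TE) and posterior (TEO) subdivisions differ in this *viewing-angle
tolerance* — is a population-level question. `viewdecode` implements the
decoding analysis that answers it:

1. spike events → sliding-window rates (100 ms windows, 20 ms steps,
   71 bins from −450 to 950 ms around stimulus onset), per-trial baseline
   subtraction, and per-cell z-normalization
   `r_norm = (r − r_mean) / r_std`;
2. Wilcoxon/Bonferroni responsiveness screening;
3. pseudo-population vectors per stimulus image (cells recorded separately,
   trials aligned by per-cell random permutation);
4. one-vs-rest **linear SVM** hyperplanes trained at an anchor viewing
   angle (one object labeled 1, the other three 0) and tested on held-out
   vectors at viewing-angle differences Δ ∈ {0, 30, 60, 90}°;
5. performance scored as **d′ = z(TP) − z(FP)** (inverse-normal transform,
   proportions clipped to [1/(2n), 1 − 1/(2n)]), 25 estimates per time bin
   from a 5-fold × 5-repeat split plan;
6. a **random-labeling permutation null**, per-bin two-sided Mann-Whitney
   tests (25 vs 25), and significance intervals defined by ≥ 5 consecutive
   bins with p < 0.001;
7. decoding performance vs population size (random cell subsets over a
   single 100–600 ms window, mean ± SE of 5 draws).

The synthetic generator simulates inhomogeneous-Poisson cells with early
and late response phases and an *association strength* α that mixes
view-invariant object tuning (weight α) with independent per-view tuning
(weight 1 − α) — high α for TE-like, low for TEO-like populations.

## Worked example

```r
library(viewdecode)

cfg  <- sim_config(groups = preset_two_population(), seed = 7)
spk  <- simulate_spikes(build_population(cfg))
rate <- subtract_baseline(bin_rates(spk))
norm <- normalize_cells(rate)
scr  <- screen_responsive(spk)
plan <- plan_splits(20, folds = 5, repeats = 5, seed = 11)

pds  <- assemble_repeats(norm$rates, area = "TE", report = scr, seed = 3)
real <- decode_timecourses(pds, 90, plan)[[1]]
nul  <- decode_timecourses(pds, 90, plan, null = TRUE, null_seed = 5)[[1]]
significance_track(real, nul, bin_centers = pds[[1]]$bin_centers)
```

```
<significance_track> 71 bins, alpha = 0.001, min run = 5 bins
significant: 70-750 ms (35 bins)
```

(`assemble_repeats()` draws one independent pseudo-trial alignment per
analysis repeat; `assemble()` builds a single pseudo-population when one
alignment is all you need.)

The TE-like population (mean α = 0.8, 60 cells) keeps separating the four
objects when the classifier is tested 90° away from the training view:
its d′ time course differs from the random-labeling null from 70 ms to
750 ms after stimulus onset. The TEO-like population (mean α = 0.1) shows
only weak, marginal cross-view transfer — which deltas reach the
5-consecutive-bin criterion varies between simulated populations; the
methods vignette discusses why that regime is intrinsically marginal.

A file-based interface with provenance logging is available through
`run_simulate()` / `run_decode()` / `run_report()` (figures plus CSVs of
all plotted values), or from a shell via the bundled CLI:

```sh
Rscript inst/cli/viewdecode simulate --seed 1 --outdir out/
Rscript inst/cli/viewdecode decode   --outdir out/
Rscript inst/cli/viewdecode report   --outdir out/
```

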