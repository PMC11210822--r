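# cpdm — change-point detection via diffusion maps

`cpdm` detects change points in one- or multi-channel time series — the
motivating application is spotting respiratory-arrest events in contact-free
(radar) sleep-monitoring signals, where the interesting waveforms are
nonlinear and noisy and linear subspace methods lose sensitivity.

## The method

At each evaluation time $t$, two Hankel matrices are built from the series:
a *past* window $P^{(t)} \in \mathbb{R}^{h \times r_1 m}$ whose columns are
overlapping $h$-point sub-sequences ending just before $t$, and a *current*
window $Q^{(t)}$, the same columns shifted forward by a lag
$L = \lfloor h/4 \rfloor$. **CPD-DM** embeds the columns of $P$ with a
diffusion map — a self-tuning Gaussian affinity
$w_{ij} = \exp(-\lVert p_i - p_j\rVert^2 / 2\sigma_i\sigma_j)$ is
row-normalised into a Markov operator $D^{(1)}$, raised to diffusion time
$\alpha$, and the leading non-trivial eigenpairs give coordinates
$\lambda_j^\alpha \phi_j$ — then maps $Q$'s columns into the same embedding
by an affine $k$-nearest-neighbour out-of-sample extension. The change
score is

$$S(t) = \lVert \tilde P^{(t)} - \tilde Q^{(t)} \rVert_F ,$$

large when the local/global geometry of the recent data has changed.
Baselines in the same interface: singular spectrum transformation
($1 - \sigma_{\max}(U^\top Z)^2$ over the windows' principal subspaces),
Hotelling's T², and a k-nearest-neighbour distance score. Margin-based
evaluation (precision/recall/F1 with margin $M$, margin-labelled ROC AUC,
Rand index of the induced segmentations), per-sample hyperparameter grid
search, synthetic mean-shift / variance-shift benchmark generators, and
noise-robustness sweeps are included.

## A worked example

```r
library(cpdm)

sf  <- step_fixture(N = 200, tau = 100, amplitude = 5)   # clean step at t = 100
fit <- cpd(sf$series[[1]], method = "cpd_dm", h = 20, lag = 5, r_hat = 2)
fit
#> Change-point score series (method: cpd_dm)
#>   series: 200 time points x 1 channel(s), range-normalized
#>   windows: h = 20, r1 = 10, r2 = 10, lag = 5, stride = 1
#>   params: r_hat = 2, alpha = 1, K = 7, k_map = 7, kernel_two_factor = TRUE
#>   167 scores defined on t in [30, 196]; max 2.421 at t = 102

evaluate_scores(fit, tau = 100, M = 25)
#> AUC 0.727 | precision 0.500 | recall 1.000 | F1 0.667 | Rand index 0.887 (M = 25)

detect_change_points(fit, min_sep = 25)
#> [1] 102 127
```

The score is near zero on both constant segments and maximal at `t = 102`,
two points after the step enters the current window — recall is 1. The
score ramp is about `h + r1` points wide, so the default detector also
flags its trailing shoulder at `t = 127`, which costs precision (0.5), and
the same width limits the AUC when the margin (±25) is narrower than the
ramp. The Rand index compares the segmentations of all 200 time points
induced by the true and detected points.

On the synthetic benchmark families:

```r
ds <- mean_shift_dataset(seed = 42)      # 10 samples, 10 channels, N = 2000
bm <- cpd_benchmark(ds, grids = list(h = c(20, 60, 120, 200)),
                    M = 20, stride = 2, r1 = 10, r2 = 10)
bm
#> Benchmark on mean_shift dataset (10 sample(s), M = 20)
#>   cpd_dm       AUC 0.769 +/- 0.030 | F1 0.685 +/- 0.154 | RI 0.960 +/- 0.009
#>   hotelling_t2 AUC 0.699 +/- 0.018 | F1 0.400 +/- 0.125 | RI 0.820 +/- 0.152
#>   knn          AUC 0.766 +/- 0.043 | F1 0.681 +/- 0.177 | RI 0.963 +/- 0.013
#>   sst          AUC 0.680 +/- 0.032 | F1 0.422 +/- 0.122 | RI 0.897 +/- 0.063
```

Each row is the mean ± SD over the 10 samples of the metrics at each
sample's AUC-optimal configuration; CPD-DM attains the best mean AUC, and
the same run on `variance_shift_dataset(seed = 43)` separates it further
(0.820 vs ≤ 0.580 for the baselines).

A command-line front-end with `simulate`, `score`, `evaluate`, `benchmark`
and `noise-sweep` subcommands ships in `inst/cli/cpdm.R`:

```sh
Rscript inst/cli/cpdm.R simulate --kind mean_shift --seed 7 --out data/
Rscript inst/cli/cpdm.R score --series data/sample01.csv --method cpd_dm \
        --h 40 --r1 10 --r2 10 --lag 10 --out scores.csv
```

See `vignettes/cpd-dm.Rmd` for the full methods account: window
conventions, the diffusion operator and its normalisations, the
out-of-sample map, evaluation definitions, generator design, and known
limitations (including the detection-delay geometry that links window size
to the evaluation margin).

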