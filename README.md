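# adderfpt

Stochastic first-passage-time modelling of the **adder principle** of
bacterial cell-size homeostasis, for quantitative cell biologists and
modellers working with single-cell lineage data (mother machine or
time-lapse segmentation experiments).

## The model

Exponentially growing bacteria (*E. coli*, *B. subtilis*, *C. crescentus*,
*P. aeruginosa*, ...) add a roughly constant volume between birth and
division, independent of their birth size. `adderfpt` implements a
mechanistic explanation: a newborn cell of size *V<sub>b</sub>* grows as
*V(t) = V<sub>b</sub>e<sup>αt</sup>* while a timekeeper protein is expressed
in bursts arriving as an inhomogeneous Poisson process with rate
*r(t) = k<sub>m</sub>V(t)*, each burst adding *B<sub>i</sub>* molecules
(i.i.d., mean *b*, geometric by default). Division fires when the copy
number first reaches a sharp threshold *X*; the division time is the
first-passage time (FPT) of this compound process.

In the added-volume coordinate the arrivals are homogeneous with rate
*λ = k<sub>m</sub>/α* per size unit, so the added volume is a burst-count
mixture of Gamma laws,

&nbsp;&nbsp;&nbsp;&nbsp;*f*<sub>ΔV</sub>(*v*) = Σ<sub>n</sub> P(N = n) ·
Gamma(*v*; *n*, *λ*),&nbsp;&nbsp;&nbsp;
P(N = n) = P(S<sub>n</sub> ≥ X) − P(S<sub>n−1</sub> ≥ X),

which contains no *V<sub>b</sub>* — the adder property — while the FPT law
does: its mean decreases and its CV² increases with birth size. Mean-scaled
moments ⟨ΔV<sup>j</sup>⟩/⟨ΔV⟩<sup>j</sup> are independent of the growth
rate (scale invariance), and ⟨ΔV⟩ itself is linear in α.

The package provides:

* the analytic layer: burst-count pmf, FPT density/CDF/quantiles/moments,
  added-volume density and moments, mean-scaled moments, sharp and soft
  division hazards, and the replication-initiation variant in which the
  timekeeper accumulates per origin and division lags initiation by the
  constant C + D period (mean added volume inflated by *e<sup>αT</sup>*);
* exact stochastic simulation (no time discretization) of single cycles,
  multi-generation lineages, the initiation model, and four
  deviation-from-adder mechanisms (partial degradation, volume-dependent
  burst size, saturating transcription rate, soft threshold);
* analysis utilities for simulated or user-supplied lineage CSVs: newborn-
  size binning, bootstrap CV² confidence intervals, Kolmogorov–Smirnov
  collapse diagnostics, and permutation adder-trend tests;
* a command-line interface (`inst/cli/adderfpt`) with `simulate`,
  `distributions`, `analyze` and `fixtures` subcommands, YAML/JSON
  configuration, and fully seeded, byte-reproducible outputs.

## Worked example

```r
library(adderfpt)

p <- model_params(k_m = 0.13, alpha = 0.03, burst = burst_geometric(5),
                  X = 65, V_b = 1)

fpt_moments(fpt_distribution(p))[c("mean", "cv2")]
#> $mean [1] 46.48439   $cv2 [1] 0.0387793
deltaV_moments(added_volume_distribution(p))[c("mean", "cv2", "skewness")]
#> $mean [1] 3.184615   $cv2 [1] 0.126234   $skewness [1] 0.5469096

set.seed(1)
rec <- sample_cycles(p, 10000, V_b = runif(10000, 2, 3.5))
head(rec, 3)
#>     V_b   V_d delta_V   fpt alpha n_bursts final_count carryover_in mechanism
#> 1 2.398 4.356   1.957 19.89  0.03       12          66            0  baseline
#> 2 2.558 5.414   2.856 24.99  0.03       12          74            0  baseline
#> 3 2.859 5.277   2.418 20.43  0.03        9          68            0  baseline

adder_trend_test(rec)[c("rho", "verdict")]
#> $rho [1] 0.0066   $verdict [1] "adder"
```

A cell born at 1 size unit divides after 46.5 min on average
(CV² ≈ 0.039) having added 3.18 size units on average (CV² ≈ 0.126,
positively skewed). The simulated scan over birth sizes 2–3.5 confirms the
adder: the Spearman correlation between birth size and added volume is
indistinguishable from zero under a 999-permutation null. Replacing the
mechanism, e.g. `sample_cycles(p, n, mechanism_saturating_rate(5), ...)`,
breaks the adder with the mechanism's characteristic correlation sign.

From a shell:

```sh
Rscript inst/cli/adderfpt simulate --seed 1 --n 10000 --out run1
Rscript inst/cli/adderfpt analyze --input run1_cycles.csv --out run1
```

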