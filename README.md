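# mitorate

Birth–death kinetics reconciliation for cultured cell populations.

## The problem

Cell culture experiments measure proliferation three ways at once: growth
curves (daily cell counts over ~6 days), the **mitotic index** (fraction
of cells in mitosis among ≥ 1,000 scored), and the **apoptotic index**
(fraction of TUNEL-positive cells). The indices predict a net growth rate;
the growth curve measures it directly. When the prediction exceeds the
observation, cells must be dying faster than the apoptosis assay detects —
through necrosis, detachment, or death completed between detection
windows. `mitorate` quantifies that **excess (hidden) death rate** with a
bootstrap confidence interval, for anyone comparing proliferation and
death kinetics across cell lines and culture conditions (standard medium,
serum starvation, 5-FU, hypoxia).

## The model

Exponential birth–death kinetics, `dN/dt = (b − d) N`, with rates obtained
from occupancy indices by residence-time flux:

```
b          = MI / T_M          (mitotic index over mitotic duration)
d_detected = AI / T_A          (apoptotic index over detection window)
k_pred     = b − d_detected
k_obs      = mean over replicates of the OLS slope of ln N(t)
d_excess   = k_pred − k_obs
```

An age-structured alternative for mitosis, `MI = 2^(T_M/T_c) − 1`, sits
behind the `mi_convention` config flag. The percentile bootstrap
(`B = 2000` by default) resamples replicates **and** re-draws the binomial
index counts, recomputing the whole chain each iteration;
`hidden_death_flag` is true when the CI on `d_excess` excludes zero.

The package also implements the surrounding assay quantification and
statistics: soft-agar colony filtering at the 15 µm baseline size,
invasion field summaries (mean ± s.e.m.), nuclei-density × 9.6 cm²
well-area conversion, log-linear growth fits, Welch endpoint t tests,
per-replicate slope contrasts (a deliberate stand-in for GEE trend
analysis), 2×2 chi-square proportion tests, and an exact Gillespie
birth–death simulator with a hemocytometer/index observation layer and a
configurable TUNEL-invisible death channel for end-to-end validation.

## Worked example

Simulate two cell lines under 5-FU — one with a hidden death rate of
0.010/h invisible to the index sampler, one without — then analyze:

```r
library(mitorate)
cfg <- "readme-cfg.json"
jsonlite::write_json(list(
  global = list(seed = 42, bootstrap_B = 2000, reference_line = "DLD1"),
  scenario = list(groups = list(
    list(cell_line = "DLD1", condition = "fu5",
         b = 0.040, d_detected = 0.005, d_hidden = 0.010, N0 = 150000),
    list(cell_line = "DLD1p13", condition = "fu5",
         b = 0.030, d_detected = 0.004, d_hidden = 0, N0 = 150000)))),
  cfg, auto_unbox = TRUE, digits = NA)

run_pipeline("simulate", config_path = cfg, out = "readme-sim")
run_pipeline("analyze", config_path = cfg,
             growth = "readme-sim/growth.csv", index = "readme-sim/index.csv",
             out = "readme-sim/report.json")
run_pipeline("report", input = "readme-sim/report.json")
```

which prints:

```
 cell_line condition   k_obs  k_pred  d_excess    ci_low ci_high hidden_death
      DLD1       fu5 0.02503 0.03411 0.0090765  0.001743 0.01697         TRUE
   DLD1p13       fu5 0.02595 0.02622 0.0002735 -0.005950 0.00650        FALSE
 doubling_h
      27.69
      26.71
```

Reading it: for DLD1 the indices predict `k_pred = 0.0341/h` but the
growth curve only shows `k_obs = 0.0250/h`; the gap, `d_excess ≈
0.0091/h`, recovers the simulated hidden death rate of 0.010/h and its CI
excludes zero, so the flag fires. The second line, simulated with no
hidden death, yields `d_excess ≈ 0.0003/h` with a CI straddling zero. The
report JSON additionally carries a `tests` block with the per-condition
comparisons of each line against the reference line (chi-square on both
indices, Welch t on endpoint counts, slope-contrast z on growth trends).

A command-line wrapper with the same three subcommands is installed at
`system.file("cli", "mitorate.R", package = "mitorate")`.

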