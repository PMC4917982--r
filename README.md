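# rootcap

Benchmarking electrical impedance variables as estimators of plant root
biomass.

## The problem

Root system size is a key trait for drought-adapted crop breeding, but
weighing roots means washing them out of the soil — slow and destructive.
A long-standing shortcut measures the **electrical capacitance** of the
plant–soil system through a stem electrode and a soil electrode: parallel
capacitance correlates linearly with root dry mass (RDM). In practice the
measurement leaves many choices open — which electrical variable to read
off the impedance spectrum, at which injected-current frequency, with how
many terminals (2T/3T/4T), and with which stem electrode (clamp or
needle). `rootcap` implements the benchmarking analysis that settles these
choices, for researchers doing root phenotyping in pots with LCR or
impedance meters.

## The method

An impedance sample is a magnitude/phase pair, `Z* = Z e^(jθ)`. Through
the serial and parallel equivalent RC circuits (with `ω = 2πf`) it yields
the candidate predictors

    Rs = Z cos θ     Cs = −1 / (ω Z sin θ)     X = Z sin θ
    Rp = Z / cos θ   Cp = −sin θ / (ω Z)       G = cos θ / Z

plus `Z` and `θ` themselves. Each variable `y` is screened by fitting
`y = a·RDM + b` at every frequency of the sweep; the frequency with the
largest determination coefficient is the **maximum determination
frequency** `f_max` with value `r²_max`. Because a large intercept makes
measurement ratios misrepresent root-mass ratios, predictors are ranked by
the **sensitivity score**

    s = max( r²_max · (1 − |b / (a·m₀)|), 0 )

with `m₀` a characteristic root mass (1 g by default). The package also
compares clamp vs needle stem electrodes per frequency via the relative
difference `|C_c − C_n| / C_c` and an exact Wilcoxon signed-rank test at
α = 0.01, and recomputes sensitivity scores for published
capacitance–root-mass regressions from their printed `(b/(a·m₀), r²)`
summaries.

Since no raw spectra are distributed, the package ships a plant–soil
equivalent-circuit simulator (`simulateStudy()`) emulating the study
design (30 wheat plants, three soils, 26 log-spaced frequencies from
0.5 Hz to 20 kHz, `Cp = 4.2·RDM + 0.37` nF as the generating relation)
so the entire pipeline is testable against a known ground truth. See the
methods vignette (`vignettes/rootcap-methods.Rmd`) for the model, the
noise structure and its rationale.

## Worked example

```r
library(rootcap)

study <- simulateStudy(SimulationConfig(seed = 7))   # 30 plants, 3 soils
bench <- runBenchmark(study$spectra, seed = 7)
head(bench$table1[, c("variable", "config", "frequency_hz", "s", "r2", "ratio")], 8)
```

```
 variable config frequency_hz     s    r2 ratio
        G     3T     1857.000 0.969 0.978 0.009
        G     2T     1250.000 0.962 0.974 0.012
       Cs     2T      256.400 0.913 0.978 0.066
       Cs     3T      256.400 0.913 0.977 0.066
       Cp     3T       23.810 0.904 0.957 0.055
       Cp     2T       35.380 0.897 0.957 0.063
       Cp     4T        3.286 0.850 0.885 0.040
        G     4T      380.900 0.809 0.862 0.062
```

Each row is one (variable, terminal configuration): `frequency_hz` is its
maximum determination frequency, `r2` the screened determination maximum,
`ratio` the intercept:slope ratio `|b/(a·m₀)|` and `s` the sensitivity
score the table is ranked by. In this synthetic cohort conductance and the
capacitances rank highest — capacitance-family variables with small
intercept ratios — while every 4T row sits lower: the simulated stem-base
position noise degrades four-terminal sensing, as expected from its
electrode layout.

The electrode comparison on the same run:

```r
bench$electrodes[bench$electrodes$config == "2T", ][c(1, 13, 20, 26), ]
```

```
 config frequency_hz mean_delta p_value n_pairs significant
     2T          0.5      0.092 8.2e-01      30       FALSE
     2T        116.1      0.099 1.4e-05      30        TRUE
     2T       1857.0      0.132 1.8e-06      30        TRUE
     2T      20000.0      0.169 1.8e-06      30        TRUE
```

The mean clamp/needle difference grows with frequency (9% → 17%) and the
simulated needle distortion becomes significant above the hookup noise
floor.

Published regressions are re-scored from their printed summaries:

```r
lit <- recomputeScores(bundledLiterature())
lit[lit$study %in% c("Kendall et al. 1982", "Dietrich et al. 2013",
                     "Wheat multi-soil benchmark") & is.finite(lit$s),
    c("study", "ratio", "r2", "s", "s_printed")]
```

```
                        study ratio    r2       s s_printed
9         Kendall et al. 1982  0.03 0.500 0.48500      0.48
17       Dietrich et al. 2013  0.32 0.750 0.51000      0.51
19 Wheat multi-soil benchmark  0.09 0.787 0.71617      0.72
```

A thin command-line wrapper over the same functions is installed at
`system.file("scripts", "rootcap", package = "rootcap")`, with
subcommands `validate`, `simulate`, `variables`, `screen`, `score`,
`electrodes`, `literature` and `demo`.

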