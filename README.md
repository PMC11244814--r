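# cocount

Crossover interference and synaptonemal-complex (SC) morphometry from
cytological focus-position data.

## What problem this solves

In meiotic prophase, crossover sites are visible as fluorescent foci
(e.g. Hei10 foci) along the SC of each bivalent.  Crossovers *interfere*:
one crossover suppresses others nearby, so foci are more evenly spaced
than random.  Geneticists quantify this from focus-position tables with
two standard statistics, both implemented here for anyone analysing
per-bivalent focus coordinates (or comparing genotypes):

* **Gamma shape ν of inter-focus spacings.**  Adjacent-focus distances are
  fitted by maximum likelihood to a gamma distribution; ν = 1 is the
  Poisson (no-interference) limit, larger ν means more even spacing.  The
  shape solves the profile score equation
  `log(ν) − ψ(ν) = log(mean d) − mean(log d)` by safeguarded Newton
  iteration on the digamma equation, with a seeded bootstrap SE
  (`fit_gamma_shape()`).
* **Coefficient of coincidence (CoC).**  Each bivalent is cut into equal
  intervals (≈ 5 × its mean crossover count); for every interval pair,
  CoC = observed double-crossover frequency / product of the marginal
  frequencies.  Classes are pooled by inter-interval distance, and the
  **interference distance** is where the curve first rises through
  CoC = 0.5 (`coc_curve()`, `interference_distance()`).

Around these sit the routine companions of such studies: focus-count
distributions per bivalent or SC segment (`e_distribution()`, where E0 = 0
is the "obligatory crossover" signature), per-nucleus morphometry and
crossover density (`summarize_cohort()`, `co_density()`), focus-count
versus SC-length regression (`regress_count_on_length()`), Student/Welch
two-sample comparisons (`two_sample_test()`), delimited-table and
supplementary-workbook ingestion (`read_focus_table()`,
`read_supplementary_workbook()`), and a seeded end-to-end pipeline
(`run_pipeline()`).

Because real measurements come with no ground truth, the package also
ships a generator (`simulate_cohort()`): crossovers are placed along each
bivalent as a **stationary gamma renewal process** (spacings gamma(ν),
first focus from the equilibrium residual distribution), with options for
the obligate crossover (rejection sampling), fragmented-SC phenotypes
(end-biased segment placement, foci outside segments lost) and
measurement noise.  Every statistic in the package is validated against
this generator and against independent brute-force oracles in the test
suite.

## Worked example

Simulate a wild-type-like cohort (7 bivalents totalling 52.2 µm,
ν = 5.03, ~22 foci per nucleus) and a fragmented low-interference mutant
(ν = 2.77, 60% SC retained in ~15 end-biased segments), then run the full
analysis:

```r
library(cocount)
wt  <- sim_config(n_nuclei = 80, genotype = "WT", seed = 1)
mut <- sim_config(n_nuclei = 80, genotype = "fragmented", shape = 2.77,
                  fragmentation = list(), seed = 2)
report <- run_pipeline(run_config(list(wt, mut), n_bootstrap = 100))
report
```

```
<coc_report> 2 genotype(s); seed 1, config 0f3988f0
-- WT (80 nuclei) --
Gamma fit to 1243 inter-focus spacings (um)
  shape nu = 5.203 +/- 0.225 (bootstrap SE), scale = 0.416, mean spacing = 2.162
  CoC group 1-2 : interference distance 0.990 um
  CoC group 3-7 : interference distance 0.842 um
  foci/nucleus 22.54 +/- 3.13; SC total 52.80 +/- 5.25 um
  foci ~ length: slope 0.4040, R^2 0.4584
-- fragmented (80 nuclei) --
Gamma fit to 276 inter-focus spacings (um)
  shape nu = 3.313 +/- 0.328 (bootstrap SE), scale = 0.462, mean spacing = 1.532
  CoC group 1-2 : interference distance 0.000 um
  CoC group 3-7 : interference distance 0.000 um
  foci/nucleus 11.34 +/- 2.88; SC total 27.10 +/- 4.07 um
  foci ~ length: slope 0.4366, R^2 0.3823
```

Reading this: the WT-like cohort recovers its generating shape
(ν ≈ 5.2 vs 5.03 truth — spacings observable on a finite bivalent are
slightly truncation-biased), an interference distance near 1 µm, and
≈ 22.5 foci over ≈ 52.8 µm of SC.  The fragmented cohort shows the
low-interference signature: smaller ν, mean spacing 1.5 µm instead of
2.2 µm, a CoC curve already above 0.5 in its first distance class
(interference distance 0 at this binning), and 60% of the SC remaining.
The genotype difference in focus counts is then a one-liner:

```r
two_sample_test(report$genotypes$WT$morphometry$focus_count,
                report$genotypes$fragmented$morphometry$focus_count)
#> two-sample t (student): t = 23.5474, df = 158.00, two-sided p = 1.515e-53
#>   means: 22.5375 vs 11.3375
```

Measured data enter the same way via `read_focus_table("foci.csv")`
(schema: `nucleus_id, genotype, bivalent_rank, axis_length_um,
segment_start_um, segment_end_um, focus_position_um`, one row per focus)
or `read_supplementary_workbook("S1.xlsx", sheet_map = ...)` for
published per-panel tables.

See `vignettes/crossover-interference.Rmd` for the model, the
interval-binning conventions, the generator's assumptions and the
package's numerical choices.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end analysis from scratch against the
installed package: it simulates a wild-type-like and a fragmented
mutant-like cohort from the seed, runs the full pipeline (gamma fit, CoC
curves per bivalent group, E-distribution, morphometry, regression),
prints the comparison report and writes the JSON result file.
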