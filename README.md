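# proxidyn

Dynamic proximity-labeling proteomics of nanoparticle trafficking.

When nanoparticles conjugated with horseradish peroxidase are taken up by
macrophages, the enzyme biotinylates proteins in the particle's immediate
neighbourhood. Quantifying those proteins by label-free mass spectrometry
(LFQ) at a series of chase times — 0, 5, 10, 20, 30 and 60 min after
synchronized uptake, each with an enzyme-active (HRP(+), `POS`) and an
enzyme-inactive (HRP(−), `NEG`) reference condition — produces a
time-resolved interactome of intracellular delivery. `proxidyn` is the
statistics half of such an experiment, for proteomics analysts working
with protein-group intensity tables:

* **Preprocessing** — MaxQuant-style `proteinGroups` ingestion, log2
  transform, valid-value filtering, downshifted-normal imputation
  (Perseus-default parameters).
* **Ratiometric screening** — per time point $t$ and protein $i$,
  $\mathrm{log_2FC}_i(t) = \bar{x}^{POS}_i(t) - \bar{x}^{NEG}_i(t)$, with
  an empirical FDR estimated from the shape of the ratio distribution by
  the mirror (sign-flip) rule
  $\widehat{\mathrm{FDR}}(x) = (1 + \#\{x_j \le -x\}) / \#\{x_j \ge x\}$
  on median-centered ratios, monotonized into q-values. Interactors pass
  at fold change ≥ 1.2 and q ≤ 0.05.
* **Trajectory clustering** — z-normalized six-point abundance
  trajectories of the screened union, k-means with k = 10 (kmeans++
  restarts, deterministic given a seed), per-cluster organelle
  composition.
* **Organelle timelines** — per-organelle protein counts and mean
  relative-abundance trends over time, and participation windows:
  maximal runs of time points where the min-max-rescaled trend is ≥ θ
  (default 0.7).
* **Colocalization** — pixelwise Pearson plus thresholded region-overlap
  coefficients (Manders M1/M2, Jaccard; Otsu or fixed thresholds).
* **Conjugation math** — enzyme-activity standard curves and enzyme
  molecules per nanoparticle from particle geometry.
* **Synthetic data** — a generator with planted ground truth (organelle
  annotations, trajectory archetypes, log-normal noise, MNAR dropout)
  so the whole pipeline runs and is tested without any deposited data.

See `vignettes/proxidyn-methods.Rmd` for the models, assumptions and
design decisions.

## Worked example

Simulate a full experiment (2000 proteins, 10% planted interactors at
1.0 log2FC on organelle-specific schedules, replicate noise 0.25) and run
the whole pipeline:

```r
library(proxidyn)

cfg <- pipeline_config(
  simulate = sim_config(n_proteins = 2000, planted_fraction = 0.1,
                        planted_log2fc = 1, noise_sd = 0.25,
                        dropout_rate = 0, seed = 101),
  seed = 101)
bundle <- run_pipeline(cfg)

bundle$dynamics
#>   time_min n_pass sum_lfq_pos
#> 1        0    108 37540167087
#> 2        5     60 14956197592
#> 3       10     55 30644908888
#> 4       20     46 17460494180
#> 5       30    110 48894554641
#> 6       60     54 17636383614
```

`n_pass` is the number of proteins called as interactors at each chase
time and `sum_lfq_pos` their summed raw-scale LFQ intensity in the
active-condition samples — both show the zigzag over time that comes
from different organelles engaging on different schedules. Replicate QC
(`min(bundle$qc$replicate_correlation$pearson)` = 0.984) clears the 0.8
bar expected of LFQ replicates.

The organelle timeline recovers the planted schedule — early endosomes
and ER first, late endosomes/lysosomes mid-course, Golgi late, and the
ER returning late:

```r
subset(bundle$timeline$windows,
       organelle %in% c("EE", "ER", "LE", "Lysosome", "Golgi"))
#>   organelle t_start t_end degenerate
#> 1        EE       0     5      FALSE
#> 2        LE      10    20      FALSE
#> 3  Lysosome      10    30      FALSE
#> 4        ER       0     5      FALSE
#> 5        ER      30    60      FALSE
#> 6     Golgi      30    60      FALSE
```

Colocalization coefficients on a synthetic two-channel pair with target
correlation 0.6:

```r
pair <- generate_coloc_images(0.6, c(128, 128), seed = 2)
pearson_coloc(pair)          #> 0.593
region_overlap(pair)[1:3]    #> M1 0.716, M2 0.712, jaccard 0.536
```

Enzyme molecules per particle from a guaiacol-assay standard curve
(rates in ΔA470/min against µg/mL HRP) and particle geometry (100 nm
diameter, matrix density 1.34 g/cm³, 1 mg/mL suspension):

```r
curve <- fit_activity_standard_curve(
  concentrations = c(0.01, 0.02, 0.05, 0.08, 0.1),
  rates          = c(0.052, 0.101, 0.253, 0.402, 0.499))
conc <- activity_to_hrp_mass(0.30, curve)   #> 0.0598 ug/mL
hrp_per_particle(conc, particle_spec(100, 1.34, 1, 44000))
#> 0.57 molecules per particle
```

A thin command-line runner over the same functions lives at
`inst/scripts/run-pipeline.R`.

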