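# owlfield

Binocular visual-field configuration in birds of prey, and its relation to
ecology under phylogenetic control.

Nocturnal raptors such as owls carry unusually broad frontal binocular
fields. Whether that configuration tracks ecology — what a species eats,
how dense the habitat it forages in is — or simply phylogeny and body size
is a comparative question that needs three kinds of machinery at once:

1. **Perimetry geometry** — turning raw ophthalmoscopic perimeter readings
   (margin azimuths at 10° elevation steps, read from an apparatus of
   finite radius) into corrected visual-field profiles, binocular /
   cyclopean / blind sectors, and summary statistics: the maximum
   binocular overlap `max(0, left − right)`, its elevation relative to the
   bill-tip projection, and the vertical extent of the binocular field.
2. **Outline morphometrics** — elliptic Fourier analysis
   (Kuhl–Giardina) of the closed binocular-field outline,
   `x(t) = a₀ + Σ aₙ cos(2πnt/T) + bₙ sin(2πnt/T)` (and likewise `y(t)`
   with `cₙ, dₙ`), harmonic selection by cumulative power, and a principal
   component shape space over the normalized coefficients.
3. **Phylogenetic comparative statistics** — Pagel's-λ phylogenetic
   generalized least squares (`V = σ²·C_λ`, λ estimated by profile maximum
   likelihood on [0, 1]), bidirectional stepwise AIC model selection,
   simulation-based phylogenetic ANOVA (observed one-way F against a
   Brownian-motion null simulated on the tree), Brownian ancestral state
   reconstruction, and maximum-clade-credibility summaries of tree
   samples.

A seeded synthetic-data generator (`sim_config()` / `simulate_study()`)
produces trees, ecological covariates and perimeter measurement records
with exactly the statistical structure the analyses assume, so the whole
pipeline — records → profiles → summaries/outlines → comparative models —
can be exercised and validated end to end without any external data.

Everything is tidyverse-shaped: functions take data frames first and
return tibbles, fitted objects have `tidy()` / `glance()` methods, and
result types have `autoplot()` / `plot_*()` companions. Trees are
`ape::phylo` objects throughout.

## Worked example

```r
library(owlfield)
library(dplyr)

cfg   <- sim_config(n_species = 23, seed = 42)   # study-sized synthetic data
study <- simulate_study(cfg)                      # tree + traits + perimeter records

# raw records -> corrected profiles -> per-species summaries
summ <- species_field_summaries(
  study$records, study$traits[, c("species", "bill_tip_elevation_deg")])
head(summ, 3)
#> # A tibble: 3 × 6
#>   species n_individuals max_overlap_deg elevation_of_max_deg vertical_extent_deg
#> 1 sp01                2            41.5                   10                88.6
#> 2 sp02                1            50.5                    0                98.9
#> 3 sp03                3            42.7                   10                89.2

analysis <- left_join(summ,
  study$traits[, c("species", "diet", "habitat", "body_mass_g",
                   "eye_axial_length_mm")], by = "species")

# stepwise AIC selection of ecological/allometric predictors under PGLS
sel <- phylostep(analysis, "max_overlap_deg",
                 c("diet", "habitat", "body_mass_g", "eye_axial_length_mm"),
                 study$tree)
sel$trace
#>    step action term      AIC
#> 1     0 start  <NA>     145.
#> 2     1 add    habitat  130.
#> 3     2 add    diet     129.
tidy(sel$model)
#>   term             estimate std.error statistic  p.value
#> 1 (Intercept)         52.4       1.75     29.9  1.94e-17
#> 2 habitatsemi-open    -5.52      1.57     -3.51 2.33e- 3
#> 3 habitatopen        -12.1       2.24     -5.40 3.30e- 5
#> 4 dietvertebrate      -3.09      1.71     -1.81 8.68e- 2

# whole-factor habitat test against a Brownian null on the tree
phylo_anova(analysis, "max_overlap_deg", "habitat", study$tree,
            n_sims = 999, seed = 1)
#> Phylogenetic ANOVA (BM simulation null)
#> F(2, 20) = 12.775, p_sim = 0.002 (999 simulations, seed 1)

# outline shape space
ol    <- species_outlines(study$records)
space <- pca_shapes(purrr::map(ol, ~ eft_forward(resample_outline(.x, 256), 8)))
glance(space)
#>   n_outlines n_components pc1_proportion pc2_proportion
#> 1         23           15          0.871          0.105
```

Reading the output: the generator built habitat effects (dense >
semi-open > open) and a diet effect into the maximum binocular overlap;
the stepwise search recovers habitat (AIC 145 → 130) then diet (→ 129),
the PGLS table shows species in open habitat with ~12° less overlap than
the dense-habitat baseline, and the phylogenetic ANOVA confirms the whole
habitat factor (F = 12.8, simulation p = 0.002). The shape space
concentrates most outline variance on its first two components, as
expected for fields that share a common tent-like plan and differ mainly
in width and height.

The orchestration wrappers `run_unidimensional()` (λ signal + stepwise
PGLS + habitat ANOVA per trait, with optional dual diet coding of an
ambiguous species), `run_multidimensional()` (EFT → PCA → PC-score PGLS)
and `run_group_comparison()` (two-taxon contrasts) bundle these steps and
return tidy report tables.

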