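# memorder

Membrane-ordering analysis for sterol- and hopanoid-containing lipid
systems.

## The problem

Cholesterol (Chol) and the bacterial hopanoid diplopterol (Dpop) are both
"ordering lipids": they condense phospholipid acyl chains, decoupling
membrane mechanical stability from fluidity.  How strongly they do so
depends on where the phospholipid carries its cis double bond (the
Δ6/Δ9/Δ11 positional isomers of di-C18:1 PC): methyl groups projecting
from the terpenoid ring can sit at the same depth as the double bond and
frustrate packing.  Three kinds of measurement probe this interaction:

1. **Langmuir monolayer isotherms** — surface pressure Π (mN/m) vs mean
   molecular area A (Å²/molecule).  The condensing effect at a reference
   pressure (30 mN/m) is

   c = 100 · (1 − A₀ / (X₁A₁ + X₂A₂)) (%)

   with A₀ the mixture area and A₁, A₂ the pure-component areas weighted
   by mole fractions X₁, X₂.  The excess free energy of mixing is the
   pressure integral of the excess area,
   ΔG_exc = N_A ∫₀^25 [A_mix − X₁A₁ − X₂A₂] dΠ, zero for ideal mixing and
   negative for favourable interactions (1 Å²·mN/m = 10⁻²³ J).

2. **Bilayer simulation observables** — the deuterium order parameter per
   chain carbon, S_CD = ½⟨3cos²φ − 1⟩ for the C–H bond angle φ to the
   membrane normal; depth distributions of ring methyl groups (M1–M4) and
   chain double bonds along the normal (0.87 Å bins, midplane at z = 0)
   and their overlap coefficient Σ min(d₁, d₂)·w; terpenoid tilt angles
   (C24→O3 vector vs normal); and the Voronoi area per lipid from
   anchor-point tessellation per leaflet under periodic boundaries.

3. **Cell assays** — growth rates of *Mesoplasma florum* on defined lipid
   diets (negative slope of the phenol-red OD₅₆₂ decline over the
   indicator window 0.75–0.40) and the fraction of cells lysed under
   hypoosmotic shock, normalized per sample to its 0 % and 100 %
   wash-buffer anchors, with one-way ANOVA + Tukey HSD group statistics.

`memorder` implements all three stages as tested, reusable R functions,
plus seeded synthetic-data generators whose ground truth is known in
closed form, so every stage can be exercised and validated without
laboratory data or molecular-dynamics trajectories.

## Worked example

```r
library(memorder)

## --- monolayer thermodynamics: a 2:1 PC:terpenoid mixture with a known
##     injected excess area of -4 A^2 ---------------------------------------
grid  <- seq(0.5, 40, by = 0.5)
pc    <- gen_pure_isotherm(isotherm_model(100, 18, 55), grid, composition = "d11-PC")
terp  <- gen_pure_isotherm(isotherm_model(48, 25, 36),  grid, composition = "Dpop")
truth <- mixture_ground_truth(c(2/3, 1/3), excess_area = -4)
reps  <- lapply(1:3, function(r)
  gen_mixture_isotherm(pc, terp, truth, noise_sd = 0.8, seed = r,
                       composition = "d11-PC:Dpop 2:1",
                       replicate_id = paste0("r", r)))
mix <- average_replicates(reps)

condensation(mix, pc, terp, X1 = 2/3)
#> Condensing effect at 30 mN/m: 7.01% +/- 1.83%
#>   d11-PC:Dpop 2:1 vs 0.667 x d11-PC + 0.333 x Dpop (A0 = 51.64, ideal = 55.54 A^2)
excess_mixing_energy(mix, pc, terp, X1 = 2/3)
#> Excess free energy of mixing: -598.1 J/mol (nodes 0,5,10,15,20,25 mN/m)
```

A positive condensing effect (7 % here) means the mixture packs more
tightly than the mole-fraction-weighted ideal; the negative ΔG_exc says
the same thermodynamically.  The noiseless ground truth implied by the
−4 Å² excess is 7.2 %, inside the propagated ±1.83 % band.

```r
## --- bilayer observables on generated frames ------------------------------
spec <- synthetic_bilayer_spec(n_lipids_per_leaflet = 50, composition = 1/3,
                               target_cos2 = 0.6, n_frames = 20, seed = 7)
fr <- center_and_assign_leaflets(gen_bilayer_frames(spec))

head(as.data.frame(scd_profile(fr, chain = "sn2")), 3)
#>     carbon_index carbon       scd   abs_scd          se n_samples chain
#> C22            2    C22 0.4028409 0.4028409 0.011761501      2640   sn2
#> C23            3    C23 0.4147727 0.4147727 0.007984926      2640   sn2
#> C24            4    C24 0.4011364 0.4011364 0.012685860      2640   sn2
```

The generator draws C–H bonds with ⟨cos²φ⟩ = 0.6, so the analytic
S_CD = (3·0.6 − 1)/2 = 0.40 is recovered within the block-averaged
standard errors.

```r
zh <- group_z_distribution(fr)            # depth histograms, 0.87 A bins
overlap_coefficient(zh, "double_bond", "M2")
#> [1] 0.9568627                           # double bond sits at the M2 depth

voronoi_totals(voronoi_apl(fr))
#>   frame leaflet area     rel_error
#> 1     1      -1 3249  9.233611e-10      # per-leaflet areas = box section
#> 2     1       1 3249 -3.077870e-10

## --- cell assays -----------------------------------------------------------
growth_rate(gen_growth_curve(0.05, od_start = 0.9, noise_sd = 0.01, seed = 3))
#> Growth rate (synthetic): 0.0499 OD/h (R^2 = 0.992, 13 points in [0.40, 0.75])
lysed_fraction(gen_lysis_plate(c(0.65, 0.35), noise_sd = 5, seed = 4,
                               diet = c("d9", "d11")))
#>   sample diet  fraction flagged
#> 1    s01   d9 0.6574498   FALSE
#> 2    s02  d11 0.3473357   FALSE
```

## Command line

A thin `Rscript` wrapper exposes the pipeline:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/memorder.R", package = "memorder"))')
Rscript $CLI simulate --seed 1 --out run1         # generate all fixtures
Rscript $CLI isotherm --mix run1/inputs/mix.csv \
    --pure1 run1/inputs/pure1.csv --pure2 run1/inputs/pure2.csv \
    --x1 0.667 --pressure 30 --dgmix
Rscript $CLI assay --growth run1/inputs/growth.csv \
    --lysis run1/inputs/lysis.csv --report-at 80 --out run1
Rscript $CLI selftest --seed 1                    # end-to-end invariants
```

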