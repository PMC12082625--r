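# redoxmap

Analysis of redox-state-dependent structural change in isomorphous
crystal pairs: q-weighted Fo–Fo difference electron-density (DED) maps,
extrapolated structure factors with occupancy estimation by a
negative-density inflection scan, difference-map real-space correlation
(dFoCC) refinement of flavin isoalloxazine butterfly bending, and
geometry / B-factor / anisotropic-displacement analytics — together
with a synthetic two-state crystal generator that gives every stage a
recoverable ground truth.

The intended user is a structural biologist who has two isomorphous
amplitude sets — a dark/reference state and a perturbed state (a
photoreduced flavoprotein, an oxidized iron–sulfur cluster, a
ligand-triggered intermediate) — and wants to answer, reproducibly and
at desk scale: *where* did density move, *what fraction* of the crystal
converted, and *how far* did the cofactor bend.

## The models in one paragraph

A crystal with a fraction *N* of perturbed unit cells diffracts with
the complex mixture `F_mix = (1−N)·F_ground + N·F_excited`, so observed
amplitude differences carry the change only in dark-phase projection.
The pipeline scales both observed sets to the dark calculated
amplitudes (`k·exp(−B s²/4)` least squares), forms Bayesian-weighted
normalized differences `dFo_WN = w·ΔF/⟨w⟩` with
`w = 1/(1 + σ²_ΔF/⟨σ²_ΔF⟩ + α·ΔF²/⟨ΔF²⟩)` in equal-count resolution
shells, synthesizes the DED map `dFo_WN·exp(i·φc_dark)`, extrapolates
`|F_ext| = |Fc_dark| + dFo_WN/n` over trial occupancies and reads *N*
off the onset of spurious negative density at the vacated sites, and
refines the flavin fold angles (ρC, ρN) about the N5–N10 axis by
maximizing the correlation between observed and model-calculated
difference density. The methods vignette
(`vignettes/difference-map-methods.Rmd`) derives each step and records
every numerical convention.

## Worked example

The packaged demonstration mimics a redox perturbation at toy scale: a
40-atom P1 cell holding a mock isoalloxazine and a 4Fe-4S cluster; in
the perturbed state the cluster shifts 0.6 Å, the Fe4–SG4 bond
lengthens from 2.3 to 3.0 Å and the flavin bends by (5°, 7°); the two
states mix at occupancy 0.30 with 3% amplitude noise.

```r
library(redoxmap)

run <- run_pipeline(default_config(seed = 3))
run
#> <pipeline_run>
#>  stages:
#>   simulate     ok
#>   scale        ok
#>   diffmap      ok
#>   extrapolate  ok
#>   bend         ok
#>   geometry     ok
#>  headline:
#>   n_true                     0.3
#>   scale_k_dark               0.9981
#>   scale_k_mix                0.99231
#>   top_peak_sigma             30.337
#>   top_peak_atom              SF42/FE4
#>   n_est                      0.26
#>   rho_c                      3.5
#>   rho_n                      5
#>   dfocc                      0.57255
#>   fe_sg_distance             3
#>   mean_cluster_displacement  0.64733
#>   bfactor_pearson            1
```

Reading the headline block: the strongest DED peak (±30σ) sits on the
shifted cluster iron (`SF42/FE4` = atom FE4 of residue SF4 2); the
occupancy scan estimates `n_est = 0.26` against a ground truth of 0.30
(the demo's heavy-cluster shift is deliberately outside the linear
extrapolation regime — see the vignette — so the demo documents a
±0.15 band, while linear-regime fixtures recover occupancy to ~0.03);
the bend refinement finds (3.5°, 5°) against (5°, 7°) at this noisy
0.3-occupancy setting; the Fe4–SG4 distance in the perturbed model is
exactly the injected 3.0 Å; and the mean cluster displacement of
0.647 Å is seven atoms at 0.6 Å plus FE4 carried further by the bond
elongation.

Individual stages compose with pipes and return tibbles or tidy-able
objects:

```r
fx  <- two_state_fixture(n_true = 1, noise_frac = 0,
                         perturbation = perturbation_spec(bend = c(10, 12)),
                         d_min = 2, seed = 9)
scd <- scale_to_reference(fx$fo_dark, fx$fc_dark)$scaled
scm <- scale_to_reference(fx$fo_mix,  fx$fc_dark)$scaled
ded <- qweight_differences(scm, scd, alpha = 0) |>
  fofo_map(fx$fc_dark, model = fx$ground)

frame <- flavin_frame(fx$ground, "FLV")
fit   <- dfocc_refine(ded, fx$ground, frame, scan_bound = 15, d_min = 2)
fit
#> <bending_result> rho_c = 10.00 deg, rho_n = 12.00 deg, dFoCC = 1.0000 (step 0.50 deg)

glance(fit)        # one-row tibble: rho_c, rho_n, dfocc, step, scan_bound
autoplot(fit)      # dFoCC score surface over (rho_c, rho_n)
```

Geometry helpers work on any `crystal_model`:

```r
butterfly_angles(fx$excited, frame)
#> rho_c rho_n
#>    10    12
min_edge_distance(fx$ground, "FLV", c("SF4", "CYS"))
cluster_oxidation_fraction(deltaA470 = 0.0336, A470_fad = 0.5)
```

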