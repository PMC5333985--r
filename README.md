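# bcrsim

A seedable, discrete-time simulator of B-cell clonal homeostasis for
computational immunologists who want a transparent, testable implementation
of selection by B-cell receptor (BCR) saturation.

## The model in one paragraph

Every clone lives on a plane of free antigen concentration [Ag] versus
apparent dissociation constant K_D, both spanning 1e-14 to 1e-3 M. Receptor
occupancy at equilibrium is

    θ = [Ag] / ([Ag] + K_D)

so θ = 50% exactly when [Ag] = K_D. The model's central tenet: a B cell must
keep its receptor *partially* saturated to remain responsive, so it rests in
G0 inside a "comfort" band |log10([Ag]/K_D)| ≤ 0.5 and otherwise dies,
divides, edits its receptor, switches isotype or hypermutates to get back.
Compartments (niches) differ in one crucial contract: bone marrow, follicles
and germinal centers are *depletable* (division lowers free antigen through
mass-action binding, solved from the stable quadratic root
x = 2AB/(S + √(S²−4AB)), S = A+B+K), while the blood pool is *inexhaustible*
(concentrations never move, producing B1 and marginal-zone fates instead).
A germinal-center engine runs mutation–selection cycles — competitive
antigen capture, capture-proportional divisions, somatic hypermutation with
mostly-deleterious steps and hard caps of 30 heavy-/20 light-chain
mutations — and exports memory, plasmablast and long-lived plasma-cell
clones. See `vignettes/bcell-homeostasis-model.Rmd` for the full account.

## Worked example

```r
library(bcrsim)

occupancy(1e-9, 1e-9)       # 0.5 — half saturation exactly at [Ag] = K_D
solve_equilibrium(1e-9, 1e-9, 1e-9)$complex
                            # 3.819660e-10 — the stable quadratic root k(3−√5)/2

cfg <- default_config(seed = 1)
ens <- run_gc_ensemble(cfg, n_seeds = 30)   # three-dose schedule per seed
ens$summary
#> $n_seeds     30
#> $n_clones    8860
#> $kd_geomean  2.110825e-09
#> $kd_min      2e-12
#> $kd_max      9.99738e-08
#> $mut_h_max   12
#> $mut_l_max   11
```

The pooled geometric-mean K_D of 2.1e-9 M sits in the calibration band
[1e-10, 1e-8] M around the documented post-vaccination average of 1.0e-9 M;
every exported clone lies inside the documented matured range
[2.0e-12, 1.0e-7] M (the floor is a hard clamp, the ceiling is enforced by
selection); the maximum mutation loads (12 heavy, 11 light) respect the
30/20 caps.

```r
res <- simulate(default_config(seed = 3, n_steps = 30))
head(res$trajectory, 2)
#>   step       niche clone_id    stage n_cells  kd_apparent occupancy      ag_free  action
#> 1    1 BONE_MARROW     c001 IMMATURE       1 4.706244e-08 0.6603581 9.150245e-08 REST_G0
#> 2    1 BONE_MARROW     c002 IMMATURE       1 2.232888e-07 0.9795858 1.114652e-05  DIVIDE
```

Clone `c001` sits near half-saturation against its bone-marrow display
antigen and is selected into quiescence (it will emigrate to blood); `c002`
is over-engaged and proliferates.

## Command line

```sh
BIN=$(Rscript -e 'cat(system.file("exec", "bcrsim", package = "bcrsim"))')
Rscript "$BIN" simulate --seed 1 --out out/          # trajectory.csv, summary.json
Rscript "$BIN" phase-map --band 0.5 --grid 23 --out phase.tsv
Rscript "$BIN" gc --seeds 30 --out out/              # pooled maturation summary
```

Exit code 0 on success, 2 on validation error; logs go to stderr.
Configuration is strict, versioned JSON (`default_config()` documents every
key; unknown keys are errors).

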