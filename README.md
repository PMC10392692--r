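# saltsyn

Salt-dependent aggregation kinetics and constant-pH Monte Carlo
simulation of alpha-synuclein (α-syn).

α-Syn is a 140-residue intrinsically disordered protein whose
aggregation into amyloid fibrils is linked to Parkinson's disease.  Its
charge distribution is strongly asymmetric — basic residues cluster in
the N-terminal region, while the C-terminal tail (residues 101–140) is
highly acidic — and at mildly acidic pH its aggregation is dominated by
catalysis on surfaces decorated with those acidic tails.  Adding salt
*slows* aggregation even though monomers and catalytic surfaces are both
net negative: an anomalous salt dependence that implicates a short-range
electrostatic attraction (positive N-terminus into the negative tail
layer) being screened away.  `saltsyn` implements the computational
toolkit for studying this from both ends:

* **Sequence titration** — per-site Henderson–Hasselbalch charges,
  net charge vs pH, isoelectric point, region charges
  (`net_charge()`, `isoelectric_point()`, `charge_profile()`).

* **Seeded aggregation kinetics** — moment equations for primary
  nucleation, elongation and secondary nucleation,

      dP/dt = k_n m^nc + k2 m^n2 M ,   dM/dt = 2 k+ m P ,  m = m_tot − M,

  an exact integrated rate law for the seeded model (k_n = 0) via the
  first integral k+(P² − P0²) = k2 ∫ (m_tot−u)^{n2−1} u du, the
  generalized-logistic closed form built from κ, λ, C±, k∞, ǩ∞, B±,
  half-time extraction, trace normalisation, and per-salt global fits
  that recover the identifiable pair (k2·k+, k+·P0)
  (`moment_odes()`, `closed_form_mass()`, `fit_salt_series()`).

* **Constant-pH coarse-grained Monte Carlo** — one free α-syn chain
  above 208 (or 32 at desk scale) surface-grafted C-terminal tails at
  one tail per 1,200 Å², Debye–Hückel + Lennard-Jones interactions,
  harmonic bonds, bead/chain/pivot/titration moves, deterministic seeds
  (`slit_system()`, `cpmc_run()`), and the derived observables:
  mass-centre density g(z) relative to bulk, dipole-orientation
  profiles, average net charges (`gz_profile()`,
  `alignment_profile()`, `charge_summary()`).

* **Synthetic data** — plate-reader tables with the statistical
  structure of the seeded salt-series assay and a truth table for
  recovery testing (`make_salt_series()`, `simulate_plate()`).

## Worked example

Charge analysis of the packaged sequence:

```r
library(saltsyn)
s <- asyn_sequence()
isoelectric_point(s)
#> [1] 4.619515
net_charge(s, 5.5)
#> [1] -6.626285
print(charge_profile(s, 5.5))
#> charge_profile of 'asyn_human' at pH 5.50
#>   net charge: -6.626 e over 46 titratable sites
#>   region nterm    +6.325 e
#>   region nac      -0.853 e
#>   region ctail    -13.129 e
```

The protein is net negative at pH 5.5 (pI ≈ 4.6) but the charge is
sharply partitioned: +6.3 e over residues 1–60 against −13.1 e over the
C-terminal tail — the asymmetry that drives the oriented surface
attraction.

Simulate a seeded salt series and recover the rate-constant product:

```r
spec   <- make_salt_series(rng_seed = 1)
plate  <- simulate_plate(spec)
paths  <- write_plate(plate, tempfile())
traces <- read_plate(paths["plate"], paths["meta"])
fit    <- fit_salt_series(traces)
subset(fit$table, seed_uM == 0.05,
       select = c(salt_mM, k2kplus, t_half, aggregating))
#>    salt_mM      k2kplus    t_half aggregating
#> 9        0 1.664455e+16  2.670651        TRUE
#> 10      20 7.971605e+15  3.732165        TRUE
#> 11      40 4.020008e+15  5.234748        TRUE
#> 12      80 1.011883e+15 10.119967        TRUE
#> 13     120 2.534694e+14 19.089869        TRUE
#> 14     200           NA        NA       FALSE
#> 15     500           NA        NA       FALSE
#> 16    1200           NA        NA       FALSE
```

`k2kplus` (M⁻³ h⁻², for n₂ = 2) falls monotonically with salt — the
fitted analogue of the assay's progressive retardation — and conditions
at ≥200 mM are flagged non-aggregating (censored at the 64 h horizon)
rather than fitted.

Desk-scale constant-pH simulation at 20 mM and pH 5.5:

```r
sys <- slit_system(n_tails = 32, c_salt = 0.02,
                   cutoff_el = "auto", cutoff_lj = 12)
run <- cpmc_run(sys, n_equil = 3000, n_prod = 10000, sample_every = 5,
                seed = 1, runs = 2)
profile_max(alignment_profile(run))   # peak dipole orientation, max 1
#> [1] 0.8900392
charge_summary(run)
#>        species mean_net_charge     spread c_salt  pH
#> 1   free-chain       -1.621500 0.02687006   0.02 5.5
#> 2 grafted-tail       -7.705523 0.02179878   0.02 5.5
```

At 20 mM the free chain adsorbs with its positive end toward the
surface (alignment near 0.9 of the theoretical maximum of 1.0) and both
species partially neutralise; rerunning with `c_salt = 0.5` shows the
orientation collapse toward zero and the net charges deepen to about
−6.4 e (chain) and −12.8 e (tails), the charge-regulation signature of
screening.

A thin command-line front end over these functions is installed at
`system.file("cli", "saltsyn", package = "saltsyn")` with subcommands
`charge`, `make-synthetic`, `fit`, `kinetics-sim`, `cpmc-run` and
`cpmc-analyze`; every invocation writes a plain-text manifest of seeds,
inputs and outputs.

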