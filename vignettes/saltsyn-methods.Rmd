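---
title: "Models and methods in saltsyn"
author: "saltsyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in saltsyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`saltsyn` analyses the anomalous salt dependence of alpha-synuclein
(α-syn) amyloid formation at mildly acidic pH from two directions: a
kinetic one (seeded aggregation assays read out by thioflavin-T
fluorescence, fitted with a secondary-nucleation model) and a structural
one (a constant-pH coarse-grained Monte Carlo simulation of one free
monomer above a surface grafted with the protein's own C-terminal
tails).  A synthetic-data generator supplies plate-reader inputs with
known ground truth, because raw assay data are not deposited anywhere
the package could fetch them from.  This vignette records the models,
the tunable parameters and the design decisions, in the package's own
words.

# Sequence titration model

Each titratable group (D, E, H, Y, K, R, C side chains plus free
termini) carries a Henderson–Hasselbalch mean charge at pH $p$:
acid $-1/(1+10^{pK_a-p})$, base $+1/(1+10^{p-pK_a})$.  Net charge is
the sum over sites; the isoelectric point is the unique zero of the
strictly decreasing net-charge curve, found by bisection to
$|q|<10^{-6}$ e.

The intrinsic pKa set is configurable; the default is the common
coarse-grained model compound set (D 4.0, E 4.4, H 6.3, Y 9.6, K 10.4,
R 12.0, C 10.8, N-terminus 7.5, C-terminus 3.6).  With it the packaged
140-residue sequence has pI 4.62 and net charge $-6.6$ e at pH 5.5,
consistent with the reported pI of about 4.7.  A measured per-type pKa
table can be loaded with `read_pka_set()`; no measured per-site values
are hard-coded.  The N-terminus is treated as a free amine (bacterially
expressed material, no acetylation).

A note on the "uncharged central region": residues 61–95 of the real
sequence do contain three titratable side chains (E61, K80, E83) whose
mean charges nearly cancel; the region is *near*-neutral rather than
literally free of titratable groups, and the tests assert the former.

# Seeded aggregation kinetics

The moment equations for fibril number $P$ and fibril mass $M$
(monomer equivalents, $m = m_{tot} - M$) are

$$\frac{dP}{dt} = k_n m^{n_c} + k_2 m^{n_2} M,\qquad
  \frac{dM}{dt} = 2 k_+ m P ,$$

covering primary nucleation ($k_n$), secondary nucleation on fibril
surfaces ($k_2$) and elongation ($k_+$).  `moment_odes()` integrates
them with `deSolve::lsoda` at relative tolerance $10^{-8}$.  Reaction
orders default to $n_c = n_2 = 2$, the customary choice when the orders
are not reported; they are plain arguments.

`derived_rates()` evaluates the auxiliary combinations of the
generalized-logistic integrated rate law exactly as printed
($\kappa,\lambda,C_\pm,k_\infty,\bar k_\infty,B_\pm$); in the seeded
limit $k_n=0$ they collapse to $\lambda=0$, $C_\pm=0$,
$\bar k_\infty=k_\infty$, $B_-=0$.

## The exact seeded integrated rate law

For the seeded case ($k_n = 0$), dividing the two moment equations
gives an exact first integral,

$$k_+\left(P^2 - P_0^2\right)
   = k_2 \int_{M_0}^{M} (m_{tot}-u)^{\,n_2-1}\, u \, du ,$$

with the right-hand integral available through the regularised
incomplete beta function for any $n_2 \ge 1$.  The rate law then
separates, $dt = dM / (2 k_+ m P(M))$, and `closed_form_mass()`
(method `"exact"`) evaluates $t(M)$ by quadrature in the variable
$u=-\log(1-M/m_{tot})$ — in which the integrand $1/(2k_+P)$ is smooth
and bounded — on a geometric grid of 4000 nodes clustered at the start
(where $P \approx P_0$ makes the integrand vary over orders of
magnitude), inverts by monotone interpolation, and attaches the
asymptotic exponential tail $1 - \varepsilon e^{-2k_+P(\infty)(t-t_\varepsilon)}$
beyond the grid ($\varepsilon = 10^{-9}$).  Agreement with the moment
equations is $\sim 10^{-5}$ in mass fraction across the seeded regime,
which is why the equivalence property in the test suite can demand
$10^{-3}$.

The generalized-logistic closed form itself (method `"logistic"`; the
form used by global-fitting web tools for plate data, and the only
option when $k_n>0$) is also provided, with seeds entering through the
initial mass fraction, the growing-mode amplitude
$C_\pm \to x_0/2 \pm k_+P_0/\kappa + C_\pm$, and the terminal rate
$k_\infty \to (k_\infty^2 + (2k_+P_0)^2)^{1/2}$.  Measured against the
moment equations, the *best achievable* accuracy of this functional
family in the seeded regime — obtained by numerically optimising all of
its closure constants, not just the analytic choices — is about
$10^{-3}$ in mass fraction (typical analytic accuracy 0.3–2%).  It is
therefore documented as an approximation and the exact route is the
default for everything quantitative.

`half_time()` reports the linear interpolation of the first upward
crossing of baseline + half amplitude, and returns `NA` for traces that
never get there (flat or incomplete wells), which downstream tables
convert into censoring at the observation horizon.

# Trace normalisation and fitting

`normalize_trace()` fits a four-parameter logistic envelope to each
well, takes the baseline from the pre-growth segment (points earlier
than $t_0 - 6w$, where the sigmoid sits below 0.3% of its amplitude)
or from the envelope when growth starts immediately, and flags a well
non-aggregating when the fitted amplitude fails plausibility checks or
does not exceed ten times the residual noise.  At the series level a
condition is censored when its amplitude is below 5% of the maximum
amplitude on the plate.

`fit_salt_series()` fits the seeded exact rate law jointly to all
replicates of each condition.  Seeded traces determine exactly two
shape parameters — the product $k_2 k_+$ (through
$\kappa=\sqrt{2k_+k_2 m_0^{n_2+1}}$) and the elongation-seeding rate
$k_+P_0$ (early growth from seed ends) — so the fitter fixes $k_+=1$
internally and estimates both combinations: a 25-point log-spaced scan
over $\log_{10} k_2k_+$ refined by Brent's method with $k_+P_0$ held at
its prior $k_{+}^{prior}\,[seed]/L_{seed}$ (defaults $10^7$ M$^{-1}$h$^{-1}$
and $L_{seed}=500$ monomers), then a joint Nelder–Mead refinement.
Fitting only the product with $k_+P_0$ pinned to its internal-unit
value was tried first and biases the product upward by up to ~20% in
slow, high-salt conditions, because the model then lacks the early
elongation contribution of the seeds; fitting the two identifiable
combinations removes the bias (recovery within a few per cent on the
synthetic series).  Per-well amplitude and baseline are profiled out
linearly (optionally shared across replicates; off by default since the
assay does not state sharing); the time offset is fixed at zero because
plates start recording at $t=0$.  Confidence intervals come from the
curvature of the profiled sum of squares at the optimum.

# The synthetic plate generator

`make_salt_series()` encodes the study conditions: 5 µM monomer, seed
levels 0.005 and 0.05 µM (monomer equivalents), NaCl 0, 20, 40, 80,
120, 200, 500, 1200 mM, three replicates, 64 h horizon sampled every
0.25 h.  The generating truth is log-linear in salt,
$k_2k_+(c) = 1.6\times10^{16}\,10^{-0.015c}$ M$^{-3}$h$^{-2}$, flat
(zero rate) at and above 200 mM.  The base value gives
$\kappa \approx 2$ h$^{-1}$ at 0 mM (overall aggregation within a few
hours) and the decay stretches half times several-fold by 120 mM while
keeping them inside the horizon, mirroring the qualitative shape of the
assay; the true split uses $k_+=10^7$ M$^{-1}$h$^{-1}$, a literature-
plausible elongation constant, so the generator is *not* matched to the
fitter's internal parameterisation.  Noise is multiplicative (1% sd)
plus additive (0.5% of amplitude) iid Gaussian, with per-well amplitude
(5% relative sd) and baseline (2 a.u. sd) variation — chosen once to
resemble plate-reader traces.  Every plate ships its truth table;
recovery tests compare against it, never against constants.

What the generator does not emulate: drifting baselines, pipetting
covariance between wells, evaporation late in long runs, detector
saturation, or any mechanistic salt dependence beyond the monotone
product decay; passing recovery tests therefore demonstrates estimator
correctness under the stated statistical structure, not robustness to
every artefact of real plates.

# Constant-pH Monte Carlo in a slit

Peptides are flexible chains of beads (one per residue), harmonically
bonded ($r_{eq}=4.1$ Å, $k=0.76\,kT/$Å$^2$), with nonbonded pair energy

$$ u(r) = l_B z_i z_j \frac{e^{-r/\lambda_D}}{r}
   + 4\varepsilon\left[(\sigma/r)^{12}-(\sigma/r)^6\right], $$

in $kT$, $l_B=7.0$ Å, $\varepsilon=0.05$, uniform $\sigma=4.0$ Å,
$\lambda_D=(8\pi l_B N_A c_s)^{-1/2}$.  The slit is periodic in $x,y$
with hard walls at $z=0$ and $z=L_z$; `n_tails` copies of the
C-terminal tail (residues 101–140) are anchored by their N-terminal
bead on a grid at one tail per 1,200 Å$^2$ ($L_{xy}=\sqrt{1200\,n}$,
$L_z=L_{xy}$), plus one free full-length chain.  The full-scale system
uses 208 tails; the desk preset uses 32 at the same grafting density,
which is the quantity that controls the brush physics.  Bond force
constant, bead diameter and box construction are the values of the
coarse-grained model family this simulation belongs to, exposed as
arguments and logged with every run.

Moves per sweep: one translation attempt per mobile bead (cubic, step
auto-tuned to 30–50% acceptance during equilibration and then frozen),
one rigid translation+rotation per chain (rotation about the anchor for
grafted chains), one pivot rotation about a random bond per chain, and
one titration swap attempt per site.  A fraction (default 0.2) of
free-chain rigid moves is proposed as a symmetric global re-placement
of the mass centre anywhere in the slit; this exchanges adsorbed and
bulk states whose interconversion by local moves is exponentially slow,
and, being symmetric, needs no acceptance correction.  The
rigid-translation step is deliberately excluded from auto-tuning: its
acceptance is governed by the adsorption free energy, and shrinking the
step would only suppress $z$ transport.

Titration swaps toggle one site's protonation with
$\Delta U = \Delta q\,\phi + s\ln(10)(pH-pK_a)$, $s=+1$ for
protonation, $\phi$ the screened-Coulomb potential at the site; on an
isolated site this reproduces Henderson–Hasselbalch occupancy exactly,
which the test suite checks against the analytic value at
$pH-pK_a \in \{-2,\dots,2\}$.

Numerical bookkeeping: energies are updated incrementally and
re-derived from scratch at regular sampling intervals; the maximum
discrepancy is reported and the run aborts above $10^{-4}\,kT$ (typical
values are $10^{-11}\,kT$).  Rigid moves must include the moved set's
*internal* nonbonded pairs in $\Delta U$: rigid motion preserves true
internal distances but not minimum-image distances once a chain spans
more than half the box.  Electrostatics defaults to all minimum-image
pairs; a cutoff of $\min(6\lambda_D, L_{xy}/2)$ (`cutoff_el = "auto"`)
is used for production-style runs, truncating pair energies below
$l_B e^{-6}/r \approx 10^{-3}\,kT$ per unit-charge pair, and a 12 Å
Lennard-Jones cutoff (tail magnitude $<4\times10^{-4}\,kT$) enables a
linked-cell neighbour search.  Randomness comes from a deterministic
per-run generator seeded from the run seed, so trajectories are
bit-reproducible; independent runs use consecutive derived seeds, two
runs by default so every profile carries a run-to-run spread.

# Observables

`gz_profile()` histograms the free-chain mass-centre height (5 Å bins)
and normalises by the mean density in the bulk slab
$z \in [0.7, 0.9]\,L_z$ — away from both the brush and the far wall —
so the far field tends to one.  At 20 mM the chain is bound strongly
enough that desk-scale runs may never sample the bulk slab; the default
is then an error, and `bulk_pseudocount = TRUE` floors the bulk density
at one sample per slab, turning the profile into a flagged,
conservative lower bound (sufficient to establish a peak above bulk,
not its height).

`dipole_moment()` uses the mass centre of the equal-mass beads as
reference; `dipole_alignment()` is $(\mu\cdot\hat n)/|\mu|$ with
$\hat n$ the unit normal pointing from solution toward the grafting
surface, so $+1$ means the positive (N-terminal) end points at the
surface and the metric can never exceed one.  `alignment_profile()`
bins the alignment by mass-centre height; `profile_max()` reports the
profile maximum over bins with at least 20 samples (a stability filter;
sparser bins carry standard errors above 0.2 and would report noise).
`charge_summary()` averages the species net charges per run and
reports the across-run spread.

At desk scale the simulations reproduce the expected physics: at 20 mM
the free chain adsorbs into the tail layer with its positive end
surface-oriented (peak alignment ~0.9 at this scale and parameter set,
against the reported ~0.8 at full scale) and both species' net charges
are partially neutralised; at 500 mM the chain is depleted from the
surface (g(z) < 1 nearby), orientation largely vanishes and both
species become several units more negative, because screening lowers
the electrostatic penalty of ionisation and pushes protonation states
toward their intrinsic pKa values.

# Problem sizes

The test suite and the acceptance script run the desk preset (32
tails), with 3,000 equilibration plus 10,000 production sweeps and two
independent runs at 20 mM, and 2,000 + 6,000 at 500 mM where the
observables converge faster; sampling every 5 sweeps.  The kinetic
property tests draw parameters from the seeded, secondary-nucleation-
dominated regime of the study (amplification rate
$\kappa \in [0.3, 3]$ h$^{-1}$, seeds 0.1–1% of monomer, seed length
200–1000, $2k_+P_0 \le 0.2\kappa$), which is where the assay operates
and where the integrated rate law is the fitted model.

# Known limitations

* The slit model has implicit salt (Debye–Hückel) and no explicit ions
  or lipid membrane; the grafted-tail layer abstracts both fibril and
  protein-coated vesicle surfaces.
* Desk-scale adsorption at low salt is strong enough that absolute
  g(z) peak heights are reported only as lower bounds; relative and
  directional statements (peak vs depletion, alignment trends, charge
  trends) are the reliable outputs.
* The kinetic model omits fragmentation and saturating secondary
  nucleation; fits are per-condition, with no global mechanistic model
  of the salt dependence.
* Reaction orders, the intrinsic pKa set, bond parameters and bead size
  are configurable conventions, not fitted quantities; conclusions that
  depend on them should be checked for robustness by varying the
  configuration.
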