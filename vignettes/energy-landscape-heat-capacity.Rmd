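---
title: "Energy landscapes and low-temperature heat-capacity features"
author: "elcv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy landscapes and low-temperature heat-capacity features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elcv)
```

# The problem

Short peptides that form amyloid fibrils tend to support several structurally
distinct low-energy conformations — hairpin-like, partially helical, and
extended backbones — lying at the bottoms of different funnels of the
potential-energy surface, separated by significant barriers. Because those
funnel bottoms differ in both enthalpy and vibrational entropy, the
equilibrium population shifts between them as temperature rises, and that
shift appears as a peak or shoulder in the constant-volume heat capacity
$C_V(T)$ at low temperature. Control sequences with a single dominant
backbone conformation lack this feature: their first $C_V$ peak is simply the
melting peak. The low-temperature heat-capacity feature is therefore a
thermodynamic diagnostic of structural polymorphism, and `elcv` implements
the full analysis chain behind it at desk scale:

1. **explore** a potential-energy surface with basin-hopping (optionally
   basin-hopping parallel tempering, BHPT) and keep the lowest-energy minima;
2. **connect** minima into a stationary-point database with doubly nudged
   elastic band (DNEB) seeding and hybrid eigenvector-following refinement of
   transition states;
3. **compute** harmonic-superposition heat capacities, detect the first
   feature above a threshold temperature, and decompose it into minima with
   positive and negative occupation-probability derivatives;
4. **visualise** the landscape as a disconnectivity graph with
   feature-coloured branches; and
5. **characterise** the contributing minima with two order parameters — the
   end-to-end distance and a four-site signed dihedral.

Everything runs on differentiable toy potentials, and a synthetic-data module
generates multi-funnel databases with *designed* feature temperatures so that
each downstream stage can be validated against construction truth.

# Thermodynamics: the harmonic superposition approximation

The total partition function is approximated as the sum of harmonic
partition functions of all catalogued local minima. In the classical limit,
minimum $a$ with energy $E_a$, degeneracy order $n_a$, and $\kappa$ positive
normal modes of frequencies $\nu_{a,i}$ contributes

$$Z_a(\beta) \;\propto\; n_a\, e^{-\beta E_a}\, \beta^{-\kappa}\,
  e^{-L_a}, \qquad L_a = \sum_{i=1}^{\kappa} \ln \nu_{a,i},$$

with constants common to all minima dropped. All temperature axes are $k_BT$
in the same energy units as the minima (kcal/mol for peptide databases;
reduced units for the toy potentials). Occupation probabilities are
$p_a = Z_a / \sum_b Z_b$, evaluated with log-sum-exp arithmetic so that
arbitrarily low temperatures are representable. The heat capacity in units
of $k_B$ is

$$C_V/k_B \;=\; \kappa \;+\;
  \frac{\langle E^2\rangle - \langle E\rangle^2}{(k_BT)^2},$$

where the averages run over $p_a$. The classical form was adopted because it
is the one for which this moment identity holds exactly, which gives the
package a sharp internal consistency check: $C_V = k_B\beta^2\,
\partial^2 \ln Z/\partial\beta^2$, verified against finite differences of
$\ln Z$ in the test suite. The constant $\kappa k_B$ offset affects no
feature location; users who prefer the configurational part can subtract
$\kappa$.

For two minima separated by a gap $\delta$ with a temperature-independent
weight ratio $g$, the configurational heat capacity has the closed form

$$C_V/k_B - \kappa = \left(\frac{\delta}{k_BT}\right)^2
  \frac{g\,e^{-\delta/k_BT}}{(1 + g\,e^{-\delta/k_BT})^2},$$

a Schottky-type peak. This closed form is both a test oracle and the design
equation of the synthetic generator.

```{r two-state}
db <- spdb(data.frame(energy = c(0, 0.3), log_freq_product = 0, horder = 1),
           kappa = 5)
grid <- kbt_grid(0.02, 1, 200)
curve <- heat_capacity_curve(db, grid)
max(abs(curve$cv - 5 - two_state_cv(0.3, grid)))   # closed-form agreement
```

## Feature detection

Peaks are interior local maxima of $C_V(k_BT)$; inflections are local maxima
of $dC_V/d(k_BT)$ on rising parts of the curve. Every resolved peak owns one
rising-flank slope maximum, which is suppressed, so an inflection feature is
a genuine *shoulder* — a slope maximum separated from the next peak by
another slope maximum, or followed by no peak at all. A relative prominence
floor of $10^{-3}$ on the slope curve suppresses numerical ripple; since HSA
curves are analytic no smoothing is applied. Whether the original analyses
detected inflections visually or algorithmically is not something the code
can settle; the shoulder rule here is a stated convention.

Three conventions mirror the hexapeptide analysis protocol and are defaults
of `feature_config()`:

* the feature of interest is the **first** feature above
  $k_BT = 0.086$ (small side-chain rearrangements produce features below
  this threshold that do not change the backbone);
* for cross-sequence comparisons the feature must fall in the window
  $(0.076, 0.300)$ — `first_feature_temperature()` uses
  `threshold_low`/`threshold_high` for this;
* the **melting peak** — identified as the highest-temperature peak on the
  grid, which requires the grid to extend past it — is excluded, so a
  database whose only peak is the melting peak reports *no* feature.

Feature decomposition follows the occupation-derivative sign structure:
$dp_a/d(k_BT) = p_a (E_a - \langle E\rangle)/(k_BT)^2$, which sums to zero
over the database. At the feature temperature, minima are split by sign and,
within each sign group sorted by $|dp_a/dT|$ (ties broken by lower id), the
minimal prefix covering 98% of the group total is reported. The 98% rule is
applied per sign group — matching the two-colour visualisation of draining
and filling minima on disconnectivity graphs — rather than jointly.

# Exploration: basin-hopping and move sets

`basin_hop()` perturbs the current structure, quenches the proposal to the
nearest local minimum, and accepts or rejects on quenched energies with a
Metropolis rule. Moves are uniform Cartesian displacements, optionally mixed
with **group rotations** (a contiguous tail segment rotated about the axis of
its preceding bond) for chains, and **rigid-body dimer moves** for two-body
systems: the two monomer centroids are expanded radially from the overall
centroid, each monomer is rotated in the angle–axis framework about its own
centroid and translated, with a rigid-body move performed after every 111
Cartesian moves by default. The 1000 lowest-energy structures are kept in a
sorted, deduplicated pool and re-converged tighter
(RMS gradient $\le 10^{-7}$) by `tight_converge()`. Production-scale dimer
exploration in this protocol family accumulates $6\!-\!8 \times 10^5$
basin-hopping steps; the package documents that scale but defaults to
desk-scale runs, and its validation uses 5,000-step LJ$_7$ runs and
20,000-step LJ$_{13}$ runs, which recover the reference global minima
($-16.505384$ and $-44.326801$ reduced units, established by longer in-repo
reference runs) in nearly every seed.

`bhpt()` runs replicas at temperatures distributed exponentially
(geometrically) between $T_{\min}$ and $T_{\max}$ — 16 replicas between 300
and 575 by default — with Metropolis swaps of adjacent-temperature replicas
every `exchange_interval` steps. Replicas execute sequentially from one seed,
so runs are exactly reproducible; the sampling temperatures and the
thermodynamic-analysis $k_BT$ grid are deliberately independent settings.

Deduplication calls two minima identical when their energies agree within
$10^{-6}$ *and* their best-aligned RMSD (centring plus optimal proper
rotation, Horn's quaternion method) is below $10^{-3}$. No permutational
alignment is attempted, so permutation–inversion isomers of one structure
may coexist in the pool; this is conservative and only affects pool
occupancy, not the lowest energy found.

# Connections: DNEB + hybrid eigenvector-following

`grow_database()` alternates four steps until its two endpoint minima are
connected or the attempt budget is spent:

1. **pair selection** (`select_next_pair()`): Dijkstra's algorithm on a
   complete graph in which TS-connected pairs have weight 0 and unconnected
   pairs a weight increasing with structural distance (best-aligned RMSD
   squared — the metric is a configuration choice, documented here); failed
   pairs are removed, and the first unconnected pair on the minimum-weight
   path is attempted next;
2. **DNEB** (`dneb()`): a linearly interpolated band (11 images, spring
   constant 1 by default) relaxed under the doubly nudged force — the
   perpendicular true-gradient component, the parallel spring component, and
   the portion of the perpendicular spring force orthogonal to the
   perpendicular gradient — using FIRE; interior energy maxima of the
   relaxed band are transition-state candidates;
3. **hybrid eigenvector-following** (`hybrid_ef_refine()`): uphill Newton
   steps along the lowest Hessian eigenmode with Newton minimisation in the
   orthogonal complement, a trust-radius cap, mode-continuity alignment
   between iterations, and a floor on the uphill step so the walk cannot
   stall inside a convex region. Convergence requires RMS gradient below
   tolerance *and* exactly one negative eigenvalue; reaching a minimum or a
   higher-index saddle raises a classed error, and such candidates are
   quenched and kept as intermediate minima instead;
4. **two-sided descent** (`descend_both_sides()`): displacements of
   $\pm$`displacement` along the negative mode, relaxed first by fine
   steepest-descent steps — so each path stays in the basin its
   steepest-descent trajectory enters instead of hopping past an
   intermediate minimum — then quenched.

Hessians are central finite differences of the analytic gradient (step
$10^{-5}$) with dense symmetric eigensolves — adequate at toy scale. For
translation/rotation-invariant potentials the six rigid-body modes are
removed by explicit projection (shifted to a large eigenvalue) rather than an
eigenvalue threshold: away from stationary points those modes are not exact
eigenvectors, and following a rotational pseudo-zero mode is the classic
failure of threshold-based zero-mode handling. Frequencies enter the
thermodynamics through $L_a = \frac{1}{2}\sum_i \ln \lambda_i$ over positive
modes (unit masses, constants dropped).

On the Müller–Brown surface the full pipeline reproduces the complete
stationary-point inventory — three minima and two index-1 saddles, with
energies matching a grid-scan + Newton oracle to $10^{-6}$ — and assembles a
fully connected database. Removal of unphysical barriers from grown
databases is out of scope; databases are used as grown.

# The toy potentials

* **Müller–Brown**: the standard four-Gaussian 2D surface; no zero modes,
  cheap Hessians — the reference system for the transition-state machinery.
* **LJ clusters**: reduced units ($\epsilon = \sigma = 1$); configurations
  with any pair distance below $10^{-6}\sigma$ are rejected with a classed
  error rather than evaluated.
* **Bead chain**: harmonic bonds ($k_b = 100$, $r_0 = 1$), a
  harmonic-cosine bond-angle term
  $\tfrac{1}{2}k_a(\cos\theta - \cos\theta_0)^2$ ($k_a = 20$,
  $\theta_0 = 109.5^\circ$), a cosine-series backbone dihedral
  $\sum_m A_m(1 + \cos(m\phi - \gamma_m))$ with $A_1 = 0.2$, $A_3 = 0.4$,
  and Lennard-Jones attraction ($\epsilon_{nb} = 0.4$) between beads three
  or more bonds apart. The angle term is not optional decoration: without
  it the 1–3 pairs are unconstrained, so minimisation collapses bead $i$
  onto bead $i+2$ and near-collinear bends make the torsion gradient
  singular. With it, the multi-well dihedral plus nonbonded attraction give
  at least two distinct backbone basins (compact vs extended) — a desk-scale
  analogue of the hairpin/helix competition.

All gradients are analytic (compiled), verified against central finite
differences; quenching is a compiled limited-memory quasi-Newton (L-BFGS)
descent converging on the RMS gradient, with an iteration cap of $10^4$.

# Descriptors and conformation classes

For a hexapeptide the end-to-end distance runs from the N atom of residue 1
to the C atom of residue 6, and the dihedral is the signed IUPAC torsion over
the C$\alpha$ atoms of residues 1, 3, 4 and 6, reported in $(-180, 180]$
degrees. `site_selection()` generalises this by explicit indices;
`default_site_selection()` maps it onto bead chains via fractional positions
$0, \tfrac{2}{5}, \tfrac{3}{5}, 1$. Hairpins sit at small distance and small
dihedral; helices at larger distance and large positive dihedral; extended
chains at the largest distances with dihedrals near $\pm 180^\circ$ (where
positive and negative are geometrically similar). The five conformation
classes — hairpin (U-shaped), S-shaped, question-mark-shaped, W-shaped
(almost helical), extended (Z-shaped) — are ordered by increasing end-to-end
distance; the literature provides the ordering but no numeric cut points, so
`classify_conformation()` exposes the four boundaries as configuration with
toy-scale defaults and half-open bins (a value on a cut belongs to the upper
class).

`correlation_data()` restricts records to a feature's contributing minima
and, when an energy window is set (2.6 energy units above the global minimum
by default — the dimer-analysis convention), to minima inside the window.
Whether the monomer analysis windows as well as restricts is ambiguous in
the source protocol; both switches are exposed, and the default treats the
window as always active (set `energy_window = Inf` to disable). For dimers,
descriptors are computed and reported per monomer (two records per
structure), and the minimum inter-monomer site distance is recorded as an
auxiliary *interstrand separation* descriptor. `spread_statistics()` turns
the qualitative "spread of points" in distance–dihedral correlation plots
into ranges and standard deviations; `feature_vs_propensity()` computes the
Spearman rank correlation between first-feature temperatures and external
aggregation-propensity scores, plus the per-protein-group comparison (does
the amyloid-forming member show the lowest feature temperature in its
group?), excluding and listing sequences with no feature.

# Synthetic data: what it emulates and what it does not

`generate_funnel_db()` builds databases with the statistical structure the
analysis assumes: per funnel, a bottom minimum plus minima at exponentially
distributed energies above it (scale = `spread`, mimicking dense low-lying
spectra); entropy control through a per-funnel constant offset of the log
frequency product (the entropic funnel wins at high temperature, reproducing
the enthalpy/entropy competition); star-topology transition states inside
each funnel below a high inter-funnel barrier that alone connects funnel
bottoms; TS log-frequency products set to the endpoint mean minus a constant
(thermodynamics never uses TS frequencies, so this only exercises I/O). A
configuration whose inter-funnel barrier fails to exceed the intra-funnel
transition states is rejected.

With a target feature temperature, design proceeds in two stages. The
two-state closed form fixes the funnel-bottom gap
$\delta = x^*(g)\,k_BT_{\mathrm{target}}$, where $x^*(g)$ is the argmax of
the closed-form peak; the intra-funnel spread defaults to 5% of that gap so
the designed two-state transition dominates the drawn fine structure. The
drawn minima then still shift the exact peak by a few percent, so a second
stage solves a one-dimensional root problem — a rigid energy shift of the
second funnel — placing the argmax of the *exact* HSA curve of the generated
database on the target. The designed temperature in the manifest is thus a
property of the generated database itself, and recovery tests measure the
detector, not the design.

Conformer generators produce hairpin (U-turn), helical (positive twist:
radius 1.2, $100^\circ$/site, rise 0.45) and extended templates with
Gaussian site jitter, with per-sample truth descriptors; the dimer generator
places two jittered monomers at a set centroid separation in a random
relative orientation. What the synthetic data does **not** emulate: real
force-field energetics, realistic frequency spectra, correlated
energy–entropy disorder, or hexapeptide geometry beyond the descriptor
level. Green tests therefore demonstrate that the analysis machinery is
correct and calibrated on landscapes with the assumed structure — not that
any particular real sequence shows a feature.

# Numerical choices and degenerate inputs

* Temperature grids are log-spaced (`kbt_grid()`, default 400 points); peak
  locations are reported at grid resolution and the recovery tolerance in
  tests is two grid spacings.
* Probabilities and partition sums live in the log domain; $\sum_a p_a = 1$
  and $\sum_a dp_a/dT = 0$ hold to $10^{-12}$ across all test databases.
* Dedup tolerances ($10^{-6}$ energy, $10^{-3}$ RMSD) are conservative
  choices; the underlying protocol does not state values.
* Step-size adaptation in basin-hopping is off by default (fixed steps are
  exactly reproducible); temperature and step defaults used in validation
  (LJ runs at $k_BT$ 1.0–1.2, steps 0.35) are typical reduced-unit choices.
* Degenerate descriptors (vanishing middle bond, collinear sites), zero
  displacement off a saddle, empty databases, non-increasing grids,
  out-of-range site indices and dangling TS references all raise immediate,
  specific errors rather than propagating NaNs.
* Disconnectivity levels default to $\Delta E = (E_{\mathrm{top}} -
  E_{\mathrm{gm}})/50$; an internal node is drawn at the lowest threshold at
  which its basin is still merged, and the tree is invariant to input
  ordering of minima and transition states.
* Problem sizes used in the validation suite — LJ$_7$/LJ$_{13}$ with
  5,000/20,000 steps over 5 seeds, Müller–Brown budgets of 10 connection
  attempts, 50-minimum random databases, 20-seed recovery sweeps — were
  chosen as the smallest systems on which each property is
  non-trivially exercised.

# File formats and the command line

Stationary points travel as flat text in the `min.data`/`ts.data`
convention: per minimum `energy log_freq_product degeneracy` plus three
placeholder columns (moments-of-inertia slots in the ecosystem format,
written as 1.0 and ignored); per transition state the same plus the two
connected minimum ids. Ids are 1-based both in files and in R. Round-trips
are value-exact at 17 significant digits; all writes are atomic
(temp-file-and-rename). Coordinates use standard XYZ (2D serialised with
$z = 0$); curves and contribution sets are CSV; features, trees and
manifests are JSON; configs are YAML or JSON. See `docs/formats.md` in the
repository for schemas.

The exported `cli_entry()` (wrapped by the `inst/cli/elcv.R` Rscript)
dispatches `explore`, `connect`, `thermo`, `tree`, `descriptors`, `synth`
and `correlate` with global `--seed`, `--log-level` and `--config` flags;
exit codes are 0/2/1 for success/input error/internal failure, and all
stochastic commands are byte-reproducible from `--seed`.

# Known limitations

* The harmonic superposition approximation ignores anharmonicity and
  landscape regions not catalogued as minima; quantum partition functions
  and free-energy disconnectivity graphs are out of scope.
* Basin-hopping replicas run sequentially; there is no parallel execution.
* No permutational alignment in deduplication (see above).
* Melting-peak identification assumes the grid extends beyond the melting
  peak; on a truncated grid the highest-temperature peak is excluded even if
  it is not the true melting peak.
* Rate constants, committor analysis and kinetics beyond connectivity are
  not computed.
* The toy potentials are stand-ins: conclusions about real peptides require
  real force fields, which this package deliberately does not interface.
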