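---
title: "Characterizing phosphoryl-transfer mechanisms from reaction-path data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing phosphoryl-transfer mechanisms from reaction-path data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ircmech)
```

## The scientific problem

Protein kinases transfer the terminal (gamma) phosphate of ATP to a serine
or threonine hydroxyl. Electronic-structure calculations along an intrinsic
reaction coordinate (IRC) produce, for each frame of the path, a geometry,
an energy, Wiberg bond orders and natural-population-analysis (NPA) atomic
charges. Turning those raw series into mechanistic statements requires a
consistent analysis layer, and that layer is what `ircmech` implements:

* **Topology** -- is the path concerted (one transition state) or stepwise
  (two TSs flanking an intermediate)? What are the barrier and reaction
  energy?
* **TS character** -- is each TS associative ("tight", phosphorane-like) or
  dissociative ("loose", metaphosphate-like)?
* **Synchronicity** -- do the bond-breaking and bond-forming events (P--O
  rupture/formation, the proton transfers) peak at the same point of the
  reaction coordinate, or are they staggered?
* **Charge flow** -- how do the charges of the transferred PO~3~ group, the
  Mg^2+^ cofactor and the catalytic side chains evolve, and which bond
  events move charge between which fragments?

None of this needs a quantum-chemistry engine: the inputs are plain series
over frames, and every operation here is deterministic arithmetic on them.

## Data model and units

A `reaction_path` holds an atom table, an `n_atoms x 3 x n_frames`
coordinate array (Å), optional per-frame energies (kcal/mol only; Hartree
inputs are converted once at the boundary with 627.5095 kcal/mol per
Hartree, so no mixed-unit state can exist internally) and a strictly
increasing scalar reaction coordinate `xi`. Because IRC outputs do not
agree on an abscissa, `xi` defaults to the frame index `0..n-1` and can be
overridden by a sidecar table of arc lengths; all derivative-based analyses
differentiate with respect to whichever `xi` is present. Bond orders and
charges travel as long-format CSV tables keyed by frame, which is
unambiguous for sparse pair selections; a parser for the column-chunked
`Wiberg bond index matrix` text block of standard NBO output is provided
(the dialect is frozen in `inst/extdata/wiberg_block_example.txt`).
Indices are 1-based everywhere in the R API; the CSV dialects label frames
0-based externally and are remapped on read. Validation is strict: frame
counts must agree across channels, missing table cells are errors rather
than interpolation targets, and per-frame charge totals must be constant
within `charge_sum_tol` (default 0.01 a.u.) or a warning is recorded in the
report.

## Stationary points and mechanism class

`detect_stationary_points()` labels the first and last frames reactant and
product and accepts an interior local maximum as a transition state iff its
topographic prominence reaches `prominence_tol`. The default of
**0.5 kcal/mol** is deliberately small: stepwise phosphoryl-transfer
profiles can separate a TS from its flanking intermediate by only about
1 kcal/mol, and a coarser detector would silently merge exactly the feature
the analysis exists to find. Local minima between two retained TSs become
intermediates. Reported energies are always the raw energies relative to
the reactant, even when a moving-average window (odd, in frames; default
off) is used for detection. Adjacent equal-height maxima are both kept and
flagged as a "shoulder pair" instead of arbitrarily dropping one, because
on a potential-energy surface the stepwise/concerted distinction can sit
below the method's resolution. A profile with no interior maximum yields
pathway class `"none"` rather than an error.

```{r stationary}
xi <- seq(0, 10, by = 0.1)
e <- generate_path(path_preset("base_assisted_like"))$path$energy
detect_stationary_points(e, xi)
```

## Pauling associativity

The degree of associativity of a group-transfer TS is quantified with
Pauling's bond order--distance relation

$$D(n) = D(1) - 0.60\,\log_{10} n,$$

solved for the fractional bond number $n$ at
$D_\mathrm{avg} = (d_\mathrm{break}+d_\mathrm{form})/2$, the mean of the TS
distances from the transferred phosphorus to the leaving and entering
oxygens. $100\,n$ percent is the associative character. The logarithm is
fixed to base 10: with the 0.60 Å coefficient this is the form used for
P--O bonds in the phosphoryl-transfer literature, and it is the only base
that reproduces published fractional bond numbers from their printed
distances (base e does not). $D(1)$ defaults to 1.73 Å, the P--O
single-bond distance, and is overridable for other transferred groups.
`n` is carried at full precision and printed to 3 decimals, percentages to
1 decimal, matching the conventions of published tables.

```{r pauling}
pauling_bond_number(3.04, 2.10)   # a loose, metaphosphate-like TS
```

`classify_mechanism()` combines both analyses and additionally flags
metaphosphate-like intermediates: when bond orders are available the flag
requires both triad bond orders below 0.5; without them a geometric
fallback is used (both P--O distances beyond $D(1) + 0.60$ Å, i.e. bond
number below 0.1). The label `associative`/`dissociative` is the mean TS
associative percentage against the 50% midpoint.

## Synchronicity from bond-order derivatives

Bond-order derivatives $dB/d\xi$ are positive where bonds form or
strengthen and negative where they break or weaken, so their extrema locate
the bond events and the spread of the extrema measures asynchronicity.
Differentiation uses the three-point central formula valid on non-uniform
grids (exact for linear data), one-sided at the endpoints; optional
Savitzky--Golay pre-smoothing (window 5, degree 2 is the suggested setting
for noisy bond orders) is off by default because smoothing biases narrow
peaks.

Event detection applies two thresholds chosen to be scale-free: a peak must
reach `min_peak_frac` (default 0.2) of the *global* derivative magnitude --
a fraction rather than an absolute unit, so one default works across pairs
with very different net changes -- and the net bond-order change across the
event window must reach `min_net_change` (default 0.1), which is what
separates chemistry from noise-induced derivative spikes. The event window
is the contiguous region around the peak where $|dB/d\xi|$ holds half the
peak height with the peak's sign (brief dips of up to two points are
tolerated; pure-noise oscillations otherwise fragment one physical event
into several). Overlapping same-sign candidate windows on a pair are merged
into a single event, keeping the strongest peak.

The reported peak position is *not* the raw derivative argmax. For a
sigmoidal transition the derivative extremum coincides with the half-rise
point of $B(\xi)$ itself, and locating that point (median interpolated
crossing of the mid-level between the two plateaus) is markedly more robust
because differentiation amplifies observation noise while the half-rise
estimator averages over the whole transition. On noise-free logistic
transitions the two definitions agree to numerical precision.

Curve crossings (`find_crossings()`) are linearly interpolated sign changes
of $B_a - B_b$; a crossing of a forming and a breaking curve near a TS at
$B \approx 0.5$ says the two processes are synchronous and half-complete
there. The synchronicity span of an event group is
$(\max \xi_\mathrm{peak} - \min \xi_\mathrm{peak})$ normalized by the path
length, so 0 is perfect synchronicity.

## Fragment charges

`fragment_charge()` is exact per-frame summation over a fragment's atoms --
no smoothing, no interpolation, matching how published charge curves are
plotted. `charge_profile_report()` tabulates fragments at the stationary
points, reports reactant-to-minimum and reactant-to-product deltas, and
identifies monotone segments. `charge_event_correlation()` measures each
fragment's change across a `xi` window centred on each bond event (windows
reaching past the path are clipped with a warning), which is how a proton
transfer is attributed to the fragment it neutralizes. Charges are NPA by
convention but the scheme is metadata only; nothing in the arithmetic
depends on it.

## The synthetic-path generator

Because the upstream QM/MM data of a real study is not reproducible at desk
scale, the generator (`synthetic_path_spec()`, `generate_path()`) emulates
its statistical and mechanistic structure with known ground truth:

* **Bond orders**: additive logistic transitions per atom pair (sigmoidal,
  like real bond-formation curves), plus i.i.d. Gaussian noise (default
  sigma 0.005), clamped at zero.
* **Energies**: piecewise-cubic interpolation with zero slope at every
  prescribed stationary target, so the planted reactant/TS/intermediate/
  product energies are exact stationary points; Gaussian noise sigma
  0.02 kcal/mol by default.
* **Geometry**: the reactive triad (leaving O, P, entering O) is collinear
  with P--O distances derived from the noise-free bond orders through the
  inverted Pauling relation (clamped at $B < 0.01$); spectator atoms are
  static. This is sufficient for every implemented measurement -- the
  in-line attack angle is 180 degrees by construction and coordination
  shells are planted as explicit ligand distances -- and full 3D realism is
  deliberately out of scope.
* **Charges**: named fragment trends interpolated through control points
  and split equally within the fragment; all remaining atoms share the
  residual so each frame sums *exactly* to the system charge before noise.
  The default per-atom charge noise of 0.0003 a.u. models the rounding of
  population-analysis tables printed to three decimals, which is why
  generated paths respect the 0.01 a.u. conservation tolerance the data
  model enforces.
* **Determinism**: the RNG is pinned (Mersenne-Twister, inversion normal
  sampling); the same spec and seed reproduce the bundle bit for bit, and
  specs round-trip through JSON at 17 significant digits.

Four frozen presets cover the mechanistic space: a stepwise dissociative
path with a shallow metaphosphate-like intermediate (TS--intermediate gap
1.1 kcal/mol, barrier 14.3 kcal/mol, two slightly staggered late proton
transfers, peak offset 0.05 of the path, and the PO~3~ fragment planted at
exactly -1.00 a.u. at the intermediate -- the ideal metaphosphate charge);
a concerted dissociative path with a single high barrier and
proton-transfer events synchronized at the TS; an associative toy with a
tight TS (bond orders about 0.6); and a barrierless toy. Default problem
sizes are 101 frames and 61 atoms (a typical kinase QM-region size), which
keeps the full test suite in seconds.

What the generator does **not** emulate -- correlated noise, anharmonic
profile shapes, curvilinear geometry changes, thermal or solvent effects,
multiple conformers -- bounds what passing tests prove: they validate the
analysis arithmetic and its noise robustness under the stated noise model,
not the physics of any particular enzyme.

## Numerical choices and degenerate inputs

* Mg coordination cutoff 2.6 Å: conserved Mg--O contacts in kinase active
  sites sit at 1.9--2.4 Å while a decoordinated phosphate oxygen drifts to
  about 3 Å, so 2.6 Å separates the two populations; configurable.
* Hydrogen-bond criteria 3.5 Å / 120 degrees are common structural-biology
  defaults, exposed in the config since there is no community standard;
  donor--hydrogen pairs farther than 1.3 Å apart are not covalently bonded
  and are skipped with a warning.
* `atom_distance(i, i)` returns 0 (flagged in reports rather than
  erroring); coincident points in an angle are an error because the
  geometry is undefined.
* Distance tables are rounded to 2 decimals for display, with the
  full-precision matrix kept in an attribute.
* Fewer than 3 frames cannot support stationary-point or derivative
  analysis and raise immediately; a monotone profile is not an error but a
  "none"-class mechanism.
* Combined reports embed the package version and an MD5 of the resolved
  config, and contain no timestamps, so identical inputs serialize
  byte-identically.

## Known limitations

The in-line angle is only meaningful if the trajectory geometry is
physical; the generator's collinear triad trivially satisfies it. The
half-rise peak estimator assumes transitions are approximately symmetric in
$\xi$; strongly asymmetric transitions would bias it toward the steep side
(the derivative argmax is still reported through the event's `frame`
column). Free-energy effects, a second Mg^2+^ cofactor, and the upstream
electronic-structure steps (IRC tracing, NBO computation, pKa estimation)
are out of scope by design: this package analyzes reaction-path data, it
does not produce it.
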