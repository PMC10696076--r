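---
title: "Chromophore networks and energy-transfer geometry in phycobilisomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromophore networks and energy-transfer geometry in phycobilisomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbsnet)
```

## The problem

Phycobilisomes (PBS) harvest light with hundreds of bilin chromophores —
linear tetrapyrroles such as phycocyanobilin (PCB) covalently bound to
phycobiliprotein subunits — and funnel the excitation through the complex to
terminal emitters that hand it to the photosystems. Two geometric quantities
dominate the efficiency of each transfer step between a donor and an
acceptor bilin: their separation and the mutual orientation of their
transition dipoles. Given a coordinate model of a PBS (or any
pigment-protein assembly), `pbsnet` reduces each bilin to a point anchor,
measures these quantities, and turns them into transfer-pathway and
packing-comparison analyses.

## The measurement model and its assumptions

**Anchors.** Each bilin is represented by its C10 atom, the central methine
carbon between pyrrole rings B and C — a standard single-point proxy for the
centre of the conjugated system. All inter-bilin distances are Euclidean
distances between anchors. The anchor atom name is configuration, not code:
chemical-component dictionaries name this carbon differently across
depositions, so `ligand_config()` ships `"C10"` as an overridable default
and the component codes to treat as chromophores are likewise configurable.

**Orientation factor.** For unit transition dipoles $\hat\mu_D$,
$\hat\mu_A$ and the unit inter-anchor vector $\hat R$,

$$\kappa = \hat\mu_D\cdot\hat\mu_A -
  3(\hat\mu_D\cdot\hat R)(\hat\mu_A\cdot\hat R), \qquad
  \kappa^2 = (\cos\theta_\tau - 3\cos\theta_D\cos\theta_A)^2 ,$$

where $\theta_\tau$ is the angle between the dipoles and $\theta_D$,
$\theta_A$ the angles each dipole makes with the donor–acceptor line. The
angular form is the algebraic expansion of the vector form; the package
implements both and tests their agreement to $10^{-10}$ over $10^5$ random
configurations. $\kappa^2$ ranges over $[0,4]$ (4 for collinear
head-to-tail dipoles, 1 for parallel dipoles perpendicular to the
separation, 0 for mutually orthogonal dipoles both perpendicular to it) and
averages $2/3$ over isotropic orientations. This is the point-dipole
approximation: it ignores the extended shape of the conjugated system, which
matters at separations comparable to the chromophore length (~10 Å and
below).

**What is deliberately not computed.** `forster_edge_weight()` is
proportional to $\kappa^2 / D^6$ only — the geometric part of a Förster
rate. No spectral-overlap integral, site energies, or refractive screening
are modelled, so no quantity in physical rate units is ever reported, and no
claim is made about delivery efficiency to the photosystems.

**Dipole vectors.** Proper transition dipoles come from quantum-chemical
calculations and are consumed as a sidecar table
(`apply_dipole_table()`). When none are supplied, `estimate_dipoles()`
substitutes the first principal axis of each bilin's conjugated-system heavy
atoms. This geometric axis is a stand-in: it captures the long axis of the
π system, which for linear tetrapyrroles is a reasonable first approximation
of the transition-dipole direction, but it carries no information about the
electronic structure. Its sign is inherently ambiguous; the package orients
it so the dot product with the direction towards a configurable reference
atom is positive. $\kappa^2$ is sign-invariant, so the convention affects
only the reported $\theta$ angles (which may flip to their supplements).
When neither supplied nor estimated dipoles exist, graph weighting falls
back to the isotropic $\kappa^2 = 2/3$, and outputs tag the provenance
(`supplied` vs `geometric_axis`).

## Pathways: one rule, two readings

Pathways are deduced on an undirected graph whose edges join chromophore
pairs within a distance cutoff. "Shortest distances among bilin pairs" is
genuinely ambiguous between two optimisation targets, so both are exposed
rather than baking one in:

* `min_total` — minimise the summed step distance (Dijkstra on edge
  distances); the default.
* `min_max_step` — minimise the longest single hop (bottleneck search by
  thresholding the sorted edge distances), reporting the summed-shortest
  route among those attaining the optimal bottleneck.

Since single-step transfer probability falls off as $D^{-6}$, the longest
hop usually dominates a route's throughput — which is why the bottleneck
objective is offered — but the summed objective matches the intuitive
reading of "shortest path" and is what the default reports. On strongly
structured assemblies (e.g. the synthetic chains below) both agree on
topology and differ only in tie handling. Terminal emitters are always
user-designated site sets: in organisms that lack the specialised ApcD/ApcF
subunits, terminal emitters cannot be inferred from subunit identity, so the
package never guesses.

Determinism: ties anywhere (minimal pairs, path choice among equal-cost
terminals) are broken lexicographically on (distance rounded to $10^{-6}$ Å,
site-id pair), so identical inputs give byte-identical reports.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| edge cutoff | 45 | Å | comfortably above the longest functional inter-hexamer bilin step seen in chain-packed PBS (37 Å) while pruning the quadratic pair set; configurable everywhere it appears |
| anchor atom | `"C10"` | — | the bilin C10 methine; overridable per component dictionary |
| default $\kappa^2$ | 2/3 | — | isotropic average, used only when no dipoles exist and flagged as such |
| alt-loc policy | highest occupancy, ties alphabetical | — | deterministic and conventional |
| printed precision | 0.1 | Å | distances in human-readable reports; machine outputs keep full precision |

## The synthetic generator

`make_assembly()` builds toy assemblies whose every geometric property is
known in closed form, so the analysis stack can be validated end-to-end
(write fixture → parse → label → measure) without any downloads.

A hexamer is six protomers at 60° azimuths on a toroid (default radius
35 Å). Each protomer carries one alpha chromophore on the outer rim and, by
default, two beta chromophores inset 8 Å per level and rotated 20° per
level, all in the hexamer plane — a deliberately flat caricature of the real
two-layer (αβ)₆ disc. Chromophores are written as three-atom pseudo-bilins
(axis-start, C10 anchor, axis-end at ±1.8 Å along the true dipole): the
minimal geometry that exercises anchor extraction and axis fitting; a full
tetrapyrrole adds nothing testable.

* **Rod packing** translates hexamers along the toroid axis
  (default spacing 30 Å). With zero stagger the junction is a pure
  translation, so *every* site has its translate at exactly the spacing: the
  minimal contact is the spacing with multiplicity $6\times$
  (chromophores per protomer) $= 18$, and the junction is a many-contact
  *network* by construction.
* **Chain packing** translates hexamers laterally. With the default offset
  $2R + 37$ Å along $x$, the facing rim chromophores form a single closest
  contact of exactly 37 Å — the inset and rotation of the beta sites keep
  every other cross-junction pair above the 45 Å cutoff — so each junction
  is a *single-pathway* contact by construction, echoing the staggered chain
  packing of paddle-shaped PBS against the coaxial rod packing of
  hemidiscoidal PBS.

Dipole modes (`tangent`, `radial`, `axial`) give each site a unit dipole in
a known direction; for the chain's facing contact, tangent dipoles are
antiparallel and perpendicular to the separation, so the contact's
$\kappa^2$ is exactly 1. Optional Gaussian jitter (default 0) is the only
stochastic element; the seed makes fixtures byte-identical.

What the generator does **not** emulate: protein atoms and sterics, the
two-layer hexamer geometry, realistic bilin conformations, linker-bound
chromophore environments, or quantum-chemical dipoles. Tests passing on
these fixtures therefore validate the *measurement machinery* — parsing,
distance/orientation arithmetic, graph search, bookkeeping — not the
biological interpretation of any particular deposited structure.

## Assembly census

`census()` is exact integer arithmetic over a declarative schema
(component × copies × per-subunit chromophore counts). The shipped
`ap_pbs_schema.tsv` describes a paddle-shaped PBS: 72 allophycocyanin αβ
protomer equivalents in the core (the two chromophorylated ApcE domains each
counted as an alpha-equivalent — required for the core bilin count of
$72\times2 = 144$ to close), 72 phycocyanin protomers in the periphery
($72\times3 = 216$ bilins), 360 bilins in all. The polypeptide total is
*schema-dependent*, not a shipped constant: the core-membrane linker domain
accounting and the CpcD copy number admit more than one defensible
bookkeeping, and the shipped schema's choices sum to 310. Users can close
the books differently by editing `polypeptides_per_copy`.
`validate_against_model()` reports (rather than errors on) schema/model
disagreements, since deposited models legitimately omit components too
dynamic to build.

## Numerical choices and degenerate inputs

* `acos` inputs are clamped to $[-1, 1]$, avoiding NaN at exactly parallel
  or antiparallel limits.
* Coincident donor/acceptor anchors make $\hat R$ undefined and raise an
  error; likewise a requested inter-group distance between overlapping site
  sets.
* PDB fixed-width output rounds coordinates to $10^{-3}$ Å; round-trip
  tests tolerate exactly that, and fixture-based distance checks use
  $10^{-2}$ Å.
* A ligand lacking its anchor atom stays in the model with a warning record
  (so counts are conserved) and errors only when a distance is actually
  requested from it.
* Multi-model files use the first model block with a warning; alternate
  locations collapse before site construction.

## Problem sizes

The test suite and acceptance script run at sizes chosen to make every
oracle exhaustive: brute-force pair scans up to 500 sites, exhaustive
path enumeration on graphs of at most 8 nodes over 1000 random instances,
$10^5$ random dipole pairs for the two-form agreement, $10^4$ samples for
the isotropic mean, and fixtures of 2-5 hexamers (36-90 chromophores).
These are the package's validation conditions; the analysis functions
themselves handle full-size models (hundreds of chromophores) without
special handling.

## Limitations

* The mmCIF reader covers the `atom_site` loop of ordinary coordinate
  files, not the full dictionary (no semicolon-delimited multi-line values
  inside `atom_site`).
* Multi-file assemblies are assumed co-registered in one frame; the package
  checks only that chain ids do not clash when merging.
* Orientation factors from geometric axes are approximations; analyses that
  depend on the *value* of $\kappa^2$ for specific pairs (rather than its
  invariants) need supplied transition dipoles.
* Reproducing published inter-group distances for specific deposited
  structures requires downloading those coordinate files and a label map
  tying their chain ids to hexamer nomenclature; the corresponding
  acceptance test documents the expected manifest and fails informatively
  when the files are absent.
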