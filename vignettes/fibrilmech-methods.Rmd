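---
title: "Coarse-grained mechanics and thermodynamics of cross-beta fibrils with fibrilmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained mechanics and thermodynamics of cross-beta fibrils with fibrilmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilmech)
```

## The model

`fibrilmech` implements a structure-based (Go-like) coarse-grained model of
protein fibrils. Each amino acid is one bead at its C-alpha position, and the
potential energy is

$$
E = \sum_{\mathrm{bonds}} K_r (r - r_0)^2
  + \sum_{\mathrm{angles}} K_\theta (\theta - \theta_0)^2
  + \sum_{\mathrm{dihedrals}} K_\phi (\phi - \phi_0)^2
  + \sum_{\mathrm{native}} 4\epsilon\!\left[\left(\tfrac{\sigma_{ij}}{r_{ij}}\right)^{12}
    - \left(\tfrac{\sigma_{ij}}{r_{ij}}\right)^{6}\right]
  + \sum_{\mathrm{non\text{-}native}} V_{\mathrm{rep}}(r_{ij}),
$$

with every equilibrium value ($r_0$, $\theta_0$, $\phi_0$, $r_{ij0}$) taken
from the input structure, so the native conformation is the exact minimum of
every term. Defaults are $K_r = 100$ kcal/mol/A$^2$, $K_\theta = 45$
kcal/mol/rad$^2$, $K_\phi = 5$ kcal/mol/rad$^2$ and a uniform contact depth
$\epsilon = 1.5$ kcal/mol; $\sigma_{ij} = r_{ij0}/2^{1/6}$ places each
Lennard-Jones minimum at the native separation. The dihedral term is harmonic
in the angle difference wrapped to $(-\pi, \pi]$.

Native contacts come from the heavy-atom *overlap criterion*: each heavy atom
carries a van der Waals sphere (Tsai-style packing radii, shipped as a
configurable table keyed by atom class, 1.80 A fallback) enlarged by a factor
1.24; two residues form a contact between their C-alpha beads when any pair
of their spheres overlaps (strict inequality). Within a chain a sequence
separation $|i - j| > 4$ is required; between chains no separation rule
applies. Contacts are classified by the fibril frame: *intrachain* (same
chain), *interchain* (different chains, same stacking layer — side-by-side
protofilaments) and *intersheet* (different layers along the fibril axis).

Non-native pairs (excluding 1-2, 1-3, 1-4 bonded neighbours) interact through
a purely repulsive wall: the repulsive branch of a Lennard-Jones whose
shifted minimum sits exactly at $r_\mathrm{cut} = 4$ A, i.e.
$\sigma_\mathrm{rep} = r_\mathrm{cut}/2^{1/6}$, zero with zero slope at and
beyond the cutoff. Pairs that share a native contact are governed solely by
their own Lennard-Jones wall; the model leaves them out of the non-native
sum, since adding a second wall on top of the $r^{-12}$ branch would double
count the same excluded volume.

Internal units: length in Angstrom, energy in kcal/mol, time in $\tau$
(of order 1 ns), temperature in $\epsilon/k_B$ with room temperature
calibrated to $0.35\,\epsilon/k_B$. Stress and moduli convert by
1 kcal/(mol A$^3$) = 6.9477 GPa; $\epsilon/k_B \approx 754.8$ K is available
as a reporting convenience only.

## Dynamics

Overdamped (inertialess) Langevin dynamics with the Euler-Maruyama update
$x \leftarrow x + (F/\gamma)\,dt + \sqrt{2 k_B T\, dt / \gamma}\,\xi$,
friction $\gamma = 2\,m/\tau$ per bead. The default step is $dt = 0.002\,\tau$:
the stiffest modes are pseudo-bond stretches with curvature $2 K_r$ acting on
a relative coordinate, whose explicit-update stability product
$2\,(2K_r)\,dt/\gamma$ reaches unity near $dt = 0.005\,\tau$; the default
keeps a threefold margin so that anchor springs and repulsive walls never
push a mode over the limit. A per-step displacement above 0.5 A aborts with
an instability error rather than integrating garbage. In temperature scans
the step additionally shrinks as $\min(1, 0.5/T)$ above $T = 0.5\,\epsilon/k_B$,
because beads penetrate repulsive walls to depths where the restoring force
scales with $k_B T$. Randomness comes from R's RNG stream, so any run is
bitwise reproducible under `set.seed()`.

The non-native repulsion uses a Verlet neighbour list (2 A skin) rebuilt
whenever any bead has moved more than half the skin, which makes results
independent of the rebuild schedule.

## Deformation protocols

All three protocols drive the system at constant speed and record
interval-averaged restraint forces (averaging between recording points
suppresses thermal force noise without touching the dynamics).

**Tensile.** Beads within a 5 A axial slab at each fibril end are selected;
the bottom slab is tethered by stiff springs ($k_\mathrm{bottom} = 100$
kcal/mol/A$^2$) to its equilibrated positions and each top-slab bead to a
target point moving along the axis at $v_\mathrm{pull}$ with soft springs
($k_\mathrm{top} = 0.1$ kcal/mol/A$^2$; the printed units kcal/mol/A are
read as harmonic spring constants kcal/mol/A$^2$ for dimensional
consistency). Strain is $(L - L_0)/L_0$ with $L$ the axial distance between
the anchor-set centroids and $L_0$ its value after a 100 $\tau$
equilibration; stress is the summed tether force projected on the axis over
the cross-section area, the convex hull of all beads projected perpendicular
to the axis (record-mean area by default, as its fluctuations are small).

**Shear.** The bottom plane is a transverse slab (low end of the
least-variance direction perpendicular to the axis, i.e. the face the fibril
rests on); the top plane is a configured residue segment replicated over the
remaining chains. Top tether targets translate along the axis; strain is
$x/y$, the measured axial displacement of the top-plane centroid over the
transverse distance between plane centroids. The reported plane area is the
convex hull of the top-plane beads projected on the plane spanned by the
axis and the widest perpendicular direction — a stated convention, since a
"plane area" is not otherwise well defined for a bead set.

**Indentation.** The fibril is rotated so its axis lies along x and its
thinnest direction along z, and rests on a repulsive base plane
$V \propto z_0^{-10}$. A rigid sphere (radius $R_\mathrm{ind}$, default
100 A) descends at $v_\mathrm{ind}$ above the axial midpoint
($L = 0.5\,L_0$); the tip-bead interaction is a divergent inverse-10th-power
law in the surface gap, matching the base plane, so no adhesion is possible.
Both amplitudes are set so the potential equals room-temperature $k_B T$ at
a 1 A gap. Depth $h$ is measured from the first tip-particle interaction
(interval-mean tip force crossing 0.1 kcal/mol/A). The transverse modulus
comes from the Hertz relation
$F = \tfrac{4}{3}\,\tfrac{Y_T}{1-\nu^2}\,\sqrt{R_\mathrm{ind}}\,h^{3/2}$
with $\nu = 0.5$ (the 4/3 prefactor is adopted explicitly), and a free
exponent $n$ in $F \propto h^n$ is fitted independently over the same
window.

Any pseudo-bond stretched past $3 r_0$ truncates the record with a rupture
flag, so post-failure frames never enter a fit.

## Fitting noisy force records

Thermal noise enters both the stress and the measured strain, so all fits
first average the scatter into equal-count bins ordered by the abscissa
(25 bins by default). The linear window defaults to the largest initial
interval whose binned fit keeps $R^2 \ge 0.99$; when noise keeps every
candidate below threshold the full recorded range is used — the protocols
already stop inside the intended regime (`max_strain`, `max_depth`) — and an
$R^2 < 0.9$ attaches a poor-fit warning rather than failing. Replicas are
pooled before binning; the standard error of a pooled slope comes from a
seeded bootstrap over replicas (1000 resamples by default).

## Thermodynamic characterization

Temperature scans run, per temperature, an equilibration ($10^3\,\tau$ by
default) followed by production ($10^4\,\tau$ by default; both scalable),
on a grid defaulting to 35 uniform temperatures in
$[0.1, 0.7]\,\epsilon/k_B$. A production frame is *native* when every native
contact is shorter than 1.5 times its native length (the factor is
configuration and reported in outputs; the criterion is the standard
all-contacts-formed convention, chosen because no operational definition is
otherwise fixed — an RMSD-based criterion can be substituted through the
same interface). $P_0$ is the fraction of native frames and the folding
temperature $T_f$ interpolates the $P_0 = 1/2$ crossing linearly, reporting
the lowest-temperature crossing with a warning if there are several. RMSD
uses least-squares rigid-body superposition (SVD/Kabsch construction, the
global optimum); RMSF is the per-residue fluctuation about the mean
superposed structure.

## The synthetic fibril generator

`generate_synthetic_fibril()` builds idealised cross-beta fibrils so the
whole pipeline runs without any downloaded structure: `n_layers` stacked
layers with a 4.8 A axial rise, optionally several protofilaments spaced
9 A apart. Each chain folds into a two-strand beta-arch (arms are extended
strands with a 3.8 A C-alpha step and a pleat zigzag so no three
consecutive beads are collinear and dihedrals stay well defined). An
extended-strand mode exists, but such a chain cannot form intrachain
contacts, which is why the arch is the default.

Each body residue carries three pseudo-atoms chosen to distribute contact
density the way real cross-beta chemistry does: the C-alpha trace, a
C-beta side chain pointing into the steric-zipper interfaces between arms
and protofilaments (side chains alternate perpendicular to the sheet
plane), and a backbone-carbonyl O along the stacking axis, bridging
adjacent layers like the inter-strand hydrogen-bond ladder. With a single
bridging pseudo-atom per residue the axial ladder carries roughly one
contact per residue per interface while the lateral zippers pack tightly —
the balance that real fibrils show. An earlier two-atom variant (C-alpha
plus one side group doing double duty as the axial bridge) overloaded the
stacking direction with contacts and inverted the lateral/axial stiffness
balance. Optional disordered tails (`n_tail`) drape past the arch with
side groups facing the body, so the first tail residues form a few weak,
singly-coordinated contacts and the rest stay contact-free.

A seed jitters every coordinate by at most 0.05 A to break exact
degeneracies; the same seed reproduces the fixture bitwise.

The fibril frame (axis and layer assignment) uses the principal eigenvector
of the chain-centroid covariance rather than of the full C-alpha gyration
tensor: collapsing each chain to its centroid removes intra-chain spread,
which on short fibrils (few layers, long chains) would otherwise dominate
the gyration tensor and point the "axis" along the chains. Layers are
1-D gap clusters of centroid projections (threshold 2.4 A, half a typical
rise), and the axis is oriented so projections increase with layer index.

## What the tests show — and what they cannot

The test suite validates the machinery on closed-form cases (numerical
gradients, equipartition, springs-in-series moduli, forward-generated Hertz
curves, brute-force hulls and contact maps) and checks qualitative
signatures on the synthetic fixtures: intersheet contacts stretch and
interchain contacts shorten under tension; force-depth curves are monotone
at small depth; native-state probability falls with temperature; a
size-matched comparison between a rigid two-protofilament stack and a
single protofilament with a looser (5.4 A) rise and disordered tails gives
a higher folding temperature for the stack. For that comparison the systems
are deliberately size-matched because the all-or-none native criterion
multiplies over contacts, so raw contact count would otherwise dominate any
stability ordering.

Synthetic fixtures are idealised: uniform residues, perfect symmetry, three
pseudo-atoms per residue. Passing these tests shows the pipeline measures
what it claims on controlled geometry; it does not certify absolute moduli
for any particular experimental fibril, which depend on the real contact
map of the deposited structure and on the production-scale protocol
(50 replicas, $v = 5\times10^{-4}$ A/$\tau$, 10 nm tips) rather than the
desk-scale settings used in the tests (fixtures of 10-12 layers, speeds
4-20 times faster, tip radii 20-30 A matched to fixture size, indentation
depths matched to the production protocol's fraction of fibril thickness).

## Numerical choices and degenerate inputs

Angle forces guard the $\sin\theta \to 0$ singularity (collinear triplets
contribute no dihedral force, and the collinear dihedral is skipped);
equilibrium angles from exactly collinear traces are $\pi$ to within acos
conditioning ($\sim 10^{-8}$). Convex hulls require three non-collinear
projected points and raise degenerate-geometry errors otherwise; a tensile
record of a degenerate (linear) system can still be analysed by declaring
the cross-section area. Multi-model PDB files use model 1 only; alternate
locations other than blank/"A" are dropped; residues without a C-alpha are
dropped with a warning. Boundary overlaps (distance exactly at the enlarged
radius sum) are not contacts; the set has measure zero.
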