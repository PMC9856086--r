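---
title: "Ring-penetration repair: model, biases and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ring-penetration repair: model, biases and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringfree)
```

# The artifact and its symptom

A ring-penetration artifact places a bonded atom pair on opposite sides of
a small closed ring, so the bond segment crosses the ring's face. Under a
classical force field this configuration is a local energy minimum: the
Lennard-Jones cost of dragging an atom through the ring face exceeds the
harmonic cost of stretching the bond, so minimization *extends* the bond
instead of resolving the threading. The detectable symptom is therefore a
bond whose measured length exceeds its force-field equilibrium length
`b0` by a large margin. `ringfree` flags a bond when
`length - b0 >= cutoff`, with `cutoff = 0.4` Å by default. The deviation is
signed internally (compressed bonds are negative) but only stretching is
ever flagged — compression is not a piercing symptom. A legacy mode flags
bonds by absolute length > 1.65 Å instead; it is off by default because
that rule misflags ordinary bonds to third-row elements, which is exactly
why a parameter-aware cutoff is used.

The symptom detector is cross-checked by a purely geometric oracle:
`findPiercings()` fan-triangulates each chordless ring of size 3–7 about
its centroid and tests every bond that shares no atom with the ring against
the fan with a closed (boundary-inclusive) segment–triangle test. Fan
triangulation about the centroid is watertight for planar aromatics and
puckered hexose chairs alike. The size cap of 7 reflects what "small ring"
means here: aromatics and sugar rings. Larger macrocycles arise legitimately
(e.g., through polymerization) and are not artifacts, so they are excluded
by construction. Chordless cycles, rather than all cycles, are enumerated
so each minimal face is tested exactly once — the 10-membered perimeter of
a fused bicyclic is shortcut by the fusion bond and is not a face a bond
can meaningfully pierce without also piercing one of the two six-rings.

# The energy model

The internal model implements the terms the repair actually needs:

* harmonic bonds `k_b (b - b0)^2` and angles `k_θ (θ - θ0)^2`, cosine
  dihedrals `k_φ (1 + cos(nφ - δ))`, harmonic impropers — CHARMM
  conventions, parameters read from PRM/RTF/STR files;
* Lennard-Jones 12-6 with Lorentz–Berthelot-style CHARMM combination
  (`ε_ij = sqrt(ε_i ε_j)`, `rmin_ij = rmin_i/2 + rmin_j/2`) and Coulomb
  `332.0636 q_i q_j / (ε_r r)`;
* a CHARMM switching function taking both nonbonded terms smoothly to zero
  between 10 and 12 Å; no periodic images and no Ewald treatment — repair
  runs are non-periodic, and a relative dielectric of 80 stands in for the
  screening a solvated system would provide;
* 1–2 and 1–3 pairs excluded; 1–4 pairs interact at full strength.
  Special 1–4 scaling tables, NBFIX overrides, Urey–Bradley and CMAP terms
  are omitted. These refinements matter for accurate dynamics but are
  negligible for artifact-removal geometry; for production force fields
  this is a documented approximation of the energy, not of the detection
  (detection uses only the bond table).

Forces are the exact analytic negative gradient of the implemented energy;
the test suite verifies every term, including all biases, against central
differences at 10⁻⁴ relative tolerance.

## Soft-core treatment

During a biased round, atoms near a target bond are "alchemically flagged":
any pair with at least one flagged atom interacts at the effective distance
`r_eff = sqrt(r² + δ²)` in both LJ and Coulomb. The energy is then finite
down to `r = 0` and an atom can pass through a ring face at bounded cost.
A single softened state with one parameter realizes the alchemical idea —
the workflow only ever needs a softened landscape, never a free-energy
estimate, so there is no λ staging. Both LJ and electrostatics are
softened; softening only LJ would leave bare Coulomb singularities between
flagged partial charges.

The default is `δ = 2.5` Å. This value matters: for a carbon–carbon pair
(`rmin ≈ 4` Å) the residual barrier at contact is
`ε (rmin/δ)^12 ≈ 10^7` kcal/mol at `δ = 1` — no passage at all — versus
roughly 10 kcal/mol at `δ = 2.5`, which biased minimization crosses
easily. The certifying round runs with no flagged atoms, so the softening
never contaminates the converged result.

# The repair loop

Each stage minimizes for `stepsPerStage` steps (default 500) under the
current model, measures the stretch report, records the longest bond, and
branches:

1. max deviation ≥ cutoff → biased round;
2. otherwise, if the previous minimization was perturbed → one unperturbed
   certifying round;
3. otherwise → converged.

The loop is capped at `maxStages = 100`; a clean structure takes the
minimum path — one unperturbed stage — and never builds a bias. Reaching
the cap returns a nonzero exit status with all outputs still written.

Targets are the *worst* bonds only: every flagged bond within `window`
(default 0.1 Å, closed at the boundary) of the maximum deviation.
Attacking all long bonds at once destabilizes complex tangles; attacking
the worst first lets secondary long bonds surface on later iterations.

Per target bond, the biased round attaches:

* **Perpendicular pulls** — `perpendicularTarget()` draws a random
  in-plane direction and returns two opposite points 10 Å from the bond
  midpoint in the plane normal to the bond. Both bond atoms are pulled
  toward the *same* one of them (half-k harmonic point restraints,
  `pointK = 10` kcal/mol/Å²). This was a genuinely open design point: an
  earlier variant pulled the two atoms toward *opposite* targets, which
  merely elongates the bond symmetrically — its midpoint, and hence the
  threading segment, never leaves the ring face, and the benzene–ethane
  fixture stalls indefinitely. A shared target shears the whole bond
  sideways out of the ring, and the fixture resolves in one biased round.
* **Separation bias** — a one-sided harmonic (`sepK = 10` kcal/mol/Å²)
  on the mass-weighted center distance between the bond pair and the
  nearby ring neighborhood (rings with an atom within `nearbyRadius = 4` Å
  of the midpoint, expanded two bond hops), active only below the 10 Å
  target: the bias pushes apart "up to" the target and never pulls back.
  At exactly coincident centers the separation direction is undefined; the
  energy stays continuous there and the force is zero, with the other
  biases breaking the tie (an early implementation that skipped the term
  entirely at coincidence dug a discontinuous hole in the energy right
  where the pierced fixture sits, trapping the minimizer).
* **Density hill** — a repulsive Gaussian at the midpoint,
  `height·exp(-|r-c|²/(2(radius/2)²))` with `hillHeight = 20` kcal/mol and
  `hillRadius = 4` Å, felt by all atoms except the bond pair: it pushes
  the tangled surroundings out of the region.
* **Flagging** — the bond atoms plus every atom within 4 Å of the midpoint
  are softened.

The 4 Å "nearby" radius spans a pierced six-ring's far side without
swallowing the wider neighborhood. The bias magnitudes are starting
points, not critical values, because of **escalation**: if the same bond
remains the longest across successive iterations, all of its force
constants double (`k·2ⁿ` after n repeats). Escalation keys on bond
identity, not contiguity — a bond that dips below the cutoff during a
soft-core round, passes an unperturbed check, and re-emerges long resumes
its escalated constants. When a different bond takes over as longest, the
old record and its biases are dropped.

The random in-plane pull direction is the loop's only stochastic element,
driven by the run seed; a fixed seed reproduces the full trace and final
coordinates exactly.

# Chirality preservation

The biasing forces are large enough to push substituents through planarity,
inverting stereocenters — an artifact *worse* than the one being repaired,
because a flipped sugar center leaves no long bond behind and is nearly
invisible to inspection. By default every *potential* stereocenter is
restrained: any atom with exactly four bonded neighbors whose branches are
pairwise distinguishable at the first shell (substituent type plus the
sorted types of its own neighbors). This deliberately over-includes —
a restraint on a non-center is harmless, so no CIP machinery is needed —
while methane-like centers with identical branches are skipped. Each
center gets a harmonic improper over (center, s1, s2, s3) with
`chiralityK = 50` kcal/mol/rad², targeting the improper angle *measured in
the input structure*: the tool preserves whatever stereochemistry it was
given, correct or not, rather than imposing an idealized one. The
restraints stay active through biased and certifying rounds alike.

The limits of protection are real and worth stating: the restraint
capacity is bounded by `k·Δφ²`, so a center held by a sufficiently strong
steric press will still invert — the shipped adversarial cage fixture does
exactly that by construction. What the default protects against is the
transient, bias-induced force spike of a normal repair, which the
glyco-peptide fixture demonstrates (all nine centers preserved through a
full repair).

# The minimizer

Conjugate gradient (Polak–Ribière+ with periodic restarts) with a
backtracking Armijo line search, displacement capped at 0.3 Å per step.
Only energy-decreasing steps are accepted, so the per-stage energy trace
is non-increasing and the whole run is deterministic given its inputs.
Termination is by step budget, gradient infinity-norm below 10⁻⁴
kcal/mol/Å, or a stalled line search. A gradient-based minimizer (rather
than anything inertial) is important for the local-minimum demonstrations:
it cannot jump the ring barrier by momentum, which is precisely the trap
the biases exist to open.

# What the fixtures emulate — and what they do not

The generators build the smallest systems exhibiting each phenomenon, with
an embedded minimal CHARMM-format parameter set (aromatic/aliphatic
carbon, ether/ring/hydroxyl oxygen, amide nitrogen, carbonyl pair,
hydrogens, one bulky LJ type) that is written out and re-read through the
real parser, so fixtures exercise the same code paths as user files.
Hydrogens are explicit everywhere: piercing geometry and LJ contacts
depend on them.

* `makePiercedBenzeneEthane()` — the canonical single piercing: a
  two-carbon unit threaded through an aromatic ring, bond midpoint at the
  ring centroid, starting 0.67 Å past equilibrium. Plain minimization
  *increases* the stretch to ~1.65 Å and keeps the piercing: the
  local-minimum signature.
* `makeToyPolymer(nUnits, nPiercings, seed)` — a chain of aromatic
  six-ring units with two-carbon linkers, where the first `nPiercings`
  rings are threaded by the linker two units further along the chain. The
  threaded bond is ≥ 5 bonds from the ring it pierces and tethered on both
  sides of the ring plane, so it cannot swing out during plain
  minimization (an adjacent-linker variant proved escapable and was
  rejected — its piercings evaporated under plain minimization, which
  defeats the purpose of a trap fixture). Requests above `nUnits - 2`
  piercings are geometrically infeasible and error. The seed only jitters
  coordinates by < 0.005 Å to break exact symmetry.
* `makeGlycoPeptideToy(seed)` — a three-residue peptide-like backbone with
  two puckered pyranose rings on ether linkages; the second ring is built
  around the middle residue's CA–CB bond, so a backbone-adjacent bond
  pierces a sugar ring. Nine detectable stereocenters (three per ring,
  one per α-carbon).
* `makeStrainedChiralToy()` — the adversarial cage: a bulky apex bonded
  through three bridges to all three heavy substituents of a stereocenter,
  pressing on the center's hydrogen with no lateral escape path, so an
  unrestrained run inverts the center silently.

Every fixture is self-validating: construction fails unless the geometric
oracle and stereocenter detector reproduce the manifest counts.

What the fixtures do *not* emulate: system scale (tens of atoms versus the
10⁵–10⁶-atom assemblies the method is meant for), solvent, full production
force fields (CMAP, NBFIX, 1–4 scaling), and the density of simultaneous
piercings in heavily glycosylated proteins. Passing tests demonstrate the
mechanism — detection, trapping, biased release, certification, chirality
protection — not wall-clock performance or force-field fidelity at scale.
Problem sizes were chosen so the full suite and the acceptance script each
run in well under a minute on one core: 20–76 atoms per fixture, repair
runs converging in ~3 stages of 500 minimizer steps.

# Numerical choices

* Segment–triangle tests are closed with a 10⁻⁹ boundary tolerance, so a
  fan of triangles sharing edges has no gaps; a segment through a shared
  edge may hit two triangles, which is harmless because events are
  recorded per (bond, ring). Degenerate triangles (area ≤ 10⁻⁸ Ų) are an
  error, not a silent miss.
* Ties for the longest bond break by smaller first atom index, so repeated
  runs target identically.
* The target-selection window is closed (`deviation ≥ max - window`).
* Chirality signs within 10⁻⁶ Å³ of coplanarity are refused as
  geometrically degenerate rather than guessed.
* Stage counting includes the certifying unperturbed round — it is a
  minimization stage like any other and counts against the cap.
* Trace row 0 is the unminimized input measurement.

# Known limitations

* The energy model is for repair, not production: no PME, no CMAP, no
  NBFIX, no 1–4 scaling, no Urey–Bradley. Re-minimize under your
  production engine after repair.
* A converged structure can still hold bonds stretched by up to 0.4 Å
  (tens of kcal/mol of bond energy); the cutoff certifies "not pierced",
  not "relaxed".
* Chirality restraints preserve the input stereochemistry — including any
  centers that were already wrong in the input.
* Detection keys on stretching only; an artifact that happens to leave all
  bonds near equilibrium (none is known from pierced rings) would be
  invisible to the symptom detector, though not to `findPiercings()`.
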