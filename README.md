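# ringfree

Detection and repair of ring-penetration artifacts in biomolecular
simulation systems.

## The problem

When complex simulation systems are assembled — polymers inflated from
optimized fragments, docked capsid subunits, glycans grafted onto a protein
— a bonded atom pair sometimes ends up on opposite sides of a small ring
(an aromatic six-ring, a pyranose). Classical force fields cannot fix this
by minimization: pushing atoms through the ring costs more Lennard-Jones
energy than stretching the bond far past its equilibrium length, so the
threaded configuration is a *local energy minimum* whose telltale symptom
is a bond much longer than its force-field equilibrium value. Left in
place, the artifact either blows up the integrator or — worse — survives
the simulation silently.

`ringfree` is for people preparing such systems. It

- **detects** long bonds against the CHARMM parameter tables: a bond is
  flagged when its length `b` exceeds the equilibrium length `b0` of its
  atom-type pair by more than a cutoff (default **0.4 Å**, replacing the
  historic absolute 1.65 Å rule, which misflags normal bonds to large
  elements);
- **confirms** the geometry with an exact segment-through-ring test
  (chordless rings of size ≤ 7, fan-triangulated about their centroid);
- **repairs** the artifact with an iterative biased minimization loop.

## The repair loop

Each stage is a bounded minimization (default 500 steps) followed by a
stretch report and a branch decision:

- max deviation ≥ cutoff → **biased round**: the worst bonds (within
  0.1 Å of the maximum) are targeted. For each target bond the loop
  applies
  - *soft-core nonbonded treatment* of atoms within 4 Å of the bond
    midpoint — pairs interact at `r_eff = sqrt(r² + δ²)`, so atoms can
    pass through the ring;
  - *perpendicular pulls*: both bond atoms are drawn toward a point 10 Å
    from the bond midpoint in the plane normal to the bond, shearing the
    bond sideways out of the ring face (the in-plane direction is the
    loop's only stochastic element, driven by the run seed);
  - a one-sided *center-of-mass separation bias* (harmonic up to a 10 Å
    target) between the bond pair and the nearby ring neighborhood;
  - a repulsive Gaussian *density hill* at the bond midpoint;
  - *force-constant escalation*: all of a bond's bias constants double
    each iteration it remains the longest bond in the system.
- max deviation < cutoff after a biased round → one certifying
  **unperturbed round** with every bias removed;
- max deviation < cutoff in an unperturbed round → **done**. The loop is
  capped at 100 stages.

Because the biasing forces are large, every *potential stereocenter* (an
atom with four pairwise-distinguishable substituent branches) is restrained
by default with a harmonic improper dihedral targeting the angle measured
in the input structure, so repair preserves — never imposes — the input
stereochemistry.

Inputs are CHARMM PSF topology (standard or EXT), PDB coordinates and
PRM/RTF/STR parameter files, plus a flat YAML run configuration. Runs are
non-periodic with switched nonbonded interactions (10–12 Å) and a relative
dielectric of 80 by default, emulating screening in an unsolvated system.

## Worked example

The canonical artifact: a two-carbon unit threaded through a benzene ring.

```r
library(ringfree)

fx <- makePiercedBenzeneEthane()
fx
#> FixtureBundle: 20 atoms; manifest: 1 piercing(s), 0 chiral center(s)

det <- detectArtifacts(RunConfig(), system = fx@system, params = fx@params)
det$stretch
#> StretchReport: 19 bonds, max deviation 0.672 A, 1 flagged, 1 targeted
det$piercings
#>   ai aj ringIndex px py pz
#> 1 13 14         1  0  0  0

out <- runLBE(RunConfig(label = "demo", outdir = tempdir()),
              system = fx@system, params = fx@params)
longestBondTrace(out$state)
#>   stage ai aj deviation perturbed            branch
#> 1     0 13 14   0.67200     FALSE
#> 2     1 13 14   1.64976     FALSE      BIASED_ROUND
#> 3     2  2  3   0.00032      TRUE UNPERTURBED_ROUND
#> 4     3  2  3   0.02883     FALSE              DONE

nrow(findPiercings(out$system))
#> [1] 0
```

Reading the trace: the threaded C–C bond (atoms 13–14) starts 0.67 Å past
equilibrium; plain minimization in stage 1 *stretches it further* (to
1.65 Å past `b0` — the local-minimum signature), which triggers a biased
round; the biased stage 2 frees the bond (longest bond now a relaxed ring
bond at 0.0003 Å); stage 3 re-certifies without any perturbation and the
loop terminates with zero geometric piercings.

File-driven runs work the same way: write a PSF/PDB/PRM/YAML quartet with
`writeFixture()` (or point the YAML at your own system) and call
`runLBE(parseRunConfig("run.yaml"))`, or use the thin command-line wrapper
`inst/cli/ringfree.R fix run.yaml`. Outputs are the repaired coordinates
(`<label>-opt.pdb`), the longest-bond trace (`<label>-trace.tsv`), a
flagged-bond report and a stage log.

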