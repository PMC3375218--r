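---
title: "Coarse-grained folding simulations and knot detection with knotfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained folding simulations and knot detection with knotfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knotfold)
```

## The scientific problem

A small but striking fraction of proteins are natively knotted: pulling the
termini of the native C-alpha trace apart and closing the ends into a ring
yields a non-trivial knot, most often a trefoil.  How and when such knots
form during folding is an open question.  One influential proposal is that
*non-native* interactions -- transient, sequence-dependent attractions
between residue pairs that are not in contact in the native state -- help
thread a chain terminus through loops of the partially folded globule at
early folding stages, whereas a purely native-centric (Go-type) energy
function almost never produces early knots.

`knotfold` implements the computational machinery needed to study this
question at residue resolution:

* a C-alpha coarse-grained force field with two switchable variants
  (purely native-centric, or native plus quasi-chemical non-native and
  screened electrostatic terms),
* a kink-jump Metropolis Monte Carlo engine with the four classic move
  types and a two-phase relaxation/production protocol,
* an open-chain topology engine (KMT-style rectification, Alexander
  determinants, minimally interfering and stochastic chain closure with a
  majority rule, knot-core localization and chirality from the Gauss
  writhe), and
* seed-deterministic generators for curves of known topology and for a
  matched pair of knotted/unknotted toy native structures, so that the
  entire pipeline runs and is testable without any external input.

## The model

Each residue is a bead at its C-alpha position.  The potential is

$$V = V_\text{bonded} + V_\text{native} + V_\text{non-native} + V_\text{elec},$$

with all energies in thermal units ($k_BT \equiv 1$ at the nominal Monte
Carlo temperature; `kT_kcal = 0.593` kcal/mol fixes unit conversions).

**Bonded terms.** Harmonic pseudo-bonds $k_b (r - b_0)^2$ with
$b_0 = 3.8$ Å and $k_b = 20\,k_BT/\text{Å}^2$; a double-well pseudo-angle
potential, the soft minimum (log-sum-exp with parameter $\gamma$) of a
helical basin at $\theta_\alpha = 1.60$ rad and an extended basin at
$\theta_\beta = 2.27$ rad; and a four-term cosine series in the
pseudo-torsion whose coefficients depend only on the middle two residue
types.  The per-pair statistical torsion tables of the transferable model
this construction follows are not redistributable, so the package generates
a residue-class table (helix formers biased towards $+50^\circ$, sheet
formers towards the extended region, glycine nearly free, proline
stiffened); amplitudes sum to about 1.5 $k_BT$, so torsions shape but do
not dominate the landscape.  As an alternative, a model can be built with
*native-referenced* bonded terms (harmonic angles about the native
$\theta_i^0$ and a $1{+}3$ cosine torsion about $\phi_k^0$, the classic
native-centric choice); the designed toy structures use this option, since
their geometry is constructed rather than drawn from protein statistics.

**Native term.** Residue pairs in the native contact map interact through
the 12-10-6 well
$\varepsilon_{ij}\left[13 x^{12} - 18 x^{10} + 4 x^6\right]$ with
$x = r^0_{ij}/r$, whose minimum is exactly $-\varepsilon_{ij}$ at the
native separation $r^0_{ij}$.  For structures parsed from PDB files the
map follows the hydrogen-bond/side-chain construction: a pair (sequence
separation at least 3) is native if its backbone hydrogen bond is stronger
than $-0.5$ kcal/mol in the Kabsch--Sander electrostatic model (with the
amide hydrogen rebuilt from the preceding peptide plane), or if any two
heavy side-chain atoms are within 4.5 Å.  Hydrogen-bonded pairs inherit
$|E_{hb}|$ (converted to $k_BT$) as strength; side-chain-only pairs get a
strength proportional to their quasi-chemical matrix entry, rescaled so
the class means match; and around every pair held by two hydrogen bonds
(or one plus a side-chain contact) the four neighbouring $(i\pm1, j)$,
$(i, j\pm1)$ pairs join as a weak network at a configurable fraction
(default 0.25) of the parent strength.

**Non-native term.** Non-native pairs at separation $\ge 3$ interact with
effective strength $\varepsilon_{ab} = \lambda (e_{ab} - e_0)$, where
$e_{ab}$ is a 20$\times$20 quasi-chemical contact matrix, $e_0 = -2.27$ an
offset separating effectively attractive from effectively repulsive pairs,
and $\lambda$ a global scale.  Attractive pairs ($\varepsilon < 0$) get a
Lennard-Jones well of depth $|\varepsilon|$ at the contact distance
$\sigma_{ab}$ (arithmetic mean of the residue diameters); repulsive pairs
a monotone repulsion of scale $\varepsilon$ at $\sigma_{ab}$.  The true
statistical-potential matrix could not be redistributed, so the shipped
table (`qc_contact_potential_synthetic.tsv`) is a synthetic analogue built
from per-residue contact propensities with an arithmetic-mean combining
rule; it preserves the hydrophobic/hydrophilic sign structure (ILE-LEU
attractive, GLU-GLN repulsive under the offset) and can be replaced by any
file in the same format.  Crucially, the one quantitative constraint the
study imposes does not depend on the matrix details:
`calibrate_nonnative_scale()` rescales $\lambda$ so that the mean
$|\varepsilon_{ab}|$ over all non-native pairs of the given sequence is
exactly one tenth of the mean native strength.  Under the purely
native-centric variant the non-native term reduces to the standard 4 Å
hard-core repulsion $(\sigma_{ev}/r)^{12}$.

**Electrostatics.** ASP/GLU carry $-1$, LYS/ARG $+1$; pairs interact
through a Debye-Hueckel screened Coulomb term with relative dielectric 80
and a 10 Å screening length (near-ambient water; ionic strength is not
specified by the study, so the screening length is a parameter).  On
sampled conformations the electrostatic segment energies are more than an
order of magnitude smaller than the quasi-chemical ones, which the test
suite asserts.

## The Monte Carlo engine

Moves are (i) crankshaft rotations of a single interior bead about the
axis through its neighbours (amplitude $\pm 15^\circ$ by default), (ii)
single-bead cartesian displacements uniform in a 0.15 Å sphere, (iii)
global pivots of one chain arm about a random axis through a random
residue, and (iv) rigid rotations of the terminal 10 residues about the
most interior bead of the segment ($\pm 30^\circ$).  One MC time unit is
100 attempted moves per residue.  Phase 1 (relaxation of the common
stretched-coil start, built from extended pseudo-angles with torsions
jittered $\pm 30^\circ$ around trans) draws crankshaft/cartesian/pivot at
0.8/0.1/0.1; when the pivot acceptance over a 1000-attempt window drops
below 1% -- or at a configurable hard cap, needed for small systems whose
open coils never stop accepting pivots -- the run switches to phase 2,
where end-segment moves take the pivot slot.  Proposals are accepted by
the standard Metropolis criterion; energy differences come from an
incremental evaluation over the affected terms only, which the tests hold
to the full recomputation within $10^{-8}\,k_BT$ and whose accumulated
drift over full trajectories stays below $10^{-11}\,k_BT$.

Local moves are small enough that the chain cannot pass through itself; as
in the study the pipeline follows, this is *verified a posteriori*: a
configurable fraction of accepted local moves is audited by testing the
triangle swept between the old and new bead position against all
non-adjacent segments, and a trajectory aborts if any crossing is found.
The same primitive drives `evolve_ring()`, which the acceptance suite uses
to evolve a closed trefoil through a million audited moves and verify the
knot type never changes.

Boltzmann correctness is checked on a three-bead chain, whose pseudo-angle
marginal $\propto \sin\theta\, e^{-V(\theta)}$ is known by quadrature; a
$\chi^2$ test at $10^6$ samples must not reject.  The C++ engine uses a
self-contained xoshiro256** generator, so a seed fixes a trajectory
bit-for-bit across platforms; trajectory $k$ of a campaign uses
`base_seed + k`.

## Topology classification

A conformation's knot state is defined after closure into a ring.  Two
schemes are combined, as in the study: the deterministic *minimally
interfering* closure (termini near the surface of the bead cloud are
prolonged radially outward and bridged far from the chain; buried termini
are bridged directly) is evaluated first because it is cheap; a
non-trivial result is validated by a poll of 100 stochastic closures, each
prolonging the termini along random directions constrained to point more
than $90^\circ$ away from the segment towards the C-alpha ten residues
inward, and the chain counts as entangled only if a strict majority of
closures returns non-trivial determinants.

Rings are first rectified KMT-style (a vertex is removed whenever its
elementary triangle is pierced by no other segment), then classified by
the Alexander determinants $|\Delta(-1)|, |\Delta(-2)|$ computed from the
crossing pattern of a generic planar projection (re-drawn on degeneracy;
the values are projection-invariant integers): unknot $(1,1)$, trefoil
$(3,7)$, figure-eight $(5,11)$, anything else "other".  The knot core is
localized by trimming residues from both ends while the closed subchain
stays knotted, followed by a tightening re-pass -- a two-sided search that
costs $O(N)$ closures and coincides with the exhaustive bottom-up search
for the single-knot chains in scope.  A knot whose core reaches a terminus
(or that vanishes for every subchain) spans the closure arcs and is
flagged *improper*.  Chirality is the sign of the Gauss writhe of the
rectified closed core: positive means right-handed; $|Wr| < 0.5$ is
reported indeterminate (the figure-eight, being amphichiral, lands there).
A knotting event counts as *persistent* when the closure consensus reaches
0.9 -- the printed consensus threshold of the source study is not legible,
so this is a configurable default -- or the core sits at least 20 residues
from both termini.

## The synthetic study system

The full-scale campaign of the source study (150 trajectories of two
332/313-residue proteins under two potentials, 3000 MC units each) is far
beyond a test suite, so the package carries a desk-scale analogue designed
around the same mechanism, generated by `make_toy_native()`:

* the **knotted** toy opens a right-handed (2,3) torus knot (48 beads) at
  the cut phase whose knot core touches the C-terminal end, and continues
  the chain with a 12-residue helix: the terminal helix is the
  knot-completing thread;
* the **unknotted** toy winds the same tube as a topologically trivial
  (1,3) coil of equal length, with the same body sequence;
* both bodies use a polar 10-residue repeat (`ASEKVGTNQL`); the terminal
  helix is hydrophobic (`LIVA` repeat) in the knotted toy and neutral
  hydrophilic (`EQN` repeat) in the unknotted one -- the C-terminal
  chemistry contrast that distinguishes the natively knotted protein from
  its unknotted homolog, and the axis probed by the in-silico mutants;
* a short packing stage (30-50 MC units of crossing-audited local moves
  under a temporarily strengthened non-native attraction, pivots disabled
  so the embedded topology is provably conserved) settles the helix
  against the body.  This stage matters: it creates native contacts
  between the tail and the knot loop, and those contacts are what reward
  the *correctly threaded, correctly handed* knot during folding.  The
  packing lengths (30 units knotted, 50 unknotted) were fixed by
  calibration runs so that the two kinds end with matched contact counts;
* contact maps use the geometric C-alpha rule (< 6 Å, separation $\ge 3$,
  uniform 3 $k_BT$ -- the hydrogen-bond scale); toys have no side chains,
  so the atomic construction rule does not apply;
* every generated toy re-verifies its declared topology (and right-handed
  chirality for the knotted kind) before being returned, retrying with a
  shifted seed a bounded number of times.

The toy campaigns (`toy_campaign_config()`) run 500 MC units per
trajectory with snapshots every 10 units, the relaxation phase capped at
100 units, and a crankshaft amplitude widened to $\pm 30^\circ$ -- still
inside the non-crossing displacement bound and audited -- because the
toys' kinetics would otherwise be impractically slow at desk scale.  These
conditions, like the toy geometry itself, were fixed once by calibration
runs that set how hard the toy problem is; they are not tuned per seed.

What the toys do and do not show: they reproduce the mechanism-level
contrasts -- knotting requires the full potential, is concentrated in the
knotted-native system, proceeds through C-terminal threading, and produces
trefoils -- but a 60-bead chain is far below the length at which collapsed
polymers entangle spontaneously, so absolute knotting probabilities are
small and dominated by rare, long-lived threading events; ensemble
statistics over 20 seeds remain bursty.  Passing toy campaigns therefore
demonstrate that the machinery detects and discriminates the designed
behaviour, not that the model quantitatively reproduces any real protein.

## A worked desk-scale example

```{r example, eval = FALSE}
toy <- make_toy_native("knotted")
model <- toy_model(toy, mode = "full")
traj <- run_trajectory(model, toy_campaign_config(seed = 7))
traj
knots <- analyze_trajectory_knots(traj, seed = 1)
table(knots$label)
```

## Numerical choices and degenerate inputs

* Pair interactions are truncated at $3\sigma_{ab}$ (non-native), $4$
  Debye lengths (electrostatics) and $2.5\sigma_{ev}$ (hard core); native
  pairs are always evaluated.  With at most a few hundred beads the pair
  loops are brute force in C++; neighbour lists were deliberately omitted
  because they could only match, not beat, that cost here, and brute force
  trivially satisfies the "identical to the double loop" contract.
* Collinear pseudo-torsion quadruplets have no defined dihedral; their
  term contributes zero and the evaluation warns.
* Beads closer than 0.1 Å make the state unphysical: a hard error in full
  evaluations, an automatic rejection inside the sampler.
* Rejected proposals restore coordinates bit-exactly; identical seeds give
  identical snapshot streams.
* Degenerate projections in the Alexander computation (parallel segments,
  endpoint hits, equal heights) are retried with fresh directions from a
  deterministic stream; `|\Delta(-2)|` is reported modulo the powers of
  two inherent to the determinant convention, which leaves the
  classification table unambiguous.
* The internal non-native interaction of a rigidly moved segment is
  skipped in the incremental energy difference; rigidity preserves those
  distances, and the residual floating-point discrepancy is orders of
  magnitude below the $10^{-8}\,k_BT$ contract.

## Known limitations

* The quasi-chemical matrix, torsion tables and several printed constants
  of the source construction are approximated by documented defaults; all
  are configuration parameters, and the one-tenth calibration makes the
  headline comparison insensitive to most of them.
* The real-protein checks (chain lengths, native trefoil with its core
  near K172-G255, collapse to about 30 Å in 100 units) require the two
  public structure files at run time; the corresponding tests fail on
  machines without network access rather than silently skipping.
* Chirality for very shallow or improper knots rests on the writhe of a
  short core and can be reported indeterminate.
* The toy campaigns are subject to the burstiness discussed above: the
  knotting-probability thresholds of the acceptance suite sit close to
  the event rate, so individual seed batches can land on either side.
* No slipknot detection, no composite knots, no physical-time mapping of
  MC time.
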