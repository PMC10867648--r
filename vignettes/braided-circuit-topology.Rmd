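---
title: "Braided circuit topology: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Braided circuit topology: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braidct)
```

This vignette is the package's own account of the science it implements:
the models, the conventions that had to be fixed where the underlying
theory leaves freedom, and the numerical choices and their limits.

## 1. The physical setting

The reference system is a small aggregate of `M = 4` semiflexible
bead-spring chains of `N = 10` beads in reduced Lennard-Jones units
(`sigma = epsilon = m = kB = 1`).  Beads interact through a truncated,
shifted 12-6 Lennard-Jones potential; backbone neighbours are additionally
joined by FENE springs; successive bonds pay a bending energy
`U_bend = kappa * kB * T * (1 - cos theta)`.  At fixed low temperature the
chains aggregate; sweeping the stiffness `kappa` from 0 to 12 drives the
aggregate from an amorphous globule to an aligned bundle.  The package
tracks that transition with structural order parameters (the multichain
radius of gyration and the end-to-end correlation `CR`), with circuit
topology motif fractions, and with braid invariants of the entanglement
skeleton.

Model constants not fixed by the published description were chosen once,
on standard grounds, and are exposed in `sim_config()`:

* FENE constants `K = 30 epsilon/sigma^2`, `R0 = 1.5 sigma` — the standard
  bead-spring choice, consistent with the quoted mean bond length
  `l_b = 0.965 sigma` at `T = 1`.
* The pair potential is the full attractive Lennard-Jones with cutoff
  `2.5 sigma`, shifted to zero at the cutoff.  Aggregation requires
  cohesion, and a published cohesive strength is not available; unit
  epsilon is the neutral choice.  Quantities that are robust to this
  choice (bond length, equipartition, the interchain motif saturation, the
  sign-symmetry of the writhe) are the ones asserted tightly in the tests;
  quantities that are not (the saturation value of `CR`, the residual
  braid content of an aligned bundle) are discussed in section 7.
* Bonded neighbours feel FENE *plus* the pair potential.  A description in
  which bonds feel only FENE is not viable: the FENE energy alone is
  minimal at zero extension, so bonds would collapse; the pair repulsion
  is what produces the equilibrium bond length near `0.965 sigma`.
* Langevin damping time 1 tau (BAOAB splitting), timestep `0.01 tau`.
* Initial states are self-avoiding random walks (bond `0.97 sigma`, no
  pair closer than `0.9 sigma`) in the cubic box fixed by the density.

## 2. Circuit topology

`detect_contacts()` declares a contact between any bead pair within
`rc = 1.4 sigma` (minimum image in periodic systems).  Intrachain pairs
must in addition be at least 3 bonds apart along the backbone, so bonded
and next-nearest neighbours can never close a two-bond loop.  The
published description also mentions a separate self-interaction range
`3 sigma`; we read its *purpose* — excluding near-diagonal pairs — as the
backbone-separation rule, and expose the alternative reading (a different
Euclidean cutoff for intrachain pairs) as `contact_config(rc_intra = )`.

`classify_pair()` implements the full decision tree on the chain
memberships of the four contact sites, and `motif_fractions()` takes the
census over all unordered contact pairs.  Contacts are non-saturating (a
bead may appear in many contacts); pairs sharing a site are skipped and
counted, because the four-site motif alphabet is undefined for them.
Degenerate subtypes (parallel vs cross loop, umbrella vs arc tandem) are
assigned from the site ordering along the shared chains, but only
class-level fractions enter the order parameters, since subtype-resolved
fractions have no published reference values.

## 3. Braid words and loop coordinates

A braid word is a sequence of signed Artin generators; `sigma_i` means
the strand at position `i` (from the left) passes over strand `i + 1`.
Words are equivalent under three moves: commutation of distant
generators, the braid relation
`sigma_i sigma_{i+1} sigma_i = sigma_{i+1} sigma_i sigma_{i+1}`, and
cancellation of inverse pairs.

All invariants are computed through the action of the braid group on
isotopy classes of multicurves in the punctured disk, encoded in integer
Dynnikov coordinates (`loop_coords()`).  The update rule for a generator
is an exact piecewise-linear map; its correctness was established against
an independent geometric oracle (polyline curves moved by half-twist
homeomorphisms, with taut intersection counts obtained by removing
puncture-free bigons), which remains part of the test suite.  Boundary
generators are handled by embedding into a disk with one phantom puncture
on each side, where every generator acts by the interior rule.

Two implementation choices deserve note:

* **Equality testing.**  Two words are equal in the braid group exactly
  when they act identically on the canonical multiloop of the disk with
  one extra basepoint puncture (`canonical_loop()`); the basepoint records
  the framing of the fixed disk boundary, so central elements (powers of
  the full twist) are distinguished from the identity.
* **Arithmetic.**  Coordinates are held as integer-valued doubles with an
  overflow guard at `2^49`, beyond which exact integer arithmetic in
  doubles is not certain; the guard raises an error rather than returning
  wrong integers.  Words arising from four-chain systems reduce to a
  handful of letters and stay far below the guard.  For growth-rate
  estimation the update's homogeneity (degree 1) is exploited: the
  coordinate vector is renormalized after every application and only the
  log-growth accumulated, which is scale-free and cannot overflow.

## 4. Minimal length and reduction

`reduce_braid()` first shrinks the word by free cancellation assisted by
commutation, then certifies minimality by iterative-deepening search over
all words up to the current length, comparing candidates through the
loop-coordinate total invariant and pruning by writhe (conserved by all
moves) and by a canonical ordering of commuting adjacent letters.  The
search is exponential in the word length and is attempted only up to
`max_exact = 9` pre-reduced letters; longer words return the shrunken word
flagged `exact = FALSE`.  Exact geodesic length in braid groups is
expensive in general; the words this package meets reduce to about three
letters, where the certified search runs in milliseconds.  An independent
breadth-first-search oracle over the rewriting system cross-checks the
minimum in the test suite.

## 5. The complexity index and its calibration

The complexity of a braid is `C = log(#betaE / #E)`: the factor by which
the braid multiplies the number of taut intersections between a canonical
curve diagram `E` and the real axis through the punctures, in a chosen
logarithm base (3 by default for four-strand work, natural log for the
worked examples).

The canonical diagram is not drawn explicitly in the published account,
which instead pins the convention through example values; the package's
choice is:

> `E` = `n - 1` parallel copies of the **central wall**, the transversal
> arc crossing the middle gap between punctures once, with the disk
> boundary held fixed.

so `#E = n - 1` by construction.  Holding the boundary fixed matters (a
full twist must increase complexity) and is encoded by doubling the disk
across its boundary: the wall doubles to a round loop around the middle
block of `2n` punctures, and each generator `sigma_i` acts at its own
position and at the mirror position `2n - i`.  This equivalence was
verified case by case against the boundary-anchored geometric oracle.

The convention reproduces exactly: `C(sigma1 sigma2) = ln 3 = 1.099` on
four strands (natural log); base-3 complexity 1 for `sigma1 sigma2^{-1}`;
and `C/L = 1/3` (base 3) for `sigma1 sigma2 sigma3`.  One published value
is *not* reproduced and cannot be: a claimed natural-log complexity
`1.386 = ln 4` for `sigma1 sigma2^{-1}`, i.e. `#betaE = 12` from
`#E = 3`.  The intersection parity of each component of any curve system
with a fixed line is invariant under homeomorphisms, and a system with an
odd total count of 3 must contain an odd number of odd-parity components,
so every image count is odd — 12 is unreachable for *any* choice of `E`
under the stated definition.  The same source also states that the base-3
complexity of this braid is unity, which implies `#betaE = 9` and agrees
exactly with the package's convention; we therefore follow the
self-consistent statement and report `ln 3` for this braid.

## 6. Thurston–Nielsen classification (heuristic)

`tn_classify()` distinguishes the three isotopy classes as follows, in
order: a braid is **finite-order** when some power up to `n` is central —
the candidate full-twist power is pinned by the writhe and verified
exactly on the canonical multiloop, which covers all periodic braids since
their orders divide `n` or `n - 1`; it is **reducible** when a family of
disjoint round multicurves (loops around blocks of adjacent punctures) is
permuted by its action; otherwise the loop-coordinate norm is iterated 40
times with renormalization and the braid is **pseudo-Anosov** when the
mean growth factor per application over the last half exceeds 1.5.
Pseudo-Anosov dilatations on at most 4 strands are at least about 2.3,
while non-pA braids grow at most polynomially (growth factors within a few
percent of 1 at these iteration counts), so the threshold sits in a wide
empty band; the per-letter threshold of `1 + 10^{-3}` sometimes suggested
for such tests would misclassify reducible braids with linear growth at
realistic iteration counts, and is not used.  Reducible braids whose
reducing curves are not isotopic to round ones are missed by the curve
search and fall through to the growth test; the classification is
heuristic by design — exact train-track methods are out of scope — and is
documented as such.

## 7. From conformations to braids

`primitive_paths()` contracts each chain's contour with its endpoints
frozen: intrachain interactions are disabled except the FENE bonds, a
purely repulsive truncated pair term acts between different chains, and
the energy is minimized by damped steepest descent whose per-bead step is
capped at `0.01 sigma` per iteration — two orders of magnitude below the
excluded-volume core, which is the no-strand-passage guarantee.  The step
size backs off geometrically whenever the residual force grows, curing
the oscillation that plain steepest descent develops on taut chains;
convergence is declared at maximum residual force `10^-4 epsilon/sigma`
(at most `10^5` iterations, returning the best iterate with a warning
otherwise).  The published account does not state a minimizer or stopping
rule; these choices are validated by the invariants (fixed endpoints,
monotone contour, straight-segment limits, link preservation) rather than
by reference numbers.

`find_projection_frame()` follows the endpoint-plane construction: seed
endpoint, nearest other-chain endpoint (excluding the seed's partner),
nearest endpoint to their line, plane through the three, and the farthest
remaining endpoint fixing the parallel plane; axes are `z'` along the
normal, `x'` along the first edge, `y'` completing a right-handed frame.
The seed endpoint defaults to chain 1's first bead and is exposed as an
option, because the frame — and through it projection-sensitive
quantities such as the isotopy class — can depend on it.  Two
degeneracies get deterministic treatment: with only two chains the third
point is drawn from the excluded partners, and collinear candidates are
skipped in favour of the nearest genuinely off-line endpoint.

`extract_braid()` resamples each strand's lateral position at equally
spaced heights, monotonizing non-monotone height sequences with a running
maximum (flagging chains that backtrack by more than 5% of their
contour), and emits one generator per exchange of laterally adjacent
strands.  Between consecutive heights the strand paths are linear, so all
exchange events within a gap are located exactly and ordered; exact ties
are broken by a fixed `10^-9 sigma` perturbation.  The sign convention —
the strand arriving from the left passing in front (+y') gives a positive
generator — matches the fixture generator `make_braided_bundle()`, and
the agreement is enforced by round-trip tests: bundles built from random
words return words with identical writhe, minimal length and complexity
in at least 95% of cases, and doubling the slice count changes nothing.

## 8. Synthetic data

`make_random_walks()` produces ideal freely-jointed chains (verified
against `b^2 (N - 1)` end-to-end statistics); `make_motif_system()`
builds, for each of the nine motif classes, a sparse bead arrangement
with exactly two contacts of the designed class; `make_braided_bundle()`
realizes a prescribed braid word as smooth strand exchanges between two
planes, with a front/back offset of `0.5 sigma` making over/under
unambiguous in projection, and a small seeded jitter breaking exact
lateral degeneracies.  These generators emulate geometry, not physics:
bundles are not thermally equilibrated, walks have no excluded volume,
and motif fixtures place beads without bond-length constraints.  Tests
passing on them therefore validate the classification and extraction
machinery, not the statistical mechanics of real aggregates — that is
what the simulator-driven sweep is for.

## 9. Desk-scale study conditions and what they show

The published sweeps average 1000 realizations per stiffness value over a
61-point grid after equilibrations of 20000 tau.  The package's
`run_sweep()` defaults are a deliberate desk-scale reduction: the
stiffness endpoints (or a 7-point grid), tens of replicas, and
equilibration by a stationarity criterion — blocks of 100–300 tau until
the block means of the normalized radius of gyration and of `CR` stop
moving — capped at a few thousand tau.  The acceptance checks run
`kappa in {0, 12}` with 10 replicas and a 2400 tau cap.

Under these conditions the robust signatures reproduce cleanly: at
`kappa = 12` the interchain motif sum reaches 1, `CR` rises from its
amorphous value to about 0.9, the ensemble-mean writhe fluctuates around
zero, and the braid class distribution is dominated by finite-order
(unbraided) outcomes.  One reported quantity does not reproduce at this
scale: the mean complexity-to-length ratio of the residual braid words.
Our bundles align slightly more completely than the published saturation
(`CR ~ 0.9` vs `~ 0.84`) and anneal their projected crossings away, so
most extracted words are empty and the few short survivors give a noisy
`C/L` around 0.6 rather than 1/3.  The residual braid content of an
aligned bundle is exactly the kind of quantity that depends on the
unpublished cohesive strength; it is reported as measured rather than
adjusted for.

## 10. Known limitations

* The TN classification is heuristic (section 6) and, as with any single
  projection, the extracted braid itself can change class under a
  different projection seed.
* Complexity counts are exact only up to the `2^49` guard; pathological
  words (hundreds of pseudo-Anosov letters) would need big-integer
  arithmetic.
* `reduce_braid()` certifies minimality only up to `max_exact` pre-reduced
  letters.
* The simulator is an O(N²) pairwise implementation intended for a few
  hundred beads, with no pressure control and 1-2 bonded exclusions only.
* The combined contact/braid string (`braided_string()`) is a
  serialization format with at most 26 contacts; it is not used in any
  computation.
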