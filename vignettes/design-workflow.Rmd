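---
title: "Artificial design of inverted-gap organic emitters: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Artificial design of inverted-gap organic emitters: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The design problem

Organic light-emitting diodes are limited by non-emissive triplet excitons.
A molecule whose first excited singlet lies *below* its first excited
triplet — an inverted singlet-triplet gap (INVEST), violating Hund's first
rule for excited states — would avoid triplet accumulation entirely, but
known INVEST cores (azulene among them) have nearly dark S0→S1 transitions.
The design task is therefore multi-objective: minimize the singlet-triplet
gap ΔE(S1–T1) (STG, eV), maximize the oscillator strength f12 (OS,
dimensionless), and, for blue emitters, hold the vertical excitation energy
ΔE(S0–S1) (VEE, eV) near 3.2 eV.

`investga` implements the full desk-side machinery of such a campaign: a
genetic algorithm over a robust molecular string representation,
domain-knowledge π-system filters, symmetry-aware azaazulene scaffold
enumeration, a surrogate classifier that gates expensive property
evaluation, hierarchical multi-objective ranking for lead selection, and a
profactual/counterfactual explainer. The one component that cannot run at
desk scale — the quantum-chemistry property oracle — is a pluggable
contract: a function from SMILES to (STG, OS, VEE) triples. Two concrete
oracles ship with the package: a deterministic synthetic oracle (below) and
a lookup oracle backed by a user-supplied CSV table.

## The robust string representation

Random edits of SMILES strings almost always produce invalid molecules, so
the genetic operators act on a robust token representation in which
*every* token sequence decodes to a valid molecule. Decoding is a
valence-constrained derivation over a 16-token alphabet: C/N/O/S atom
tokens with single/double/triple bond prefixes, branch tokens, ring-closure
tokens, and a padding token. Valence caps (C:4, N:3, O:2, S:2) are enforced
during derivation — a token that cannot be applied is skipped, never an
error — and decoded molecules are neutral, closed-shell Kekulé structures.
Aromaticity is perceived downstream by the chemical toolkit (RDKit, running
as a persistent worker process; its version is recorded in campaign logs
because aromaticity and conjugation degrees are model-dependent).

The alphabet is deliberately smaller than a full general-purpose grammar:
the target chemical space is conjugated C/N heterocycles with N/O/S donor
substituents, and no halogens, charges or radicals survive the π-system
filters anyway. Hydrogens are implicit and fill remaining valence.

Two operators generate structures: random token edits (insertion, deletion,
replacement, chosen uniformly) and string interpolation (the shorter parent
is padded, offspring take a prefix of one parent and the suffix of the
other at a random crossover point). The mutation/interpolation mix is 50/50
and parents are drawn uniformly from the elites; neither ratio is dictated
by the source protocol, and fitness-weighted parent sampling is
deliberately not used.

**Edit counts.** Steady-state mutations draw 1–3 token edits. Generation 1
is different: it must scatter widely around a possibly tiny seed (methane
is one of the reference seeds, and a ring costs roughly six tokens), so the seeding
generation draws 1–30 edits. Without this, a methane-seeded run produces an
empty first generation — whereas the reference campaign rediscovered
azulene in generation 1, implying wide seeding.

## π-system filters

Every generated structure must satisfy, simultaneously: formal charge 0;
zero radical electrons; zero bridgehead and zero spiro atoms; at least half
of the heavy atoms aromatic; at least 70% of heavy-heavy bonds conjugated;
every ring of size 4–8 (acyclic molecules fail by convention — the target
space is cyclic π-systems); no forbidden substructure (a config-supplied
SMARTS list, empty by default); and at most 70 atoms *including* implicit
hydrogens. Degree thresholds are compared with `>=` exactly as stated.
These filters run inside the genetic operators, so the GA never wastes an
oracle call on an inadmissible structure.

## Azaazulene scaffolds

Azulene's eight CH positions (IUPAC numbering: 1–3 on the five-ring, 4–8 on
the seven-ring; fusion carbons 3a/8a are never substituted) admit 2^8 = 256
nitrogen-substitution masks. The molecular mirror plane induces the
permutation σ = (1 3)(4 8)(5 7), and the number of symmetry-distinct cores
is the number of σ-orbits: (2^8 + 2^5)/2 = 144 by Burnside's lemma. The
enumerator canonicalizes patterns at the set level *and* the package
cross-checks by building all 256 molecules and deduplicating canonical
SMILES — the two counts must agree, a built-in self-check.

Constrained generation modes mirror the campaign designs: `free`,
`azulene_required` (a fused, fully conjugated C/N 5–7 bicycle must be
present), `identical_1_6` (the GA evolves a substituent string that is
attached identically at positions 1 and 6 of a core with carbon at those
positions), and `symmetric_4_8_fixed_core` (substituents at 4 and 8 of the
fixed 2,5,7-triaza core, giving a mirror plane through the core). In the
attachment modes the substituent genome is seeded with a single `[C]`
token, since the bare core leaves nothing to mutate; the attachment point
is the substituent's first atom and must carry a free valence.

## Fitness

Fitness is a sum of three dimensionless components (eV quantities are
divided by 1 eV):

* STG component: `threshold − stg` if non-negative, else −10^6. Thresholds:
  0.6 (run 1), 0.3 (runs 2–6). Run 3 keeps the threshold *requirement* but
  zero weight — a satisfied component contributes 0, a violated one is
  still penalized.
* OS component: `os` if non-negative (weight 1) else −10^6.
* VEE component: −10^6 if `vee < 0` (enforced in every run, since the
  requirement is stated unconditionally); otherwise `−|vee − target|` when
  a target is set (3.2 eV in run 4), else 0.

Penalties add, so a molecule violating two requirements scores −2·10^6;
the ordering among all-penalized molecules is immaterial, but every
penalized molecule ranks below every clean one. Oracle *failures* (crashed
property simulations in the real workflow) are excluded from ranking with
an explicit status, never given a stand-in fitness — penalties keep their
semantic meaning.

## The synthetic oracle — a stated world

The synthetic oracle is a deterministic closed form on graph descriptors,
chosen once so that the GA's optimization behaviour is testable: with H =
heavy atoms, nN = aromatic ring nitrogens, D = H-bond donors, C =
conjugation degree and azu the azulene-likeness indicator,

```
stg = 0.9 − 0.55·azu − 0.08·min(nN, 6) + 0.015·|H − 22|
os  = 0.02 + 0.08·min(D, 4) + 0.3·C·azu·min(H, 40)/40
vee = 1.8 + 0.04·min(H, 40)
```

Its minimum STG is −0.13 (azulene-like, ≥ 6 aromatic N, 22 heavy atoms),
so gap inversion is reachable but requires the GA to assemble
nitrogen-rich azulene derivatives of the right size — a miniature of the
real discovery task. It emulates the real property landscape's qualitative
structure (azulene cores lower the gap; ring nitrogens lower it further;
donors and conjugated size raise the oscillator strength) and none of its
physics: no conformers, no electronic structure, no noise. A green test on
this oracle establishes that the *search machinery* works — seeding,
filtering, constraint handling, elitism, uniqueness, gating — not that any
real molecule has any real property.

## Surrogate classifier

Campaign data up to the training generation (11 in the reference protocol)
are labeled good iff STG < 0.6 *and* OS > 0 (strict), featurized as binary
1024-bit Morgan fingerprints (radius 2 — the radius is a package choice,
configurable and logged), and split 48/32/20 into train/validation/holdout.
A fully connected network with two hidden layers (ReLU, dropout, sigmoid
output, binary cross-entropy, Adam, minibatch 64, early stopping on
validation loss) is tuned by random search over epochs 10–200, patience
5–30, learning rate 1e-4–1e-2 (log scale), 32–512 neurons per layer and
dropout 0–0.5; the trial with the best validation accuracy wins and
accuracy is reported on the holdout set. The trained model then gates the
genetic operators — only predicted-good structures (probability > 0.5)
reach the oracle — for the remaining generations.

**Class imbalance** is the one place this package departs from a purely
literal reading: good molecules are a few percent of desk-scale campaign
data, and unweighted training collapses to the majority class, after which
the gate rejects *everything* and the gated generations starve. The loss
therefore weights positive examples by the inverse class frequency (capped
at 50). The decision threshold stays at 0.5.

## Lead ranking and reporting

Lead selection uses a hierarchical scalarization with absolute tolerances:
at each level of an importance-ordered objective list, points meeting the
tolerance form the feasible block and are ordered by the next level;
infeasible points follow, ordered by their value at the violated level.
Maximize goals negate values and tolerances. Two preset objective lists
are shipped: A (STG minimize, tolerance 5.00; OS maximize, 0.35) and B
(STG 3.000; OS 0.175; |VEE − 3.2| minimize, 0.350). Only the induced
ordering is used — the original method's smoothed merit function is not
reconstructed, because selection depends only on the ordering; users
comparing merit *values* against other implementations should be aware of
this. Ties break on canonical SMILES under C collation for determinism.

Reporting constants: molecules with STG < 0.36 eV are counted as likely
INVEST, and those additionally with OS > 0.05 as INVEST with appreciable
fluorescence (both strict); the blue-emitter VEE target is 3.2 eV on the
fitness scale and 2.83 eV on the lead-validation scale.

## Explainer

For a baseline molecule, the neighborhood is sampled by 1–3 random token
edits per sample (the reference "medium" sampler settings are not fully
specified; 1–3 edits is the adopted convention), keeping only
filter-passing, non-baseline structures. Samples are labeled by the model;
profactuals keep the baseline's predicted label, counterfactuals flip it;
each side retains the k = 9 most Tanimoto-similar members on the
classifier's own fingerprints (the similarity metric is a package choice —
the source protocol does not name one, and fingerprint Tanimoto is the
field convention). No diversity re-selection is applied: top-k by
similarity only.

## Numerical and degenerate-input choices

* Elite count is `max(1, floor(0.2·N))`; the rounding rule is a package
  choice.
* Ranking ties break on canonical SMILES under C collation.
* `propose_offspring` uses an attempt budget (20× the target by default);
  shortfalls warn and return a partial generation rather than failing.
* The uniqueness registry is append-only per run and persists as a sorted
  text file for resumption.
* Structure verdicts are memoized per campaign (mutation operators
  regenerate the same structures constantly); this is pure caching and
  does not change results.
* Conjugation degree of a molecule with no heavy-heavy bonds is 0 by
  convention; aromaticity degree of an empty molecule is an error.
* Seeds are evaluated in generation 1 even when they fail the filters
  (methane does, by design); only offspring are filtered.

## Known limitations

* The synthetic oracle is a caricature; no conclusion about real
  excited-state properties follows from any run of it.
* The robust grammar covers neutral C/N/O/S chemistry only; charged or
  radical species and other elements cannot be encoded (they could not
  pass the filters regardless).
* The worker-process design means the first chemistry call in a session
  pays the RDKit import cost (~1 s).
* Aromaticity/conjugation degrees — and therefore two filter rules and the
  azulene-likeness test — depend on the toolkit's perception model; the
  RDKit version is logged with every campaign.
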