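# investga

Genetic-algorithm design of organic emitters with **inverted
singlet-triplet gaps** (INVEST) in R.

Most organic light-emitting materials are limited by non-emissive triplet
excitons. A molecule whose first excited singlet S1 lies *below* its first
excited triplet T1 — ΔE(S1–T1) < 0, violating Hund's first rule for excited
states — would sidestep the problem, but the known inverted-gap cores
(azulene and friends) are nearly dark emitters. Designing a molecule with
both an inverted gap and an appreciable oscillator strength f12 is a
multi-objective search over a huge chemical space. `investga` implements
the full desk-side machinery for such a campaign:

* a **robust molecular string representation** (16-token, SELFIES-style,
  implemented natively in R) on which random token edits and string
  interpolation always yield valid molecules — the substrate of the
  genetic operators;
* **π-system filters** (neutral, closed-shell, no bridgehead/spiro atoms,
  aromaticity ≥ 0.5, conjugation ≥ 0.7, rings of size 4–8, ≤ 70 atoms
  including hydrogens) applied inside the operators;
* symmetry-aware **azaazulene scaffold enumeration**: the 8 CH positions of
  azulene under the mirror permutation σ = (1 3)(4 8)(5 7) give
  (2⁸ + 2⁵)/2 = **144** distinct nitrogen-substituted cores;
* a **generation engine** with top-20% elitism, a per-generation population
  cap, run-wide uniqueness, and constrained modes (azulene-likeness
  required; identical substituents at positions 1/6; mirror-symmetric
  substitution at 4/8 of the fixed 2,5,7-triaza core);
* multi-component **fitness** `(threshold − stg) + os − |vee − 3.2|` with
  hard −10⁶ penalty gates for violated requirements;
* a **surrogate classifier** (1024-bit Morgan fingerprints, two-hidden-layer
  network, 48/32/20 split, random-search tuning) labeling molecules good
  (stg < 0.6 and os > 0) or bad, gating the operators so only
  predicted-good structures reach property evaluation;
* hierarchical **multi-objective ranking** with absolute tolerances for
  lead selection, and a **profactual/counterfactual explainer** (9 + 9
  nearest filter-passing neighbors by fingerprint Tanimoto).

The quantum-chemistry oracle of the real workflow is abstracted behind a
pluggable contract (`function(smiles) -> data.frame(canonical, stg, os,
vee, status)`). A deterministic **synthetic oracle** — whose minimum
attainable gap is −0.13 so inversion is discoverable — and a CSV-backed
**lookup oracle** make the whole loop runnable and testable on a laptop.

Chemical perception (canonical SMILES, aromaticity, conjugation, rings,
fingerprints, substructure matching) is delegated to **RDKit**, running as
a persistent Python worker process; `python` with `rdkit` must be on the
PATH.

## Worked example

```r
library(investga)

# every Table-4-style rule, one verdict
apply_pi_filters("C1=CC2=CC=CC=CC2=C1")   # azulene
#> <filter_verdict> passed: TRUE
#>   charge         TRUE  (observed: 0)
#>   radicals       TRUE  (observed: 0)
#>   bridgehead     TRUE  (observed: 0)
#>   spiro          TRUE  (observed: 0)
#>   aromaticity    TRUE  (observed: 1)
#>   conjugation    TRUE  (observed: 1)
#>   ring_min       TRUE  (observed: 5)
#>   ring_max       TRUE  (observed: 7)
#>   substructures  TRUE  (observed: FALSE)
#>   atom_cap       TRUE  (observed: 18)

# a desk-scale campaign: mirror-symmetric 4,8-substitution on the
# 2,5,7-triazaazulene core, synthetic oracle, 8 generations of 120
cfg <- campaign_preset(6, population_cap = 120L, rng_seed = 7L)
cfg$n_generations <- 8L
res <- run_campaign(cfg, synthetic_oracle)
campaign_report(res)
#> <campaign_report>
#>   molecules generated: 621
#>   evaluated:           621
#>   oracle failures:     0
#>   likely INVEST (stg < 0.36):          621
#>   ... with appreciable OS (os > 0.05): 621
```

Every molecule in this constrained run carries the triaza-azulene core, so
under the synthetic oracle all 621 fall below the 0.36 eV INVEST heuristic;
the best candidate after 8 generations is a donor-substituted core
(`stg = 0.140`, `os = 0.490`, fitness `0.3 − 0.14 + 0.49 = 0.65`). Longer
runs (15 generations, population 500) reach the oracle's inverted-gap
region `stg < 0` — that behaviour is asserted by the acceptance tests.

Other entry points: `enumerate_core_patterns()` (the 144 cores),
`train_with_tuning()` / `gate()` (surrogate classifier),
`chimera_order()` / `select_top()` with `lead_ranking_spec("A"|"B")`
(lead ranking), `explain_molecule()` (9 + 9 explanations), and the CLI
launcher `inst/scripts/investga` (`enumerate-cores`, `filter`, `rank`,
`run`).

## What the synthetic oracle does and does not establish

The synthetic oracle is a fixed closed form on graph descriptors (azulene
cores lower the gap, aromatic ring nitrogens lower it further, H-bond
donors and conjugated size raise the oscillator strength). It reproduces
the qualitative shape of the real design landscape so the search machinery
can be tested end to end; it contains no physics, and no result obtained
with it says anything about a real molecule. See the methods vignette
(`vignettes/design-workflow.Rmd`) for the model, parameters and design
choices in full.
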