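---
title: "Methods: completing and evaluating syndrome-symptom knowledge graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: completing and evaluating syndrome-symptom knowledge graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kgceval)
```

## The setting

A TCM knowledge graph asserts typed triples among syndromes (diagnostic
patterns), subsyndromes (*Fangzheng*, "the syndrome treated by a given
prescription"), symptoms, pathogenesis factors (the location/nature
elements composing a syndrome), prescriptions and treatment methods. Its
core inference chain — symptoms point to pathogenesis factors, factors
compose syndromes, prescriptions treat syndromes — gives the graph enough
latent redundancy that missing assertions can be recovered from structure,
which is what this package exploits.

Triples are stored directed; every topology metric (components, degree,
density, closeness, k-core) is computed on the undirected view. The edge
count `M` defaults to the triple count, because the reference conventions
`⟨k⟩ = 2M/N` and `ρ = 2M/(N(N−1))` only reproduce the published
before/after table values under that reading; a deduplicated-endpoint-pair
mode is available via `completeness_report(kg, edge_mode = "simple")`.

## Completion stages and their assumptions

**Outliers.** Isolated subgraphs are connected components other than the
largest. Only components containing a SubSyndrome entity are completed, by
a `(Prescription, Treat, SubSyndrome)` link; the default resolver maps a
subsyndrome id `"<x> Syndrome"` to the prescription `<x>`, mirroring the
naming convention of prescription-derived subsyndromes. Components hinted
`Other` (treatment methods, rarely used prescriptions) are reported but
left untouched.

**Path ranking (PRA).** The score of a candidate pair is the classic
linear form `score(s, t) = Σ_j P(s → t; π_j) θ_j` plus the intercept of the
logistic fit; `P(s → t; π_j)` is the probability that a random walker
constrained to the relation/direction sequence `π_j` reaches `t` from `s`,
taking each conforming edge uniformly. Assumptions and choices:

- Feature discovery is by bounded random walks from the heads of known
  target-relation triples (defaults: `max_path_length = 3`, `n_walks =
  1000` per seed triple, both configurable; tests and the pipeline use far
  fewer walks since the feature space at length ≤ 3 is small). Inverse
  steps are allowed — the manifestation evidence path
  `Contain / CorrespondTo⁻¹` needs one.
- The classifier is a logistic-loss linear model; negatives are
  tail-corrupted positives sampled uniformly among entities of the same
  type as the true tail. On separable fixtures the weights diverge in
  magnitude; only their sign/ordering matters for ranking, so the fit
  warnings are suppressed.
- A candidate needs strictly more than 2 supporting paths (features with
  nonzero walk probability) — the literal "more than 2" reading —
  and must pass the ontology filter: every pathogenesis factor the symptom
  corresponds to must be contained by the syndrome (for `Treat`
  candidates, by at least one of the prescription's curable syndromes).
  Symptoms with no factor mapping are rejected as unmappable.

**Ontology reasoning.** Transitivity and symmetry are implemented in their
standard form (the formal statements in the source table contain
typographical slips; the prose intent is `P(x,y) ∧ P(y,z) ⇒ P(x,z)` and
`P(x,y) ⇒ P(y,x)`). Closure on cyclic data is well defined; self-loops
arising from cycles are discarded. Contradictions are `(head, tail)` pairs
carrying both relations of a declared mutual-exclusivity pair; resolution
policies are `drop_both` (default — without an expert in the loop the
safe action is to trust neither assertion), `keep_first_relation`, or an
explicit decisions table standing in for expert review.

**Association rules.** Apriori with level-wise candidate generation and
subset pruning; minimum support 0.10 by default, interpreted on the joint
itemset (standard semantics). Rules are restricted to one syndrome
antecedent and one symptom consequent, because that is the shape that
converts to a `Manifest` triple; lift > 1 is the sole filter (no minimum
confidence is applied — none is specified by the method being
implemented). Lift ties are broken by support then labels for determinism.

**Stage order.** Explicit → implicit → tacit, fixed. Contradiction removal
runs before the tacit additions so association-rule triples are never
silently deleted by a cleanup that happens to follow them.

## Evaluation dimensions

**Completeness** reports N, M, `k_max`, `⟨k⟩`, `ρ`, and the least-squares
slope of `log10(count)` vs `log10(degree)` over nonzero histogram bins. The
slope is a descriptive heavy-tail indicator, not a fitted power-law
exponent (no xmin selection, no MLE); it is deliberately excluded from
acceptance checks.

**Accuracy** combines the contradiction count with two prior-agreement
statistics: the fraction of the top-k (default 20) closeness-centrality
prescriptions found in a prior core-prescription list, and the fraction of
innermost-k-core symptoms found in a prior symptom list. Closeness is
`CC(i) = (N_c − 1)/Σ_j d_ij` within the node's component, scaled by
`(N_c − 1)/(N − 1)` (Wasserman–Faust) for cross-component comparability —
a no-op on connected graphs, which is what a completed graph should be.
Reported fractions are rounded half-up to 4 decimals, matching the
published tables' precision.

**Usability** trains TransE (`−‖h+r−t‖₂`), RotatE (`−‖h∘r−t‖` with
unit-modulus phase-parametrized relations), DistMult (`Σ hᵢrᵢtᵢ`) and
ComplEx (`Re⟨h, r, conj(t)⟩` — the canonical form; the source table's
"Re(⟨h+r−t⟩)" is not a valid ComplEx score) with per-triple SGD on the
margin ranking loss (logistic loss behind a flag), one fresh
tail-corrupted negative per positive per epoch, entity vectors renormalized
to unit L2 after each epoch. Evaluation is tail ranking with optimistic tie
handling; raw (unfiltered) ranking is the default, filtered ranking is a
flag. Hyperparameters (dimension, margin, learning rate, epochs) are not
specified by the method source and are fully exposed; published embedding
table values are therefore not reproduction targets.

## The synthetic world

`generate_kg()` emits a schema-conformant graph at roughly the scale of the
reference graph (about 1100 entities and 4700 triples at defaults) with a
planted-truth ledger:

- Symptom→factor assignment uses preferential attachment, so factor
  popularity — and hence the degree distribution — is heavy-tailed
  (log–log slope ≈ −1.3 at defaults).
- Syndromes form `Contain` chains of three; the transitive closure
  complement is withheld and recorded (ontology-recoverable). Symmetric
  differential-diagnosis pairs are emitted in one direction only.
- Withheld `Manifest` triples are guaranteed a surviving
  `Contain / CorrespondTo⁻¹` evidence path (generation fails otherwise),
  making them path-recoverable.
- Contradictions are planted as `Treat` + `ContraindicationIs` on the same
  (prescription, syndrome) pair.
- Isolated components are planted explicitly; any *accidental* stray
  component (e.g. a factor no syndrome contains) is bridged back into the
  giant component, so planted isolation is the only isolation — a property
  the ledger-exact component tests rely on.
- Planted record-mining rules sit on three syndromes with prevalences
  0.45/0.35/0.20 and penetrance 0.8, emulating the strongly imbalanced
  case mix described for the reference records (45% one syndrome, 35%
  another, the rest rare — rare-syndrome rules fall below the support
  floor, as they did in the original study). Each rule mixes symptoms
  already in the graph, withheld path-recoverable symptoms, and one
  ontology-underivable symptom that only record mining can contribute.
  Noise symptoms enter each record independently with probability 0.01 —
  the simplest exchangeable noise model.

What the generator does **not** emulate: natural-language labels, the
semantic coherence of real syndromes (factors are exchangeable), inter-rule
symptom correlation beyond shared factors, and record-level comorbidity
(exactly one syndrome per record). A green planted-recovery test therefore
establishes that the machinery recovers structure of the stated shape — not
that it would reach any particular precision on real clinical text.

## Numerical choices

- Rounding in reports is half-up to 4 decimals (`round()`'s banker's
  rounding would turn 0.34375 into 0.3437, not the published 0.3438).
- Walk probabilities conserve mass: summed over all targets they are ≤ 1,
  with mass lost exactly when the walker has no conforming edge.
- Ranking ties are resolved optimistically (rank = 1 + strictly-better
  count), making metrics deterministic.
- All randomness is seeded through a local-RNG wrapper that restores the
  caller's RNG state; identical configs give byte-identical outputs.

## Design decisions taken where the method source was open

- **Filtered ranking for the completion-direction experiment.** Restoring
  withheld true triples adds more true tails per (head, relation); under
  raw ranking those newly-trained-true tails outrank the evaluated tail
  and mask the improvement. The directional acceptance check therefore
  uses filtered ranking with a filter set fixed across both sides, and a
  depleted graph missing ~25% of its manifestation triples so restoration
  is material. With that protocol all four models improve on MR, MRR and
  Hits@10 when the withheld triples are restored.
- **Model ordering on symmetric relations.** DistMult's score is symmetric
  by construction, so on a purely symmetric-relation evaluation it is at
  least as strong as any other model; the package's property test asserts
  the theoretically sound ordering — every symmetry-capable model (RotatE,
  ComplEx, DistMult) beats TransE on held-out relation reversals — rather
  than an ordering among the capable models, which is data- and
  hyperparameter-dependent.
- **PRA negatives are sampled** (not closed-world), count configurable;
  supporting paths count feature types, not path instances.
- **`M` = triple count** by default (see above), dual mode provided.
- Run configuration files for the pipeline CLI are JSON, not YAML (no YAML
  parser among the package's dependencies).

## Known limitations

- The PRA walk-based feature discovery can miss rare evidence paths at low
  walk budgets; the feature space at length ≤ 3 is small enough that the
  defaults are generous, but the budget is the user's responsibility.
- Apriori is exponential in the number of frequent items; it is meant for
  record vocabularies of hundreds of items, not thousands.
- Embedding training is plain R SGD: adequate for graphs of a few thousand
  triples (seconds to minutes), not for large-scale benchmarks.
- Closure materializes the full transitive closure; on deep `Contain`
  chains of tens of thousands of nodes the quadratic memory would bite.
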