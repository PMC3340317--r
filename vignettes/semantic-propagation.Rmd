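---
title: "Semantic propagation: comparing, aligning and annotating network models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic propagation: comparing, aligning and annotating network models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semprop)
```

## The problem

Systems-biology models are built, compared and merged element by element:
before two SBML models can be combined, one has to decide which species,
reactions and compartments correspond. MIRIAM-style annotations — qualified
cross-references from a model element to entries in public resources such as
ChEBI, KEGG Compound or UniProt — make elements comparable across models
regardless of local naming conventions. In practice, however, many elements
carry no annotations at all, and others (a kinase in several phosphorylation
states, say) carry identical annotations that cannot be told apart.

`semprop` addresses both problems with one idea: *propagate* semantic
information along the references inside each model (reaction to reactant,
reaction to product, enzyme to reaction, species to compartment), so that an
element is described not only by its own annotations but also by those of its
network neighbourhood. An unannotated reaction between glucose and
glucose-6-phosphate inherits the identity of its substrates; two identically
annotated kinase species are separated by their different contexts.

## Feature vectors and direct similarity

Every distinct `(resource, identifier)` annotation pair — collapsed across
resources by an optional synonym table — defines one *biological concept*,
one coordinate of a shared feature space. An element's **direct feature
vector** $v_x$ is binary: component $i$ is 1 exactly when the element carries
an annotation mapping to concept $i$, and non-annotated elements have
$v_x = 0$ by definition. Binary values are the minimal faithful choice here;
the containers accept fractional confidences should a source provide them.

Two elements are compared by the normalised quadratic form

$$\sigma_{xy} \;=\; \frac{v_x^\top S\, v_y}
  {\sqrt{(v_x^\top S v_x)\,(v_y^\top S v_y)}},$$

with $\sigma_{xy} = 0$ whenever either vector is zero. With the default
$S = I$ — concepts treated as logically independent — this is exactly the
cosine of the angle between the two vectors. A user-supplied symmetric
positive-semidefinite $S$ with unit diagonal can encode known similarity
between concepts (e.g. $\beta$-D-glucose vs D-glucose); deriving such a
matrix is outside the package's scope, which is why $S$ is an opaque input.
Similarities between elements of different types (species vs reaction) are
fixed to 0 throughout. Denominators below $10^{-15}$ are treated as zero
vectors.

## Feature propagation (FP)

The network structure of a model $M$ is condensed into a sparse
$|M|\times|M|$ **propagation matrix** $R$: if reaction $x$ lists species $a$
as reactant or product, $R_{xa} = \alpha$ (the reaction receives information
from the species) and $R_{ax} = \beta$; modifier edges carry their own
weight in both directions, compartment edges likewise. Rows and columns of
*cofactor* species (ATP, NADH, water, … — matched against a shipped,
user-overridable table of ChEBI/KEGG identifiers) are zeroed: currency
metabolites are hubs that would otherwise smear similarity across unrelated
reactions.

The **inferred feature vectors** $w_x$ satisfy the self-consistent system

$$w_x \;=\; v_x + \lambda \sum_{a \in M} R_{xa}\, w_a
  \qquad\Longleftrightarrow\qquad
  W = (I - \lambda R)^{-1} V,$$

computed by a sparse LU solve (the inverse is never formed). The scaling
factor is $\lambda = c/r$ with $r$ the spectral radius of $R$ and $c = 1/2$
by default, which guarantees the Neumann series
$\sum_k (\lambda R)^k V$ converges; the solver refuses
$\lambda r \ge 1$. Elements that receive nothing keep $w_x = v_x$; on an
acyclic one-directional structure the series is exactly finite; inferred
vectors are non-negative whenever $V$ and $R$ are. The inferred similarity
$\psi^{\mathrm{fp}}_{xy}$ is the quadratic form above applied to $w$.

## Similarity propagation (SP)

SP refines the pairwise similarities directly, which also works for
similarity scores that do not come from feature vectors. Nodes of the **pair
graph** are same-type element pairs $(x \in M,\, y \in N)$; the edge from
pair $(a,p)$ into pair $(x,y)$ has weight
$Q_{(xy)(ap)} = R^M_{xa} R^N_{yp}$ — information flows only when it flows
simultaneously in both models. The inferred similarities solve

$$\psi^{\mathrm{sp}} = \sigma + \lambda\, Q\, \psi^{\mathrm{sp}}
  \qquad\Longleftrightarrow\qquad
  \psi^{\mathrm{sp}} = (I - \lambda Q)^{-1} \sigma,$$

the stationary state of a diffusion-like process with production $\sigma$
and linear decay. Because cross-type pairs are not nodes at all, an initial
species matching can never induce species–reaction similarity — the typed
subgraphs are separate by construction. SP sees strictly more context than
FP but pays for it: $Q$ has $O(|M|\cdot|N|)$ nodes against $R$'s $|M|$, so
SP costs $O(|M|^3|N|^3)$ where FP costs $O(|M|^3 + |N|^3)$.
$\psi^{\mathrm{sp}}$ can exceed 1 and is deliberately *not* clipped in the
core; clipping is a display decision.

Both solvers also expose a truncated-series mode (`max_steps = K`). With
$K = 1$ and $\lambda = 1$ the one-reaction worked example is reproduced in
closed form: two models of the same conversion with annotated reactants and
products but unannotated reactions give the reactions the inferred
similarity $\psi_{xy} = \alpha^2(\sigma_{ap} + \sigma_{bq})$. The full
fixed point and the single-step reading are both available because the
worked example is naturally stated in single-step form while the method's
definition is the fixed point.

## Greedy alignment

Given similarity tables for every model pair, the aligner repeatedly matches
the highest-$\psi$ remaining pair while $\psi > 0$ (an epsilon floor of
$10^{-12}$ avoids matching on numerical dust). A candidate that would place
two elements of one model into the same tuple is discarded and the next best
pair considered. With three or more models, matching two elements merges
their whole tuples, so transitivity holds by construction. The final score
is $f = \sum_{(x,y) \in P} \psi_{xy}$ over all matched cross-model pairs
inside tuples. Exact score maximisation is deliberately avoided — it is
computationally hard, and on instances small enough to enumerate, the tests
check the greedy score never exceeds the exhaustive optimum and attains it
whenever the similarity table has a strictly dominant diagonal.

Ties are broken lexicographically by `(model_id, element_id)` of both
members, making alignments fully deterministic — important precisely when
elements carry identical annotations and direct similarity cannot separate
them. Alignment quality is scored against a reference alignment by precision
and recall counted over matched pairs within tuples; singleton tuples
contribute no pairs (the convention when nothing is predicted is precision
1, recall 0).

## Annotation prediction

To suggest annotations for unannotated elements, a corpus of annotated
models replaces the large curated pathway map: for every corpus element its
propagated vector is computed, and for each of its annotation concepts $i$ a
copy of that vector with component $i$ zeroed is stored under concept $i$
(the leave-one-feature-out **collection**). A query element's propagated
vector is then compared (cosine on propagated vectors) against every entry;
concepts are ranked by best entry similarity, de-duplicated and truncated to
`top_n`.

Prediction uses a deliberately restricted propagation: weight $1/2$ between
reaction and reactant/product in both directions, all other edges 0, one
propagation step only ($\lambda = 1$, series truncated at $k = 1$). This
keeps suggestion lists short and local. The construction has an exact
property the tests exploit: for a corpus model lacking a single annotation
on one element, the query vector equals that element's own collection entry,
so the hidden concept is recovered at rank 1 with similarity 1 — provided no
other element carries the hidden concept in the element's one-step
neighbourhood. The query element's retained annotations do contribute to its
query vector, which is why predictions improve as more of the model is
annotated.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.5 | transfer species → reaction (dimensionless weight) |
| `beta` | 0.5 | transfer reaction → species |
| `modifier_weight` | 0.5 | enzyme/regulator edges, both directions |
| `compartment_weight` | 0 | compartment edges, both directions |
| `lambda_fraction` | 0.5 | $c$ in $\lambda = c/r$ |
| `cofactors` | shipped table | species at which propagation stops |
| `top_n` | 10 | suggestions per element |

No canonical values exist for the transfer weights; within reasonable
ranges their exact values have little influence on alignments, and the
scaling factor $\lambda$ is what prevents overly strong propagation. We set
$\alpha = \beta = 1/2$, matching the prediction-mode weight. Modifier edges
default to the same $1/2$: an enzyme's identity is genuinely informative
about its reaction, and the inferred vector of a reaction is meant to
describe "its reactants, enzyme, or regulators" alike. Compartment edges
default to 0 — nearly every species in a compartment shares it, so
compartment-mediated propagation behaves like an unblocked hub — but the
references are present in the structure, so a nonzero weight is one
configuration flag away.

## What the generators emulate — and what they do not

The fixture generators produce the three study conditions the methods are
evaluated on:

* **Linear chain** (`make_linear_chain`, default length 5): species
  $s_1 \ldots s_n$ joined by $n-1$ reactions, each species with a distinct
  single concept; in endpoint-only mode just $s_1$ and $s_n$ are annotated.
  This is the setting where direct similarity can match exactly two
  elements while FP and SP recover the entire chain.
* **Single-reaction pair** (`make_reaction_pair`): two one-reaction models
  with $\sigma_{ap} = 1/\sqrt2$, $\sigma_{bq} = 1$ and unannotated
  reactions — the closed-form worked example.
* **Random bipartite models** (`make_random_model`): Erdős–Rényi-style
  species–reaction networks, degree-capped at 4, with configurable
  annotation density, concept pool, annotations per element, and an option
  for globally unique concepts (used by the leave-one-out corpus, where
  uniqueness makes rank-1 recovery exact rather than probabilistic).
* **Removal protocol** (`remove_annotations`, `benchmark_alignment`):
  annotations are removed per *element* (all or none), matching the notion
  of "fraction of annotated model elements"; the benchmark crosses removal
  fractions $\{0, .2, .4, .6, .8\}$ with 25 replicates and all three
  measures. The shipped benchmark pair is a length-10 chain with all
  species annotated.

Synthetic fixtures share the real data's *structure* (typed elements,
role-labelled references, sparse annotations from a finite vocabulary) but
not its messiness: real curated models have skewed annotation vocabularies,
inconsistent qualifiers, cross-resource synonyms that no equivalence table
declares, and hub metabolites beyond the cofactor list. Passing tests
therefore demonstrate correctness of the algorithms and the direction of the
qualitative trends (propagation raises recall; SP ≥ FP ≥ direct on these
fixtures), not performance guarantees on curated model repositories.

## Numerical choices

* Linear systems $(I - \lambda R)W = V$ and $(I - \lambda Q)\psi = \sigma$
  are solved with `Matrix`'s sparse LU; solutions must satisfy their
  fixed-point equations to $10^{-9}$ (asserted in tests) and agree with the
  $K = 100$ truncated series to $10^{-8}$.
* The spectral radius uses dense `eigen` below dimension 200 and power
  iteration above (valid for these non-negative matrices), with a dense
  fallback when iteration stalls; $r = 0$ yields $\lambda = 1$ by
  convention, the series having only its $k = 0$ term.
* Zero-vector guards: norms below $10^{-15}$ give similarity 0; match
  candidates need $\psi > 10^{-12}$; prediction entries with similarity
  $\le 10^{-12}$ are dropped.
* All randomness flows through explicit integer seeds (`with_seed` scoping
  inside the generators), so fixtures and benchmark tables are bit-for-bit
  reproducible.

## Worked example

```{r chain}
a <- make_linear_chain(5, model_id = "chain_a")
b <- make_linear_chain(5, model_id = "chain_b")
ref <- identity_alignment(a, b)
for (ms in c("direct", "fp", "sp")) {
  tb <- similarity_table(a, b, measure = ms)
  al <- greedy_align(tb, list(a, b))
  pr <- evaluate_alignment(al, ref)
  cat(sprintf("%-7s matched pairs: %d  recall: %.2f\n",
              ms, length(alignment_pairs(al)), pr[["recall"]]))
}
```

Direct similarity matches only the two annotated endpoints; either
propagation scheme recovers all 9 species and reactions.

## Known limitations

* Only species, reactions and compartments become elements; rules, events
  and parameters are ignored, and SBML is validated no deeper than the
  parse level.
* The aligner is greedy: on adversarial similarity tables it can fall short
  of the optimal matching (bounded above by it, never below a dominant
  diagonal).
* The collection search is an exhaustive linear scan — appropriate for
  desk-scale corpora, not for a full model-repository mirror.
* Concept similarity matrices $S$ are consumed, never derived; without one,
  closely related but distinct concepts count as fully dissimilar.
* The problem sizes exercised in the test suite (models up to ~50 elements,
  pair graphs up to a few hundred nodes, 10-model corpora with ~200
  annotations) were chosen as the scale at which every property can be
  verified against independent oracles — dense eigensolvers, series
  expansions, exhaustive matching enumeration.
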