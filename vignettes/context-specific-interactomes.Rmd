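---
title: "Building weighted, context-specific interactomes with ppinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building weighted, context-specific interactomes with ppinet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppinet)
```

# The problem

A cell's protein–protein interactions (PPIs) are documented across many
databases, in records of very different reliability, and almost always
without regard to where or when the interaction can actually occur. An
analysis of, say, a human tissue or a signaling pathway therefore needs
three things done consistently: the available experimental evidence pulled
together without double counting, an honest reliability weight per
interaction, and a filter that removes interactions impossible in the
studied context. `ppinet` implements this as a deterministic pipeline over
plain text files.

# Consolidation

Input is PSI-MITAB 2.5: one tab-delimited row per interaction record, with
interactor identifiers in columns 1–2, PSI-MI detection-method terms in
column 7 and the source database in column 13. We deliberately ignore the
MITAB confidence column — weights are recomputed by our own scheme so that
scores are comparable across source databases.

Three decisions shape this stage:

* **Experimental validation.** A record survives only if at least one of
  its methods is on the validation whitelist; its method set is then reduced
  to the whitelisted subset. The default whitelist
  (`default_method_whitelist()`) covers the common experimental families
  (two-hybrid variants, coimmunoprecipitation, affinity chromatography,
  pull down, cross-linking, X-ray, NMR, FRET, SPR). It is a curated default,
  not a universal truth; projects with their own standards should supply a
  whitelist file.
* **Identifier mapping.** Raw protein identifiers map to gene identifiers
  through a user-supplied table. A protein with several gene mappings
  multiplies its records (cross product over both interactors); unmappable
  records are dropped *and counted* — silent attrition is the classic bug in
  interactome assembly.
* **Canonical, non-redundant edges.** Each unordered gene pair is stored
  once, with the lexicographically smaller identifier first; its evidence is
  the union of method accessions and source labels. An accession appears at
  most once per edge, so repeated observations of the same method never
  inflate later scoring. Consolidation is idempotent and invariant to the
  order of input sources — both properties are tested against a brute-force
  union oracle.

Self-interactions are retained as edges (they are real biochemistry) but
excluded from clustering-coefficient and degree computations, where loops
have no standard interpretation; this retain-but-exclude rule is our
documented choice.

# Reliability scoring

Weights come from a two-step Bayesian scheme anchored on GO annotations.

**Step 1 — reference sets and method ratios.** The user selects GO terms
describing a biologically coherent context (a pathway, a compartment).
Edges with *both* pair-mates annotated to the selection form the positive
set $P$; edges with *neither* annotated form the negative set $N$. Edges
with exactly one annotated endpoint are genuinely ambiguous — the two
definitions do not cover them — so they are excluded from both sets rather
than contaminating either. Because rarely used detection methods cannot be
scored on their own, near-identical PSI-MI terms are first merged into
combined methods (`default_method_grouping()`: e.g. anti-bait MI:0006 and
anti-tag MI:0007 coimmunoprecipitation under one label; the two-hybrid
variants under another). Each combined method $m$ then receives

$$\mathrm{lr}(m) = \frac{(TP_m + \alpha)/(|P| + 2\alpha)}
                        {(FP_m + \alpha)/(|N| + 2\alpha)},$$

with $TP_m$, $FP_m$ the positive/negative edges $m$ detected. Detection is
presence of the method on the consolidated edge — multiplicity was erased
by unification, on purpose.

**Step 2 — per-edge posterior.** An edge's distinct combined methods
$m_1 \dots m_k$ combine under naive-Bayes independence,
$L = \prod_i \mathrm{lr}(m_i)$, giving posterior weight
$\pi L / (\pi L + 1 - \pi)$. Each combined method contributes exactly once,
however many of its variants observed the edge.

Tunable parameters, with defaults and rationale:

| parameter | default | meaning |
|---|---|---|
| `pseudocount` ($\alpha$) | 1 | Laplace smoothing; keeps every ratio finite and strictly positive, shrinks ratios of rarely observed methods toward 1 |
| `prior` ($\pi$) | 0.5 | prior probability an edge is true; at 0.5 the weight is $L/(L+1)$ and uninformative evidence returns 0.5 |
| `terms` | — | the GO anchor; choose terms matching the biology you want scores to favor |
| `max_term_size` | unset | drop terms annotated to more genes than this; very broad terms (thousands of genes) make the positive set meaningless |
| `allowed_evidence` | all | restrict to e.g. experimental codes (`IDA`, `IMP`, …) to harden the anchor against electronic (`IEA`) annotations |

The exact parametrization of the Bayesian combination (pseudocount form,
prior) is our own fixed, testable choice; all of it is exposed as
configuration rather than hard-coded. "Annotated to" means *direct*
annotation by default; GO-graph ancestor propagation is available behind
the explicit `ancestors` argument because the right behavior depends on how
the annotation table was produced, and silent propagation is the harder
error to notice.

A scheme anchored on GO terms has a known circularity risk: if the same
terms later serve as a GO *filter*, high-weight edges are enriched by
construction. The scoring anchor and the context filter are therefore
independent arguments, and nothing forces them to coincide.

# Context filtering

Expression filtering uses per-resource thresholds: a gene is expressed when
its value exceeds the threshold in at least one selected resource
(OR-combination; `combine = "all"` is available for stringent use).
"Exceeds" is strictly greater by default and configurable to `>=` — the
boundary is a genuine toss-up, so it is explicit. When a resource provides
p-values and a p-value cutoff is set, both rules must pass within that
resource. We never normalize values across platforms: RNA-seq, microarray
and protein-level numbers live on incomparable scales, which is exactly why
thresholds are per-resource.

Both the expression filter and the GO filter apply the same dual-endpoint
rule — an edge survives only when *both* pair-mates qualify — and therefore
commute with each other, a property the test suite checks on random
networks. Raising any threshold can only remove edges (antitone), also
tested.

# Network statistics

For each network we report protein and PPI counts, connected components,
average clustering, degree distribution and (when scored) the weight
histogram on 20 equal right-closed bins over $[0,1]$. Local clustering is
$2T(v)/(d(v)(d(v)-1))$; nodes of degree $< 2$ contribute 0 to the average —
one of the two standard conventions, chosen and documented so results are
comparable across runs. Components and clustering are computed with igraph
and verified against a brute-force BFS/triangle-enumeration oracle on random
graphs of up to 30 nodes.

# What the synthetic generator emulates — and what it does not

`generate_fixture()` writes the exact formats the pipeline reads, with a
two-block structure chosen so every stage has a known outcome:

* genes partition into GO modules plus a background set, each gene carrying
  exactly one direct annotation — so complementing the selected terms
  exactly swaps the positive and negative reference sets;
* a neutral method (two hybrid) sits on every record, pinning its
  likelihood ratio near 1, while a boosted method (a coimmunoprecipitation
  variant) sits only on within-module records, forcing its ratio above 1 —
  the *sign* of every planted effect is known in advance;
* non-experimental rows, one-to-many and missing identifier mappings, and
  cross-source duplicate pairs are planted in known numbers, and a JSON
  manifest records every count the pipeline must recover.

Defaults (60 genes, 120 interactions, 2 sources, 10% non-experimental rows,
two modules of 12 genes at 25% within-module density, two expression
resources at 70% and 60% expressed) give a network large enough that
reference sets are never degenerate and small enough that the whole test
suite replays the pipeline many times in seconds. These are the study
conditions for all package-level checks.

What the generator does **not** emulate: literature-curation bias (hub
proteins attract evidence), database-specific method vocabularies,
scale-free degree structure, noisy or batch-confounded expression values,
and disagreement between annotation releases. Passing tests demonstrate
that the algorithms are implemented correctly, not that any particular
biological interactome is accurate; on real data the dominant error sources
are upstream (curation and mapping quality), which the pipeline surfaces as
counts but cannot fix.

# Numerical and degenerate-case choices

* Empty inputs: an empty MITAB file parses to an empty record set without
  warnings; an empty interactome yields all-zero statistics with average
  clustering 0 by convention.
* An empty positive or negative reference set aborts scoring with
  instructions to broaden or narrow the GO selection — there is no sensible
  silent fallback.
* A combined method seen on an edge but absent from scoring (possible only
  with a user-supplied score table) contributes ratio 1, with a warning.
* Keyword ranking (`extract_keywords()`) lower-cases descriptions, strips a
  fixed affix list (-ation, -ion, -ing, -es, -s; de-, re-), drops function
  words plus "process"/"activity", counts each keyword once per term, and
  breaks ties alphabetically — a deliberately simple, fully specified
  stemmer rather than a linguistic one, so rankings are reproducible.
* All tabular outputs are written with fixed column order and 15-digit
  weight formatting; re-running a pipeline with identical inputs produces
  byte-identical files (there is no unseeded randomness anywhere).

# Problem sizes used by the checks

The test suite runs consolidation against its brute-force oracle on over a
hundred record sets of up to 10 records, scoring against enumeration on
random interactomes of up to 20 edges and on three full fixture replicates,
and graph statistics against triangle/BFS enumeration on a hundred random
graphs of up to 30 nodes; the end-to-end check replays the default fixture
twice and compares outputs byte for byte. These sizes keep the full suite
under a minute while exercising every contract at scales where independent
enumeration is exact.

# Known limitations

* MITAB 2.6/2.7 expansion columns are ignored; only the 2.5 core layout is
  read.
* Orthology-based interaction transfer, alternative weighting schemes and
  cross-platform expression normalization are out of scope.
* The default whitelist and method grouping are curated stand-ins;
  organism- or project-specific curation should replace them.
* GO-graph propagation requires a user-supplied ancestor table; the package
  does not parse ontology OBO files.
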