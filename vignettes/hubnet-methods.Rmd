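---
title: "Methods: multi-omics pathway-network meta-analysis with hubnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics pathway-network meta-analysis with hubnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hubnet)
```

## The analysis problem

Non-functional pituitary adenoma (NFPA) has been profiled at several
molecular levels — transcriptome, proteome and post-translational
modifications — but each published dataset covers only one level and one
comparison. hubnet implements a meta-analysis that integrates nine such
heterogeneous datasets against a shared knowledge base of molecular
interactions and canonical pathways, and asks two questions:

1. Which pathways are over-represented in each dataset, and which recur
   across datasets?
2. Which molecules sit at the centre of the interaction subnetworks built
   from each dataset ("hub molecules"), which hubs recur across the
   tumour-group datasets, and which of those are corroborated by an
   independent phosphoproteomics experiment?

The nine datasets follow a fixed layout: serials 1–4 come from NFPA versus
control comparisons (quantitative transcriptomics, quantitative proteomics,
a presence-only protein inventory and a nitroprotein inventory), serials
5–6 from invasive versus non-invasive NFPA comparisons, and serials 7–9
from control pituitary inventories (proteins, nitroproteins,
phosphoproteins). Quantitative datasets carry signed fold-changes;
presence-only ("mapping") datasets do not.

## Data model and ingestion rules

Signed fold-changes use the symmetric ratio convention: `t/c` when the
quotient is at least 1, otherwise `-(c/t)`, so magnitudes are comparable
about ±1 and the open interval (−1, 1) cannot occur. Values inside that
interval are rejected at load time rather than silently normalized,
because they indicate a unit mistake (most commonly log ratios being fed
where plain ratios are expected).

Duplicate identifiers are collapsed before any analysis. For quantitative
datasets the surviving record is the one with the largest *absolute*
fold-change, sign retained. Reading "highest fold-change" as the largest
raw value would make −1000-fold repression lose to a 1.1-fold induction,
which is meaningless under the signed convention. For mapping datasets,
which carry no values, the first occurrence survives.

Identifier classification against the knowledge base mirrors the
subdataset bookkeeping of commercial pathway tools: all identifiers are
split into mapped (present in the interaction graph or any pathway) and
unmapped; the network-eligible set is the mapped set after de-duplication.
The pipeline treats the "functions/pathways-eligible" notion as identical
to network-eligible, as nothing in the analysis distinguishes them.
Identifiers are canonicalized to uppercase only; alias expansion is an
input concern, not something this package guesses at.

## Pathway over-representation

Each dataset's network-eligible molecules are tested against every pathway
with the one-sided hypergeometric upper tail (Fisher's exact right tail):
with a universe of `N` annotated molecules, a pathway of size `K`, a query
of size `n` and an observed overlap `k`, the p-value is `P(X >= k)` for
`X ~ Hypergeometric(N, K, n)`. The background `N` is the knowledge base
universe — the union of all pathway annotations and graph nodes — and can
be overridden when a different background is appropriate. Benjamini–
Hochberg correction is applied per dataset (not globally across datasets),
matching the per-dataset significant-pathway counts such analyses report;
significance is adjusted p strictly below 0.05. Pathways significant in at
least two datasets are collected into shared-pathway records and annotated
with cancer-related and panel labels. Those labels are curated inputs: the
original adjudication of "cancer-related" was a literature exercise, and
this package deliberately does not attempt to automate it.

## Network construction and scoring

The knowledge base's network-growth algorithm that inspired this design is
proprietary and undisclosed, so hubnet ships a documented, deterministic
stand-in whose outputs satisfy the properties such networks are described
to have: at most 35 nodes by default, a mix of dataset ("eligible") and
knowledge-base filler nodes, connectivity, and a −log10 overlap score.

Construction is seed-and-extend. The unassigned eligible node of highest
full-graph degree seeds a network (lexicographic tie-break). Growth then
repeatedly considers every graph neighbour of the current network and adds
the candidate maximizing, in order:

1. the number of new connections it adds to eligible molecules already in
   the network — the cohesion criterion used by seed-extension module
   detectors such as DIAMOnD;
2. its total graph degree;
3. lexicographic order.

Growth stops at `max_size` nodes or when no connected candidate remains;
then the next unassigned eligible node seeds the next network. Each
eligible node belongs to at most one network (once claimed it cannot
re-enter a later one), while filler nodes may recur. An alternative
reading of the growth priority — the number of *unclaimed eligible
molecules reachable through* the candidate — was implemented first and
rejected: it makes growth breadth-first across all eligible-dense regions
simultaneously, so coherent modules are interleaved and then truncated by
the size cap. The cohesion form keeps growth depth-first around one module
at a time, which is both the field convention and the behaviour that
preserves module structure.

Direct and indirect relationship edges contribute equally to adjacency,
degree and hub status. A hub molecule is a node adjacent to at least five
other nodes *of the same network* (induced degree ≥ 5). Adjacency, not
reachability: within a connected 35-node network nearly every node can
reach five others, which would make hub lists vacuous.

The network score is `-log10` of the hypergeometric upper-tail probability
of the network's eligible-node overlap (`k` eligible among `K` network
nodes, query `n`, universe `N`); a network with no eligible nodes scores 0.
Scores are kept at full precision internally and rounded to one decimal
only in reports. Eligible-node coverage is reported as a percentage
rounded half away from zero (23/35 → 66%, 18/35 → 51%).

## Cross-dataset hub meta-analysis

Hub occurrences from all networks are pooled. A molecule's frequency is the
number of *distinct* tumour-group datasets (serials 1–6) in which it is a
hub; several networks within one dataset count once. Control datasets
(serials 7–9) provide baseline networks but do not contribute to the
frequency, matching the convention that high-frequency tables list only
tumour-group serials. Molecules with frequency ≥ 3 are high-frequency
hubs. Each is then cross-tabulated against the phosphoproteomics results:
detected if any quantified peptide maps to it, and flagged as a large
change if its largest absolute signed ratio is at least 2.5. The detection
percentage is truncated — not rounded — to one decimal, the convention
under which 25/57 = 43.859…% prints as 43.8%.

The packaged reference table (`nfpa_hub_reference()`) transcribes the
published 57-row high-frequency hub inventory with its dataset serials and
detection flags (Greek letters romanized); it doubles as an integration
fixture and a worked example.

## Phosphopeptide quantification

The package starts after database searching: inputs are modified-peptide
strings (`#` marks methionine oxidation, e.g. `NLLHVTDTGVGM#TR`), site
tokens (`S236`, or `S236?` for ambiguous localizations, kept with a
`confident = FALSE` flag), and per-injection peak areas for a pooled tumour
and a pooled control sample, two injections each. Group areas are summed
over injections — the signed ratio is invariant to sum versus mean as long
as both groups use the same rule — and converted to the signed convention.
Rows lacking a positive area in either group are dropped with a warning;
malformed annotations go to a rejects table rather than aborting a run.

Peptide-spectrum matches are thresholded by the classical target–decoy
estimate: scanning score cutoffs from the top, the FDR at a cutoff is the
number of decoys at or above it divided by the number of targets at or
above it; the accepted cutoff is the lowest one with FDR at or below the
level (default 5%), i.e. the one admitting the most targets, with ties at
the cutoff score all included.

## The synthetic benchmark generator

No raw data accompany the study design this package implements, and the
knowledge base it presumes is proprietary. The generator therefore
fabricates both, at the study's printed scale, with known truth:

* **Universe and graph.** 2000 molecules; a preferential-attachment graph
  (3 edges per node) supplies the scale-free background typical of
  interaction databases. Edge relation labels (direct/indirect) are
  assigned at random.
* **Pathways.** 300 gene sets with sizes uniform on 10–40 (planted ones
  fixed at 30), sampled uniformly from the universe.
* **Datasets.** The nine serials reproduce the printed sizes exactly —
  280 (114 up, 166 down), 50 (21, 29), 218, 12, 346 (233, 113),
  57 (30, 27), 1469, 8, 28 — with fold-change magnitudes log-uniform on
  [1.5, 10], a realistic differential-expression range.
* **Planted pathways.** Ten pathways are enriched in chosen serials by
  forcing half their members into the dataset. Planting is restricted to
  the larger serials (1, 3, 5): in serial 7 the query is so large
  (1469/2000) that a half-pathway overlap falls *below* chance and cannot
  be significant.
* **Planted hubs.** Twenty molecules are wired as 7-cliques (hub plus six
  dedicated partners); a planted serial receives the hub and all six
  partners. Partner molecules carry only their clique edges, so each
  planted module is an isolated component of the graph. This makes hub
  recovery a construction guarantee: no other network can absorb part of a
  module, and the module's own network gives the hub induced degree 6.
  Entangled modules were tried first and are the documented reason for
  this choice: high-degree background nodes repeatedly outbid degree-6
  partners on cohesion ties (the tie-break is total degree), splitting
  modules across networks. Isolation trades some realism — real hubs are
  embedded in the global interactome — for a deterministic ground truth.
  Consequently, passing recovery tests demonstrates that the pipeline's
  bookkeeping (classification, construction, hub extraction, frequency,
  cross-tabulation) is correct, *not* that the greedy builder would
  recover hubs embedded in an adversarial background.
* **Phosphopeptides.** Planted signed ratios generate two-injection peak
  areas around a log-normal base intensity with multiplicative log-normal
  noise (σ = 0.1 by default); with σ = 0 the planted ratios are recovered
  exactly, a property the tests assert.

Everything is reproducible from a single integer seed; every emitted file
is byte-identical across runs.

### What the generator does not emulate

Real gene-symbol vocabularies and aliasing; probe-to-gene collapsing;
correlated pathway membership (real pathways overlap heavily); mass
spectra and peak integration; batch structure between the source studies.
Tests passing on synthetic data say nothing about identifier-mapping
quality on real inputs.

## Numerical and design choices

* Hypergeometric tails use `stats::phyper(k-1, ..., lower.tail = FALSE)`;
  BH uses `stats::p.adjust`. Enumeration oracles in the test suite verify
  both on small universes.
* Problem sizes in the tests: the recovery test runs the full nine-dataset
  pipeline at the study scale (2000-molecule universe), which completes in
  well under a minute; unit tests use toy universes of 12–400 molecules.
* Determinism everywhere: sorted iteration orders, explicit tie-breaks,
  fixed file formats. Two runs with the same inputs are byte-identical.
* `run_pipeline` aborts on the first stage error, naming the stage and
  input; partial output directories are possible only past validation,
  which checks all paths up front.
* The decoy-FDR cutoff is ≥-inclusive at tied scores; an input with no
  qualifying cutoff returns `NULL` rather than a sentinel score.

## Known limitations

* The network-growth algorithm is a documented stand-in; it is not claimed
  to reproduce the proprietary tool's specific networks, only their stated
  structural properties.
* Cancer-related and panel labels are inputs; the package performs no
  literature mining.
* Invasive-NFPA fold-changes (tumour-versus-tumour) are never pooled with
  NFPA-versus-control fold-changes; datasets stay separate throughout, so
  sign-compatibility across comparison types is never assumed.
* The hub-frequency convention counts datasets, not panel appearances; the
  reference table's frequency column equals the dataset count in every
  row, which fixes this reading.
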