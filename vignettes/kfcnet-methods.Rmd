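---
title: "Methods: scoring, screening and component selection in kfcnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, screening and component selection in kfcnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A multi-herb formula contains hundreds of chemical components, each hitting
many protein targets, most of which are irrelevant to any one disease. kfcnet
implements an integrated network-pharmacology workflow that asks: *which
small subset of components carries most of the formula's predicted action on
a disease?* The answer proceeds in four stages: ADMET screening, construction
of a weighted multi-layer network, importance-based extraction of a key
functional network, and greedy selection of key functional components (KFC).

## ADMET screening

A component is *active* when it passes the applicable screening rules or has
been experimentally validated at high concentration:

* Lipinski's rule of five, with its classical mixed bounds: H-bond donors
  $\le 5$, H-bond acceptors $< 10$, molecular weight $\le 500$ Da,
  $\log P \le 5$, rotatable bonds $< 10$;
* oral bioavailability OB $\ge$ 30% (threshold configurable);
* high gastrointestinal absorption class.

The sources describing these rules never state how the three screens
combine; `select_active_components()` defaults to their conjunction
(`combine = "all"`) and offers the disjunction behind a switch. A rule whose
inputs are missing is treated as *not applicable* and drops out of the
combination instead of failing it: many compounds outside curated TCM
databases lack OB annotation, and failing them wholesale would empty entire
herbs from the analysis. A record with every rule missing is inactive and
flagged. Experimental validation overrides everything, mirroring how
high-concentration compounds (e.g. rutin) belong in the active set even when
their descriptors violate the rule of five.

## The CTP network

`build_ct_network()` builds the simple bipartite component–target (CT)
graph; duplicate edges from multiple target predictors collapse to one,
following the convention that the CT network is a simple graph.
`merge_ctp()` adds an undirected protein–protein interaction (PPI) layer and
a disease-gene layer. Gene symbols are upper-cased exactly once at ingest; no
alias resolution is attempted (that would silently import a database
dependency). PPI confidence scores, when present, are carried along but
never used for filtering — no score threshold is imposed.

Each pathogenic gene carries a weight derived from the number of
publications supporting its disease association:

$$w(u) = 1 + \ln(1 + \text{publications}(u)),$$

log-damped because publication counts are heavily right-skewed (most disease
genes have a single supporting reference; a handful have dozens to
hundreds). Non-pathogenic nodes have weight 1. Pathogenic genes with no
interactions at all are kept as isolated weighted nodes: dropping them would
silently shift the median importance threshold downstream.

## Node importance

The importance score combines a node's *probability of connection* with its
damped, weight-propagating *influence* over the nodes it can reach:

$$\mathrm{score}(v) \;=\; \frac{\deg(v)}{N-1}
  \sum_{\substack{u \ne v \\ d(v,u) \le D}} w(u)\,\alpha^{d(v,u)},$$

with shortest-path distance $d$, damping $\alpha = 0.5$ and horizon $D = 3$
hops by default. The horizon bounds the all-pairs cost on large networks;
the damping makes a weighted neighbour at one hop worth four times one at
three hops. Both are arguments of `novel_importance()`. The scorer sits
behind `key_functional_network(method = ...)` next to six classical
baselines (degree, closeness, radiality, local clustering coefficient,
neighbourhood connectivity, average shortest path length), so an alternative
scoring rule can be dropped in without touching anything downstream.

Numerical conventions: distance-based centralities are computed per
connected component with their textbook definitions; a singleton component
scores 0 (closeness, radiality) or $\infty$ (average shortest path); nodes
with fewer than two neighbours have clustering coefficient 0; isolated nodes
have neighbourhood connectivity 0 and importance 0. Average shortest path is
negated before thresholding so that "key" always means "most central".

**Key functional network.** Nodes whose score *strictly* exceeds the median
score of all nodes — one joint median, not per layer — are retained together
with their induced edges. Strict inequality follows the rule's wording
("larger than the median"); with all-distinct scores at most half the nodes
survive. If every node scores the same the key network is empty and a
warning is raised. Retained nodes that end up isolated are kept and counted.

## CDR and key functional components

The contribution decision rate (CDR) model is implemented as greedy weighted
maximum coverage — the standard tractable reading of a knapsack-style
selection when no component costs are given. The coverage universe is the
set of non-component key-network nodes adjacent to at least one component
(an edge-based universe is available behind `universe = "edges"`). At each
step the component with the largest marginal gain is appended; its CDR is
that gain as a fraction of the universe. Ties break by higher key-network
degree, then lexicographic id, so rankings are bit-for-bit reproducible.
Greedy maximum coverage carries the classical $1 - 1/e$ guarantee at every
prefix size, which the test suite verifies against exhaustive search on
instances of up to twelve components, and it is exact when component target
sets are disjoint. A static single-pass ordering (rank once by individual
coverage) is available behind `order = "static"`.

The KFC are the shortest ranking prefix whose cumulative coverage reaches
the threshold (default 0.90). If the threshold cannot be reached the full
positive-contribution prefix is returned with a warning.

## Enrichment-based validation

`ora()` is a self-contained hypergeometric over-representation test:
$P(X \ge k)$ for a query of $n$ genes hitting $k$ of a term's $K$ genes in a
background of $N$, followed by Benjamini–Hochberg adjustment. The default
background is every gene appearing in the GMT file, and the default
significance rule is raw $p < 0.05$ — the cutoff quoted by the sources this
workflow follows — with an adjusted-p mode available, since modern
enrichment tools default to adjusted cutoffs; the ambiguity is surfaced as
an argument rather than hidden.

*Effective terms* are the terms significant for **both** the full predicted
target set and the disease-gene set; they serve as the reference against
which scoring methods are compared. `method_coverage()` reports, per method,
the fraction of effective terms recovered as significant when the query is
the method's key-network gene set.

## The synthetic-data generator

`generate_ctp_data()` draws a complete study — component table with ADMET
descriptors, CT edges, PPI edges, weighted disease genes, a GMT and planted
ground truth — from a single seed. Its defaults are the study-scale
conditions: 523 components over 7 herbs of which ~55% are active (9 of them
validated regardless of their descriptors), mean active-component degree
40.5 with target degree ≈ 9.4, and 2973 disease genes of which a quarter are
also predicted targets. Publication counts follow a geometric law
(1 + Geom(0.55)) with a 3% heavy mixture component, so that more than half
the genes have one supporting publication and a rare tail exceeds 40.

The PPI layer is a preferential-attachment (scale-free) graph. The 150
highest-weight disease genes form a *disease-core module*: 55% of their edge
endpoints are redirected inside the module by degree-preserving edge swaps.
Degree preservation is deliberate — degree-based centralities cannot see the
module, while weight-propagating scores can. Three hundred decoy 5-cliques
placed away from the module's halo give the clustering coefficient plenty of
triangle-rich structure that has nothing to do with the disease, as real
interactomes do. Signal annotation terms sample the module and its halo with
per-term sizes (60–140 genes) and hot shares that vary term to term, giving
a difficulty gradient rather than an all-or-nothing detection boundary;
decoy terms are random draws from a ~17,900-gene universe padded with
annotation-only null genes.

Fifteen planted key components are wired with a 3× sampling bias towards
*hot targets* (targets inside the module or one PPI hop from it, hence at
most two hops from top-decile genes) and drawn with a 4.5× degree
multiplier, the remaining components' degrees being deflated so the overall
mean stays at its requested value. The multiplier reflects what "key
component" means in this field: the components that dominate coverage
rankings in real analyses are the broad-acting, high-degree ones, so
recoverable planted truth must be broad-acting too. A planting bias alone is
deliberately insufficient: greedy coverage anti-selects components that
overlap on the same hot neighbourhood.

**What passing tests do and do not show.** The generator emulates degree
structure, weight skew, a weight-coherent module and annotation structure;
it does not emulate real interactome topology (communities beyond one
module, date/party hubs), correlated target prediction errors, or the GO
DAG. On these synthetic studies the damped-influence score and the
distance-based centralities (closeness, radiality and average shortest path
are rank-equivalent within a connected component, since each is a monotone
transform of the distance sum) select nearly identical key networks and all
saturate effective-term coverage; the weight-propagating score's advantage
shows as a tie-or-better against every baseline, a strict margin over the
clustering coefficient, and a consistently better placement of the planted
module than degree centrality gives it. Magnitude-level differences between
the top methods on real data depend on annotation-database structure the
generator does not model, and are not claimed. Likewise, CDR recovery of
planted components is compared between the weight-aware and degree key
networks as a difference of means across seeds: the two pipelines recover
similar truth fractions, with the weight-aware one ahead on average but not
strictly on every seed.

## Problem sizes and runtimes

All study-scale analyses in the tests and the acceptance script run at the
default generator conditions (~3,750-node CTP networks). Aggregate
properties use 20 replicate seeds for the method-coverage comparison and
planted-component recovery, 10 seeds in the acceptance script's medians,
200 random graphs of up to 60 nodes for the brute-force score oracles, and
exhaustive subset search up to 12 components for the greedy-coverage bound.
These sizes were chosen so the full suite completes in minutes on a single
CPU while keeping every estimate comfortably away from its decision
boundary.

## Known limitations

* Symbol matching is exact after upper-casing; records using aliases or
  non-HGNC identifiers must be harmonised upstream.
* The importance model treats the CTP graph as unweighted on edges; STRING
  confidence scores are preserved but not used.
* `extract_key_network()` computes one global median; per-layer
  thresholding, if ever wanted, must be done by calling it per subgraph.
* The CDR universe counts covered nodes (or edges); it does not model
  component costs, doses or synergies.
* Distance computations materialise distance-matrix slabs; networks beyond
  ~50,000 nodes would need a sparser implementation.
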