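---
title: "Methods: A-B-C discovery, sense disambiguation, and the synthetic evaluation world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: A-B-C discovery, sense disambiguation, and the synthetic evaluation world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Literature-based discovery (LBD) looks for *hidden knowledge*: pairs of
biomedical concepts that have never been published together but are both
connected to a common linking concept, so that a connection between them is
plausible and worth a researcher's attention (Swanson's A-B-C schema — a
paper links A with B, another links B with C, so A–C is hypothesized).
Working with surface words over-generates badly, and one major source of
over-generation is lexical ambiguity: if one publication connects A to sense
B1 of an ambiguous term and another connects sense B2 to C, a word-level
system manufactures an A–C "discovery" that no reading of the literature
supports. Mapping text to concept identifiers (CUIs) via word sense
disambiguation (WSD) is the standard remedy — but WSD is itself errorful,
so the practical question is how strongly LBD quality is coupled to WSD
quality. This package implements the full pipeline — concept mapping,
pluggable WSD, matrix-based discovery, time-sliced evaluation — together
with a synthetic-world generator so that the coupling can be measured end to
end on a desk, without licensed resources.

## The discovery model

Documents are reduced to the concepts assigned in their **titles** (title
co-occurrence is the classic, conservative relation; abstracts are stored
but unused for counting). Over a document collection the package builds a
sparse symmetric matrix \(A\) with

\[ a_{ij} = \#\{\,d : \text{concepts } c_i \text{ and } c_j \text{ are both
assigned in the title of } d\,\} \]

(one count per document by default; mention-level counting is a config
option, see `build_matrix(counting=)`). The square \(B = A^2\) counts
weighted length-2 paths, so

\[ \text{hidden knowledge} = \{\,(i,j) : B_{ij} > 0 \text{ and } A_{ij} = 0\,\}. \]

`hidden_knowledge()` reports each pair with `score` \(= B_{ij}\) (the natural
matrix-native ranking statistic) and `link_count` (number of distinct
linking concepts); `open_discovery()` restricts and ranks from a chosen A
term. The diagonal of \(A\) is forced to zero before squaring so that self
co-occurrence cannot inflate path counts. Before any counting, concepts
whose semantic types are *all* in a user-supplied exclusion list are removed
(`filter_concepts()`); untyped concepts are kept, since missing typing is
not evidence of uninformativeness. The exclusion list is deliberately a
config input: the field practice is a manual selection of uninformative
types (roughly half of a UMLS-style inventory), and no authoritative list is
bundled.

## Sense disambiguation backends

All backends consume the mention table of `match_corpus()` — greedy,
leftmost, longest-match lookup of normalized inventory terms, with 0-based
half-open offsets over the normalized title — and return, per mention,
either a member of its candidate set or an abstention (`NA`). Ties are
always broken toward the lexicographically smallest CUI.

* **random** — uniform over candidates; the floor.
* **first_sense** — always the lexicographically first candidate. This is
  the *sense-collapsing* annotator: every occurrence of a term maps to one
  concept, which is exactly the failure mode that produces confound-driven
  spurious discoveries.
* **oracle** — gold with probability `target_accuracy`, otherwise a uniform
  wrong candidate; monosemous mentions always correct. This stands in for
  WSD systems of arbitrary quality (including the out-of-scope rule-based
  mapper) and drives the accuracy sweep.
* **ppr** — personalized PageRank over an undirected concept relation
  graph. The rank vector solves \(r = d\,M r + (1-d)\,p\) with
  column-stochastic \(M\), damping \(d = 0.85\), and teleport vector \(p\);
  mass reaching edgeless nodes is redistributed to \(p\), keeping
  \(\sum r = 1\). The default single-pass mode runs one PPR per document
  with \(p\) uniform over all candidates of all its mentions and assigns
  each mention its best-ranked candidate; per-target mode reruns per
  ambiguous mention with its own senses removed from \(p\) (the tool the
  approach descends from documents the single-pass wording, not the
  teleport details, so both are provided).
* **vsm** — sense-centroid vector space model. Mention context features are
  the lemmas of sentence content words plus all tokens within ±`window`
  (default 4) tokens; centroids are arithmetic means of pseudo-labeled
  training vectors; cosine similarity decides. Training data comes from
  `generate_pseudo_labels()`: mentions of *monosemous relatives* —
  unambiguous terms sharing a concept with some ambiguous term's sense —
  are harvested as labeled instances (the co-occurring-concepts variant of
  pseudo-labeling is out of scope).

### Parameters that matter

| parameter | default | why |
|---|---|---|
| `damping` | 0.85 | conventional PageRank damping; the upstream tool is cited without parameters |
| `max_iter`, `tol` | 30, 1e-9 | knowledge-graph WSD practice; 30 sweeps rank senses reliably but for numerical work (agreement with a direct linear solve) `max_iter` must be raised — the tests use up to 5000 |
| `window` | 4 tokens | the ±4 window of the centroid-based system; token units (the source leaves the unit unstated) |
| stoplist | ~55 function words | shipped in `inst/extdata/stoplist.txt`; only sentence features are stoplisted, window features are not |
| lemmatizer | identity | lemma-aware behaviour is pluggable (`lemmatizer=` argument); nothing tested depends on real lemmatization |
| counting | document | "frequency with which a CUI is linked" read as document frequency; mention counting available |
| cutoff semantics | `year <= cutoff` is pre | matches a 2000–2005 generation segment vs a 2006-onward gold segment |

## Time-sliced evaluation

`build_timeslice_gold()` extracts all title co-occurrence pairs from
post-cutoff documents and eliminates every pair already seen in or before
the cutoff year; what survives is "new published knowledge".
`evaluate_lbd()` is plain set arithmetic over unordered CUI pairs;
`evaluate_wsd()` aligns predictions to gold sense instances by
`(doc_id, char_span)` and reports precision over attempted, recall over
gold, and their harmonic mean (percentages printed to one decimal).
`scaled_f()` divides every system's F by the best F so the reference system
scores exactly 1 — the plain-ratio reading of "scaled F"; a
links-generated normalization is *not* applied, but `n_hidden` is always
reported so readers can apply one. The same semantic-type filter can be
applied to the gold side so both sides share a concept vocabulary; the
sweep driver does this.

`run_accuracy_sweep()` is the experiment in a function: for each (target
accuracy, seed), annotate pre-cutoff documents with the oracle, build the
matrix, extract hidden knowledge, score against the gold built from gold
sense annotations of the full timeline; per-accuracy means are scaled-F
normalized. On synthetic worlds the gold segment is annotated with the
generator's own truth (which system annotated the real gold segment is
unknowable from the source; in real-data mode that choice is the caller's).

## The synthetic world

`generate_world(world_config())` emits a complete input set — inventory,
semantic types, relation graph, dated corpus, gold senses — plus planted
truth. The default config **is** the stated world of the test suite: 200
concepts, 150 terms (30 % ambiguous, ≤3 senses, 20 % multiword), 30 planted
triples, 5 confounds, 800 pre / 400 post documents around cutoff 2005
(years uniform in cutoff−5..cutoff and cutoff+1..cutoff+5, mirroring a
2000–2005 vs 2006+ split), distractor rate 0.5. Unstated constants were
fixed once: 10 semantic types with half excluded (mirroring the ~70-of-133
removal ratio of real deployments), and 5 % of concepts as "noise" hubs
carrying excluded types, which attach to otherwise unrelated titles — the
*geographical location* effect that semantic-type filtering exists to
remove.

Structure, and what it buys the tests:

* **Planted triples.** Per triple, pre-cutoff titles realize (A,B) and
  (B,C), never (A,C); one post-cutoff title realizes (A,C). Planted
  concepts appear in no other titles, so with gold senses every planted
  pair is recoverable hidden knowledge *and* in the time-slice gold — the
  100 %-recall acceptance check. Where the term budget allows, B is a sense
  of an ambiguous term, so WSD errors directly sever or distort the
  discoverable paths; this is what makes LBD quality respond to oracle
  accuracy in the sweep.
* **Topics.** Non-noise concepts are partitioned into topics of ~8;
  relation-graph edges are within-topic cliques plus the planted A–B/B–C
  edges. Coherent background titles draw concepts from one topic, so an
  ambiguous mention's context is graph-adjacent to its gold sense and PPR
  has signal; distractor titles (half, by default) draw across topics and
  give PPR nothing. Planted and confound concepts are clique members too:
  with only their minimal edges they would have degree 2, and PPR would
  prefer them *because* low-degree teleport seeds hoard rank mass — a pure
  graph-shape artifact that inverted the PPR-beats-random property until
  degrees were made uniform. Graph edges never enter the co-occurrence
  matrix, so corpus guarantees are unaffected.
* **Ambiguity.** Each ambiguous term's senses live in different topics
  (disjoint contexts). Surface tokens are globally unique per term, so
  `match_corpus()` provably recovers the construction — the generator is
  its own matching oracle.
* **Confounds.** `plant_ambiguity_confound()` adds, per confound, a fresh
  two-sense term and two pre-cutoff titles A′–B1 and B2–C′ with no true
  A′–C′ link. Under gold senses the paths stay separate (0 spurious
  pairs); under the first-sense collapser both titles share one linking
  concept and the spurious (A′,C′) appears — at least one per confound.
  Note the accuracy-0 oracle does **not** reproduce this: it flips each
  mention to the *other* sense, so the two titles still disagree on the
  linking concept; sense collapse, not mere inaccuracy, is the mechanism.
* **Determinism.** Everything flows from the config seed through one
  generator; regenerating and rewriting a world is byte-identical.

What the generator does *not* emulate: linguistic realism (titles are
bags of synthetic terms), realistic frequency distributions, abbreviation
or gene-name ambiguity as distinct mechanisms, and the scale of a real
bibliographic database. A green end-to-end test therefore establishes the
*mechanics* — matching, disambiguation, counting, squaring, slicing and
scoring compose correctly and respond to WSD quality in the right
direction — not performance on real literature.

## Numerical and degenerate-input choices

* PPR stops at L1 change < `tol` or `max_iter` sweeps; scores are
  renormalized to sum exactly 1 on return. Dense-solve agreement at 1e-6 is
  a property of the converged iteration, so correctness tests raise
  `max_iter` rather than loosening tolerances.
* A mention abstains when: no candidate is a graph node; a lone mention's
  candidates have no edges (single-pass) or no context exists (per-target);
  its feature vector is empty/zero (VSM); or no candidate has a centroid.
* Precision with zero attempts is reported as 0 with an
  `undefined_precision` flag; `scaled_f()` refuses an all-zero F set.
* Cosine of a zero vector is undefined → abstain, by rule, not by NaN.
* All ties (PPR ranks, cosines, pair orderings) resolve to the
  lexicographically smallest CUI, making every output order-deterministic.
* `year_range` must be non-empty; malformed corpus records fail loudly with
  the record index and field named.

## Known limitations

* The VSM backend's coverage is bounded by pseudo-label availability; on the
  default world many ambiguous senses have no monosemous relative in the
  corpus, so it abstains often and its attempted-only accuracy can fall
  below random when only a wrong sense has a centroid. This mirrors the
  low recall such systems show in practice and is reported, not patched.
* The term matcher is a declared stand-in for a full lexical mapper: greedy
  longest-match over normalized tokens, no abbreviation expansion, no
  gene-name normalization.
* The CLI config dialect is JSON (not TOML/INI): no TOML parser is
  available in the supported dependency set, and jsonlite is; sections and
  flag overrides are otherwise as designed.
* Absolute published pair counts (billions of candidate pairs from a full
  bibliographic database) are out of desk-scale reach by design; only
  derivable arithmetic and the qualitative accuracy–performance coupling
  are asserted.
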