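---
title: "Ranking diseases from MeSH-annotated literature: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking diseases from MeSH-annotated literature: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meshrank)
```

## The model

MEDLINE records are manually indexed with MeSH (Medical Subject Headings)
descriptors. Descriptors sitting in the disease branches of the MeSH tree —
categories C01 through C26, plus F02 and F03 for psychological phenomena and
mental disorders — label the diseases a publication is about. `meshrank`
turns this curated indexing into a disease search engine: any query that
returns a set of publications induces a ranking of diseases by how
over-represented each disease's literature is within the query's
publications.

Formally, let $m$ be the number of publications in the publication-to-disease
link table, of which $j$ involve disease $D$. Suppose $n$ of the $m$ are
retrieved for the query and $k$ of those $n$ involve $D$. Under the null
hypothesis that the query's publications are an exchangeable draw from the
table, $k$ follows a hypergeometric distribution, and the disease's score is
the negative log upper tail:

$$ S_D = -\log_{10} f(m,n,j,k), \qquad
   f(m,n,j,k) = \sum_{i=k}^{\min(n,j)}
   \frac{\binom{j}{i}\binom{m-j}{n-i}}{\binom{m}{n}}. $$

Diseases are reported in decreasing score order. **No multiple-testing
correction is applied**: the raw tail probability is the ranking statistic,
not a calibrated p-value, and scores from queries with different $n$ are not
directly comparable as significance statements.

### Assumptions worth stating

* The null model treats the query's publications as a simple random draw
  from the table. Real queries are topically coherent, so *every* disease
  co-occurring with the topic is somewhat enriched; the ranking is
  meaningful, the absolute tail probabilities are anti-conservative.
* Disease assignment is taken at face value from MeSH indexing. Indexing
  depth varies by journal and era; a disease's $j$ reflects indexing
  practice as much as literature volume.
* A publication either involves a disease or it does not; repeated headings
  on one record count once.

## The link table

A publication enters the table iff it is dated on or after the `min_date`
floor (default 1960-01-01, the start of consistent MeSH indexing) and
carries at least one disease-passing heading. Publications with no disease
heading are excluded entirely, so $m$ counts only disease-bearing
publications — this follows from defining $m$ as the size of the
publication-to-disease link table rather than of MEDLINE.

Headings are resolved against the vocabulary by exact descriptor-name
string. Name matching keeps fixtures human-writable and matches how MeSH
headings appear in MEDLINE XML; descriptor UIs are carried through the
vocabulary for tooling that prefers them. Headings absent from the
vocabulary are ignored with a logged count rather than an error: MEDLINE
records routinely carry supplementary-concept and qualifier strings that are
not main headings.

### The disease-branch filter

* `included_prefixes` — default `C01`…`C26`, `F02`, `F03`. Matching is
  *dot-boundary aware*: a tree number matches a prefix iff it equals the
  prefix or extends it through a `"."`. This is what keeps a hypothetical
  `C260.1` from matching `C26`; MeSH tree codes make the boundary rule
  necessary even though no current release exercises it.
* `excluded_names` — default `"Disease"`, `"Disease Progression"`,
  `"Disease Attributes"`, `"Disease Models, Animal"`: headings inside the
  disease branches that are too unspecific to be useful answers. Exclusion
  is by exact, case-sensitive canonical heading, because MeSH headings are
  canonical strings; the list is a plain argument, so alternative policies
  are one call away.
* Only descriptors participate. Qualifiers (subheadings) and supplementary
  concept records are out of scope by design: the method reasons about
  main-heading disease annotation only.

## Prioritization details

* $n$ counts only query PMIDs present in the table. PMIDs the query
  retrieved but the table lacks (no disease heading, pre-dating the floor,
  not indexed) are dropped from the contingency and reported in the run
  summary — the hypergeometric model draws from the table, so they cannot
  participate.
* **Log-space evaluation is mandatory, not cosmetic.** Production-scale
  tables have $m$ in the millions and strong queries reach scores in the
  thousands, i.e. tail probabilities around $10^{-1000}$ and far below the
  smallest positive double. Each summand is evaluated as a sum of
  `lchoose` terms (log-gamma) and the series is collapsed with
  log-sum-exp, so scores stay finite for every valid contingency. A
  certain-event shortcut returns an exact 0 (log scale) when even the
  least favourable draw must contain $k$ marked publications, avoiding
  $10^{-16}$-sized rounding residue where the tail is exactly 1.
* Ties: equal scores are ordered by $j$ descending — among equally
  surprising diseases, the better-documented one is shown first — and
  residual ties by disease name ascending so output is deterministic. The
  direction of the $j$ tie-break was an open choice; surfacing
  well-supported diseases first matches the intended use as a search
  engine.
* Supporting publications for each disease are its $k$ query hits ordered
  by date, most recent first by default (`newest_first = FALSE` flips it);
  chronological ordering is all downstream consumers rely on.
* A query with no table-resident PMIDs yields an empty ranking with a
  logged notice, not an error: an empty result is a legitimate answer.
* The result list is unlimited by default (`max_diseases = Inf`); a cap is
  presentation, not statistics.

## Evaluation machinery

Gold standards are built from a neutral association-table schema (`term`,
`disease`, `source`, `publication_count`, `evidence`) rather than any one
database's file dialect, with two named sources, `"GAD"` and
`"CTD_curated"`, combined under four stringency criteria: union;
union with at least `min_pubs` (default 2, i.e. "more than one") supporting
publications in every database in which the pair appears; intersection;
intersection with the count threshold in both. The four relevant sets nest
by construction, which is what drives the precision/recall trade-off as
stringency grows. The drug benchmark keeps only `CTD_curated` rows whose
evidence code is exactly `"therapeutic"` (case-sensitive — evidence codes
are controlled vocabulary).

Metric conventions, chosen where the definitions leave room:

* Average precision gives relevant-but-never-retrieved items a
  contribution of 0 (the standard IR convention).
* Precision at $k$ keeps the denominator at $k$ even when fewer than $k$
  items were retrieved, penalising short lists.
* An empty retrieved list has precision 0 (not undefined).
* Reported mean F is the mean of per-query F values, not the F of mean
  precision and recall.

## The synthetic-corpus generator

The generator exists so the full pipeline — retrieval, table construction,
scoring, evaluation — runs offline with known ground truth. Each synthetic
publication receives a uniform-random date, a `"Humans"` heading (so
vocabulary filtering is always exercised), and a set of 1–3 disease
headings drawn without replacement from a background multinomial. The
background defaults to a Zipf profile (weight $\propto 1/i$) because
literature disease frequencies are heavy-tailed. Publications assigned to a
planted query carry the query's token in their title — the offline fixture
backend retrieves by case-insensitive whole-token match over title +
abstract — and their disease-draw weights have the target diseases
multiplied by the enrichment factor and renormalized; multiplier 1 is
exactly the null.

The association-table generator emits each planted pair under both sources
with publication counts of at least 2, so at zero noise all four criteria
coincide. With positive noise an association is perturbed (one source
dropped, or one count set to 1) with a probability that *shrinks with
enrichment strength*: weakly enriched associations are the ones a single
curated database tends to miss, which mirrors how double-curated,
well-studied associations are also the retrievable ones. An `n_spurious`
option adds single-source associations involving diseases never planted in
the corpus — curated links the literature does not support. Both features
are what make the benchmark reproduce the canonical stringency trade-off
(recall rising and precision falling from the union criterion to the
thresholded intersection); with strength-blind noise the dropped and
retained pairs would be equally retrievable and the recall trend would be
flat in expectation.

What the generator does *not* emulate: MeSH co-annotation structure
(comorbidity, hierarchy), abstract text, indexing-depth drift over time,
and PubMed's query translation. Passing tests therefore demonstrate the
statistical machinery and the pipeline plumbing, not retrieval quality
against real PubMed.

## Problem sizes used by the test and acceptance workloads

Chosen as the smallest sizes at which the checked effects are
unambiguous: rank-recovery uses 100 replicates of a 2,000-publication,
50-disease corpus with one query enriched 8× over 50 publications (the
planted target is a mid-frequency disease, index 10 of the Zipf profile);
the null calibration re-draws the planted target uniformly per replicate at
multiplier 1 and compares its mean rank percentile with an empirical null
assembled from non-target diseases of the same replicates; the evaluation
benchmark uses five queries with six targets each (enrichment 2–20×) in a
2,500-publication, 60-disease corpus with noise 0.35 and four spurious
associations per term. The exhaustive oracle check covers every valid
contingency with $m \le 12$ against a direct enumeration of all
$\binom{m}{n}$ draws.

## Known limitations

* The fixture backend is a token matcher, not PubMed: no field tags, no
  translation, no synonym expansion. The live E-utilities backend forwards
  queries verbatim and respects rate etiquette, but is necessarily
  untested offline.
* Query ambiguity is not handled: a symbol that is also a journal
  abbreviation (the classic *REN* case) retrieves both literatures and the
  ranking reflects the mixture.
* Scores are enrichment statistics, not causal claims; a disease heavily
  co-published with a query term may be an artefact of study design.
* The production-scale link table (13M publications) is out of scope for
  the test corpus sizes here; the implementation is vectorised but
  deliberately plain data-frame R, adequate to a few hundred thousand
  records per build.
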