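---
title: "Co-citation search: method, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-citation search: method, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocite)
```

## The problem

Finding the studies eligible for a meta-analysis or systematic review is
usually done with exhaustive keyword searches that retrieve thousands of
articles, nearly all irrelevant. `cocite` implements an alternative that
exploits the citation network instead of terminology. It assumes the
reviewer *knows* one or more eligible studies at the outset. Every
article that cites a known study contributes its reference list; any
work appearing on those lists has been co-cited with a known study, and
the number of distinct citing articles listing it — its co-citation
count $c$ — measures how strongly the literature associates the two.
Eligible studies tend to rank near the top of this list, so screening
only the high-ranking candidates recovers most included studies at a
small fraction of the keyword search's screening burden.

Direct (backward/forward) citation checking alone is not sufficient:
included studies are often split across several disconnected direct
citation components, while co-citation links through third-party citers
bridge them. Conversely, a study published too recently to have been
cited is invisible to co-citation, which motivates the second,
direct-citation stage.

## The statistics

For a candidate work $i$ with co-citation count $c_i$ among $n$ citing
articles (after filtering), the package computes

* the **co-citation count** $c_i \in [1, n]$, counting *distinct* citing
  articles (a work listed twice in one reference list counts once), and
* the **j-index** $j_i = 100\, c_i / n$, the count as a percentage of the
  citing set, which makes thresholds comparable between sparsely and
  densely cited topics.

Four selection rules are provided:

| rule | keeps | typical use |
|---|---|---|
| `select_min_count(tab, 1)` | everything co-cited at least once | upper bound on recall |
| `select_min_count(tab, 2)` | $c_i \ge 2$ | the standard restrictive threshold |
| `select_frequent(tab)` | smallest stratum prefix with 100–150 works | fixed screening budget |
| `select_composite(tab)` | $c_i \ge 2$ **and** $j_i > 1\%$ | standardized two-stage protocol |

Because $j_i > 1\%$ is implied by $c_i \ge 2$ whenever $n \le 100$, the
composite rule degrades exactly to the count rule for sparsely cited
topics and is driven by the index for densely cited ones; the test suite
verifies this identity exhaustively for $n = 1,\dots,99$.

The second search stage (`expand_direct`, `select_direct`) ranks every
work that cites or is cited by members of the query set — the seeds plus
the stage-1 selection — by the number of *distinct* query members linked
in either direction (a pair linked both ways counts once, since "cites
or is cited by" is a property of the pair). Works with two or more links
are added to the screening set. This stage exists specifically to pick
up recent, still-uncited studies, which reach it by citing several
already-retrieved works.

Evaluation mirrors how such searches are benchmarked against published
meta-analyses: **retrieval** (accuracy) is the percentage of the
meta-analysis' included studies present in the screening set, and
**screening** (efficiency) is the screening set's size as a percentage
of the number of articles the original keyword search screened. Both are
rounded to whole percentages, half away from zero. Missed studies are
categorized by the precedence rule abstract → non-English →
pre-1975 → recent → other, the strata that co-citation
searching systematically misses because the citing community rarely
cites them.

## Numerical choices

* **Rounding.** All reported percentages use nearest-integer rounding
  with halves away from zero, which reproduces every percentage cell of
  the bundled replication benchmarks (e.g. 62/8,646 → 1 %,
  780/784 → 99 %). An epsilon of $10^{-9}$ absorbs floating-point
  representation of exact halves.
* **Medians.** `aggregate_reports()` takes even-length medians as the
  mean of the two middle values, then rounds. Percentage columns are
  medianed on their *unrounded* values and rounded once at the end;
  medianing pre-rounded percentages can drift by a point (the bundled
  study-2 screening medians are 29 % and 50 % under the unrounded rule
  but 30 % and 51 % otherwise, and only the former match the benchmark's
  own summary figures).
* **Tie-breaks.** Within equal counts the ranked table is ordered by
  ascending refkey under C collation, so output files are byte-identical
  across runs and platforms. Ties never affect which works are
  *selected*, because every selection keeps whole count strata.
* **`select_frequent`.** When several thresholds land in the 100–150
  window the largest (most efficient) is used; when none does, the
  threshold closest to 100 wins, with equidistant ties resolved toward
  the smaller set. The window rule is the codified part of what is, in
  practice, partly a judgment call on densely cited topics.
* **Date cutoff.** Citing articles with year strictly greater than the
  cutoff are dropped (year granularity; finer dates are not reliably
  present in exports); unknown years are retained with a message, since
  dropping them silently would bias against older literature. Whether
  the cutoff also applies to stage-2 candidates is a switch
  (`cutoff_stage2`, default `TRUE`).
* **Degenerate inputs.** A seed with no citers yields a valid empty
  table (`n_citing = 0`); `select_frequent` on an empty table and a
  j-index with `n_citing = 0` are errors, since no threshold or
  percentage is defined.

## Reference identity

Co-citation counting requires collapsing duplicate reference strings to
one identity. The key rule is deliberately simple and deterministic:
a normalized DOI when present, otherwise the normalized join
`surname|year|source|volume|first_page` (lowercased, punctuation
stripped, whitespace collapsed). It is case- and spacing-insensitive by
construction — a property the tests exercise with 1,000 random
perturbations — but it is *not* probabilistic record linkage: the same
work recorded once with and once without a DOI yields two keys, and
author disambiguation is out of scope. Within a single database's
consistently formatted exports this is the behaviour wanted; across
heterogeneous sources a dedicated linkage step should precede `cocite`.

## What the simulator emulates — and what it does not

`generate_corpus()` plants `n_eligible` eligible studies in a corpus of
`n_citing` citing articles, a shared pool of `n_noise` related-but-
ineligible works, and per-citer one-off background references:

* Each citing article includes each eligible work with probability
  `p_cite_eligible` (default 0.3) and each noise work with
  `p_cite_noise` (default 0.006), independently. Counts are therefore
  exactly Binomial, which the tests use as a distributional oracle
  (chi-square goodness of fit on a pure-noise corpus).
* A negative-binomial number of unique background references per citing
  article (mean 5, dispersion 5) supplies the long singleton tail; under
  the defaults ~85–90 % of candidates are co-cited exactly once,
  matching the shape seen in real co-citation data, where about 80 % of
  candidates are singletons.
* 40 % of citable eligible studies get no direct edges to other eligible
  studies (the "disconnected" stratum a direct-citation search cannot
  reach), and 10 % are recent and uncited, citing 2–3 older eligible
  works instead — retrievable only by stage 2.
* Metadata strata (abstract 3 %, non-English 5 %, pre-1975 3 %) feed the
  missed-study classifier.
* One seed governs everything; each citing article draws from its own
  substream, so enlarging a corpus never perturbs existing articles.

Defaults (15 eligible, 80 citers, 1,200 noise works) describe a
mid-sized topic and were chosen for the singleton-fraction shape above,
with sizes small enough that a full two-stage search runs in well under
a second; the property suites run 10–50 replicates in seconds.

The generator is deliberately *not* a fitted model of real citation
graphs: there is no preferential attachment, no topic drift, no
correlated citing behaviour (review articles citing everything), and
noise works never cite anything. Passing the in-silico recovery
properties therefore shows the pipeline's logic is sound under its own
assumptions — not that real-world recall will match; for that, the
bundled benchmark tables of two replication studies against a real
citation database are the reference point.

## Known limitations

* Reference identity is rule-based; OCR-mangled strings or metadata
  inconsistencies split identities and deflate counts.
* Works cited but not indexed in the corpus are first-class candidates
  (identified by key only) but contribute no backward citations in
  stage 2 and no metadata to the missed-study classifier.
* The method inherits the citation community's blind spots: abstracts,
  non-English and very old literature are systematically under-cited
  and hence under-retrieved, whatever the threshold.
* Heterogeneous review topics whose studies do not cite one another
  violate the method's core assumption; no threshold setting rescues
  that case.
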