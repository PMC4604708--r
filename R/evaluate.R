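# Citation-network bookkeeping and evaluation against a gold standard.
#
# Accuracy is the fraction of a meta-analysis' included studies present
# in the selected set; efficiency is the selected set's size as a
# fraction of the number of articles the original keyword search
# screened. Both are reported as percentages rounded half away from
# zero.

#' Direct-citation network of a study set
#'
#' Builds the undirected direct-citation graph restricted to a set of
#' studies: an edge joins a and b when the indexed article for a lists
#' b's key or vice versa. Studies not indexed in the corpus become
#' isolated nodes. Connected components come from igraph; a
#' "disconnected" study is a singleton component with no direct link to
#' any other study in the set.
#'
#' @param corpus a [citation_corpus()].
#' @param studies non-empty character vector of refkeys.
#' @return list of class `study_network`: `nodes`, `edges` (two-column
#'   data frame), `membership` (named component index), `n_components`,
#'   `n_disconnected`.
#' @export
build_study_network <- function(corpus, studies) {
  studies <- unique(as.character(studies))
  if (!length(studies)) stop("study set is empty")
  ids <- vapply(studies, function(k) id_for_key(corpus, k), character(1))
  if (anyNA(ids)) {
    cocite_msg(sum(is.na(ids)), " study(ies) not indexed become isolated nodes")
  }
  from <- character(); to <- character()
  for (i in seq_along(studies)) {
    if (is.na(ids[[i]])) next
    hit <- intersect(corpus$articles[[ids[[i]]]]$cited_refs, studies)
    hit <- setdiff(hit, studies[[i]])
    from <- c(from, rep(studies[[i]], length(hit)))
    to <- c(to, hit)
  }
  edges <- unique(data.frame(
    a = pmin(from, to), b = pmax(from, to), stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = studies))
  comp <- igraph::components(g)
  deg <- igraph::degree(g)
  structure(list(
    nodes = studies, edges = edges,
    membership = comp$membership[studies],
    n_components = comp$no,
    n_disconnected = sum(deg[studies] == 0)
  ), class = "study_network")
}

#' @export
print.study_network <- function(x, ...) {
  cat("<study_network>", length(x$nodes), "studies,", nrow(x$edges),
      "direct links,", x$n_components, "components,",
      x$n_disconnected, "disconnected\n")
  invisible(x)
}

#' Categorize studies a search failed to retrieve
#'
#' Assigns each missed study the first matching category in precedence
#' order: `abstract` (available only as an abstract), `non_english`
#' (language recorded and not English), `old_pre1975` (published before
#' 1975), `recent` (published in or after `search_year`, i.e. too new to
#' have accumulated citations), else `other`. Studies not indexed in the
#' corpus have no metadata and fall to `other`.
#'
#' @param missed_keys character vector of refkeys.
#' @param corpus a [citation_corpus()], or `NULL` (everything `other`).
#' @param search_year the year the search was run; `NULL` disables the
#'   `recent` category.
#' @return data frame with columns `refkey`, `category`.
#' @export
classify_missed <- function(missed_keys, corpus = NULL, search_year = NULL) {
  cat_of <- function(k) {
    id <- if (is.null(corpus)) NA_character_ else id_for_key(corpus, k)
    if (is.na(id)) return("other")
    a <- corpus$articles[[id]]
    if (identical(a$doc_type, "abstract")) return("abstract")
    if (nzchar(a$language) && tolower(a$language) != "english") {
      return("non_english")
    }
    if (!is.na(a$year) && a$year < 1975) return("old_pre1975")
    if (!is.null(search_year) && !is.na(a$year) && a$year >= search_year) {
      return("recent")
    }
    "other"
  }
  data.frame(refkey = as.character(missed_keys),
             category = vapply(as.character(missed_keys), cat_of,
                               character(1), USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

new_evaluation_report <- function(n_screened, n_screened_original,
                                  n_included, n_retrieved, missed) {
  structure(list(
    n_screened = n_screened, n_screened_original = n_screened_original,
    screening_pct = pct_of(n_screened, n_screened_original),
    screening_pct_exact = 100 * n_screened / n_screened_original,
    n_included = n_included, n_retrieved = n_retrieved,
    retrieval_pct = pct_of(n_retrieved, n_included),
    retrieval_pct_exact = 100 * n_retrieved / n_included,
    missed = missed
  ), class = "evaluation_report")
}

#' Evaluate a selection against a gold-standard study list
#'
#' @param selected a `selection_result` or character vector of refkeys.
#' @param gold_included non-empty character vector: the studies the
#'   original meta-analysis included.
#' @param n_screened_original number of articles the original search
#'   screened (>= 1); the efficiency denominator.
#' @param corpus,search_year optional, forwarded to [classify_missed()]
#'   for the missed studies.
#' @return an `evaluation_report`: screened / retrieved counts, rounded
#'   and exact percentages, and the categorized `missed` table. Always
#'   `n_retrieved + nrow(missed) = n_included`.
#' @examples
#' evaluate_search(c("a", "b", "c"), gold_included = c("a", "b", "z"),
#'                 n_screened_original = 100)
#' @export
evaluate_search <- function(selected, gold_included, n_screened_original,
                            corpus = NULL, search_year = NULL) {
  gold_included <- unique(as.character(gold_included))
  if (!length(gold_included)) stop("gold-standard study list is empty")
  stopifnot(n_screened_original >= 1)
  keys <- unique(as_selected_keys(selected))
  hit <- intersect(keys, gold_included)
  missed <- classify_missed(c_sort(setdiff(gold_included, hit)),
                            corpus, search_year)
  new_evaluation_report(length(keys), n_screened_original,
                        length(gold_included), length(hit), missed)
}

#' Build an evaluation report from pre-tabulated counts
#'
#' For re-analyses where only the per-meta-analysis counts are available
#' (e.g. the bundled replication benchmark tables), not the study lists
#' themselves.
#'
#' @param n_screened,n_screened_original,n_retrieved,n_included counts.
#' @return an `evaluation_report` (with an empty `missed` table).
#' @export
evaluation_report_from_counts <- function(n_screened, n_screened_original,
                                          n_retrieved, n_included) {
  stopifnot(n_screened_original >= 1, n_included >= 1,
            n_retrieved <= n_included)
  new_evaluation_report(n_screened, n_screened_original, n_included,
                        n_retrieved,
                        classify_missed(character()))
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n",
      sprintf("  screened : %d of %d originally screened (%d%%)\n",
              x$n_screened, x$n_screened_original, x$screening_pct),
      sprintf("  retrieved: %d of %d included studies (%d%%)\n",
              x$n_retrieved, x$n_included, x$retrieval_pct))
  if (nrow(x$missed)) {
    cat("  missed by category:\n")
    print(table(x$missed$category))
  }
  invisible(x)
}

#' Median summary over evaluation reports
#'
#' Column-wise medians over a collection of reports. Counts are medianed
#' directly; percentages are medianed on their *unrounded* values and
#' rounded once at the end (medians of pre-rounded percentages can drift
#' by a point). Even-length medians are the mean of the two middle
#' values, then rounded half away from zero.
#'
#' @param reports list of `evaluation_report` objects (>= 1).
#' @return named list of class `aggregate_summary` with medians of
#'   `n_screened_original`, `n_included`, `n_screened`, `screening_pct`,
#'   `n_retrieved`, `retrieval_pct`, plus `n_reports`.
#' @export
aggregate_reports <- function(reports) {
  stopifnot(length(reports) >= 1)
  if (inherits(reports, "evaluation_report")) reports <- list(reports)
  grab <- function(f) vapply(reports, function(r) as.numeric(r[[f]]), numeric(1))
  med <- function(x) round_half_away(stats::median(x))
  structure(list(
    n_reports = length(reports),
    n_screened_original = med(grab("n_screened_original")),
    n_included = med(grab("n_included")),
    n_screened = med(grab("n_screened")),
    screening_pct = med(grab("screening_pct_exact")),
    n_retrieved = med(grab("n_retrieved")),
    retrieval_pct = med(grab("retrieval_pct_exact"))
  ), class = "aggregate_summary")
}

#' @export
print.aggregate_summary <- function(x, ...) {
  cat("<aggregate_summary> medians over", x$n_reports, "searches\n",
      sprintf("  originally screened %d, included %d\n",
              x$n_screened_original, x$n_included),
      sprintf("  screened %d (%d%%), retrieved %d (%d%%)\n",
              x$n_screened, x$screening_pct, x$n_retrieved, x$retrieval_pct))
  invisible(x)
}

#' Bundled meta-analysis replication benchmarks
#'
#' Per-meta-analysis screening and retrieval counts from a two-part
#' published evaluation that replicated the literature searches of 10
#' (study 1) and 42 (study 2) published meta-analyses against a citation
#' database. Study 1 reports three co-citation thresholds (all, co-cited
#' more than once, frequently co-cited); study 2 reports the composite
#' first-stage search and the combined two-stage search. All percentages
#' in this package are recomputed from these counts.
#'
#' @return data frame of counts, one row per meta-analysis.
#' @export
study1_benchmark <- function() {
  utils::read.csv(system.file("extdata", "study1_benchmark.csv",
                              package = "cocite"),
                  stringsAsFactors = FALSE)
}

#' @rdname study1_benchmark
#' @export
study2_benchmark <- function() {
  utils::read.csv(system.file("extdata", "study2_benchmark.csv",
                              package = "cocite"),
                  stringsAsFactors = FALSE)
}

#' Evaluation reports for one benchmark threshold
#'
#' Turns a benchmark counts table into `evaluation_report`s for one pair
#' of screened/retrieved columns.
#'
#' @param bench data frame from [study1_benchmark()] /
#'   [study2_benchmark()].
#' @param screened_col,retrieved_col column names holding the counts.
#' @return list of `evaluation_report` objects.
#' @export
benchmark_reports <- function(bench, screened_col, retrieved_col) {
  lapply(seq_len(nrow(bench)), function(i) {
    evaluation_report_from_counts(
      n_screened = bench[[screened_col]][i],
      n_screened_original = bench$screened_original[i],
      n_retrieved = bench[[retrieved_col]][i],
      n_included = bench$included[i]
    )
  })
}
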