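# Co-citation search engine: from known seed articles to the ranked
# candidate table.
#
# The search assumes one or more eligible studies are known at the start.
# Every corpus article whose reference list contains a known article is a
# "citing article"; a candidate's co-citation count is the number of
# distinct citing articles whose reference lists contain it. The count is
# therefore bounded by 1 and the number of citing articles, and a key
# listed twice in one reference list still counts once.

#' Define the seed set for a search
#'
#' @param known_ids article ids of the known (seed) articles; non-empty.
#' @param exclusion_ids article ids removed from the citing set before
#'   counting (e.g. the meta-analysis whose search is being replicated).
#'   Must be disjoint from `known_ids`.
#' @param date_cutoff_year optional year; citing articles published
#'   *after* this year are dropped (strictly greater). `NULL` = no cutoff.
#' @return object of class `seed_set`.
#' @export
seed_set <- function(known_ids, exclusion_ids = character(),
                     date_cutoff_year = NULL) {
  known_ids <- unique(as.character(known_ids))
  exclusion_ids <- unique(as.character(exclusion_ids))
  if (!length(known_ids)) stop("seed set needs at least one known article id")
  overlap <- intersect(known_ids, exclusion_ids)
  if (length(overlap)) {
    stop("ids cannot be both known and excluded: ",
         paste(overlap, collapse = ", "))
  }
  if (!is.null(date_cutoff_year)) {
    date_cutoff_year <- as.integer(date_cutoff_year)
    stopifnot(length(date_cutoff_year) == 1L, !is.na(date_cutoff_year))
  }
  structure(list(known_ids = known_ids, exclusion_ids = exclusion_ids,
                 date_cutoff_year = date_cutoff_year),
            class = "seed_set")
}

seed_keys_of <- function(corpus, seeds) {
  missing <- setdiff(seeds$known_ids, names(corpus$articles))
  if (length(missing)) {
    stop("unknown seed article id(s): ", paste(missing, collapse = ", "))
  }
  unname(corpus$refkey_of_article[seeds$known_ids])
}

#' Collect the citing articles of a seed set
#'
#' Returns the union over known articles of the ids citing each one; an
#' article citing several knowns contributes a single reference list, so
#' two knowns cited 50 times each yield *up to* 100 citing articles.
#'
#' @param corpus a [citation_corpus()].
#' @param seeds a [seed_set()]; every known id must exist in the corpus.
#' @return character vector of citing article ids (sorted).
#' @export
collect_citing_articles <- function(corpus, seeds) {
  keys <- seed_keys_of(corpus, seeds)
  citers <- unique(unlist(corpus$cited_by[keys], use.names = FALSE))
  c_sort(citers %||% character())
}

#' Filter the citing set before counting
#'
#' Drops excluded ids and, when a cutoff year is set, every citing
#' article published strictly after it (the cutoff models removing works
#' more recent than the meta-analysis being replicated; publication dates
#' finer than the year are not reliably available in exports). Citing
#' articles with unknown year are retained with a message.
#'
#' @inheritParams collect_citing_articles
#' @param citing character vector of citing article ids.
#' @return filtered character vector of ids.
#' @export
filter_citing_articles <- function(citing, corpus, seeds) {
  citing <- setdiff(citing, seeds$exclusion_ids)
  cutoff <- seeds$date_cutoff_year
  if (!is.null(cutoff) && length(citing)) {
    years <- vapply(corpus$articles[citing], function(a) a$year, integer(1))
    if (anyNA(years)) {
      cocite_msg(sum(is.na(years)),
                 " citing article(s) with unknown year retained despite cutoff")
    }
    citing <- citing[is.na(years) | years <= cutoff]
  }
  c_sort(citing)
}

cocitation_table <- function(records, n_citing, seed_keys,
                             provenance = list()) {
  structure(list(records = records, n_citing = as.integer(n_citing),
                 seed_keys = seed_keys, provenance = provenance),
            class = "cocitation_table")
}

#' @export
print.cocitation_table <- function(x, ...) {
  cat("<cocitation_table>", nrow(x$records), "candidates from",
      x$n_citing, "citing articles\n")
  if (nrow(x$records)) {
    print(utils::head(x$records, 10L), row.names = FALSE)
    if (nrow(x$records) > 10L) cat("...", nrow(x$records) - 10L, "more rows\n")
  }
  invisible(x)
}

#' Count co-citations over a filtered citing set
#'
#' For every refkey on any citing article's reference list, the
#' co-citation count is the number of *distinct* citing articles whose
#' list contains it (duplicates within one list count once). The j-index
#' is the count as a percentage of `n_citing`. Seed keys are excluded
#' from the candidate records (they are carried in `seed_keys`); rows are
#' ordered by descending count with ties broken by ascending refkey, so
#' output is deterministic. An empty citing set yields a valid empty
#' table with `n_citing = 0` (an uncited seed).
#'
#' @inheritParams filter_citing_articles
#' @param citing the already-filtered citing ids.
#' @return a `cocitation_table`: `$records` is a data frame with columns
#'   `refkey`, `cocitation_count`, `j_index`, `rank`; `$n_citing`,
#'   `$seed_keys` and `$provenance` carry the run context.
#' @export
count_cocitations <- function(corpus, citing, seeds) {
  skeys <- seed_keys_of(corpus, seeds)
  n_citing <- length(citing)
  keys <- unlist(lapply(corpus$articles[citing],
                        function(a) unique(a$cited_refs)), use.names = FALSE)
  keys <- keys[!(keys %in% c(skeys, REFKEY_UNUSABLE))]
  if (!length(keys)) {
    rec <- data.frame(refkey = character(), cocitation_count = integer(),
                      j_index = numeric(), rank = integer(),
                      stringsAsFactors = FALSE)
    return(cocitation_table(rec, n_citing, skeys))
  }
  counts <- table(keys)
  rec <- data.frame(refkey = names(counts),
                    cocitation_count = as.integer(counts),
                    stringsAsFactors = FALSE)
  rec <- rec[c_order(-rec$cocitation_count, rec$refkey), , drop = FALSE]
  rec$j_index <- 100 * rec$cocitation_count / n_citing
  rec$rank <- seq_len(nrow(rec))
  rownames(rec) <- NULL
  cocitation_table(rec, n_citing, skeys)
}

#' Run the full co-citation search
#'
#' Composition collect -> filter -> count, with the run parameters
#' recorded in the table's `provenance`.
#'
#' @inheritParams collect_citing_articles
#' @return a `cocitation_table`.
#' @examples
#' corp <- citation_corpus(list(
#'   article_record("S", first_author_surname = "Seed", year = 2000,
#'                  source = "J"),
#'   article_record("A", year = 2005, cited_refs = c("seed|2000|j||", "x|1||")),
#'   article_record("B", year = 2006, cited_refs = c("seed|2000|j||", "x|1||",
#'                                                   "y|2||"))))
#' run_cocitation_search(corp, seed_set("S"))
#' @export
run_cocitation_search <- function(corpus, seeds) {
  citing <- collect_citing_articles(corpus, seeds)
  kept <- filter_citing_articles(citing, corpus, seeds)
  tab <- count_cocitations(corpus, kept, seeds)
  tab$provenance <- list(
    known_ids = seeds$known_ids, exclusion_ids = seeds$exclusion_ids,
    date_cutoff_year = seeds$date_cutoff_year,
    n_citing_collected = length(citing), n_citing_kept = length(kept)
  )
  tab
}
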