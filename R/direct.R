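# Second-stage expansion through direct citations.
#
# The co-citation stage cannot retrieve works that have not been cited
# yet (very recent studies in particular). The direct stage ranks every
# work that cites, or is cited by, members of the query set (the seeds
# plus the first-stage retrieval) by the number of distinct query members
# it is linked to, in either direction; a pair linked both ways counts
# once.

#' Expand a query set through direct citations
#'
#' Candidates are all keys referenced by any indexed query member
#' (backward) together with all corpus articles citing any query member
#' (forward). Per candidate, `n_links` counts the distinct query members
#' linked in either direction; `as_cited` and `as_citer` split the links
#' by direction (their sum can exceed `n_links` when a pair is linked
#' both ways). Query members themselves are excluded, and the result is
#' ranked by descending `n_links` with ties by ascending refkey.
#' Non-indexed query members have no reference list and contribute only
#' as forward-citation targets; a message reports how many.
#'
#' @param corpus a [citation_corpus()].
#' @param query_set non-empty character vector of refkeys.
#' @return data frame with columns `refkey`, `n_links`, `as_cited`,
#'   `as_citer`.
#' @export
expand_direct <- function(corpus, query_set) {
  query_set <- unique(as.character(query_set))
  if (!length(query_set)) stop("direct expansion needs a non-empty query set")
  idx <- vapply(query_set, function(k) id_for_key(corpus, k), character(1))
  if (anyNA(idx)) {
    cocite_msg(sum(is.na(idx)),
               " non-indexed query member(s) contribute no backward citations")
  }
  cited <- character()   # one entry per (query member, work it cites)
  citers <- character()  # one entry per (query member, work citing it)
  both <- character()    # distinct linked pairs
  for (i in seq_along(query_set)) {
    q <- query_set[[i]]
    back <- if (!is.na(idx[[i]])) {
      unique(corpus$articles[[idx[[i]]]]$cited_refs)
    } else character()
    back <- back[back != REFKEY_UNUSABLE]
    fwd_ids <- corpus$cited_by[[q]] %||% character()
    fwd <- unname(corpus$refkey_of_article[fwd_ids])
    fwd <- fwd[fwd != REFKEY_UNUSABLE]
    cited <- c(cited, back)
    citers <- c(citers, fwd)
    both <- c(both, unique(c(back, fwd)))
  }
  n_links <- table(both)
  cand <- setdiff(names(n_links), query_set)
  if (!length(cand)) {
    return(data.frame(refkey = character(), n_links = integer(),
                      as_cited = integer(), as_citer = integer(),
                      stringsAsFactors = FALSE))
  }
  tab_cited <- table(cited)
  tab_citer <- table(citers)
  out <- data.frame(
    refkey = cand,
    n_links = as.integer(n_links[cand]),
    as_cited = as.integer(tab_cited[cand]),
    as_citer = as.integer(tab_citer[cand]),
    stringsAsFactors = FALSE
  )
  out$as_cited[is.na(out$as_cited)] <- 0L
  out$as_citer[is.na(out$as_citer)] <- 0L
  out <- out[c_order(-out$n_links, out$refkey), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select directly linked works
#'
#' Keeps every candidate with at least `min_links` distinct direct
#' citation links to the query set (default two or more).
#'
#' @param records data frame from [expand_direct()].
#' @param min_links minimum number of linked query members (>= 1).
#' @return a `selection_result` with strategy `"direct"`.
#' @export
select_direct <- function(records, min_links = 2) {
  stopifnot(min_links >= 1)
  selection_result("direct", as.integer(min_links),
                   records$refkey[records$n_links >= min_links])
}

#' Run the two-stage search protocol
#'
#' Stage 1: co-citation search plus the composite count / j-index
#' selection. Stage 2: direct expansion of the seed keys united with the
#' stage-1 selection, keeping works with `min_links` or more direct
#' links. The combined screening set is the union of both selections;
#' works found by both stages are reported once (stage-1 provenance).
#' The protocol runs exactly these two searches - no iteration to a
#' fixed point.
#'
#' @inheritParams expand_direct
#' @param seeds a [seed_set()].
#' @param min_links stage-2 link threshold.
#' @param cutoff_stage2 apply the seed set's `date_cutoff_year` to
#'   stage-2 candidates that are indexed in the corpus (default `TRUE`;
#'   non-indexed candidates are always retained).
#' @return a list of class `two_stage_result`: `stage1_table`,
#'   `stage1` / `stage2` selection results, `direct_records`, `combined`
#'   (a `selection_result` with strategy `"two_stage"`), and
#'   `provenance`.
#' @export
run_two_stage_search <- function(corpus, seeds, min_links = 2,
                                 cutoff_stage2 = TRUE) {
  stage1_table <- run_cocitation_search(corpus, seeds)
  stage1 <- select_composite(stage1_table)
  skeys <- seed_keys_of(corpus, seeds)
  query <- unique(c(skeys, stage1$selected_keys))
  direct_records <- expand_direct(corpus, query)
  cutoff <- seeds$date_cutoff_year
  if (cutoff_stage2 && !is.null(cutoff) && nrow(direct_records)) {
    yrs <- vapply(direct_records$refkey, function(k) {
      id <- id_for_key(corpus, k)
      if (is.na(id)) NA_integer_ else corpus$articles[[id]]$year
    }, integer(1))
    direct_records <- direct_records[is.na(yrs) | yrs <= cutoff, , drop = FALSE]
  }
  stage2 <- select_direct(direct_records, min_links)
  combined <- selection_result(
    "two_stage", c(count = 2, j_pct = 1, links = as.integer(min_links)),
    union(stage1$selected_keys, stage2$selected_keys)
  )
  structure(list(
    stage1_table = stage1_table, stage1 = stage1,
    direct_records = direct_records, stage2 = stage2, combined = combined,
    provenance = list(seeds = seeds, min_links = min_links,
                      cutoff_stage2 = cutoff_stage2,
                      n_query = length(query))
  ), class = "two_stage_result")
}

#' @export
print.two_stage_result <- function(x, ...) {
  cat("<two_stage_result>\n",
      " stage 1 (co-citation, composite):", x$stage1$size, "works\n",
      " stage 2 (direct, >=", x$provenance$min_links, "links):",
      x$stage2$size, "works\n",
      " combined screening set:", x$combined$size, "works\n")
  invisible(x)
}
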