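# Threshold strategies for screening the ranked co-citation table.
#
# Selections are always whole strata of the ranked table: if a work with
# count c is selected, every work with a higher count is too. Ties in
# count therefore never change selection membership.

selection_result <- function(strategy, threshold_used, selected_keys) {
  structure(list(strategy = strategy, threshold_used = threshold_used,
                 selected_keys = as.character(selected_keys),
                 size = length(selected_keys)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>", x$strategy,
      "(threshold", paste(x$threshold_used, collapse = " "), "):",
      x$size, "works selected\n")
  invisible(x)
}

as_selected_keys <- function(x) {
  if (inherits(x, "selection_result")) x$selected_keys else as.character(x)
}

#' Select all works co-cited at least k times
#'
#' `k = 1` keeps the entire candidate table; `k = 2` keeps works co-cited
#' more than once. Rank order is preserved.
#'
#' @param table a `cocitation_table`.
#' @param k minimum co-citation count (>= 1).
#' @return a `selection_result` with strategy `"all"` (k = 1) or
#'   `"min_count"`.
#' @export
select_min_count <- function(table, k) {
  stopifnot(k >= 1)
  k <- as.integer(k)
  rec <- table$records
  keep <- rec$refkey[rec$cocitation_count >= k]
  selection_result(if (k == 1L) "all" else "min_count", k, keep)
}

#' Select the frequently co-cited works
#'
#' Chooses an integer count threshold so that the selection lands in the
#' target window (by default 100 to 150 works, the short list a reviewer
#' can screen quickly). Every threshold from 1 to the maximum count is
#' evaluated; selection sizes are stratum-cumulative. If several
#' thresholds land in the window the largest (most efficient) is chosen;
#' if none does, the threshold whose size is closest to `target_low`
#' wins, with equidistant ties resolved toward the smaller set.
#'
#' @param table a non-empty `cocitation_table`.
#' @param target_low,target_high the window for the selection size.
#' @return a `selection_result` with strategy `"frequent"` and the chosen
#'   count threshold in `threshold_used`.
#' @export
select_frequent <- function(table, target_low = 100, target_high = 150) {
  rec <- table$records
  if (!nrow(rec)) stop("cannot choose a frequent-co-citation threshold on an empty table")
  counts <- rec$cocitation_count
  ts <- seq_len(max(counts))
  sizes <- vapply(ts, function(t) sum(counts >= t), integer(1))
  in_window <- sizes >= target_low & sizes <= target_high
  t_star <- if (any(in_window)) {
    max(ts[in_window])
  } else {
    d <- abs(sizes - target_low)
    cand <- ts[d == min(d)]
    max(cand)  # equidistant -> smaller set
  }
  keep <- rec$refkey[counts >= t_star]
  sel <- selection_result("frequent", t_star, keep)
  sel
}

#' The j-index of a co-citation count
#'
#' The number of times a work was co-cited, expressed as a percentage of
#' the number of citing articles; ranges over (0, 100] and is returned
#' unrounded.
#'
#' @param count co-citation count(s), `1 <= count <= n_citing`.
#' @param n_citing number of citing articles (>= 1).
#' @return numeric percentage(s).
#' @examples
#' compute_j_index(5, 50)
#' @export
compute_j_index <- function(count, n_citing) {
  if (any(n_citing < 1)) stop("j-index undefined for n_citing = 0")
  if (any(count < 1) || any(count > n_citing)) {
    stop("count must lie in [1, n_citing]")
  }
  100 * count / n_citing
}

#' Composite count / j-index selection
#'
#' Keeps works co-cited more than once *and* co-cited in more than 1 % of
#' the citing articles (j-index > 1, strictly). For fewer than ~100
#' citing articles the count rule binds and the selection equals
#' [select_min_count()] with k = 2; for large citing sets the index rule
#' binds, capping the screening burden on highly cited topics.
#'
#' @param table a `cocitation_table` (carries `n_citing`).
#' @param min_count,min_j_pct the two strict-side thresholds.
#' @return a `selection_result` with strategy `"composite"`.
#' @export
select_composite <- function(table, min_count = 2, min_j_pct = 1) {
  rec <- table$records
  keep <- rec$refkey[rec$cocitation_count >= min_count &
                       rec$j_index > min_j_pct]
  selection_result("composite", c(count = min_count, j_pct = min_j_pct), keep)
}
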