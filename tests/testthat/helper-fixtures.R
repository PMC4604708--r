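# Fixtures built in code, plus independent brute-force oracles used to
# cross-check the engine. The oracles deliberately use naive double loops
# and never call the functions they verify.

# Toy corpus mirroring the schematic two-seeds / three-citers layout:
# citers A, B, C cite the seeds plus candidate works X, Y, Z with
# hand-countable co-citation counts (X: 3, Y: 2, Z: 1).
make_toy_corpus <- function() {
  key <- function(id) paste0("10.1000/", tolower(id))
  work <- function(id, year = 2000, refs = character(), dt = "article",
                   lang = "English") {
    article_record(id, title = id, first_author_surname = id, year = year,
                   source = "J FIX", doi = key(id), language = lang,
                   doc_type = dt, cited_refs = refs)
  }
  corpus <- citation_corpus(list(
    work("S1", 1998), work("S2", 1999),
    work("X", 1997), work("Y", 1996), work("Z", 1995),
    work("A", 2005, refs = c(key("S1"), key("X"), key("Y"), key("Z"))),
    work("B", 2006, refs = c(key("S1"), key("S2"), key("X"), key("Y"))),
    work("C", 2007, refs = c(key("S2"), key("X")))
  ))
  list(corpus = corpus, key = key,
       seeds = seed_set(c("S1", "S2")))
}

# Random corpus for oracle equivalence: n_work citable works, n_citer
# citing articles sampling references from the works (and a few external
# never-indexed keys). Deterministic under `seed`.
random_corpus <- function(seed, n_work = 20, n_citer = 15, p_ref = 0.2) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed({
    wkey <- sprintf("10.2000/w%03d", seq_len(n_work))
    ext <- sprintf("10.3000/x%03d", seq_len(5))
    works <- lapply(seq_len(n_work), function(i) {
      refs <- wkey[seq_len(n_work) < i & stats::runif(n_work) < 0.1]
      article_record(sprintf("W%03d", i), first_author_surname = sprintf("W%03d", i),
                     year = sample(1980:2010, 1), source = "J RND",
                     doi = wkey[[i]], cited_refs = refs)
    })
    citers <- lapply(seq_len(n_citer), function(i) {
      refs <- c(wkey[stats::runif(n_work) < p_ref],
                ext[stats::runif(5) < 0.2])
      article_record(sprintf("C%03d", i), first_author_surname = sprintf("C%03d", i),
                     year = sample(2005:2015, 1), source = "J RND",
                     doi = sprintf("10.2000/c%03d", i), cited_refs = refs)
    })
    citation_corpus(c(works, citers))
  })
}

# --- brute-force oracles ---------------------------------------------------

# every article whose reference list contains any seed key
bf_citers <- function(corpus, seed_keys) {
  hits <- character()
  for (id in names(corpus$articles)) {
    if (length(intersect(corpus$articles[[id]]$cited_refs, seed_keys))) {
      hits <- c(hits, id)
    }
  }
  sort(hits, method = "radix")
}

# named count vector over (citing article, reference) pairs with
# per-citer deduplication; seed keys dropped
bf_cocite <- function(corpus, citing, seed_keys) {
  counts <- new.env(parent = emptyenv())
  for (id in citing) {
    for (k in unique(corpus$articles[[id]]$cited_refs)) {
      if (k %in% seed_keys || k == REFKEY_UNUSABLE) next
      counts[[k]] <- (counts[[k]] %||% 0L) + 1L
    }
  }
  out <- unlist(as.list(counts))
  if (is.null(out)) integer() else out[sort(names(out), method = "radix")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-candidate distinct linked query members, scanning all pairs in both
# directions
bf_direct <- function(corpus, query) {
  all_keys <- unique(c(
    unname(corpus$refkey_of_article),
    unlist(lapply(corpus$articles, function(a) a$cited_refs), use.names = FALSE)
  ))
  all_keys <- setdiff(all_keys, c(query, REFKEY_UNUSABLE))
  id_of <- function(k) {
    m <- names(corpus$refkey_of_article)[corpus$refkey_of_article == k]
    if (length(m)) m[[1]] else NA_character_
  }
  res <- integer()
  for (cand in all_keys) {
    n <- 0L
    cid <- id_of(cand)
    for (q in query) {
      qid <- id_of(q)
      back <- !is.na(qid) && cand %in% corpus$articles[[qid]]$cited_refs
      fwd <- !is.na(cid) && q %in% corpus$articles[[cid]]$cited_refs
      if (back || fwd) n <- n + 1L
    }
    if (n > 0L) res[[cand]] <- n
  }
  res[sort(names(res), method = "radix")]
}

# components by boolean transitive closure of the adjacency matrix
bf_components <- function(nodes, edges) {
  n <- length(nodes)
  A <- diag(TRUE, n)
  dimnames(A) <- list(nodes, nodes)
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      A[edges$a[r], edges$b[r]] <- TRUE
      A[edges$b[r], edges$a[r]] <- TRUE
    }
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  # canonical membership label: smallest node name reachable
  vapply(nodes, function(v) min(nodes[A[v, ]]), character(1))
}

# partitions equal regardless of labelling
canonical_partition <- function(membership) {
  groups <- split(names(membership), as.character(membership))
  groups <- lapply(groups, sort, method = "radix")
  unname(groups[order(vapply(groups, `[[`, character(1), 1))])
}

same_partition <- function(m1, m2) {
  identical(canonical_partition(m1), canonical_partition(m2))
}
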