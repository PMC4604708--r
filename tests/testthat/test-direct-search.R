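# Direct-citation expansion and the two-stage protocol.

test_that("a pair linked in both directions counts once in n_links", {
  k <- function(id) paste0("10.1000/", tolower(id))
  corp <- citation_corpus(list(
    article_record("S1", first_author_surname = "S1", year = 2000,
                   source = "J", doi = k("S1"), cited_refs = k("X")),
    article_record("S2", first_author_surname = "S2", year = 2001,
                   source = "J", doi = k("S2")),
    article_record("X", first_author_surname = "X", year = 1999,
                   source = "J", doi = k("X"), cited_refs = k("S2")),
    article_record("Y", first_author_surname = "Y", year = 2005,
                   source = "J", doi = k("Y"), cited_refs = k("S1"))
  ))
  rec <- expand_direct(corp, c(k("S1"), k("S2")))
  # X is on S1's reference list and cites S2 -> 2 links
  expect_equal(rec$n_links[rec$refkey == k("X")], 2L)
  expect_equal(rec$as_cited[rec$refkey == k("X")], 1L)
  expect_equal(rec$as_citer[rec$refkey == k("X")], 1L)
  # Y cites S1 only -> 1 link
  expect_equal(rec$n_links[rec$refkey == k("Y")], 1L)
  # query members themselves are excluded
  expect_false(any(rec$refkey %in% c(k("S1"), k("S2"))))
  expect_error(expand_direct(corp, character()), "non-empty")
})

test_that("direction counts never exceed their union and ranking is deterministic", {
  corp <- random_corpus(51, n_work = 25, n_citer = 20, p_ref = 0.25)
  query <- unname(corp$refkey_of_article[c("W005", "W010", "C001")])
  suppressMessages(rec <- expand_direct(corp, query))
  expect_true(all(rec$n_links >= 1))
  expect_true(all(rec$as_cited + rec$as_citer >= rec$n_links))
  expect_true(all(rec$n_links <= length(query)))
  expect_false(is.unsorted(rev(rec$n_links)))
})

test_that("expansion equals the brute-force pair scan on random corpora", {
  for (seed in c(5, 6, 7)) {
    corp <- random_corpus(seed, n_work = 20, n_citer = 15)
    query <- unname(corp$refkey_of_article[c("W003", "W007", "W011")])
    suppressMessages(rec <- expand_direct(corp, query))
    oracle <- bf_direct(corp, query)
    got <- structure(rec$n_links, names = rec$refkey)
    got <- got[sort(names(got), method = "radix")]
    expect_identical(names(got), names(oracle))
    expect_identical(unname(got), unname(as.integer(oracle)))
  }
})

test_that("reversing every stored edge direction leaves n_links unchanged", {
  corp <- random_corpus(61, n_work = 15, n_citer = 10)
  query <- unname(corp$refkey_of_article[c("W002", "W009")])
  suppressMessages(fwd <- expand_direct(corp, query))

  # rebuild the corpus with every citation edge reversed
  key_of <- corp$refkey_of_article
  id_of <- structure(names(key_of), names = key_of)
  incoming <- lapply(names(corp$articles), function(id) {
    k <- key_of[[id]]
    unname(key_of[corp$cited_by[[k]] %||% character()])
  })
  names(incoming) <- names(corp$articles)
  recs <- lapply(names(corp$articles), function(id) {
    a <- corp$articles[[id]]
    article_record(id, first_author_surname = a$first_author_surname,
                   year = a$year, source = a$source, doi = a$doi,
                   cited_refs = incoming[[id]])
  })
  corp_rev <- citation_corpus(recs)
  suppressMessages(rev_ <- expand_direct(corp_rev, query))

  fwd_in <- fwd[fwd$refkey %in% names(id_of), ]   # only indexed works survive reversal
  m <- merge(fwd_in[, c("refkey", "n_links")], rev_[, c("refkey", "n_links")],
             by = "refkey")
  expect_equal(nrow(m), nrow(fwd_in))
  expect_equal(m$n_links.x, m$n_links.y)
})

test_that("link-count selection keeps records above the threshold, nested over it", {
  rec <- data.frame(refkey = c("a", "b", "c", "d"),
                    n_links = c(3L, 2L, 1L, 1L),
                    as_cited = c(3L, 2L, 1L, 0L),
                    as_citer = c(0L, 0L, 0L, 1L), stringsAsFactors = FALSE)
  expect_equal(select_direct(rec, 2)$size, 2L)
  expect_equal(select_direct(rec, 1)$size, 4L)
  for (m in 1:3) {
    expect_true(all(select_direct(rec, m + 1)$selected_keys %in%
                      select_direct(rec, m)$selected_keys))
  }
})

test_that("a recent uncited study citing two seed-era studies appears only in stage 2", {
  k <- function(id) paste0("10.1000/", tolower(id))
  work <- function(id, year, refs = character()) {
    article_record(id, first_author_surname = id, year = year, source = "J",
                   doi = k(id), cited_refs = refs)
  }
  corp <- citation_corpus(list(
    work("S1", 1998), work("S2", 1999), work("OLD", 1997),
    work("RECENT", 2015, refs = c(k("S1"), k("OLD"))),
    work("A", 2006, refs = c(k("S1"), k("OLD"))),
    work("B", 2007, refs = c(k("S2"), k("OLD"))),
    work("C", 2008, refs = c(k("S1"), k("S2"), k("OLD")))
  ))
  seeds <- seed_set(c("S1", "S2"))
  res <- suppressMessages(run_two_stage_search(corp, seeds))
  # RECENT is never co-cited (nothing cites it), OLD is co-cited 3 times
  expect_false(k("RECENT") %in% res$stage1$selected_keys)
  expect_true(k("OLD") %in% res$stage1$selected_keys)
  # RECENT cites S1 and OLD (both in the query set) -> 2 links -> stage 2
  expect_true(k("RECENT") %in% res$stage2$selected_keys)
  expect_true(k("RECENT") %in% res$combined$selected_keys)
})

test_that("stage 2 with empty stage-1 retrieval reduces to seed expansion", {
  k <- function(id) paste0("10.1000/", tolower(id))
  corp <- citation_corpus(list(
    article_record("S1", first_author_surname = "S1", year = 2000,
                   source = "J", doi = k("S1"), cited_refs = k("P")),
    article_record("P", first_author_surname = "P", year = 1990,
                   source = "J", doi = k("P"))
  ))
  seeds <- seed_set("S1")
  res <- suppressMessages(run_two_stage_search(corp, seeds))
  expect_equal(res$stage1$size, 0L)
  direct_only <- suppressMessages(expand_direct(corp, k("S1")))
  expect_identical(res$direct_records, direct_only)
})

test_that("the combined screening set contains stage 1 and never loses recall", {
  for (seed in 1:15) {
    sim <- generate_corpus(simulation_config(
      n_eligible = 10, n_noise = 150, n_citing = 25, rng_seed = seed))
    res <- suppressMessages(run_two_stage_search(sim$corpus, sim$seeds))
    expect_true(all(res$stage1$selected_keys %in% res$combined$selected_keys))
    r1 <- evaluate_search(res$stage1, sim$gold_included, 1000)
    rc <- evaluate_search(res$combined, sim$gold_included, 1000)
    expect_gte(rc$n_retrieved, r1$n_retrieved)
  }
})
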