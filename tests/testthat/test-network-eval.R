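# Study-network components, evaluation reports, missed-study
# classification and median aggregation.

test_that("components and disconnected counts follow the direct-link structure", {
  k <- function(id) paste0("10.1000/", tolower(id))
  corp <- citation_corpus(list(
    article_record("A", first_author_surname = "A", year = 2000, source = "J",
                   doi = k("A"), cited_refs = k("B")),
    article_record("B", first_author_surname = "B", year = 1999, source = "J",
                   doi = k("B")),
    article_record("C", first_author_surname = "C", year = 2001, source = "J",
                   doi = k("C"))
  ))
  net <- build_study_network(corp, c(k("A"), k("B"), k("C")))
  expect_equal(net$n_components, 2L)
  expect_equal(net$n_disconnected, 1L)
  expect_true(net$membership[[k("A")]] == net$membership[[k("B")]])

  # chain a-b, b-c -> single component
  corp2 <- citation_corpus(list(
    article_record("A", first_author_surname = "A", year = 2000, source = "J",
                   doi = k("A"), cited_refs = k("B")),
    article_record("B", first_author_surname = "B", year = 1999, source = "J",
                   doi = k("B"), cited_refs = k("C")),
    article_record("C", first_author_surname = "C", year = 1998, source = "J",
                   doi = k("C"))
  ))
  net2 <- build_study_network(corp2, c(k("A"), k("B"), k("C")))
  expect_equal(net2$n_components, 1L)
  expect_equal(net2$n_disconnected, 0L)
})

test_that("components equal a brute-force transitive closure on random study sets", {
  for (seed in c(71, 72, 73, 74)) {
    corp <- random_corpus(seed, n_work = 18, n_citer = 5)
    studies <- unname(corp$refkey_of_article[sprintf("W%03d", 1:18)])
    net <- build_study_network(corp, studies)
    oracle <- bf_components(net$nodes, net$edges)
    expect_true(same_partition(net$membership, oracle))
    expect_equal(net$n_disconnected,
                 sum(!(net$nodes %in% c(net$edges$a, net$edges$b))))
  }
})

test_that("evaluation reproduces benchmark percentage pairs", {
  # 10 of 12 retrieved while screening 967 of 9151
  r <- evaluation_report_from_counts(967, 9151, 10, 12)
  expect_equal(r$retrieval_pct, 83)
  expect_equal(r$screening_pct, 11)
  # 8 of 10 retrieved while screening 588 of 8646
  r2 <- evaluation_report_from_counts(588, 8646, 8, 10)
  expect_equal(r2$retrieval_pct, 80)
  expect_equal(r2$screening_pct, 7)
})

test_that("evaluation from key sets counts hits and missed correctly", {
  gold <- c("a", "b", "c", "d")
  rep <- evaluate_search(c("a", "b", "x", "y"), gold, 100)
  expect_equal(rep$n_retrieved, 2L)
  expect_equal(nrow(rep$missed), 2L)
  expect_equal(rep$n_retrieved + nrow(rep$missed), rep$n_included)
  expect_equal(rep$screening_pct, 4)
  expect_equal(rep$retrieval_pct, 50)

  all_found <- evaluate_search(gold, gold, 100)
  expect_equal(all_found$retrieval_pct, 100)
  expect_equal(nrow(all_found$missed), 0L)
  expect_error(evaluate_search("a", character(), 10), "empty")
})

test_that("percentage rounding is nearest-integer, half away from zero", {
  expect_equal(round_half_away(0.5), 1)
  expect_equal(round_half_away(-0.5), -1)
  expect_equal(round_half_away(7.5), 8)
  # boundary cells: tiny but non-zero fractions round up past .5 only
  expect_equal(evaluation_report_from_counts(62, 8646, 1, 10)$screening_pct, 1)
  expect_equal(evaluation_report_from_counts(780, 784, 6, 6)$screening_pct, 99)
  expect_equal(evaluation_report_from_counts(109, 17500, 8, 8)$screening_pct, 1)
})

test_that("missed-study categories follow the precedence order", {
  k <- function(id) paste0("10.1000/", tolower(id))
  mk <- function(id, year, lang = "English", dt = "article") {
    article_record(id, first_author_surname = id, year = year, source = "J",
                   doi = k(id), language = lang, doc_type = dt)
  }
  corp <- citation_corpus(list(
    mk("OLD", 1969), mk("ABSOLD", 1969, dt = "abstract"),
    mk("DE", 2001, lang = "German"), mk("NEW", 2015),
    mk("PLAIN", 1990), mk("ABSDE", 2001, lang = "French", dt = "abstract")
  ))
  got <- classify_missed(
    c(k("OLD"), k("ABSOLD"), k("DE"), k("NEW"), k("PLAIN"), k("ABSDE"),
      "10.1000/notindexed"),
    corp, search_year = 2015)
  expect_equal(got$category,
               c("old_pre1975", "abstract", "non_english", "recent", "other",
                 "abstract", "other"))
})

test_that("a planted 14-study missed set recovers its category counts", {
  k <- function(i) sprintf("10.1000/m%02d", i)
  plant <- c(rep("abstract", 2), rep("non_english", 3), rep("old_pre1975", 4),
             rep("recent", 1), rep("other", 4))
  recs <- lapply(seq_along(plant), function(i) {
    article_record(sprintf("M%02d", i), first_author_surname = sprintf("M%02d", i),
                   year = switch(plant[i], old_pre1975 = 1960, recent = 2015, 1995),
                   source = "J", doi = k(i),
                   language = if (plant[i] == "non_english") "Chinese" else "English",
                   doc_type = if (plant[i] == "abstract") "abstract" else "article")
  })
  corp <- citation_corpus(recs)
  got <- classify_missed(k(seq_along(plant)), corp, search_year = 2015)
  expect_equal(as.vector(table(got$category)[c("abstract", "non_english",
                                               "old_pre1975", "recent", "other")]),
               c(2L, 3L, 4L, 1L, 4L))
})

test_that("aggregation medians counts directly and percentages unrounded", {
  reports <- list(
    evaluation_report_from_counts(100, 1000, 5, 10),
    evaluation_report_from_counts(200, 1000, 7, 10),
    evaluation_report_from_counts(300, 1000, 9, 10),
    evaluation_report_from_counts(400, 1000, 10, 10)
  )
  agg <- aggregate_reports(reports)
  expect_equal(agg$n_screened, 250)      # mean of the two middle values
  expect_equal(agg$n_retrieved, 8)
  expect_equal(agg$retrieval_pct, 80)
  expect_equal(agg$screening_pct, 25)

  single <- aggregate_reports(reports[1])
  expect_equal(single$n_screened, 100)
  expect_equal(single$retrieval_pct, 50)
})

test_that("aggregation agrees with an independent sort-based median", {
  set.seed(88)
  sort_median <- function(x) {
    s <- sort(x)
    n <- length(s)
    m <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
    round_half_away(m)
  }
  for (rep in 1:100) {
    n <- sample(1:15, 1)
    so <- sample(500:20000, n, TRUE)
    inc <- sample(4:40, n, TRUE)
    scr <- pmax(1, round(so * runif(n, 0.01, 0.9)))
    ret <- vapply(inc, function(i) sample(0:i, 1), integer(1))
    reports <- lapply(seq_len(n), function(i)
      evaluation_report_from_counts(scr[i], so[i], ret[i], inc[i]))
    agg <- aggregate_reports(reports)
    expect_equal(agg$n_screened, sort_median(scr))
    expect_equal(agg$retrieval_pct, sort_median(100 * ret / inc))
    expect_equal(agg$screening_pct, sort_median(100 * scr / so))
  }
})

test_that("retrieval is monotone as the selection grows", {
  gold <- sprintf("g%02d", 1:12)
  pool <- c(gold, sprintf("x%03d", 1:50))
  set.seed(9)
  sel <- character()
  last <- 0
  for (step in 1:10) {
    sel <- union(sel, sample(pool, 8))
    r <- evaluate_search(sel, gold, 500)
    expect_gte(r$n_retrieved, last)
    last <- r$n_retrieved
  }
})
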