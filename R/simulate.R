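# Synthetic citation corpora with planted eligible studies.
#
# The generator emulates the situation the search method assumes: a set
# of eligible studies preferentially co-cited by the articles citing the
# seeds, embedded in a much larger body of topically unrelated works.
# Inclusion of each work in each citing article's reference list is an
# independent Bernoulli draw, so a work's co-citation count is
# analytically Binomial(n_citing, p) - which gives the test suite an
# exact distributional oracle. On top of the shared noise pool, each
# citing article carries a negative-binomially distributed number of
# one-off background references; these produce the long tail of works
# co-cited exactly once that dominates real co-citation distributions.

#' Configuration for the synthetic corpus generator
#'
#' Defaults describe a mid-sized meta-analysis topic: 15 eligible
#' studies, 80 articles citing the seeds, a shared noise pool of 1200
#' related-but-ineligible works with a per-article citation probability
#' giving each noise work ~0.5 expected co-citations, and ~5 unique
#' background references per citing article. Under these defaults
#' roughly 80-90 % of candidate works are co-cited exactly once. 40 % of
#' the (citable) eligible studies get no direct citation links to other
#' eligible studies, and 10 % are too recent to have been cited at all -
#' findable only through the direct-citation stage.
#'
#' @param n_eligible number of planted eligible studies (>= 4).
#' @param n_noise size of the shared noise pool.
#' @param n_citing number of citing articles (>= 1).
#' @param refs_per_citing `c(mean=, dispersion=)` of the
#'   negative-binomial count of one-off background references per citing
#'   article.
#' @param p_cite_eligible probability an eligible study enters a given
#'   citing article's reference list.
#' @param p_cite_noise same, for each noise-pool work.
#' @param frac_disconnected_eligible fraction of citable eligible studies
#'   with no direct edges among the eligible set.
#' @param frac_recent_uncited fraction of eligible studies too recent to
#'   be cited (they cite >= 2 older eligible studies instead).
#' @param strata_probs `c(abstract=, non_english=, pre1975=)` attribute
#'   probabilities for citable eligible studies (the hard-to-find
#'   strata).
#' @param rng_seed integer seed; the same config and seed always
#'   reproduce the identical corpus.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_eligible = 15, n_noise = 1200, n_citing = 80,
                              refs_per_citing = c(mean = 5, dispersion = 5),
                              p_cite_eligible = 0.3, p_cite_noise = 0.006,
                              frac_disconnected_eligible = 0.4,
                              frac_recent_uncited = 0.1,
                              strata_probs = c(abstract = 0.03,
                                               non_english = 0.05,
                                               pre1975 = 0.03),
                              rng_seed = 1) {
  probs <- c(p_cite_eligible, p_cite_noise, frac_disconnected_eligible,
             frac_recent_uncited, strata_probs)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (n_citing < 1) stop("n_citing must be >= 1")
  if (n_eligible < 4) stop("need at least 4 eligible studies")
  n_recent <- round(frac_recent_uncited * n_eligible)
  if (n_eligible - n_recent < 3) {
    stop("infeasible config: too few citable eligible studies left to seed a search")
  }
  structure(list(
    n_eligible = as.integer(n_eligible), n_noise = as.integer(n_noise),
    n_citing = as.integer(n_citing),
    refs_per_citing = refs_per_citing,
    p_cite_eligible = p_cite_eligible, p_cite_noise = p_cite_noise,
    frac_disconnected_eligible = frac_disconnected_eligible,
    frac_recent_uncited = frac_recent_uncited,
    strata_probs = strata_probs, rng_seed = as.integer(rng_seed)
  ), class = "simulation_config")
}

#' Generate a synthetic citation corpus
#'
#' Builds the corpus described by `config`: eligible studies (with
#' metadata strata), a noise pool, citing articles whose reference lists
#' are sampled per-work Bernoulli plus one-off background references,
#' direct citation edges among the connected eligible studies, and
#' recent-uncited eligible studies that cite older eligible work but
#' receive no citations. Two seeds are drawn from the connected eligible
#' studies. Each citing article is generated under its own RNG substream
#' derived from `rng_seed`, so enlarging the corpus never perturbs
#' earlier articles; the caller's RNG state is left untouched.
#'
#' @param config a [simulation_config()].
#' @return list with elements `corpus` (a [citation_corpus()]),
#'   `gold_included` (refkeys of all eligible studies), `seeds` (a
#'   [seed_set()]), and `labels` (a data frame describing each eligible
#'   study: id, key, role `connected`/`disconnected`/`recent`, stratum).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  base <- config$rng_seed
  n_e <- config$n_eligible
  search_year <- 2015L

  n_recent <- round(config$frac_recent_uncited * n_e)
  citable <- seq_len(n_e - n_recent)
  recent <- setdiff(seq_len(n_e), citable)
  n_disc <- round(config$frac_disconnected_eligible * length(citable))

  roles <- rep("connected", n_e)
  roles[recent] <- "recent"
  disc <- with_seed(sub_seed(base, 1), {
    if (n_disc > 0) sample(citable, n_disc) else integer()
  })
  roles[disc] <- "disconnected"
  connected <- which(roles == "connected")
  if (length(connected) < 2L) {
    stop("infeasible config: fewer than two connected eligible studies to seed from")
  }

  elig_id <- sprintf("E%03d", seq_len(n_e))
  elig_key <- sprintf("10.5555/elig.%03d", seq_len(n_e))

  strata <- with_seed(sub_seed(base, 2), {
    sp <- config$strata_probs
    st <- rep("none", n_e)
    draw <- stats::runif(n_e)
    st[draw < sp[["abstract"]]] <- "abstract"
    st[draw >= sp[["abstract"]] &
         draw < sp[["abstract"]] + sp[["non_english"]]] <- "non_english"
    st[draw >= sp[["abstract"]] + sp[["non_english"]] &
         draw < sum(sp)] <- "pre1975"
    st[recent] <- "none"
    st
  })
  years <- with_seed(sub_seed(base, 3), {
    y <- sample(1976:2005, n_e, replace = TRUE)
    y[strata == "pre1975"] <- sample(1950:1974, sum(strata == "pre1975"),
                                     replace = TRUE)
    y[recent] <- search_year
    y
  })

  seeds_idx <- with_seed(sub_seed(base, 4), sample(connected, 2))

  # Direct edges among connected eligible studies: each (in year order,
  # after the first) cites at least one earlier connected study. Seeds
  # are never edge *targets*, so the citing articles of the seeds are
  # exactly the n_citing generated citing articles; seeds stay linked to
  # the component through their own outgoing references.
  conn_sorted <- connected[order(years[connected], elig_id[connected])]
  elig_refs <- rep(list(character()), n_e)
  if (length(conn_sorted) >= 2L) {
    for (j in 2:length(conn_sorted)) {
      i <- conn_sorted[[j]]
      earlier <- setdiff(conn_sorted[seq_len(j - 1)], seeds_idx)
      if (!length(earlier)) next
      cites <- with_seed(sub_seed(base, 10 + i), {
        hit <- earlier[stats::runif(length(earlier)) < 0.4]
        if (!length(hit)) hit <- earlier[sample(length(earlier), 1)]
        hit
      })
      elig_refs[[i]] <- elig_key[cites]
    }
  }
  # recent studies cite >= 2 older eligible studies (connected non-seed
  # ones, the works a first-stage search retrieves)
  recent_pool <- setdiff(connected, seeds_idx)
  if (length(recent_pool) < 2L) recent_pool <- connected
  for (i in recent) {
    elig_refs[[i]] <- with_seed(sub_seed(base, 10 + i), {
      k <- min(length(recent_pool), sample(2:3, 1))
      elig_key[recent_pool[sample(length(recent_pool), k)]]
    })
  }

  elig_records <- lapply(seq_len(n_e), function(i) {
    article_record(
      article_id = elig_id[[i]],
      title = paste("Eligible study", i),
      first_author_surname = sprintf("Author%03d", i),
      year = years[[i]],
      source = "J SYNTH EVID",
      doi = elig_key[[i]],
      language = if (strata[[i]] == "non_english") "German" else "English",
      doc_type = if (strata[[i]] == "abstract") "abstract" else "article",
      cited_refs = elig_refs[[i]]
    )
  })

  noise_key <- if (config$n_noise > 0) {
    sprintf("10.6666/noise.%04d", seq_len(config$n_noise))
  } else character()

  mu <- config$refs_per_citing[["mean"]]
  size <- config$refs_per_citing[["dispersion"]]
  cite_records <- lapply(seq_len(config$n_citing), function(i) {
    with_seed(sub_seed(base, 100000 + i), {
      hit_seed <- seeds_idx[stats::runif(2) < 0.7]
      if (!length(hit_seed)) hit_seed <- sample(seeds_idx, 1)
      others <- setdiff(citable, seeds_idx)
      hit_elig <- others[stats::runif(length(others)) < config$p_cite_eligible]
      hit_noise <- if (length(noise_key)) {
        noise_key[stats::runif(length(noise_key)) < config$p_cite_noise]
      } else character()
      n_bg <- if (mu > 0) stats::rnbinom(1, size = size, mu = mu) else 0L
      bg <- if (n_bg > 0) sprintf("10.7777/bg.%03d.%03d", i, seq_len(n_bg))
            else character()
      article_record(
        article_id = sprintf("C%03d", i),
        title = paste("Citing article", i),
        first_author_surname = sprintf("Citer%03d", i),
        year = sample(2006:2014, 1),
        source = "J CITED TOPICS",
        doi = sprintf("10.8888/cite.%03d", i),
        doc_type = "article", language = "English",
        cited_refs = c(elig_key[c(hit_seed, hit_elig)], hit_noise, bg)
      )
    })
  })

  corpus <- citation_corpus(c(elig_records, cite_records))
  labels <- data.frame(article_id = elig_id, refkey = elig_key,
                       role = roles, stratum = strata, year = years,
                       is_seed = seq_len(n_e) %in% seeds_idx,
                       stringsAsFactors = FALSE)
  list(
    corpus = corpus,
    gold_included = elig_key,
    seeds = seed_set(known_ids = elig_id[seeds_idx]),
    labels = labels,
    search_year = search_year
  )
}

#' Co-citation distribution summary of a corpus
#'
#' Runs the co-citation search for the given seeds and summarizes the
#' candidate count distribution: the histogram of co-citation counts and
#' the fraction of candidates co-cited exactly once. Real corpora show
#' ~80 % singletons with a short frequently-co-cited head; this is the
#' shape the screening thresholds exploit.
#'
#' @param corpus a [citation_corpus()].
#' @param seeds a [seed_set()].
#' @return list of class `cocitation_summary`: `histogram` (table of
#'   counts), `fraction_once`, `n_candidates`, `n_citing`.
#' @export
summarize_corpus <- function(corpus, seeds) {
  tab <- run_cocitation_search(corpus, seeds)
  counts <- tab$records$cocitation_count
  structure(list(
    histogram = table(counts),
    fraction_once = if (length(counts)) mean(counts == 1L) else NA_real_,
    n_candidates = length(counts),
    n_citing = tab$n_citing
  ), class = "cocitation_summary")
}

#' @export
print.cocitation_summary <- function(x, ...) {
  cat("<cocitation_summary>", x$n_candidates, "candidates from",
      x$n_citing, "citing articles;",
      sprintf("%.1f%% co-cited once\n", 100 * x$fraction_once))
  invisible(x)
}
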