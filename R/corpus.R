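# Citation corpus container and readers/writers.

#' Create an article record
#'
#' One indexed article: its metadata as a citable work plus its outgoing
#' reference list (as canonical refkeys). `cited_refs_raw` preserves the
#' original reference strings where they are known, so exports round-trip
#' verbatim; it defaults to the keys themselves.
#'
#' @param article_id unique corpus identifier (e.g. a `UT` value).
#' @param title,first_author_surname,source,doi,language free-text fields;
#'   empty string when unknown.
#' @param year integer publication year (`NA` = unknown).
#' @param volume,first_page of the article itself, used for its own refkey.
#' @param doc_type one of `"article"`, `"abstract"`, `"review"`,
#'   `"other"`, `"unknown"`.
#' @param cited_refs character vector of refkeys (may be empty: case
#'   reports and similar items often carry few or no references).
#' @param cited_refs_raw raw reference strings parallel to `cited_refs`.
#' @return object of class `article_record`.
#' @export
article_record <- function(article_id, title = "", first_author_surname = "",
                           year = NA_integer_, source = "", volume = "",
                           first_page = "", doi = "", language = "",
                           doc_type = "unknown", cited_refs = character(),
                           cited_refs_raw = cited_refs) {
  stopifnot(is.character(article_id), length(article_id) == 1L, nzchar(article_id))
  doc_type <- match.arg(doc_type,
                        c("article", "abstract", "review", "other", "unknown"))
  if (length(cited_refs_raw) != length(cited_refs)) {
    stop("cited_refs_raw must parallel cited_refs")
  }
  structure(
    list(article_id = article_id, title = title,
         first_author_surname = first_author_surname,
         year = as.integer(year), source = source, volume = volume,
         first_page = first_page, doi = doi, language = language,
         doc_type = doc_type, cited_refs = as.character(cited_refs),
         cited_refs_raw = as.character(cited_refs_raw)),
    class = "article_record"
  )
}

# refkey of the article itself, as a citable work
article_refkey <- function(rec) {
  make_refkey(data.frame(
    first_author_surname = rec$first_author_surname,
    year = rec$year, source = rec$source, volume = rec$volume,
    first_page = rec$first_page, doi = rec$doi,
    stringsAsFactors = FALSE
  ))
}

#' Build a citation corpus from article records
#'
#' Assembles the three views the search engine needs: the records
#' themselves, each article's own refkey (`refkey_of_article`), and the
#' inverse map `cited_by` (refkey -> ids of citing articles), which is by
#' construction the exact inverse of the union of all reference lists.
#' Two indexed articles may never share a (usable) refkey.
#'
#' @param articles list of [article_record()] objects.
#' @return object of class `citation_corpus`.
#' @export
citation_corpus <- function(articles) {
  stopifnot(is.list(articles))
  ids <- vapply(articles, function(a) a$article_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate article_id in corpus: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(articles) <- ids
  keys <- vapply(articles, article_refkey, character(1))
  usable <- keys != REFKEY_UNUSABLE
  if (anyDuplicated(keys[usable])) {
    dup <- unique(keys[usable][duplicated(keys[usable])])
    stop("two corpus articles share a refkey: ", paste(dup, collapse = ", "))
  }
  cited_pairs_key <- unlist(lapply(articles, function(a) unique(a$cited_refs)),
                            use.names = FALSE)
  cited_pairs_id <- rep(ids, vapply(articles, function(a)
    length(unique(a$cited_refs)), integer(1)))
  cited_by <- if (length(cited_pairs_key)) {
    split(cited_pairs_id, cited_pairs_key)
  } else {
    structure(list(), names = character())
  }
  structure(
    list(articles = articles, refkey_of_article = keys, cited_by = cited_by),
    class = "citation_corpus"
  )
}

#' @export
print.citation_corpus <- function(x, ...) {
  n_ref <- sum(vapply(x$articles, function(a) length(a$cited_refs), integer(1)))
  cat("<citation_corpus>", length(x$articles), "articles,",
      length(x$cited_by), "distinct cited works,", n_ref, "reference entries\n")
  invisible(x)
}

# ids of indexed articles whose own refkey equals `key` (0 or 1 of them)
id_for_key <- function(corpus, key) {
  hit <- names(corpus$refkey_of_article)[corpus$refkey_of_article == key &
                                           key != REFKEY_UNUSABLE]
  if (length(hit)) hit[[1]] else NA_character_
}

wos_tag_map <- c(
  UT = "article_id", TI = "title", AU = "first_author_surname", PY = "year",
  SO = "source", VL = "volume", BP = "first_page", DI = "doi",
  LA = "language", DT = "doc_type", CR = "cr"
)

normalize_doc_type <- function(x) {
  x <- tolower(trimws(x))
  if (!nzchar(x)) return("unknown")
  if (grepl("abstract", x)) return("abstract")
  if (grepl("review", x)) return("review")
  if (grepl("article", x)) return("article")
  "other"
}

ref_tokens_to_keys <- function(tokens) {
  tokens <- trimws(tokens)
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens)) {
    return(list(keys = character(), raw = character()))
  }
  keylike <- is_keylike(tokens)
  keys <- character(length(tokens))
  keys[keylike] <- tokens[keylike]
  if (any(!keylike)) keys[!keylike] <- refkey(tokens[!keylike], "wos")
  list(keys = keys, raw = tokens)
}

build_record_from_fields <- function(f) {
  refs <- ref_tokens_to_keys(f$cr %||% character())
  yr <- suppressWarnings(as.integer(f$year %||% NA))
  article_record(
    article_id = f$article_id,
    title = f$title %||% "",
    first_author_surname = f$first_author_surname %||% "",
    year = if (length(yr)) yr else NA_integer_,
    source = f$source %||% "",
    volume = f$volume %||% "",
    first_page = f$first_page %||% "",
    doi = f$doi %||% "",
    language = f$language %||% "",
    doc_type = normalize_doc_type(f$doc_type %||% ""),
    cited_refs = refs$keys,
    cited_refs_raw = refs$raw
  )
}

#' Read a Web of Science style export
#'
#' Reads either layout of a field-tagged export: tab-delimited (one record
#' per line, a header line of two-letter tags, references `"; "`-separated
#' inside the `CR` cell) or tag-per-line (classic plain-text export, tags
#' at line start, indented continuation lines, records terminated by
#' `ER`). Files are decoded as UTF-8 with replacement of invalid bytes.
#' Records with no `UT` identifier are skipped with a warning; a file
#' yielding zero records is a format error naming the first offending
#' line.
#'
#' @param path file path.
#' @return list of [article_record()] objects (pass to
#'   [citation_corpus()] to search them).
#' @seealso [write_wos_export()]
#' @export
read_wos_export <- function(path) {
  if (!file.exists(path)) stop("cannot read export file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- iconv(lines, from = "UTF-8", to = "UTF-8", sub = "�")
  body <- lines[nzchar(trimws(lines))]
  if (!length(body)) stop("no records parsed from ", path, " (file is empty)")
  records <- if (grepl("\t", body[[1]], fixed = TRUE)) {
    read_wos_tab(lines)
  } else {
    read_wos_tagged(lines)
  }
  no_id <- vapply(records, function(f) !nzchar(f$article_id %||% ""), logical(1))
  if (any(no_id)) {
    warning(sum(no_id), " record(s) without an identifier were skipped")
    records <- records[!no_id]
  }
  if (!length(records)) {
    stop("no records parsed from ", path,
         ": first offending line: ", substr(body[[1]], 1, 80))
  }
  lapply(records, build_record_from_fields)
}

read_wos_tab <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  lapply(rows, function(cells) {
    length(cells) <- length(header)
    cells[is.na(cells)] <- ""
    f <- list()
    for (j in seq_along(header)) {
      tag <- trimws(header[[j]])
      if (tag %in% names(wos_tag_map)) f[[wos_tag_map[[tag]]]] <- cells[[j]]
    }
    if (!is.null(f$cr)) f$cr <- strsplit(f$cr, ";", fixed = TRUE)[[1]]
    if (!is.null(f$first_author_surname)) {
      f$first_author_surname <-
        trimws(strsplit(f$first_author_surname, ";", fixed = TRUE)[[1]][1])
    }
    f
  })
}

read_wos_tagged <- function(lines) {
  records <- list()
  f <- list()
  tag <- ""
  flush <- function(f) if (length(f)) c(records, list(f)) else records
  for (ln in lines) {
    if (grepl("^[A-Z][A-Z0-9] ", ln) || grepl("^[A-Z][A-Z0-9]$", ln)) {
      tag <- substr(ln, 1, 2)
      val <- trimws(substr(ln, 3, nchar(ln)))
      if (tag == "ER") {
        records <- flush(f)
        f <- list()
        tag <- ""
      } else if (tag %in% names(wos_tag_map)) {
        nm <- wos_tag_map[[tag]]
        f[[nm]] <- c(f[[nm]], val)
      }
    } else if (grepl("^[[:space:]]", ln) && nzchar(tag) &&
               tag %in% names(wos_tag_map)) {
      nm <- wos_tag_map[[tag]]
      f[[nm]] <- c(f[[nm]], trimws(ln))
    }
  }
  records <- flush(f)
  lapply(records, function(f) {
    if (!is.null(f$cr)) {
      f$cr <- unlist(strsplit(f$cr, ";", fixed = TRUE), use.names = FALSE)
    }
    for (nm in setdiff(names(f), "cr")) f[[nm]] <- f[[nm]][[1]]
    if (!is.null(f$first_author_surname)) {
      f$first_author_surname <-
        trimws(strsplit(f$first_author_surname, ";", fixed = TRUE)[[1]][1])
    }
    f
  })
}

#' Write article records as a tab-delimited export
#'
#' Inverse of [read_wos_export()] (tab layout); reference strings are
#' written verbatim from `cited_refs_raw`, so read-write-read is stable.
#'
#' @param records list of [article_record()] objects.
#' @param path output file path.
#' @export
write_wos_export <- function(records, path) {
  tags <- c("UT", "TI", "AU", "PY", "SO", "VL", "BP", "DI", "LA", "DT", "CR")
  field_of <- c(UT = "article_id", TI = "title", AU = "first_author_surname",
                PY = "year", SO = "source", VL = "volume", BP = "first_page",
                DI = "doi", LA = "language", DT = "doc_type")
  rows <- vapply(records, function(r) {
    vals <- vapply(tags, function(tg) {
      if (tg == "CR") return(paste(r$cited_refs_raw, collapse = "; "))
      v <- r[[field_of[[tg]]]]
      if (is.na(v %||% NA)) "" else as.character(v)
    }, character(1))
    paste(vals, collapse = "\t")
  }, character(1))
  writeLines(c(paste(tags, collapse = "\t"), rows), path, useBytes = TRUE)
  invisible(NULL)
}

#' Read a corpus from metadata + citing-edge CSV files
#'
#' Generic, database-agnostic input: `metadata_path` has one row per
#' article (`article_id` required; `title`, `first_author_surname`,
#' `year`, `source`, `volume`, `first_page`, `doi`, `language`,
#' `doc_type` optional), `edges_path` has columns `citing_article_id`,
#' `cited_refkey`. Edges whose citing id is not in the metadata are an
#' error (listing the offenders), as are duplicated article ids.
#'
#' @param metadata_path,edges_path CSV file paths.
#' @return a [citation_corpus()].
#' @export
read_edge_list <- function(metadata_path, edges_path) {
  meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!"article_id" %in% names(meta)) {
    stop("metadata file lacks an article_id column")
  }
  if (anyDuplicated(meta$article_id)) {
    stop("duplicate article_id in metadata: ",
         paste(unique(meta$article_id[duplicated(meta$article_id)]),
               collapse = ", "))
  }
  edges <- utils::read.csv(edges_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("citing_article_id", "cited_refkey") %in% names(edges))) {
    stop("edge file needs columns citing_article_id, cited_refkey")
  }
  dangling <- setdiff(edges$citing_article_id, meta$article_id)
  if (length(dangling)) {
    stop("edges reference unknown citing article id(s): ",
         paste(c_sort(dangling), collapse = ", "))
  }
  refs_of <- split(edges$cited_refkey, edges$citing_article_id)
  records <- lapply(seq_len(nrow(meta)), function(i) {
    row <- as.list(meta[i, , drop = FALSE])
    refs <- refs_of[[row$article_id]] %||% character()
    article_record(
      article_id = row$article_id,
      title = row$title %||% "",
      first_author_surname = row$first_author_surname %||% "",
      year = suppressWarnings(as.integer(row$year %||% NA)),
      source = row$source %||% "", volume = row$volume %||% "",
      first_page = row$first_page %||% "", doi = row$doi %||% "",
      language = row$language %||% "",
      doc_type = normalize_doc_type(row$doc_type %||% ""),
      cited_refs = refs
    )
  })
  citation_corpus(records)
}

#' Write / read the internal JSON corpus format
#'
#' The interchange schema is `{"articles": [...]}` where each element
#' carries the [article_record()] fields, including `cited_refs` (keys)
#' and `cited_refs_raw`. `read_corpus_json(write_corpus_json(x))` is the
#' identity on the corpus.
#'
#' @param corpus a [citation_corpus()].
#' @param path file path.
#' @return `read_corpus_json` returns a [citation_corpus()].
#' @export
write_corpus_json <- function(corpus, path) {
  arts <- lapply(unname(corpus$articles), function(a) {
    list(article_id = a$article_id, title = a$title,
         first_author_surname = a$first_author_surname,
         year = if (is.na(a$year)) NULL else a$year,
         source = a$source, volume = a$volume, first_page = a$first_page,
         doi = a$doi, language = a$language, doc_type = a$doc_type,
         cited_refs = I(a$cited_refs), cited_refs_raw = I(a$cited_refs_raw))
  })
  jsonlite::write_json(list(articles = arts), path, auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(NULL)
}

#' @rdname write_corpus_json
#' @export
read_corpus_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$articles)) stop("not a corpus JSON file (no 'articles'): ", path)
  records <- lapply(obj$articles, function(a) {
    refs <- as.character(unlist(a$cited_refs, use.names = FALSE) %||% character())
    raw <- as.character(unlist(a$cited_refs_raw, use.names = FALSE) %||% refs)
    article_record(
      article_id = a$article_id, title = a$title %||% "",
      first_author_surname = a$first_author_surname %||% "",
      year = a$year %||% NA_integer_, source = a$source %||% "",
      volume = a$volume %||% "", first_page = a$first_page %||% "",
      doi = a$doi %||% "", language = a$language %||% "",
      doc_type = a$doc_type %||% "unknown",
      cited_refs = refs, cited_refs_raw = raw
    )
  })
  citation_corpus(records)
}

#' Write a ranked co-citation table as CSV
#'
#' Columns `rank`, `refkey`, `cocitation_count`, `j_index`,
#' `is_known_seed`, `display_reference`, in descending co-citation count
#' (ties by refkey), preceded by a `# n_citing:` comment line carrying the
#' denominator. Output is byte-identical across re-runs on the same
#' table.
#'
#' @param table a `cocitation_table` (see [count_cocitations()]).
#' @param path output path.
#' @param corpus optional [citation_corpus()] used to render a readable
#'   `display_reference` for indexed works.
#' @seealso [read_ranked_list()]
#' @export
write_ranked_list <- function(table, path, corpus = NULL) {
  rec <- table$records
  display <- rec$refkey
  if (!is.null(corpus) && nrow(rec)) {
    for (i in seq_len(nrow(rec))) {
      id <- id_for_key(corpus, rec$refkey[[i]])
      if (!is.na(id)) {
        a <- corpus$articles[[id]]
        display[i] <- trimws(paste0(
          a$first_author_surname,
          if (!is.na(a$year)) paste0(" (", a$year, ")") else "",
          if (nzchar(a$source)) paste0(" ", a$source) else ""))
      }
    }
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# n_citing: ", table$n_citing), con)
  header <- "rank,refkey,cocitation_count,j_index,is_known_seed,display_reference"
  writeLines(header, con)
  if (nrow(rec)) {
    esc <- function(x) {
      needs <- grepl("[\",\n]", x)
      x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
      x
    }
    writeLines(paste(rec$rank, esc(rec$refkey), rec$cocitation_count,
                     sprintf("%.10g", rec$j_index), "FALSE", esc(display),
                     sep = ","), con)
  }
  invisible(NULL)
}

#' Read a ranked co-citation table written by [write_ranked_list()]
#' @param path CSV path.
#' @return a `cocitation_table`.
#' @export
read_ranked_list <- function(path) {
  first <- readLines(path, n = 1L)
  n_citing <- if (grepl("^# n_citing:", first)) {
    as.integer(sub("^# n_citing:[[:space:]]*", "", first))
  } else {
    stop("not a ranked-list file (missing '# n_citing:' header): ", path)
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  cocitation_table(
    data.frame(refkey = as.character(df$refkey),
               cocitation_count = as.integer(df$cocitation_count),
               j_index = as.numeric(df$j_index),
               rank = as.integer(df$rank), stringsAsFactors = FALSE),
    n_citing = n_citing, seed_keys = character(),
    provenance = list(source = path)
  )
}

#' Write / read a selection of refkeys
#'
#' One refkey per line after a `# strategy:` header; `read_key_list` also
#' reads plain gold-standard lists (blank lines and `#` comments
#' ignored).
#'
#' @param selection a `selection_result` (see [select_min_count()]).
#' @param path file path.
#' @export
write_selection <- function(selection, path) {
  writeLines(c(paste0("# strategy: ", selection$strategy),
               paste0("# threshold: ", paste(selection$threshold_used,
                                             collapse = " ")),
               selection$selected_keys), path, useBytes = TRUE)
  invisible(NULL)
}

#' @rdname write_selection
#' @export
read_key_list <- function(path) {
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}
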