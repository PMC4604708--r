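# Cited-reference parsing and canonical reference keys.
#
# A "refkey" is the canonical, matchable identity of a cited work -- the
# unit that co-citation counting operates on. Two bibliographic strings
# that differ only in case, spacing or punctuation map to the same key;
# a DOI, when present, overrides the composite identity entirely.

#' Parse a cited-reference string
#'
#' Best-effort decomposition of a cited-reference string into its
#' bibliographic components. The `wos` dialect expects the comma-separated
#' layout used in Web of Science `CR` fields
#' (`"SMITH J, 2001, J CLIN ONCOL, V19, P1001, DOI 10.1000/xyz"`); the
#' `plain` dialect extracts a year and DOI by pattern and takes the text
#' before the first comma as the author surname. Unparseable components
#' are left empty (`""`) or `NA`; malformed content never errors.
#'
#' @param raw character vector of reference strings (non-empty after
#'   trimming).
#' @param dialect `"wos"` or `"plain"`.
#' @return A data frame with one row per input and columns `raw_string`,
#'   `first_author_surname`, `year`, `source`, `volume`, `first_page`,
#'   `doi`. `raw_string` is preserved verbatim.
#' @examples
#' parse_cited_reference("SMITH J, 2001, J CLIN ONCOL, V19, P1001")
#' @export
parse_cited_reference <- function(raw, dialect = c("wos", "plain")) {
  dialect <- match.arg(dialect)
  if (length(raw) == 0L || any(!nzchar(trimws(raw)))) {
    stop("blank reference token: every reference string must be non-empty")
  }
  out <- data.frame(
    raw_string = raw,
    first_author_surname = "",
    year = NA_integer_,
    source = "",
    volume = "",
    first_page = "",
    doi = "",
    stringsAsFactors = FALSE
  )
  for (i in seq_along(raw)) {
    s <- trimws(raw[[i]])
    if (dialect == "wos") {
      toks <- trimws(strsplit(s, ",")[[1]])
      toks <- toks[nzchar(toks)]
      if (length(toks) == 0L) next
      out$first_author_surname[i] <- toks[[1]]
      rest <- toks[-1]
      yr_at <- which(grepl("^[0-9]{4}$", rest))[1]
      if (!is.na(yr_at)) {
        yr <- as.integer(rest[[yr_at]])
        if (yr >= 1800 && yr <= 2100) out$year[i] <- yr
        rest <- rest[-yr_at]
      }
      doi_at <- which(grepl("^\\[?DOI[: ]", rest, ignore.case = TRUE))[1]
      if (!is.na(doi_at)) {
        out$doi[i] <- sub("^\\[?DOI[: ]+", "", rest[[doi_at]], ignore.case = TRUE)
        out$doi[i] <- sub("\\]$", "", out$doi[i])
        rest <- rest[-doi_at]
      }
      # volume/page tokens are single words anchored on a digit, so
      # sources such as "VACCINE" or "PLOS ONE" are never swallowed
      vol_at <- which(grepl("^[Vv][0-9]+[A-Za-z]*$", rest))[1]
      if (!is.na(vol_at)) {
        out$volume[i] <- sub("^[Vv]", "", rest[[vol_at]])
        rest <- rest[-vol_at]
      }
      pg_at <- which(grepl("^[Pp][A-Za-z]*[0-9]+[A-Za-z]*$", rest))[1]
      if (!is.na(pg_at)) {
        out$first_page[i] <- sub("^[Pp]", "", rest[[pg_at]])
        rest <- rest[-pg_at]
      }
      if (length(rest)) out$source[i] <- rest[[1]]
    } else {
      doi_m <- regmatches(s, regexpr("10\\.[0-9]{4,}[^ ,;]*", s))
      if (length(doi_m)) out$doi[i] <- doi_m[[1]]
      yr_m <- regmatches(s, regexpr("\\b(18|19|20)[0-9]{2}\\b", s))
      if (length(yr_m)) out$year[i] <- as.integer(yr_m[[1]])
      head_txt <- trimws(strsplit(s, ",")[[1]][1])
      out$first_author_surname[i] <- head_txt
    }
  }
  out
}

# shared normalization: lowercase, strip punctuation, collapse whitespace
norm_component <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9 ]+", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

norm_doi <- function(x) {
  x <- tolower(trimws(x))
  x <- sub("^https?://(dx\\.)?doi\\.org/", "", x)
  x <- sub("^doi:?[[:space:]]*", "", x)
  x
}

#' Sentinel key for references with no usable identity
#' @export
REFKEY_UNUSABLE <- "__unusable__"

#' Canonical key of a cited reference
#'
#' Deterministic identity rule behind duplicate collapsing: when a DOI is
#' present the key is the normalized DOI alone; otherwise it is the
#' normalized join `surname|year|source|volume|first_page`. Normalization
#' lowercases, strips punctuation and collapses internal whitespace, so
#' case- or spacing-variants of the same record collapse to one key. A
#' reference with no usable component yields [REFKEY_UNUSABLE].
#'
#' Known limitation: the same work recorded once with and once without a
#' DOI yields two different keys.
#'
#' @param ref a data frame as returned by [parse_cited_reference()] (one
#'   or more rows), or a list with the same fields.
#' @return character vector of keys, one per reference.
#' @examples
#' make_refkey(parse_cited_reference("SMITH J, 2001, J CLIN ONCOL, V19, P1001"))
#' @export
make_refkey <- function(ref) {
  if (!is.data.frame(ref)) ref <- as.data.frame(ref, stringsAsFactors = FALSE)
  n <- nrow(ref)
  get_chr <- function(nm) {
    v <- if (nm %in% names(ref)) as.character(ref[[nm]]) else rep("", n)
    v[is.na(v)] <- ""
    v
  }
  doi <- norm_doi(get_chr("doi"))
  surname <- norm_component(get_chr("first_author_surname"))
  year <- get_chr("year")
  source <- norm_component(get_chr("source"))
  volume <- norm_component(get_chr("volume"))
  page <- norm_component(get_chr("first_page"))
  composite <- paste(surname, year, source, volume, page, sep = "|")
  key <- ifelse(nzchar(doi), doi, composite)
  key[!nzchar(doi) & !nzchar(paste0(surname, year, source, volume, page))] <-
    REFKEY_UNUSABLE
  key
}

#' Parse a reference string and return its canonical key
#'
#' Convenience composition of [parse_cited_reference()] and
#' [make_refkey()].
#'
#' @inheritParams parse_cited_reference
#' @return character vector of refkeys.
#' @export
refkey <- function(raw, dialect = c("wos", "plain")) {
  make_refkey(parse_cited_reference(raw, dialect))
}

# A token already in canonical-key form (pipe-joined composite or bare
# normalized DOI) is used verbatim; needed so corpora whose reference
# lists were stored as keys survive a write/read round trip.
is_keylike <- function(tok) {
  (grepl("|", tok, fixed = TRUE) & !grepl(", ", tok, fixed = TRUE)) |
    grepl("^10\\.[0-9]{4,}", tok)
}
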