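#' Read and write the corpus CSV dialect
#'
#' The interchange format is UTF-8 CSV with one row per article and columns
#' `article_id`, `journal_id`, `pub_year`, `pub_types` (pipe-separated),
#' `has_abstract` (0/1), `authors` (pipe-separated
#' `family,given_full,initials` triplets, or `collective:NAME` for a
#' collective author; absent name parts are empty), `date_received` and
#' `date_accepted` (ISO-8601 or empty). Writing a corpus and reading it back
#' reproduces every field exactly, which the test suite asserts. Name parts
#' and publication types may not contain the separator characters (`,`, `|`)
#' or a leading/trailing space; [write_corpus_table()] refuses to write them.
#'
#' Journal metadata (title, Broad Subject Terms, aliases) travels in a
#' companion CSV with columns `journal_id`, `title`, `broad_subject_terms`
#' (pipe-separated) and `alias_of` (empty when not an alias). Without it,
#' journals are derived from the distinct `journal_id`s with no subject
#' terms, so eligibility selection then needs
#' `require_subject_term = FALSE`.
#'
#' @param x A [corpus()].
#' @param path Path of the article-level CSV.
#' @param journals_path Optional path of the journal-level CSV.
#' @param window Optional integer vector `c(first_year, last_year)` to attach
#'   (and enforce via [window_corpus()]) on read.
#' @return `read_corpus_table()` returns a [corpus()];
#'   `write_corpus_table()` returns `path` invisibly.
#' @name corpus-table
NULL

fmt_author_field <- function(authors_for_article) {
  a <- authors_for_article
  enc <- ifelse(
    !is.na(a$collective),
    paste0("collective:", a$collective),
    paste(blank_na(a$family), blank_na(a$given_full), blank_na(a$initials),
          sep = ",")
  )
  paste(enc, collapse = "|")
}

blank_na <- function(x) ifelse(is.na(x), "", x)
na_blank <- function(x) ifelse(!nzchar(x), NA_character_, x)

check_separator_safe <- function(x, what) {
  x <- x[!is.na(x)]
  bad <- grepl("[,|]", x) | x != trimws(x)
  if (any(bad))
    stop(what, " may not contain ',' or '|' or flanking whitespace: ",
         paste(head(unique(x[bad]), 3L), collapse = "; "))
  invisible(TRUE)
}

#' @rdname corpus-table
#' @export
write_corpus_table <- function(x, path, journals_path = NULL) {
  stopifnot(inherits(x, "corpus"))
  check_separator_safe(x$authors$family, "family names")
  check_separator_safe(x$authors$given_full, "given names")
  check_separator_safe(x$authors$initials, "initials")
  check_separator_safe(x$authors$collective, "collective names")
  check_separator_safe(unlist(x$articles$pub_types), "publication types")

  au_by_article <- split(
    x$authors[order(x$authors$article_id, x$authors$position), ,
              drop = FALSE],
    factor(x$authors$article_id[order(x$authors$article_id,
                                      x$authors$position)],
           levels = x$articles$article_id)
  )
  out <- data.frame(
    article_id = x$articles$article_id,
    journal_id = x$articles$journal_id,
    pub_year = x$articles$pub_year,
    pub_types = vapply(x$articles$pub_types, paste, "", collapse = "|"),
    has_abstract = as.integer(x$articles$has_abstract),
    authors = vapply(au_by_article, function(a) {
      if (nrow(a) == 0L) "" else fmt_author_field(a)
    }, ""),
    date_received = blank_na(format(x$articles$date_received, "%Y-%m-%d")),
    date_accepted = blank_na(format(x$articles$date_accepted, "%Y-%m-%d")),
    stringsAsFactors = FALSE
  )
  write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8", na = "")
  if (!is.null(journals_path)) {
    jout <- data.frame(
      journal_id = x$journals$journal_id,
      title = x$journals$title,
      broad_subject_terms = vapply(x$journals$broad_subject_terms, paste, "",
                                   collapse = "|"),
      alias_of = blank_na(x$journals$alias_of),
      stringsAsFactors = FALSE
    )
    write.csv(jout, journals_path, row.names = FALSE, fileEncoding = "UTF-8",
              na = "")
  }
  invisible(path)
}

parse_author_field <- function(field, article_id) {
  if (is.na(field) || !nzchar(field)) {
    return(NULL)
  }
  parts <- strsplit(field, "|", fixed = TRUE)[[1]]
  n <- length(parts)
  is_coll <- startsWith(parts, "collective:")
  fam <- giv <- ini <- coll <- rep(NA_character_, n)
  coll[is_coll] <- sub("^collective:", "", parts[is_coll])
  if (any(!is_coll)) {
    trip <- strsplit(parts[!is_coll], ",", fixed = TRUE)
    bad <- vapply(trip, length, 1L) > 3L
    if (any(bad))
      stop("malformed author triplet in article ", article_id, ": ",
           parts[!is_coll][bad][1])
    trip <- lapply(trip, function(p) c(p, rep("", 3L - length(p))))
    m <- do.call(rbind, trip)
    fam[!is_coll] <- na_blank(m[, 1])
    giv[!is_coll] <- na_blank(m[, 2])
    ini[!is_coll] <- na_blank(m[, 3])
  }
  tibble::tibble(article_id = article_id, position = seq_len(n),
                 family = fam, given_full = giv, initials = ini,
                 collective = coll)
}

#' @rdname corpus-table
#' @export
read_corpus_table <- function(path, journals_path = NULL, window = NULL) {
  expect_cols <- c("article_id", "journal_id", "pub_year", "pub_types",
                   "has_abstract", "authors", "date_received",
                   "date_accepted")
  raw <- read.csv(path, colClasses = "character", fileEncoding = "UTF-8",
                  check.names = FALSE)
  unknown <- setdiff(names(raw), expect_cols)
  if (length(unknown))
    stop("unknown column(s) in ", path, ": ", paste(unknown, collapse = ", "))
  miss <- setdiff(expect_cols, names(raw))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))

  articles <- tibble::tibble(
    article_id = raw$article_id,
    journal_id = raw$journal_id,
    pub_year = as.integer(raw$pub_year),
    pub_types = lapply(strsplit(raw$pub_types, "|", fixed = TRUE),
                       function(p) p[nzchar(p)]),
    has_abstract = raw$has_abstract == "1",
    date_received = parse_iso_date(raw$date_received, raw$article_id),
    date_accepted = parse_iso_date(raw$date_accepted, raw$article_id)
  )
  author_chunks <- Map(parse_author_field, raw$authors, raw$article_id)
  authors <- dplyr::bind_rows(author_chunks)
  if (nrow(authors) == 0L) {
    authors <- tibble::tibble(article_id = character(), position = integer(),
                              family = character(), given_full = character(),
                              initials = character(),
                              collective = character())
  }

  if (!is.null(journals_path)) {
    jraw <- read.csv(journals_path, colClasses = "character",
                     fileEncoding = "UTF-8", check.names = FALSE)
    journals <- tibble::tibble(
      journal_id = jraw$journal_id,
      title = jraw$title,
      broad_subject_terms = lapply(
        strsplit(jraw$broad_subject_terms, "|", fixed = TRUE),
        function(p) p[nzchar(p)]),
      alias_of = na_blank(jraw$alias_of)
    )
  } else {
    ids <- unique(articles$journal_id)
    journals <- tibble::tibble(
      journal_id = ids, title = ids,
      broad_subject_terms = rep(list(character()), length(ids)),
      alias_of = NA_character_
    )
  }
  out <- corpus(journals, articles, authors, window = window)
  if (!is.null(window)) out <- window_corpus(out, window)
  out
}

parse_iso_date <- function(x, article_id) {
  out <- rep(as.Date(NA), length(x))
  has <- nzchar(x)
  parsed <- as.Date(x[has], format = "%Y-%m-%d")
  bad <- is.na(parsed)
  if (any(bad))
    warning("unparsable date(s) treated as absent for article(s): ",
            paste(head(article_id[has][bad], 5L), collapse = ", "))
  out[has] <- parsed
  out
}
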