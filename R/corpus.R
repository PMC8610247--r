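#' Assemble a corpus of article-level journal metadata
#'
#' A `corpus` bundles the three tables every downstream computation works
#' from: one row per journal, one row per article, and one row per author
#' mention (an article's byline in order). Authors live in their own long
#' table rather than in a list-column so that per-journal tallies over
#' hundreds of thousands of mentions stay fast; the article-centric CSV
#' dialect written by [write_corpus_table()] is unaffected.
#'
#' @param journals Data frame with columns `journal_id` (character),
#'   `title` (character), `broad_subject_terms` (list of character vectors;
#'   may be empty), and optionally `alias_of` (character, `NA` for journals
#'   that are not aliases). A journal whose `alias_of` is set is treated as a
#'   former name of the target journal and pooled into it by
#'   [resolve_aliases()].
#' @param articles Data frame with columns `article_id`, `journal_id`
#'   (character), `pub_year` (integer), `pub_types` (list of character
#'   vectors), `has_abstract` (logical), `date_received`, `date_accepted`
#'   (`Date`, `NA` when unreported).
#' @param authors Data frame with columns `article_id`, `position` (integer,
#'   1-based byline order), `family`, `given_full`, `initials`, `collective`
#'   (character, `NA` when absent). Each row must carry a family name or a
#'   collective name, never both.
#' @param window Integer vector `c(first_year, last_year)` or `NULL`.
#'
#' @return An object of class `corpus`.
#' @seealso [corpus_articles()], [corpus_journals()], [corpus_authors()],
#'   [read_corpus_table()], [parse_medline_xml()]
#' @export
corpus <- function(journals, articles, authors, window = NULL) {
  journals <- tibble::as_tibble(journals)
  articles <- tibble::as_tibble(articles)
  authors <- tibble::as_tibble(authors)
  if (!"alias_of" %in% names(journals)) {
    journals$alias_of <- NA_character_
  }
  obj <- structure(
    list(journals = journals, articles = articles, authors = authors,
         window = if (is.null(window)) NULL else as.integer(window)),
    class = "corpus"
  )
  validate_corpus(obj)
}

validate_corpus <- function(x) {
  need_j <- c("journal_id", "title", "broad_subject_terms", "alias_of")
  need_a <- c("article_id", "journal_id", "pub_year", "pub_types",
              "has_abstract", "date_received", "date_accepted")
  need_au <- c("article_id", "position", "family", "given_full", "initials",
               "collective")
  miss <- setdiff(need_j, names(x$journals))
  if (length(miss)) stop("journals table lacks column(s): ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(need_a, names(x$articles))
  if (length(miss)) stop("articles table lacks column(s): ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(need_au, names(x$authors))
  if (length(miss)) stop("authors table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(x$articles$article_id))
    stop("duplicated article_id in articles table")
  # after alias resolution every article must point at a known journal
  target <- canonical_journal_ids(x$journals)
  unknown <- setdiff(unique(x$articles$journal_id), names(target))
  if (length(unknown))
    stop("articles reference unknown journal_id(s): ",
         paste(head(unknown, 5L), collapse = ", "))
  orphan <- setdiff(unique(x$authors$article_id), x$articles$article_id)
  if (length(orphan))
    stop("author rows reference unknown article_id(s): ",
         paste(head(orphan, 5L), collapse = ", "))
  bad <- is.na(x$authors$family) & is.na(x$authors$collective)
  if (any(bad))
    stop(sum(bad), " author row(s) carry neither a family nor a collective name")
  both <- !is.na(x$authors$family) & !is.na(x$authors$collective)
  if (any(both))
    stop(sum(both), " author row(s) carry both a family and a collective name")
  if (!is.null(x$window)) {
    if (length(x$window) != 2L || any(is.na(x$window)) ||
        x$window[1] > x$window[2])
      stop("window must be c(first_year, last_year)")
  }
  x
}

# named vector: journal_id -> canonical journal_id (one alias hop)
canonical_journal_ids <- function(journals) {
  target <- ifelse(is.na(journals$alias_of), journals$journal_id,
                   journals$alias_of)
  # alias targets must themselves be catalogued and not aliases
  bad <- !(target %in% journals$journal_id)
  if (any(bad))
    stop("alias_of points at unknown journal_id(s): ",
         paste(unique(target[bad]), collapse = ", "))
  setNames(target, journals$journal_id)
}

#' @export
print.corpus <- function(x, ...) {
  win <- if (is.null(x$window)) "unset" else paste(x$window, collapse = "-")
  cat("<corpus> ", nrow(x$journals), " journals, ", nrow(x$articles),
      " articles, ", nrow(x$authors), " author mentions; window ", win, "\n",
      sep = "")
  invisible(x)
}

#' Corpus accessors
#'
#' @param x A [corpus()].
#' @return The corresponding tibble (`corpus_window()` returns an integer
#'   vector or `NULL`).
#' @name corpus-accessors
NULL

#' @rdname corpus-accessors
#' @export
corpus_articles <- function(x) x$articles

#' @rdname corpus-accessors
#' @export
corpus_journals <- function(x) x$journals

#' @rdname corpus-accessors
#' @export
corpus_authors <- function(x) x$authors

#' @rdname corpus-accessors
#' @export
corpus_window <- function(x) x$window

#' Pool journals published under former names into their current name
#'
#' Journal renamings are supplied by the user as `alias_of` entries in the
#' journals table (an alias row points at the continuing journal). Articles
#' published under an alias are re-attributed to the target journal and the
#' alias rows are dropped; the target keeps the union of both journals'
#' Broad Subject Terms.
#'
#' @param x A [corpus()].
#' @return A `corpus` in which no journal is an alias.
#' @export
resolve_aliases <- function(x) {
  stopifnot(inherits(x, "corpus"))
  map <- canonical_journal_ids(x$journals)
  if (all(map == names(map))) return(x)
  articles <- x$articles
  articles$journal_id <- unname(map[articles$journal_id])
  keep <- is.na(x$journals$alias_of)
  merged_terms <- split(
    unname(x$journals$broad_subject_terms),
    unname(map[x$journals$journal_id])
  )
  journals <- x$journals[keep, , drop = FALSE]
  journals$broad_subject_terms <- lapply(
    merged_terms[journals$journal_id],
    function(ts) sort(unique(unlist(ts)))
  )
  corpus(journals, articles, x$authors, x$window)
}

#' Restrict a corpus to a publication-year window
#'
#' Keeps articles whose attributed publication year (journal-issue year,
#' falling back to the electronic year at parse time) lies in
#' `[first_year, last_year]`, and drops their author rows accordingly.
#'
#' @param x A [corpus()].
#' @param window Integer vector `c(first_year, last_year)`.
#' @return A windowed `corpus`.
#' @export
window_corpus <- function(x, window) {
  stopifnot(inherits(x, "corpus"), length(window) == 2L)
  window <- as.integer(window)
  keep <- !is.na(x$articles$pub_year) &
    x$articles$pub_year >= window[1] & x$articles$pub_year <= window[2]
  articles <- x$articles[keep, , drop = FALSE]
  authors <- x$authors[x$authors$article_id %in% articles$article_id, ,
                       drop = FALSE]
  corpus(x$journals, articles, authors, window)
}

#' Select journals eligible for index computation
#'
#' A journal enters the analysis when it carries at least one Broad Subject
#' Term and has published at least `min_authored` authored articles (articles
#' with at least one identified author) in the chosen population over the
#' corpus window. Journals published under several names are pooled into
#' their current name before counting.
#'
#' @param x A [corpus()] already restricted to the analysis window.
#' @param population `"all"` (every authored article) or `"research"`
#'   (authored research articles only; see [is_research_article()]).
#' @param min_authored Minimum authored-article count (inclusive), default 50.
#' @param include_collectives Should collective (group) author names count as
#'   identified authors? Default `TRUE`.
#' @param require_subject_term Require at least one Broad Subject Term?
#'   Default `TRUE`; set to `FALSE` for corpora without catalogue metadata.
#' @return Sorted character vector of eligible `journal_id`s.
#' @export
select_eligible_journals <- function(x, population = c("all", "research"),
                                     min_authored = 50,
                                     include_collectives = TRUE,
                                     require_subject_term = TRUE) {
  stopifnot(inherits(x, "corpus"))
  population <- match.arg(population)
  x <- resolve_aliases(x)
  pop <- build_population(x, population, include_collectives)
  counts <- table(pop$articles$journal_id)
  ids <- names(counts)[counts >= min_authored]
  if (require_subject_term) {
    has_term <- vapply(x$journals$broad_subject_terms, length, 1L) > 0L
    ids <- intersect(ids, x$journals$journal_id[has_term])
  }
  sort(ids)
}
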