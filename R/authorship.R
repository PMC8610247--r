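#' Build normalized author identity keys
#'
#' Within a journal, an author is identified by family name plus full given
#' name when the record carries one, and otherwise by family name plus
#' initials; collective (group) names form their own identity. Name parts
#' are normalized before keying: Unicode NFC, case-folded, trimmed, internal
#' whitespace collapsed to single spaces, and periods stripped (so "J.-P."
#' and "J-P" merge); hyphens are preserved. Normalization is idempotent and
#' deterministic — identical raw names always yield identical keys. No
#' cross-journal identity resolution or homonym splitting is attempted;
#' `key_kind` records whether a full given name was available so reports can
#' expose the share of initials-only identities.
#'
#' @param family,given_full,initials,collective Character vectors (recycled
#'   to a common length); `NA` for an absent part. Each author must carry a
#'   family name or a collective name.
#' @return A tibble with columns `family_norm`, `given_norm`, `key_kind`
#'   (`"full_name"`, `"initials_only"` or `"collective"`) and `key`, the
#'   identity string used for tallying.
#' @examples
#' make_author_key(family = "Raoult", given_full = "Didier")
#' make_author_key(family = "Wang", initials = "Y")
#' make_author_key(collective = "Red")
#' @export
make_author_key <- function(family = NA_character_,
                            given_full = NA_character_,
                            initials = NA_character_,
                            collective = NA_character_) {
  n <- max(length(family), length(given_full), length(initials),
           length(collective))
  family <- rep_len(as.character(family), n)
  given_full <- rep_len(as.character(given_full), n)
  initials <- rep_len(as.character(initials), n)
  collective <- rep_len(as.character(collective), n)

  usable <- !is.na(collective) | !is.na(family)
  if (any(!usable))
    stop("unidentifiable author(s): neither a family nor a collective name ",
         "at position(s) ", paste(head(which(!usable), 5L), collapse = ", "))

  is_coll <- !is.na(collective)
  fam_norm <- ifelse(is_coll, normalize_name(collective),
                     normalize_name(family))
  has_given <- !is_coll & !is.na(given_full) & nzchar(trimws(given_full))
  giv_norm <- rep("", n)
  giv_norm[has_given] <- normalize_name(given_full[has_given])
  use_ini <- !is_coll & !has_given & !is.na(initials) &
    nzchar(trimws(initials))
  giv_norm[use_ini] <- normalize_name(initials[use_ini])

  kind <- ifelse(is_coll, "collective",
                 ifelse(has_given, "full_name", "initials_only"))
  tibble::tibble(
    family_norm = fam_norm,
    given_norm = giv_norm,
    key_kind = kind,
    key = ifelse(is_coll, paste0("collective:", fam_norm),
                 paste(fam_norm, giv_norm, sep = "|"))
  )
}

#' @rdname make_author_key
#' @param x Character vector of raw name parts.
#' @export
normalize_name <- function(x) {
  out <- stringi::stri_trans_nfc(x)
  out <- stringi::stri_trans_tolower(out)
  out <- gsub(".", "", out, fixed = TRUE)
  out <- gsub("[[:space:]]+", " ", out)
  trimws(out)
}

# authors joined to article/journal metadata with identity keys attached;
# one row per (article, author mention), duplicates within an article removed
keyed_authorships <- function(x, include_collectives = TRUE) {
  au <- x$authors
  if (!include_collectives) au <- au[is.na(au$collective), , drop = FALSE]
  if (nrow(au) == 0L) {
    return(tibble::tibble(article_id = character(), journal_id = character(),
                          pub_year = integer(), key = character(),
                          key_kind = character(), family_norm = character(),
                          given_norm = character()))
  }
  keys <- make_author_key(au$family, au$given_full, au$initials,
                          au$collective)
  out <- dplyr::bind_cols(au[, "article_id", drop = FALSE], keys)
  out <- dplyr::distinct(out, .data$article_id, .data$key, .keep_all = TRUE)
  meta <- x$articles[, c("article_id", "journal_id", "pub_year")]
  dplyr::inner_join(out, meta, by = "article_id")
}

#' Tally articles per author within a journal
#'
#' Counts, for one journal (or all journals at once), how many articles each
#' normalized author identity appears on. An author listed twice on the same
#' article is credited once for it; authorless articles contribute nothing.
#'
#' @param x A [corpus()], typically already restricted via
#'   [build_population()].
#' @param journal A single `journal_id`, or `NULL` to tally every journal
#'   (the result then carries a `journal_id` column).
#' @param include_collectives Count collective names as authors? Default
#'   `TRUE`.
#' @return A tibble with columns (`journal_id`,) `key`, `key_kind`,
#'   `family_norm`, `given_norm`, `n_articles`, sorted by decreasing
#'   `n_articles` then key.
#' @export
tally_author_counts <- function(x, journal = NULL,
                                include_collectives = TRUE) {
  stopifnot(inherits(x, "corpus"))
  if (!is.null(journal)) {
    keep <- x$articles$journal_id == journal
    articles <- x$articles[keep, , drop = FALSE]
    authors <- x$authors[x$authors$article_id %in% articles$article_id, ,
                         drop = FALSE]
    x <- corpus(x$journals, articles, authors, x$window)
  }
  ka <- keyed_authorships(x, include_collectives)
  out <- dplyr::count(ka, .data$journal_id, .data$key, .data$key_kind,
                      .data$family_norm, .data$given_norm,
                      name = "n_articles")
  out <- dplyr::arrange(out, .data$journal_id,
                        dplyr::desc(.data$n_articles), .data$key)
  if (!is.null(journal)) out$journal_id <- NULL
  out
}

#' Identify the most prolific author(s) of a journal
#'
#' Returns every author identity achieving the maximal article count; when
#' several authors share the maximum they are all treated as most prolific
#' and `tied` is set.
#'
#' @param counts A per-journal tally as returned by
#'   [tally_author_counts()] for a single journal (columns `key` and
#'   `n_articles`).
#' @return A list of class `most_prolific` with elements `keys` (character),
#'   `n_max` (integer) and `tied` (logical).
#' @export
find_most_prolific <- function(counts) {
  if (is.null(counts) || nrow(counts) == 0L)
    stop("no authored articles: cannot identify a most prolific author")
  n_max <- max(counts$n_articles)
  keys <- sort(counts$key[counts$n_articles == n_max])
  structure(list(keys = keys, n_max = as.integer(n_max),
                 tied = length(keys) > 1L),
            class = "most_prolific")
}

#' @export
print.most_prolific <- function(x, ...) {
  cat("<most_prolific> n_max = ", x$n_max,
      if (x$tied) paste0(" (tied, ", length(x$keys), " authors)") else "",
      ": ", paste(head(x$keys, 5L), collapse = ", "),
      if (length(x$keys) > 5L) ", ..." else "", "\n", sep = "")
  invisible(x)
}
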