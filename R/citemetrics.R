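#' Build a journal citation profile
#'
#' Citation side-metrics need, per profiled article of a journal: which
#' journals its reference list cites and how often the article itself has
#' been cited. An article is *self-citing* when its reference list cites at
#' least one article published in the same journal (within the user's
#' reference window — the input table is expected to be restricted to it
#' already; no citation database is queried). The journal impact factor is
#' an external input, not computed here.
#'
#' @param refs Data frame with columns `article_id`, `cited_journal_ids`
#'   (character vector list-column, or pipe-separated string) and
#'   `citation_count` (non-negative integers).
#' @param journal_id The profiled journal's id.
#' @param impact_factor Externally supplied impact factor.
#' @return A list of class `citation_profile` with `journal_id`,
#'   `impact_factor`, `citation_counts`, `n_self_citing`,
#'   `n_non_self_citing`.
#' @export
citation_profile <- function(refs, journal_id, impact_factor) {
  cited <- refs$cited_journal_ids
  if (!is.list(cited))
    cited <- strsplit(ifelse(is.na(cited), "", cited), "|", fixed = TRUE)
  counts <- as.integer(refs$citation_count)
  if (any(is.na(counts)) || any(counts < 0))
    stop("citation_count must be non-negative integers")
  self <- vapply(cited, function(js) journal_id %in% js, NA)
  structure(list(
    journal_id = journal_id,
    impact_factor = as.numeric(impact_factor),
    citation_counts = counts,
    n_self_citing = sum(self),
    n_non_self_citing = sum(!self)
  ), class = "citation_profile")
}

#' @rdname citation_profile
#' @param path CSV with columns `article_id`, `cited_journal_ids`
#'   (pipe-separated), `citation_count`.
#' @export
read_citation_profile <- function(path, journal_id, impact_factor) {
  refs <- read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  need <- c("article_id", "cited_journal_ids", "citation_count")
  miss <- setdiff(need, names(refs))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  citation_profile(refs, journal_id, impact_factor)
}

#' Self-citation boost
#'
#' The number of a journal's self-citing articles divided by its
#' non-self-citing articles. Undefined (returned as `NA` with a warning)
#' when every profiled article is self-citing.
#'
#' @param profile A [citation_profile()].
#' @return The ratio, or `NA` when undefined.
#' @export
self_citation_boost <- function(profile) {
  stopifnot(inherits(profile, "citation_profile"))
  if (profile$n_non_self_citing == 0L) {
    warning("no non-self-citing articles: self-citation boost undefined")
    return(NA_real_)
  }
  profile$n_self_citing / profile$n_non_self_citing
}

#' Skewness and nonarticle inflation
#'
#' How far the journal impact factor exceeds the citation experience of the
#' typical article: (impact factor − median per-article citations) / median
#' per-article citations. A large value means the impact factor is inflated
#' by a skewed citation distribution or by citations to non-article content.
#' Undefined (returned as `NA` with a warning) when the median article
#' citation count is 0.
#'
#' @param profile A [citation_profile()].
#' @return The inflation as a fraction (0.5 prints as 50%), or `NA` when
#'   undefined.
#' @export
skewness_nonarticle_inflation <- function(profile) {
  stopifnot(inherits(profile, "citation_profile"))
  med <- median(profile$citation_counts)
  if (is.na(med) || med == 0) {
    warning("median article citation count is 0: metric undefined")
    return(NA_real_)
  }
  (profile$impact_factor - med) / med
}
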