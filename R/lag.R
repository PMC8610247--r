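#' Publication lag of each article
#'
#' The publication lag is the whole number of days between an article's
#' submission (received) and acceptance dates. It is absent (`NA`) when
#' either date is unreported, and negative differences — acceptance recorded
#' before submission — are treated as data errors and also returned as `NA`,
#' with a warning. Zero-day lags are retained: same-day acceptance is
#' suspicious but real.
#'
#' @param x A [corpus()] (or a data frame with `date_received` and
#'   `date_accepted` columns of class `Date`).
#' @return Integer vector of days aligned with the articles, `NA` where the
#'   lag is not computable.
#' @export
compute_article_lag <- function(x) {
  articles <- if (inherits(x, "corpus")) x$articles else x
  lag <- as.integer(articles$date_accepted - articles$date_received)
  neg <- !is.na(lag) & lag < 0L
  if (any(neg)) {
    warning(sum(neg), " article(s) with acceptance before submission; ",
            "lag treated as absent")
    lag[neg] <- NA_integer_
  }
  lag
}

#' Per-journal publication-lag asymmetry
#'
#' Splits each journal's authored articles into those carrying at least one
#' of its most prolific author(s) (the MPA side) and the rest, and
#' summarises each side by its median publication lag over articles with a
#' valid lag. The ratio `median_mpa / median_non_mpa` is below 1 when the
#' most prolific author's papers move faster. A journal is `calculable` only
#' when both sides contribute at least one valid lag; the median of an even
#' number of lags is the midpoint of the two central values
#' ([stats::median()]).
#'
#' @inheritParams compute_journal_indices
#' @return A tibble with columns `journal_id`, `population`,
#'   `n_mpa_articles`, `n_non_mpa_articles` (articles with valid lags on
#'   each side), `median_mpa`, `median_non_mpa`, `ratio`, `calculable`.
#' @export
summarize_journal_lag <- function(x, population = c("all", "research"),
                                  include_collectives = TRUE,
                                  journals = NULL) {
  stopifnot(inherits(x, "corpus"))
  population <- match.arg(population)
  x <- resolve_aliases(x)
  pop <- build_population(x, population, include_collectives)
  articles <- pop$articles
  if (!is.null(journals))
    articles <- articles[articles$journal_id %in% journals, , drop = FALSE]
  articles$lag <- compute_article_lag(articles)

  ka <- keyed_authorships(pop, include_collectives)
  per_author <- dplyr::count(ka, .data$journal_id, .data$key,
                             name = "n_articles")
  mpa <- dplyr::filter(
    dplyr::group_by(per_author, .data$journal_id),
    .data$n_articles == max(.data$n_articles))
  mpa <- dplyr::ungroup(mpa)[, c("journal_id", "key")]
  mpa_articles <- unique(
    dplyr::inner_join(ka, mpa, by = c("journal_id", "key"))$article_id)
  articles$is_mpa <- articles$article_id %in% mpa_articles

  out <- dplyr::summarise(
    dplyr::group_by(articles, .data$journal_id),
    n_mpa_articles = sum(.data$is_mpa & !is.na(.data$lag)),
    n_non_mpa_articles = sum(!.data$is_mpa & !is.na(.data$lag)),
    median_mpa = median(.data$lag[.data$is_mpa], na.rm = TRUE),
    median_non_mpa = median(.data$lag[!.data$is_mpa], na.rm = TRUE),
    .groups = "drop"
  )
  out$median_mpa[out$n_mpa_articles == 0L] <- NA_real_
  out$median_non_mpa[out$n_non_mpa_articles == 0L] <- NA_real_
  out$calculable <- out$n_mpa_articles >= 1L & out$n_non_mpa_articles >= 1L
  out$ratio <- ifelse(out$calculable,
                      out$median_mpa / out$median_non_mpa, NA_real_)
  out$population <- population
  out <- out[, c("journal_id", "population", "n_mpa_articles",
                 "n_non_mpa_articles", "median_mpa", "median_non_mpa",
                 "ratio", "calculable")]
  dplyr::arrange(out, .data$journal_id)
}

#' Count journals with short median lags
#'
#' Tallies, over the calculable journals, how many have a median publication
#' lag strictly below `threshold` days on the MPA side, on the non-MPA side,
#' and on both sides. The default of 21 days (3 weeks) marks a turnaround
#' short enough to question whether any thorough peer review took place;
#' journals whose median equals the threshold are not counted.
#'
#' @param summaries Output of [summarize_journal_lag()].
#' @param threshold Days; default 21.
#' @return Named list `mpa_below`, `non_mpa_below`, `both_below`,
#'   `n_calculable`.
#' @export
count_below_threshold <- function(summaries, threshold = 21) {
  s <- summaries[summaries$calculable, , drop = FALSE]
  list(
    mpa_below = sum(s$median_mpa < threshold),
    non_mpa_below = sum(s$median_non_mpa < threshold),
    both_below = sum(s$median_mpa < threshold & s$median_non_mpa < threshold),
    n_calculable = nrow(s)
  )
}
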