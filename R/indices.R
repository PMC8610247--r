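#' Percentage of papers by the most prolific author (PPMP)
#'
#' The PPMP of a journal is the number of articles carrying its most
#' prolific author, `n_max`, divided by the journal's total number of
#' authored articles, `N_tot`. When several authors tie for the maximum the
#' numerator is still the (single) maximal count. Stored as a fraction in
#' (0, 1]; multiply by 100 for display.
#'
#' @param counts Per-journal author tally ([tally_author_counts()] for one
#'   journal).
#' @param n_tot Number of authored articles in the journal (the
#'   denominator); must be at least the maximal author count.
#' @return PPMP as a fraction.
#' @export
compute_ppmp <- function(counts, n_tot) {
  if (is.null(counts) || nrow(counts) == 0L)
    stop("no authored articles: PPMP undefined")
  if (!is.numeric(n_tot) || length(n_tot) != 1L || n_tot < 1)
    stop("n_tot must be a positive count")
  mp <- find_most_prolific(counts)
  if (mp$n_max > n_tot)
    stop("n_max (", mp$n_max, ") exceeds the authored-article count (",
         n_tot, ")")
  mp$n_max / n_tot
}

#' Sample-corrected Gini index of per-author article counts
#'
#' Measures how unequally a journal's authorships are spread over its
#' authors. With the counts sorted in nondecreasing order \eqn{y_{(1)} \le
#' \dots \le y_{(n)}}, the index is
#' \deqn{G = \left[\frac{2 \sum_i i\, y_{(i)}}{n \sum_i y_{(i)}} -
#'   \frac{n+1}{n}\right] \frac{n}{n-1},}
#' i.e. the classical Gini coefficient with the small-sample correction
#' \eqn{n/(n-1)}, so that a single author holding everything scores 1
#' regardless of \eqn{n}. The value is 0 exactly when all authors published
#' equally often. A single-author journal (\eqn{n = 1}) has no inequality to
#' measure and the correction is undefined; the convention here is 0, with a
#' warning.
#'
#' @param y Vector of per-author article counts, all positive.
#' @return Gini index in \[0, 1\].
#' @seealso [gini_pairwise_oracle()] for an algebraically equivalent
#'   mean-absolute-difference form used as an independent cross-check,
#'   [lorenz_curve()] for the underlying curve.
#' @examples
#' compute_gini(c(8, 8, 8)) # perfect equality
#' compute_gini(c(1, 1, 1, 5))
#' @export
compute_gini <- function(y) {
  check_count_vector(y)
  n <- length(y)
  if (n == 1L) {
    warning("single-author journal: corrected Gini undefined, returning 0")
    return(0)
  }
  y <- sort(y)
  g <- (2 * sum(seq_len(n) * y) / (n * sum(y)) - (n + 1) / n) * n / (n - 1)
  # guard against tiny negative round-off at perfect equality
  min(max(g, 0), 1)
}

#' @rdname compute_gini
#' @details `gini_pairwise_oracle()` computes the same quantity as half the
#'   mean absolute difference between all ordered pairs of counts, relative
#'   to the mean, with the same \eqn{n/(n-1)} correction:
#'   \eqn{G = \frac{\sum_{i,j} |y_i - y_j|}{2 n^2 \bar y} \cdot
#'   \frac{n}{n-1}}. It is \eqn{O(n^2)} and exists purely as an independent
#'   implementation for testing the sorted-index form.
#' @export
gini_pairwise_oracle <- function(y) {
  check_count_vector(y)
  n <- length(y)
  if (n == 1L) {
    warning("single-author journal: corrected Gini undefined, returning 0")
    return(0)
  }
  sum(abs(outer(y, y, "-"))) / (2 * n^2 * mean(y)) * n / (n - 1)
}

check_count_vector <- function(y) {
  if (length(y) == 0L) stop("empty author-count vector")
  if (any(is.na(y)) || any(y <= 0))
    stop("author counts must all be positive")
  invisible(TRUE)
}

#' Lorenz curve of authorship concentration
#'
#' The cumulative share of authorships held by the cumulatively poorest
#' authors: authors are sorted from least to most prolific and the running
#' totals of both coordinates are accumulated, prefixed by the origin. With
#' perfect equality the curve is the diagonal; concentration bows it below.
#' The (uncorrected) Gini coefficient equals one minus twice the area under
#' this polyline.
#'
#' @inheritParams compute_gini
#' @return A tibble of class `lorenz_curve` with columns `p_authors` and
#'   `p_authorships`, both nondecreasing from (0, 0) to (1, 1).
#' @export
lorenz_curve <- function(y) {
  check_count_vector(y)
  y <- sort(y)
  n <- length(y)
  out <- tibble::tibble(
    p_authors = c(0, seq_len(n) / n),
    p_authorships = c(0, cumsum(y) / sum(y))
  )
  class(out) <- c("lorenz_curve", class(out))
  out
}

#' Trapezoid area under a Lorenz curve
#'
#' @param curve A [lorenz_curve()].
#' @return Area under the polyline, in \[0, 0.5\].
#' @export
lorenz_area <- function(curve) {
  x <- curve$p_authors
  y <- curve$p_authorships
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Compute PPMP and Gini for every journal in a population
#'
#' Assembles the per-journal authorship tallies and computes, per journal
#' (pooled over the window) or per journal-year, the authored-article count
#' `n_tot`, the most-prolific count `n_max` and tie flag, the PPMP, the
#' number of distinct author identities and the sample-corrected Gini index.
#' Journal-years (or journals) without a single authored article yield no
#' row.
#'
#' @param x A [corpus()] restricted to the analysis window.
#' @param population `"all"` or `"research"` (see [build_population()]).
#' @param grouping `"pooled"` (one row per journal) or `"by_year"`.
#' @param include_collectives Count collective names as authors?
#' @param journals Optional character vector restricting the computation,
#'   typically [select_eligible_journals()]; `NULL` computes every journal
#'   present.
#' @return A tibble with columns `journal_id`, `population`, `period`
#'   (`"pooled"` or the year as character), `n_tot`, `n_max`, `tied`,
#'   `ppmp`, `n_authors`, `gini`, sorted by journal (then period).
#' @export
compute_journal_indices <- function(x, population = c("all", "research"),
                                    grouping = c("pooled", "by_year"),
                                    include_collectives = TRUE,
                                    journals = NULL) {
  stopifnot(inherits(x, "corpus"))
  population <- match.arg(population)
  grouping <- match.arg(grouping)
  x <- resolve_aliases(x)
  pop <- build_population(x, population, include_collectives)
  articles <- pop$articles
  if (!is.null(journals))
    articles <- articles[articles$journal_id %in% journals, , drop = FALSE]

  ka <- keyed_authorships(pop, include_collectives)
  if (!is.null(journals)) ka <- ka[ka$journal_id %in% journals, , drop = FALSE]

  if (grouping == "by_year") {
    articles$period <- as.character(articles$pub_year)
    ka$period <- as.character(ka$pub_year)
  } else {
    articles$period <- "pooled"
    ka$period <- "pooled"
  }

  n_tot <- dplyr::count(articles, .data$journal_id, .data$period,
                        name = "n_tot")
  per_author <- dplyr::count(ka, .data$journal_id, .data$period, .data$key,
                             name = "n_articles")
  idx <- dplyr::summarise(
    dplyr::group_by(per_author, .data$journal_id, .data$period),
    n_max = max(.data$n_articles),
    tied = sum(.data$n_articles == max(.data$n_articles)) > 1L,
    n_authors = dplyr::n(),
    gini = gini_sorted(.data$n_articles),
    .groups = "drop"
  )
  out <- dplyr::inner_join(n_tot, idx, by = c("journal_id", "period"))
  out$ppmp <- out$n_max / out$n_tot
  out$population <- population
  out <- out[, c("journal_id", "population", "period", "n_tot", "n_max",
                 "tied", "ppmp", "n_authors", "gini")]
  dplyr::arrange(out, .data$journal_id, .data$period)
}

# corrected Gini without argument checks or the single-author warning;
# bulk path used by compute_journal_indices (n = 1 journals score 0)
gini_sorted <- function(y) {
  n <- length(y)
  if (n == 1L) return(0)
  y <- sort(y)
  g <- (2 * sum(seq_len(n) * y) / (n * sum(y)) - (n + 1) / n) * n / (n - 1)
  min(max(g, 0), 1)
}
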