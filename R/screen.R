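#' Empirical percentile threshold
#'
#' The empirical `q`-quantile by linear interpolation between order
#' statistics at position `h = (n - 1) q + 1` ([stats::quantile()] type 7,
#' the default of mainstream statistical environments). The screening
#' thresholds depend on the interpolation rule, so it is fixed here and
#' named in the threshold metadata.
#'
#' @param values Numeric vector, non-empty.
#' @param q Probability, default 0.95.
#' @return The threshold value.
#' @export
percentile_threshold <- function(values, q = 0.95) {
  if (length(values) == 0L) stop("cannot take a percentile of no values")
  unname(quantile(values, probs = q, type = 7, names = FALSE, na.rm = FALSE))
}

#' Screening thresholds for a population
#'
#' @param indices Output of [compute_journal_indices()] (pooled) for one
#'   population.
#' @param q Probability, default 0.95.
#' @return A list of class `screen_thresholds` with `population`,
#'   `q`, `q95_ppmp`, `q95_gini` and `quantile_method`.
#' @export
screen_thresholds <- function(indices, q = 0.95) {
  structure(list(
    population = unique(indices$population),
    q = q,
    q95_ppmp = percentile_threshold(indices$ppmp, q),
    q95_gini = percentile_threshold(indices$gini, q),
    quantile_method = "linear interpolation between order statistics (type 7)"
  ), class = "screen_thresholds")
}

#' Flag outlier journals above their index percentiles
#'
#' A journal is flagged on an index when its value is strictly above that
#' index's empirical `q`-quantile over the eligible journals of the same
#' population ("above the 95th percentile": a journal exactly at the
#' threshold is not flagged). `flagged_any` combines the two indices; the
#' thresholds used are attached as the `thresholds` attribute.
#'
#' @inheritParams screen_thresholds
#' @param thresholds Optional precomputed [screen_thresholds()]; computed
#'   from `indices` when `NULL`.
#' @return A tibble with columns `journal_id`, `population`, `flagged_ppmp`,
#'   `flagged_gini`, `flagged_any`.
#' @export
flag_outliers <- function(indices, thresholds = NULL, q = 0.95) {
  if (is.null(thresholds)) thresholds <- screen_thresholds(indices, q)
  out <- tibble::tibble(
    journal_id = indices$journal_id,
    population = indices$population,
    flagged_ppmp = indices$ppmp > thresholds$q95_ppmp,
    flagged_gini = indices$gini > thresholds$q95_gini
  )
  out$flagged_any <- out$flagged_ppmp | out$flagged_gini
  attr(out, "thresholds") <- thresholds
  out
}

#' Overlap between two flag sets over one journal universe
#'
#' Partitions a shared journal universe by membership in two flagged sets
#' (e.g. PPMP-flagged versus Gini-flagged, or principal versus sensitivity
#' analysis), as in a two-set Venn diagram.
#'
#' @param flags_a,flags_b Either flag tibbles from [flag_outliers()] (their
#'   `journal_id` columns must then coincide as sets and `flag_col` selects
#'   the flag), or character vectors of flagged ids (then `universe` is
#'   required).
#' @param universe Character vector of all journal ids (only when the flags
#'   are given as id vectors).
#' @param flag_col Flag column used when tibbles are supplied; default
#'   `"flagged_any"`.
#' @return Named list `only_a`, `only_b`, `both`, `neither`; the four counts
#'   sum to the universe size.
#' @export
overlap_counts <- function(flags_a, flags_b, universe = NULL,
                           flag_col = "flagged_any") {
  if (is.data.frame(flags_a) && is.data.frame(flags_b)) {
    if (!setequal(flags_a$journal_id, flags_b$journal_id))
      stop("flag sets cover different journal universes")
    universe <- flags_a$journal_id
    a <- flags_a$journal_id[flags_a[[flag_col]]]
    b <- flags_b$journal_id[flags_b[[flag_col]]]
  } else {
    if (is.null(universe))
      stop("universe is required when flags are given as id vectors")
    a <- flags_a
    b <- flags_b
    if (!all(a %in% universe) || !all(b %in% universe))
      stop("flagged ids outside the journal universe")
  }
  in_a <- universe %in% a
  in_b <- universe %in% b
  list(only_a = sum(in_a & !in_b), only_b = sum(!in_a & in_b),
       both = sum(in_a & in_b), neither = sum(!in_a & !in_b))
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' Pearson's r between two paired index vectors, with the 95% confidence
#' interval obtained by the Fisher z-transform (`atanh`), a standard error
#' of `1/sqrt(n - 3)` and the normal quantile 1.96.
#'
#' @param x,y Paired numeric vectors, `n >= 4`, each with positive variance.
#' @return A list of class `correlation_result` with `r`, `ci_low`,
#'   `ci_high`, `n`.
#' @export
correlate_indices <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: correlation undefined")
  r <- stats::cor(x, y)
  if (abs(r) == 1) {
    ci <- c(r, r)
  } else {
    z <- atanh(r)
    se <- 1 / sqrt(n - 3)
    ci <- tanh(z + c(-1, 1) * 1.96 * se)
  }
  structure(list(r = r, ci_low = ci[1], ci_high = ci[2], n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (95%% CI %.3f to %.3f), n = %d\n",
              x$r, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Index distributions per Broad Subject Term
#'
#' Summarises the PPMP and Gini distributions within each Broad Subject
#' Term. A journal carrying several terms contributes to each of them (the
#' one analysis where a journal is counted more than once); terms
#' represented by fewer than `min_journals` journals are omitted.
#'
#' @param indices Pooled output of [compute_journal_indices()].
#' @param journals Journals table ([corpus_journals()]) carrying
#'   `broad_subject_terms`.
#' @param min_journals Minimum journals per term, default 10.
#' @return A tibble with one row per retained term: `term`, `n_journals`,
#'   and `median`, `q1`, `q3`, `min`, `max` for each of `ppmp` and `gini`.
#' @export
field_summaries <- function(indices, journals, min_journals = 10) {
  terms <- tidyr::unnest(
    tibble::tibble(journal_id = journals$journal_id,
                   term = journals$broad_subject_terms),
    "term")
  dat <- dplyr::inner_join(terms, indices, by = "journal_id")
  out <- dplyr::summarise(
    dplyr::group_by(dat, .data$term),
    n_journals = dplyr::n(),
    ppmp_median = median(.data$ppmp), ppmp_q1 = percentile_threshold(.data$ppmp, 0.25),
    ppmp_q3 = percentile_threshold(.data$ppmp, 0.75),
    ppmp_min = min(.data$ppmp), ppmp_max = max(.data$ppmp),
    gini_median = median(.data$gini), gini_q1 = percentile_threshold(.data$gini, 0.25),
    gini_q3 = percentile_threshold(.data$gini, 0.75),
    gini_min = min(.data$gini), gini_max = max(.data$gini),
    .groups = "drop"
  )
  out <- out[out$n_journals >= min_journals, , drop = FALSE]
  dplyr::arrange(out, .data$term)
}

#' Deterministically sample flagged journals for manual review
#'
#' Sorts the flagged journals alphabetically by full title and draws `n` of
#' them without replacement from a generator seeded with `seed`, so the same
#' inputs always give the same sample. (Determinism holds within this
#' package; a different environment's generator would draw a different
#' sample from the same seed.) When fewer than `n` journals are flagged they
#' are all returned, with a warning.
#'
#' @param flags Output of [flag_outliers()].
#' @param journals Journals table supplying titles.
#' @param n Sample size, default 100.
#' @param seed Integer seed, default 42.
#' @param flag_col Flag column, default `"flagged_any"`.
#' @return Character vector of sampled `journal_id`s (in drawn order).
#' @export
sample_flagged <- function(flags, journals, n = 100, seed = 42,
                           flag_col = "flagged_any") {
  flagged <- flags$journal_id[flags[[flag_col]]]
  titles <- setNames(journals$title, journals$journal_id)[flagged]
  ord <- order(titles, flagged, method = "radix")
  flagged <- flagged[ord]
  if (length(flagged) <= n) {
    if (length(flagged) < n)
      warning("only ", length(flagged), " journals flagged; returning all")
    return(flagged)
  }
  with_local_seed(seed, sample(flagged, n))
}

# evaluate expr under a temporary RNG state, restoring the caller's
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Survey-style summary report
#'
#' Emits the headline descriptive table of the screening survey for one
#' population: journal counts, per-journal article and authored-article
#' counts (median, quartiles, range), the PPMP distribution (as percentages)
#' with its 95th percentile, most-prolific-author article counts, tie
#' counts, the Gini distribution with its 95th percentile, and the
#' publication-lag ratio distribution with the count of journals for which
#' the lag was not calculable. The function is pure: identical inputs give a
#' byte-identical table.
#'
#' @param x A [corpus()] restricted to the analysis window.
#' @param indices Pooled [compute_journal_indices()] output for the same
#'   population, restricted to eligible journals.
#' @param lag_summaries [summarize_journal_lag()] output for the same
#'   journals.
#' @param population Population label recorded in the table.
#' @param include_collectives Passed to the article counts.
#' @return A tibble with columns `statistic` and `value`.
#' @export
summary_table <- function(x, indices, lag_summaries,
                          population = c("all", "research"),
                          include_collectives = TRUE) {
  stopifnot(inherits(x, "corpus"))
  population <- match.arg(population)
  ids <- indices$journal_id
  x <- resolve_aliases(x)
  arts <- x$articles[x$articles$journal_id %in% ids, , drop = FALSE]
  if (population == "research") {
    arts <- arts[is_research_article(
      corpus(x$journals, arts,
             x$authors[x$authors$article_id %in% arts$article_id, ,
                       drop = FALSE], x$window)), , drop = FALSE]
  }
  n_articles <- as.vector(table(factor(arts$journal_id, levels = ids)))
  lag_summaries <- lag_summaries[lag_summaries$journal_id %in% ids, ,
                                 drop = FALSE]
  ratio <- lag_summaries$ratio[lag_summaries$calculable]

  five <- function(v) {
    c(median = median(v), q1 = percentile_threshold(v, 0.25),
      q3 = percentile_threshold(v, 0.75), min = min(v), max = max(v))
  }
  rows <- c(
    n_journals = length(ids),
    stat_rows("articles", five(n_articles)),
    stat_rows("authored_articles", five(indices$n_tot)),
    stat_rows("ppmp_pct", five(indices$ppmp * 100)),
    ppmp_pct_q95 = percentile_threshold(indices$ppmp * 100, 0.95),
    stat_rows("mpa_articles", five(indices$n_max)),
    tied_n = sum(indices$tied),
    tied_pct = 100 * sum(indices$tied) / length(ids),
    stat_rows("gini", five(indices$gini)),
    gini_q95 = percentile_threshold(indices$gini, 0.95),
    if (length(ratio)) stat_rows("lag_ratio", five(ratio)) else
      stat_rows("lag_ratio", c(median = NA_real_, q1 = NA_real_,
                               q3 = NA_real_, min = NA_real_,
                               max = NA_real_)),
    lag_not_calculable_n = sum(!lag_summaries$calculable),
    lag_not_calculable_pct =
      100 * sum(!lag_summaries$calculable) / max(nrow(lag_summaries), 1L)
  )
  tibble::tibble(population = population, statistic = names(rows),
                 value = unname(rows))
}

stat_rows <- function(prefix, v) setNames(v, paste(prefix, names(v), sep = "_"))
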