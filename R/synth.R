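#' Configure the synthetic corpus generator
#'
#' Builds the parameter object for [generate_corpus()]. The generator
#' emulates the statistical structure of a MEDLINE-style journal corpus:
#' per-journal article counts from a truncated log-normal (defaults chosen
#' to match a survey-scale corpus with a median of 500 articles per journal
#' over five years, interquartile range roughly 260--960, floor 50), a
#' heavy-tailed background authorship pattern (Zipf-like rank weights over a
#' per-journal author pool), an optionally injected *favored author* who is
#' placed on an exact share `p` of the journal's articles, authorless
#' ("anonymous") articles, initials-only and collective author names, a
#' publication-type mixture, and received/accepted date pairs in which the
#' favored author enjoys a configurable lag advantage.
#'
#' @param n_journals Number of journals.
#' @param articles_per_journal List: `dist` (`"lognormal"` or `"point"`),
#'   `median`, `sdlog` (log-normal only) and `min` (truncation floor).
#' @param author_pool_size Background authors available per journal.
#' @param zipf_exponent Exponent `s` of the rank weights `r^-s` for
#'   background author draws; 0 gives a uniform pool.
#' @param assignment `"zipf"` (weighted random draws) or `"round_robin"`
#'   (background authors dealt cyclically, giving exactly equal counts when
#'   the totals divide evenly).
#' @param mean_coauthors Mean byline length; each article gets
#'   `1 + Poisson(mean_coauthors - 1)` authors.
#' @param favored_share Fraction `p` of each journal's articles carrying the
#'   favored author; scalar (recycled) or one value per journal; 0 disables
#'   injection for that journal.
#' @param favored_lag_days,baseline_lag_days Lag distribution specs: list
#'   with `dist` (`"lognormal"` or `"point"`), `median` (days) and `sdlog`.
#'   Articles carrying the favored author draw from the favored
#'   distribution, all others from the baseline.
#' @param anonymous_rate Fraction of articles with no author at all.
#' @param initials_only_rate Fraction of background authors recorded with
#'   initials only (decided per author, so an author's identity never splits
#'   between name forms).
#' @param collective_author_rate Fraction of authored articles carrying an
#'   additional collective (group) author.
#' @param pubtype_mixture Named probabilities over primary publication-type
#'   labels; `"Review"` articles also carry `"Journal Article"`.
#' @param abstract_rate Probability that a `"Journal Article"`/`"Review"`
#'   has an abstract (non-research types get one with probability 0.1).
#' @param journal_reporting_rate Probability that a journal reports history
#'   dates at all (journals that never report make the lag ratio
#'   non-calculable).
#' @param date_reporting_rate Probability that an article of a reporting
#'   journal carries its date pair.
#' @param years Window `c(first_year, last_year)`.
#' @param seed Integer seed; the generator is a pure function of the config.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_journals = 200,
                         articles_per_journal = list(dist = "lognormal",
                                                     median = 500,
                                                     sdlog = 0.97,
                                                     min = 50),
                         author_pool_size = 500,
                         zipf_exponent = 0.4,
                         assignment = c("zipf", "round_robin"),
                         mean_coauthors = 4,
                         favored_share = 0,
                         favored_lag_days = list(dist = "lognormal",
                                                 median = 40, sdlog = 0.4),
                         baseline_lag_days = list(dist = "lognormal",
                                                  median = 100, sdlog = 0.4),
                         anonymous_rate = 0.009,
                         initials_only_rate = 0.1,
                         collective_author_rate = 0.005,
                         pubtype_mixture = c("Journal Article" = 0.85,
                                             "Review" = 0.04,
                                             "Editorial" = 0.04,
                                             "Letter" = 0.04,
                                             "News" = 0.02,
                                             "Published Erratum" = 0.01),
                         abstract_rate = 0.95,
                         journal_reporting_rate = 0.5,
                         date_reporting_rate = 0.9,
                         years = c(2015L, 2019L),
                         seed = 1L) {
  assignment <- match.arg(assignment)
  cfg <- structure(as.list(environment()), class = "synth_config")
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$n_journals >= 1, cfg$author_pool_size >= 1,
            cfg$mean_coauthors >= 1, length(cfg$years) == 2L,
            cfg$years[1] <= cfg$years[2])
  rates <- c(cfg$anonymous_rate, cfg$initials_only_rate,
             cfg$collective_author_rate, cfg$abstract_rate,
             cfg$journal_reporting_rate, cfg$date_reporting_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  p <- rep_len(cfg$favored_share, cfg$n_journals)
  if (any(p < 0 | p > 1)) stop("favored_share must lie in [0, 1]")
  if (any(p + cfg$anonymous_rate > 1))
    stop("favored_share + anonymous_rate must not exceed 1")
  a <- cfg$articles_per_journal
  if (!a$dist %in% c("lognormal", "point"))
    stop("articles_per_journal$dist must be 'lognormal' or 'point'")
  if (a$dist == "point" && any(p > 0 & round(p * a$median) < 1))
    stop("infeasible favored_share: p * N rounds to zero articles")
  for (l in list(cfg$favored_lag_days, cfg$baseline_lag_days))
    if (!l$dist %in% c("lognormal", "point"))
      stop("lag dist must be 'lognormal' or 'point'")
  if (abs(sum(cfg$pubtype_mixture) - 1) > 1e-8)
    stop("pubtype_mixture must sum to 1")
  cfg$favored_share <- p
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config> ", x$n_journals, " journals, median ",
      x$articles_per_journal$median, " articles/journal, favored share ",
      paste(unique(x$favored_share), collapse = "/"),
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Preset: outlier-recovery scenario
#'
#' Two hundred journals of which a small minority have an injected favored
#' author: 170 clean journals (`p = 0`), and 10 each at shares 0.05, 0.15
#' and 0.30. Outlier screening targets the top 5% of journals, so injected
#' journals are kept rare (15%, with 5% at the strong share) — a corpus
#' where a third of journals were nepotistic would move the percentile
#' thresholds themselves. Dates are reported by every journal so lag
#' asymmetry is measurable throughout.
#'
#' @param seed Integer seed.
#' @return A [synth_config()].
#' @export
recovery_scenario_config <- function(seed = 1L) {
  synth_config(
    n_journals = 200,
    favored_share = rep(c(0, 0.05, 0.15, 0.30), times = c(170, 10, 10, 10)),
    journal_reporting_rate = 1,
    date_reporting_rate = 1,
    seed = seed
  )
}

sample_article_counts <- function(a, n) {
  if (a$dist == "point") return(rep(as.integer(round(a$median)), n))
  meanlog <- log(a$median)
  lo <- stats::plnorm(a$min - 0.5, meanlog, a$sdlog)
  u <- runif(n, lo, 1)
  pmax(a$min, as.integer(round(stats::qlnorm(u, meanlog, a$sdlog))))
}

sample_lags <- function(spec, n) {
  if (n == 0L) return(integer())
  if (spec$dist == "point") return(rep(as.integer(round(spec$median)), n))
  as.integer(round(rlnorm(n, log(spec$median), spec$sdlog)))
}

synth_subject_terms <- c("Medicine", "Biology", "Public Health", "Surgery",
                         "Neurology", "Pediatrics", "Pharmacology",
                         "Psychiatry")

#' Generate a synthetic corpus with known ground truth
#'
#' Draws a corpus from a [synth_config()] together with a per-journal truth
#' table recording what was injected, so recovery tests can compare measured
#' indices against construction. The favored author of a journal with share
#' `p` is placed on exactly `round(p * N)` of its `N` articles (all
#' non-anonymous), and is always recorded under a full, journal-specific
#' name distinct from every background author; consequently the measured
#' PPMP equals `round(p * N) / N_authored` exactly whenever no background
#' author exceeds that count. The generator is deterministic given the
#' config (the caller's RNG state is left untouched).
#'
#' @param config A [synth_config()].
#' @return A list with elements `corpus` (a [corpus()]) and `truth` (tibble
#'   with columns `journal_id`, `favored_share`, `n_articles`, `n_authored`,
#'   `favored_key`, `favored_articles`, `expected_ppmp`,
#'   `expected_lag_ratio`, `reports_dates`, `eligible`).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_local_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(cfg) {
  nj <- cfg$n_journals
  p <- cfg$favored_share
  journal_id <- sprintf("SYNJ%04d", seq_len(nj))

  n_terms <- 1L + rbinom(nj, 1L, 0.3)
  terms <- lapply(n_terms, function(k) sort(sample(synth_subject_terms, k)))
  reports_dates <- runif(nj) < cfg$journal_reporting_rate
  n_art <- sample_article_counts(cfg$articles_per_journal, nj)

  total <- sum(n_art)
  jidx <- rep.int(seq_len(nj), n_art)
  article_id <- sprintf("SYNA%07d", seq_len(total))
  years_vec <- seq(cfg$years[1], cfg$years[2])
  pub_year <- years_vec[sample.int(length(years_vec), total, replace = TRUE)]

  primary <- sample(names(cfg$pubtype_mixture), total, replace = TRUE,
                    prob = cfg$pubtype_mixture)
  pub_types <- lapply(primary, function(t) {
    if (t == "Review") c("Journal Article", "Review") else t
  })
  researchy <- primary %in% c("Journal Article", "Review")
  has_abstract <- runif(total) < ifelse(researchy, cfg$abstract_rate, 0.1)

  anonymous <- runif(total) < cfg$anonymous_rate

  # favored-author placement: exactly round(p * N) non-anonymous articles
  k_fav <- as.integer(round(p * n_art))
  if (any(p > 0 & k_fav < 1))
    stop("infeasible favored_share: p * N rounds to zero articles for ",
         "journal(s) ", paste(journal_id[p > 0 & k_fav < 1], collapse = ", "))
  is_favored <- logical(total)
  art_of_journal <- split(seq_len(total), jidx)
  for (j in which(k_fav > 0L)) {
    idx <- art_of_journal[[j]]
    idx <- idx[!anonymous[idx]]
    if (length(idx) < k_fav[j])
      stop("infeasible favored_share for ", journal_id[j],
           ": fewer non-anonymous articles than the favored share requires")
    pick <- idx[sample.int(length(idx), k_fav[j])]
    is_favored[pick] <- TRUE
  }

  # background byline sizes (favored author takes one slot where present)
  n_auth <- 1L + rpois(total, cfg$mean_coauthors - 1)
  n_bg <- ifelse(anonymous, 0L, pmax(n_auth - is_favored, 0L))

  pool <- cfg$author_pool_size
  draws <- sum(n_bg)
  if (cfg$assignment == "round_robin") {
    rank <- rep_len(seq_len(pool), draws)
  } else {
    w <- seq_len(pool)^(-cfg$zipf_exponent)
    rank <- sample.int(pool, draws, replace = TRUE, prob = w)
  }
  bg_art <- rep.int(seq_len(total), n_bg)
  dup <- duplicated(cbind(bg_art, rank))
  bg_art <- bg_art[!dup]
  rank <- rank[!dup]

  ini_only <- runif(pool) < cfg$initials_only_rate
  has_coll <- !anonymous & runif(total) < cfg$collective_author_rate
  coll_name <- sprintf("Collective Study Group %02d",
                       sample.int(10L, sum(has_coll), replace = TRUE))

  fav_rows <- tibble::tibble(
    art = which(is_favored),
    family = sprintf("prolific%04d", jidx[is_favored]),
    given_full = "Author", initials = "A", collective = NA_character_
  )
  bg_rows <- tibble::tibble(
    art = bg_art,
    family = sprintf("family%04d", rank),
    given_full = ifelse(ini_only[rank], NA_character_,
                        sprintf("given%04d", rank)),
    initials = "G",
    collective = NA_character_
  )
  coll_rows <- tibble::tibble(
    art = which(has_coll),
    family = NA_character_, given_full = NA_character_,
    initials = NA_character_, collective = coll_name
  )
  au <- dplyr::bind_rows(fav_rows, bg_rows, coll_rows)
  au <- au[order(au$art, is.na(au$family), au$family), , drop = FALSE]
  au <- tibble::tibble(
    article_id = article_id[au$art],
    position = sequence(rle(au$art)$lengths),
    family = au$family, given_full = au$given_full,
    initials = au$initials, collective = au$collective
  )

  has_dates <- reports_dates[jidx] & runif(total) < cfg$date_reporting_rate
  received <- as.Date(sprintf("%d-01-01", pub_year)) +
    sample.int(365L, total, replace = TRUE) - 1L
  lag <- integer(total)
  lag[is_favored] <- sample_lags(cfg$favored_lag_days, sum(is_favored))
  lag[!is_favored] <- sample_lags(cfg$baseline_lag_days, sum(!is_favored))
  accepted <- received + lag
  received[!has_dates] <- NA
  accepted[!has_dates] <- NA

  articles <- tibble::tibble(
    article_id = article_id, journal_id = journal_id[jidx],
    pub_year = as.integer(pub_year), pub_types = pub_types,
    has_abstract = has_abstract, date_received = received,
    date_accepted = accepted
  )
  journals <- tibble::tibble(
    journal_id = journal_id,
    title = sprintf("Synthetic Journal %04d", seq_len(nj)),
    broad_subject_terms = terms,
    alias_of = NA_character_
  )
  corp <- corpus(journals, articles, au, window = cfg$years)

  n_anon <- unname(vapply(art_of_journal, function(i) sum(anonymous[i]), 1L))
  n_authored <- n_art - n_anon
  fav_key <- ifelse(
    p > 0,
    make_author_key(family = sprintf("prolific%04d", seq_len(nj)),
                    given_full = "Author")$key,
    NA_character_)
  ratio <- expected_lag_ratio(cfg)
  truth <- tibble::tibble(
    journal_id = journal_id,
    favored_share = p,
    n_articles = n_art,
    n_authored = n_authored,
    favored_key = fav_key,
    favored_articles = k_fav,
    expected_ppmp = ifelse(p > 0, k_fav / n_authored, NA_real_),
    expected_lag_ratio = ifelse(p > 0, ratio, NA_real_),
    reports_dates = reports_dates,
    eligible = n_authored >= 50L
  )
  list(corpus = corp, truth = truth)
}

expected_lag_ratio <- function(cfg) {
  cfg$favored_lag_days$median / cfg$baseline_lag_days$median
}

#' Closed-form expectations implied by a generator config
#'
#' What a perfect recovery should find, computable without generating: per
#' journal the favored share (the expected PPMP when positive, since the
#' favored author is placed on exactly that share of articles up to
#' rounding), the favored author's identity key, and the expected lag ratio
#' (the ratio of the two lag distributions' medians).
#'
#' @param config A [synth_config()].
#' @return A tibble with columns `journal_id`, `favored_share`,
#'   `expected_ppmp`, `favored_key`, `expected_lag_ratio`.
#' @export
expected_truth <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  nj <- config$n_journals
  p <- config$favored_share
  tibble::tibble(
    journal_id = sprintf("SYNJ%04d", seq_len(nj)),
    favored_share = p,
    expected_ppmp = ifelse(p > 0, p, NA_real_),
    favored_key = ifelse(
      p > 0,
      make_author_key(family = sprintf("prolific%04d", seq_len(nj)),
                      given_full = "Author")$key,
      NA_character_),
    expected_lag_ratio = ifelse(p > 0, expected_lag_ratio(config), NA_real_)
  )
}
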