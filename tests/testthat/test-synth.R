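test_that("the generator is deterministic given the seed", {
  cfg <- synth_config(
    n_journals = 6,
    articles_per_journal = list(dist = "lognormal", median = 100,
                                sdlog = 0.5, min = 50),
    favored_share = 0.2, seed = 5)
  g1 <- generate_corpus(cfg)
  g2 <- generate_corpus(cfg)
  expect_identical(g1$truth, g2$truth)
  expect_identical(corpus_articles(g1$corpus), corpus_articles(g2$corpus))
  expect_identical(corpus_authors(g1$corpus), corpus_authors(g2$corpus))

  # byte-identical on disk too
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_corpus_table(g1$corpus, p1)
  write_corpus_table(g2$corpus, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))

  g3 <- generate_corpus(synth_config(
    n_journals = 6,
    articles_per_journal = list(dist = "lognormal", median = 100,
                                sdlog = 0.5, min = 50),
    favored_share = 0.2, seed = 6))
  expect_false(identical(corpus_articles(g1$corpus),
                         corpus_articles(g3$corpus)))
})

test_that("generated corpora survive the CSV round-trip", {
  g <- generate_corpus(synth_config(
    n_journals = 4,
    articles_per_journal = list(dist = "lognormal", median = 80,
                                sdlog = 0.3, min = 50),
    favored_share = c(0, 0, 0.1, 0.3), seed = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  jpath <- withr::local_tempfile(fileext = ".csv")
  write_corpus_table(g$corpus, path, jpath)
  back <- read_corpus_table(path, jpath)
  expect_equal(corpus_articles(back), corpus_articles(g$corpus))
  expect_equal(corpus_authors(back), corpus_authors(g$corpus))
  expect_equal(corpus_journals(back), corpus_journals(g$corpus))
})

test_that("favored author lands on exactly round(p * N) articles", {
  cfg <- synth_config(
    n_journals = 3,
    articles_per_journal = list(dist = "point", median = 500, min = 50),
    favored_share = 0.30, anonymous_rate = 0, collective_author_rate = 0,
    seed = 2)
  g <- generate_corpus(cfg)
  counts <- tally_author_counts(g$corpus)
  fav <- dplyr::inner_join(
    counts, g$truth[, c("journal_id", "favored_key")],
    by = c(journal_id = "journal_id", key = "favored_key"))
  expect_equal(nrow(fav), 3L)
  expect_equal(fav$n_articles, rep(150L, 3))
  expect_equal(g$truth$expected_ppmp, rep(0.30, 3))
})

test_that("an equal-share round-robin pool yields Gini 0", {
  cfg <- synth_config(
    n_journals = 2,
    articles_per_journal = list(dist = "point", median = 100, min = 50),
    author_pool_size = 100, assignment = "round_robin",
    mean_coauthors = 1, favored_share = 0, anonymous_rate = 0,
    collective_author_rate = 0, initials_only_rate = 0, seed = 4)
  g <- generate_corpus(cfg)
  idx <- compute_journal_indices(g$corpus)
  expect_equal(idx$gini, rep(0, 2))
  expect_equal(idx$n_authors, rep(100L, 2))
})

test_that("infeasible and invalid configurations are rejected", {
  expect_error(synth_config(favored_share = 0.999, anonymous_rate = 0.01),
               "must not exceed 1")
  expect_error(synth_config(anonymous_rate = 1.2), "rates")
  expect_error(synth_config(
    articles_per_journal = list(dist = "point", median = 60, min = 50),
    favored_share = 0.001), "infeasible")
  expect_error(synth_config(pubtype_mixture = c("Journal Article" = 0.5)),
               "sum to 1")
})

test_that("closed-form expectations match the generator's construction", {
  cfg <- synth_config(
    n_journals = 5, favored_share = c(0, 0, 0.1, 0.2, 0.3),
    favored_lag_days = list(dist = "point", median = 40, sdlog = 0),
    baseline_lag_days = list(dist = "point", median = 100, sdlog = 0),
    seed = 12)
  et <- expected_truth(cfg)
  expect_equal(et$expected_ppmp, c(NA, NA, 0.1, 0.2, 0.3))
  expect_equal(et$expected_lag_ratio, c(NA, NA, 0.4, 0.4, 0.4))
  expect_true(all(is.na(et$favored_key[1:2])))

  g <- generate_corpus(cfg)
  expect_equal(g$truth$favored_key, et$favored_key)
  expect_equal(g$truth$expected_lag_ratio, et$expected_lag_ratio)
  # realized expected PPMP differs from p only through rounding and
  # anonymous-article denominators
  with_p <- g$truth$favored_share > 0
  expect_equal(g$truth$expected_ppmp[with_p],
               g$truth$favored_articles[with_p] / g$truth$n_authored[with_p])
})

test_that("generated structure matches the configured rates at scale", {
  cfg <- synth_config(
    n_journals = 30,
    articles_per_journal = list(dist = "lognormal", median = 300,
                                sdlog = 0.5, min = 50),
    anonymous_rate = 0.05, journal_reporting_rate = 0.5, seed = 23)
  g <- generate_corpus(cfg)
  cp <- g$corpus
  anon_rate <- 1 - mean(is_authored(cp))
  expect_lt(abs(anon_rate - 0.05), 0.01)
  # journals that never report dates produce no usable lag at all
  lg <- summarize_journal_lag(cp)
  no_dates <- g$truth$journal_id[!g$truth$reports_dates]
  expect_false(any(lg$calculable[lg$journal_id %in% no_dates]))
  # research share sits near the configured publication-type mixture
  res_rate <- mean(is_research_article(cp))
  expect_lt(abs(res_rate - 0.85), 0.05)
})
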