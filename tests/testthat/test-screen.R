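test_that("percentile threshold interpolates between order statistics", {
  expect_equal(percentile_threshold(1:20, 0.95), 19.05)
  expect_equal(percentile_threshold(rep(3.7, 12), 0.5), 3.7)
  expect_equal(percentile_threshold(c(4, 9, 2), 1.0), 9)
  expect_error(percentile_threshold(numeric()), "no values")
})

test_that("outliers are flagged strictly above their percentile", {
  idx <- tibble::tibble(
    journal_id = sprintf("J%02d", 1:20),
    population = "all",
    ppmp = (1:20) / 100,
    gini = rep(0.2, 20)
  )
  fl <- flag_outliers(idx)
  th <- attr(fl, "thresholds")
  expect_equal(th$q95_ppmp, 0.1905)
  # only the journal above 0.1905 is flagged; none on the constant gini
  expect_equal(fl$journal_id[fl$flagged_ppmp], "J20")
  expect_false(any(fl$flagged_gini))

  # a journal exactly at the threshold is not flagged
  idx2 <- tibble::tibble(journal_id = c("a", "b"), population = "all",
                         ppmp = c(0.1, 0.2), gini = c(0.1, 0.2))
  fl2 <- flag_outliers(idx2, thresholds = structure(
    list(population = "all", q = 0.95, q95_ppmp = 0.2, q95_gini = 0.15,
         quantile_method = "type 7"), class = "screen_thresholds"))
  expect_false(fl2$flagged_ppmp[fl2$journal_id == "b"])
  expect_true(fl2$flagged_gini[fl2$journal_id == "b"])
})

test_that("about 5% of journals are flagged per index on continuous data", {
  set.seed(31)
  idx <- tibble::tibble(
    journal_id = sprintf("J%04d", 1:1000),
    population = "all",
    ppmp = stats::rbeta(1000, 1.2, 30),
    gini = stats::rbeta(1000, 4, 16)
  )
  fl <- flag_outliers(idx)
  expect_gte(mean(fl$flagged_ppmp), 0.04)
  expect_lte(mean(fl$flagged_ppmp), 0.06)
  expect_gte(mean(fl$flagged_gini), 0.04)
  expect_lte(mean(fl$flagged_gini), 0.06)
})

test_that("overlap counts partition the universe", {
  ov <- overlap_counts(c("j1", "j2"), c("j2", "j3"),
                       universe = c("j1", "j2", "j3", "j4"))
  expect_equal(ov, list(only_a = 1L, only_b = 1L, both = 1L, neither = 1L))

  u <- sprintf("J%02d", 1:30)
  fa <- tibble::tibble(journal_id = u, flagged_any = u %in% u[1:5])
  fb <- tibble::tibble(journal_id = u, flagged_any = u %in% u[4:10])
  ov <- overlap_counts(fa, fb)
  expect_equal(ov$both, 2L)
  expect_equal(ov$only_a + ov$only_b + ov$both + ov$neither, 30L)

  same <- overlap_counts(fa, fa)
  expect_equal(same$only_a, 0L)
  expect_equal(same$only_b, 0L)

  disjoint <- overlap_counts(u[1:3], u[4:6], universe = u)
  expect_equal(disjoint$both, 0L)

  fb_short <- fb[-1, ]
  expect_error(overlap_counts(fa, fb_short), "different journal universes")
})

test_that("Pearson correlation and Fisher-z interval behave", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate_indices(x, 2 * x + 1)$r, 1)

  y <- c(2, 1, 4, 3, 7)
  # textbook formula evaluated directly on the fixture
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- correlate_indices(x, y)
  expect_equal(res$r, r_hand)
  expect_true(res$ci_low <= res$r && res$r <= res$ci_high)
  z_lo <- tanh(atanh(r_hand) - 1.96 / sqrt(2))
  expect_equal(res$ci_low, z_lo)

  # independent variables: r near 0 at large n
  set.seed(13)
  a <- stats::rnorm(10000)
  b <- stats::rnorm(10000)
  expect_lt(abs(correlate_indices(a, b)$r), 0.03)

  # the interval narrows with n on correlated data
  set.seed(14)
  widths <- vapply(c(50, 500, 5000), function(n) {
    u <- stats::rnorm(n)
    v <- 0.5 * u + stats::rnorm(n)
    res <- correlate_indices(u, v)
    res$ci_high - res$ci_low
  }, 0)
  expect_true(all(diff(widths) < 0))

  expect_error(correlate_indices(1:3, 2:4), "at least 4")
  expect_error(correlate_indices(rep(1, 5), 1:5), "zero variance")
})

test_that("field summaries multiply-count multi-term journals and drop rare terms", {
  journals <- tibble::tibble(
    journal_id = sprintf("J%02d", 1:21),
    title = sprintf("T%02d", 1:21),
    broad_subject_terms = c(rep(list("Medicine"), 10),
                            rep(list("Surgery"), 9),
                            list(c("Medicine", "Surgery")),
                            list("Neurology")),
    alias_of = NA_character_
  )
  idx <- tibble::tibble(journal_id = journals$journal_id,
                        population = "all",
                        ppmp = seq(0.01, 0.21, by = 0.01),
                        gini = seq(0.1, 0.3, by = 0.01))
  fs <- field_summaries(idx, journals, min_journals = 10)
  expect_setequal(fs$term, c("Medicine", "Surgery"))   # Neurology: 1 < 10
  expect_equal(fs$n_journals[fs$term == "Medicine"], 11L)
  expect_equal(fs$n_journals[fs$term == "Surgery"], 10L)

  # a single shared term reproduces the global distribution
  journals$broad_subject_terms <- rep(list("Medicine"), 21)
  fs <- field_summaries(idx, journals)
  expect_equal(nrow(fs), 1L)
  expect_equal(fs$ppmp_median, median(idx$ppmp))
  expect_equal(fs$gini_q3, percentile_threshold(idx$gini, 0.75))
})

test_that("flagged-journal sampling is deterministic and seed-sensitive", {
  journals <- tibble::tibble(
    journal_id = sprintf("J%03d", 1:500),
    title = sprintf("Journal %03d", sample(1:500)),
    broad_subject_terms = rep(list("Medicine"), 500),
    alias_of = NA_character_
  )
  flags <- tibble::tibble(journal_id = journals$journal_id,
                          flagged_any = rep(c(TRUE, FALSE), c(480, 20)))
  s1 <- sample_flagged(flags, journals, n = 100, seed = 42)
  s2 <- sample_flagged(flags, journals, n = 100, seed = 42)
  expect_identical(s1, s2)
  expect_length(s1, 100)
  s3 <- sample_flagged(flags, journals, n = 100, seed = 43)
  expect_false(identical(s1, s3))

  few <- tibble::tibble(journal_id = journals$journal_id[1:5],
                        flagged_any = TRUE)
  expect_warning(all5 <- sample_flagged(few, journals, n = 100), "returning all")
  expect_setequal(all5, journals$journal_id[1:5])
})

test_that("the summary report is pure and internally consistent", {
  cfg <- synth_config(
    n_journals = 12,
    articles_per_journal = list(dist = "lognormal", median = 120,
                                sdlog = 0.4, min = 50),
    favored_share = c(rep(0, 10), 0.1, 0.2), seed = 8)
  g <- generate_corpus(cfg)
  eligible <- select_eligible_journals(g$corpus)
  idx <- compute_journal_indices(g$corpus, journals = eligible)
  lg <- summarize_journal_lag(g$corpus, journals = eligible)
  t1 <- summary_table(g$corpus, idx, lg, "all")
  t2 <- summary_table(g$corpus, idx, lg, "all")
  expect_identical(t1, t2)

  val <- setNames(t1$value, t1$statistic)
  expect_equal(unname(val["n_journals"]), length(eligible))
  expect_equal(unname(val["authored_articles_median"]), median(idx$n_tot))
  expect_equal(unname(val["ppmp_pct_median"]), median(idx$ppmp) * 100)
  expect_equal(unname(val["tied_n"]), sum(idx$tied))
  expect_equal(unname(val["gini_q95"]),
               percentile_threshold(idx$gini, 0.95))
  expect_equal(unname(val["lag_not_calculable_n"]), sum(!lg$calculable))

  # research-population report covers at most as many journals
  idx_r <- compute_journal_indices(
    g$corpus, population = "research",
    journals = select_eligible_journals(g$corpus, "research"))
  lg_r <- summarize_journal_lag(g$corpus, population = "research",
                                journals = idx_r$journal_id)
  tr <- summary_table(g$corpus, idx_r, lg_r, "research")
  expect_lte(tr$value[tr$statistic == "n_journals"],
             t1$value[t1$statistic == "n_journals"])
})
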