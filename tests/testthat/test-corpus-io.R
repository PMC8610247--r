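test_that("MEDLINE XML fixture parses with authors, dates and types intact", {
  cp <- parse_medline_xml(medline_fixture())
  arts <- corpus_articles(cp)
  expect_equal(nrow(arts), 3L)

  a1 <- arts[arts$article_id == "1001", ]
  expect_equal(a1$journal_id, "100000001")
  expect_equal(a1$pub_year, 2018L)
  expect_true(a1$has_abstract)
  expect_equal(a1$date_received, as.Date("2018-01-01"))
  expect_equal(a1$date_accepted, as.Date("2018-02-01"))
  au1 <- corpus_authors(cp)
  au1 <- au1[au1$article_id == "1001", ]
  expect_equal(au1$family, c("Doe", "Roe"))
  expect_equal(au1$given_full, c("Jane", "Richard"))
  expect_equal(au1$position, 1:2)

  # authorless editorial: empty author list, no abstract, no dates
  a2 <- arts[arts$article_id == "1002", ]
  expect_false(a2$has_abstract)
  expect_false("1002" %in% corpus_authors(cp)$article_id)
  expect_true(is.na(a2$date_received) && is.na(a2$date_accepted))
  expect_equal(a2$pub_types[[1]], "Editorial")

  # collective author; year recovered from a MedlineDate; accepted-only history
  a3 <- arts[arts$article_id == "1003", ]
  expect_equal(a3$pub_year, 2019L)
  au3 <- corpus_authors(cp)
  au3 <- au3[au3$article_id == "1003", ]
  expect_equal(au3$collective, "Red")
  expect_true(is.na(au3$family))
  expect_true(is.na(a3$date_received))
  expect_equal(a3$date_accepted, as.Date("2018-12-15"))
})

test_that("truncated XML raises a parse error", {
  txt <- paste(readLines(medline_fixture()), collapse = "\n")
  expect_error(parse_medline_xml(substr(txt, 1, 500)), "malformed")
})

test_that("articles without a journal identifier are skipped with a warning", {
  xml <- '<PubmedArticleSet><PubmedArticle><MedlineCitation>
    <PMID>9</PMID><Article>
    <Journal><JournalIssue><PubDate><Year>2018</Year></PubDate></JournalIssue></Journal>
    <PublicationTypeList><PublicationType>Journal Article</PublicationType></PublicationTypeList>
    </Article></MedlineCitation></PubmedArticle></PubmedArticleSet>'
  expect_warning(cp <- parse_medline_xml(xml), "journal identifier")
  expect_equal(nrow(corpus_articles(cp)), 0L)
})

test_that("the CSV dialect round-trips every field exactly", {
  cp <- toy_corpus(list(
    art("a1", "J1", 2015, types = c("Journal Article", "Editorial"),
        abstract = TRUE,
        authors = list(aut("Doe", "Jane", "J"),
                       aut("Wang", initials = "Y"),
                       aut(collective = "Red")),
        received = "2018-01-01", accepted = "2018-02-01"),
    art("a2", "J1", 2019, types = "Letter", abstract = FALSE),
    art("a3", "J2", 2017, authors = list(aut("Nguyen", "Thi Minh")))
  ))
  path <- withr::local_tempfile(fileext = ".csv")
  jpath <- withr::local_tempfile(fileext = ".csv")
  write_corpus_table(cp, path, jpath)
  back <- read_corpus_table(path, jpath)

  expect_equal(corpus_articles(back), corpus_articles(cp))
  expect_equal(corpus_authors(back), corpus_authors(cp))
  expect_equal(corpus_journals(back), corpus_journals(cp))

  # and writing the re-read corpus reproduces the file byte for byte
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_corpus_table(back, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
})

test_that("tabular reader enforces the dialect", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(
    "article_id,journal_id,pub_year,pub_types,has_abstract,authors,",
    "date_received,date_accepted,mystery", sep = ""), path)
  expect_error(read_corpus_table(path), "unknown column")

  # unparsable date: record-level warning, date treated as absent
  writeLines(c(
    "article_id,journal_id,pub_year,pub_types,has_abstract,authors,date_received,date_accepted",
    'x1,J1,2016,Journal Article,1,"doe,jane,j",not-a-date,'), path)
  expect_warning(cp <- read_corpus_table(path), "unparsable date")
  expect_true(is.na(corpus_articles(cp)$date_received))

  # pipe-separated cells split into sets; empty authors cell -> authorless
  writeLines(c(
    "article_id,journal_id,pub_year,pub_types,has_abstract,authors,date_received,date_accepted",
    'x1,J1,2016,Journal Article|Editorial,1,,,',
    'x2,J1,2017,Letter,0,"roe,,r",,'), path)
  cp <- read_corpus_table(path)
  expect_equal(corpus_articles(cp)$pub_types[[1]],
               c("Journal Article", "Editorial"))
  expect_false(is_authored(cp)[1])
  expect_true(is_authored(cp)[2])
})

test_that("journal eligibility applies the authored-article floor at >= 50", {
  mk <- function(n_authored, n_anon, journal) {
    c(arts_by(journal, replicate(n_authored, list(aut("Solo", "Author")),
                                 simplify = FALSE)),
      lapply(seq_len(n_anon), function(i)
        art(paste0(journal, "-anon", i), journal)))
  }
  cp <- toy_corpus(c(mk(50, 0, "J50"), mk(49, 0, "J49"), mk(48, 12, "J60")))
  ids <- select_eligible_journals(cp)
  expect_equal(ids, "J50")   # 50 in; 49 out; 60 articles - 12 authorless out

  # monotone in the floor: raising it never adds journals
  for (thr in c(10, 30, 48, 49, 50, 51)) {
    lo <- select_eligible_journals(cp, min_authored = thr)
    hi <- select_eligible_journals(cp, min_authored = thr + 1)
    expect_true(all(hi %in% lo))
  }
})

test_that("alias journals pool into their target before counting", {
  arts <- c(
    arts_by("Jnew", replicate(30, list(aut("Doe", "Jane")),
                              simplify = FALSE)),
    arts_by("Jold", replicate(25, list(aut("Roe", "Rich")),
                              simplify = FALSE))
  )
  journals <- tibble::tibble(
    journal_id = c("Jnew", "Jold"),
    title = c("New Name", "Old Name"),
    broad_subject_terms = list("Medicine", "Surgery"),
    alias_of = c(NA, "Jnew")
  )
  cp <- toy_corpus(arts, journals = journals)
  pooled <- resolve_aliases(cp)
  expect_equal(nrow(corpus_journals(pooled)), 1L)
  expect_equal(sum(corpus_articles(pooled)$journal_id == "Jnew"), 55L)
  expect_equal(corpus_journals(pooled)$broad_subject_terms[[1]],
               c("Medicine", "Surgery"))
  # 30 + 25 authored articles meet the floor only after pooling
  expect_equal(select_eligible_journals(cp), "Jnew")
})

test_that("windowing keeps only in-window years", {
  cp <- toy_corpus(list(
    art("a1", "J1", 2014, authors = list(aut("A"))),
    art("a2", "J1", 2015, authors = list(aut("A"))),
    art("a3", "J1", 2019, authors = list(aut("A"))),
    art("a4", "J1", 2020, authors = list(aut("A")))
  ))
  w <- window_corpus(cp, c(2015, 2019))
  expect_equal(sort(corpus_articles(w)$article_id), c("a2", "a3"))
  expect_equal(corpus_window(w), c(2015L, 2019L))
})
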