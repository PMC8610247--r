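#' Parse MEDLINE/PubMed XML into a corpus
#'
#' Reads a `PubmedArticleSet` document (the format returned by the NCBI
#' E-utilities `efetch` endpoint for PubMed) and extracts, per article: the
#' PMID, the journal (NLM unique id, falling back to the ISSN), the
#' publication year, the verbatim publication-type labels, whether a
#' non-empty abstract is present, the ordered author list with all name
#' parts, and the received/accepted dates from the article history.
#'
#' Conventions, applied uniformly: the publication year is the
#' journal-issue year (`JournalIssue/PubDate/Year`, or the first four digits
#' of a `MedlineDate`), falling back to the electronic publication year
#' (`ArticleDate/Year`) when the issue year is absent; history entries map
#' `PubStatus="received"` to `date_received` and `PubStatus="accepted"` to
#' `date_accepted`, all other statuses being ignored. Articles without a
#' resolvable journal identifier are skipped with a warning. Broad Subject
#' Terms are catalogue-level metadata not present in article XML, so the
#' journals table is derived with empty term sets; supply catalogue metadata
#' separately (see [read_corpus_table()]) when eligibility requires it.
#'
#' @param x Path to an XML file, a raw vector, or a single XML string.
#' @param window Optional `c(first_year, last_year)`; when given, articles
#'   outside the window are dropped via [window_corpus()].
#' @return A [corpus()].
#' @export
parse_medline_xml <- function(x, window = NULL) {
  doc <- tryCatch(
    xml2::read_xml(x),
    error = function(e) stop("malformed MEDLINE XML: ", conditionMessage(e),
                             call. = FALSE)
  )
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")

  rows <- vector("list", length(arts))
  author_rows <- vector("list", length(arts))
  jinfo <- new.env(parent = emptyenv())
  skipped <- character()

  for (i in seq_along(arts)) {
    art <- arts[[i]]
    pmid <- xml2::xml_text(xml2::xml_find_first(art, ".//MedlineCitation/PMID"))
    jid <- xml_text1(art, ".//MedlineJournalInfo/NlmUniqueID")
    if (is.na(jid)) jid <- xml_text1(art, ".//Journal/ISSN")
    if (is.na(jid) || !nzchar(jid)) {
      skipped <- c(skipped, if (is.na(pmid)) paste0("#", i) else pmid)
      next
    }
    title <- xml_text1(art, ".//Journal/Title")
    if (is.na(title)) title <- xml_text1(art, ".//MedlineJournalInfo/MedlineTA")
    if (!exists(jid, envir = jinfo))
      assign(jid, if (is.na(title)) jid else title, envir = jinfo)

    year <- xml_int1(art, ".//Journal/JournalIssue/PubDate/Year")
    if (is.na(year)) {
      mdate <- xml_text1(art, ".//Journal/JournalIssue/PubDate/MedlineDate")
      if (!is.na(mdate) && grepl("\\d{4}", mdate))
        year <- as.integer(regmatches(mdate, regexpr("\\d{4}", mdate)))
    }
    if (is.na(year)) year <- xml_int1(art, ".//Article/ArticleDate/Year")

    ptypes <- xml2::xml_text(
      xml2::xml_find_all(art, ".//PublicationTypeList/PublicationType"))
    abst <- xml2::xml_text(
      xml2::xml_find_all(art, ".//Article/Abstract/AbstractText"))
    has_abstract <- any(nzchar(trimws(abst)))

    rows[[i]] <- tibble::tibble(
      article_id = pmid, journal_id = jid, pub_year = year,
      pub_types = list(ptypes), has_abstract = has_abstract,
      date_received = history_date(art, "received"),
      date_accepted = history_date(art, "accepted")
    )

    au <- xml2::xml_find_all(art, ".//Article/AuthorList/Author")
    if (length(au)) {
      author_rows[[i]] <- tibble::tibble(
        article_id = pmid,
        position = seq_along(au),
        family = vapply(au, xml_text1, "", xpath = "./LastName"),
        given_full = vapply(au, xml_text1, "", xpath = "./ForeName"),
        initials = vapply(au, xml_text1, "", xpath = "./Initials"),
        collective = vapply(au, xml_text1, "", xpath = "./CollectiveName")
      )
    }
  }
  if (length(skipped))
    warning("skipped ", length(skipped),
            " article(s) without a journal identifier: ",
            paste(head(skipped, 5L), collapse = ", "))

  articles <- dplyr::bind_rows(rows)
  authors <- dplyr::bind_rows(author_rows)
  if (nrow(articles) == 0L)
    articles <- tibble::tibble(article_id = character(),
                               journal_id = character(),
                               pub_year = integer(), pub_types = list(),
                               has_abstract = logical(),
                               date_received = as.Date(character()),
                               date_accepted = as.Date(character()))
  if (nrow(authors) == 0L)
    authors <- tibble::tibble(article_id = character(), position = integer(),
                              family = character(), given_full = character(),
                              initials = character(),
                              collective = character())

  ids <- unique(articles$journal_id)
  journals <- tibble::tibble(
    journal_id = ids,
    title = vapply(ids, function(j) get(j, envir = jinfo), ""),
    broad_subject_terms = rep(list(character()), length(ids)),
    alias_of = NA_character_
  )
  out <- corpus(journals, articles, authors, window = window)
  if (!is.null(window)) out <- window_corpus(out, window)
  out
}

xml_text1 <- function(node, xpath) {
  n <- xml2::xml_find_first(node, xpath)
  if (inherits(n, "xml_missing")) return(NA_character_)
  txt <- xml2::xml_text(n)
  if (!nzchar(trimws(txt))) NA_character_ else trimws(txt)
}

xml_int1 <- function(node, xpath) {
  txt <- xml_text1(node, xpath)
  if (is.na(txt)) NA_integer_ else suppressWarnings(as.integer(txt))
}

history_date <- function(art, status) {
  node <- xml2::xml_find_first(
    art, sprintf(".//PubmedData/History/PubMedPubDate[@PubStatus='%s']",
                 status))
  if (inherits(node, "xml_missing")) return(as.Date(NA))
  y <- xml_int1(node, "./Year")
  m <- xml_int1(node, "./Month")
  d <- xml_int1(node, "./Day")
  if (is.na(y)) return(as.Date(NA))
  if (is.na(m)) m <- 1L
  if (is.na(d)) d <- 1L
  out <- suppressWarnings(as.Date(sprintf("%04d-%02d-%02d", y, m, d)))
  out
}
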