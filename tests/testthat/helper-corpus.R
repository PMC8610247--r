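# Small in-code corpus builders shared across tests.

# one author mention; any part may be omitted
aut <- function(family = NA, given = NA, initials = NA, collective = NA) {
  list(family = family, given = given, initials = initials,
       collective = collective)
}

# one article; authors is a list of aut() entries
art <- function(id, journal, year = 2017, types = "Journal Article",
                abstract = TRUE, authors = list(),
                received = NA, accepted = NA) {
  list(id = id, journal = journal, year = year, types = types,
       abstract = abstract, authors = authors,
       received = received, accepted = accepted)
}

# assemble a corpus from art() entries; journal metadata is derived unless
# given explicitly as a data frame
toy_corpus <- function(arts, journals = NULL, window = NULL) {
  articles <- tibble::tibble(
    article_id = vapply(arts, function(a) as.character(a$id), ""),
    journal_id = vapply(arts, function(a) a$journal, ""),
    pub_year = vapply(arts, function(a) as.integer(a$year), 1L),
    pub_types = lapply(arts, function(a) as.character(a$types)),
    has_abstract = vapply(arts, function(a) isTRUE(a$abstract), NA),
    date_received = as.Date(vapply(
      arts, function(a) as.character(a$received), "")),
    date_accepted = as.Date(vapply(
      arts, function(a) as.character(a$accepted), ""))
  )
  chunks <- lapply(arts, function(a) {
    if (length(a$authors) == 0L) return(NULL)
    tibble::tibble(
      article_id = as.character(a$id),
      position = seq_along(a$authors),
      family = vapply(a$authors, function(u) as.character(u$family), ""),
      given_full = vapply(a$authors, function(u) as.character(u$given), ""),
      initials = vapply(a$authors, function(u) as.character(u$initials), ""),
      collective = vapply(a$authors,
                          function(u) as.character(u$collective), "")
    )
  })
  authors <- dplyr::bind_rows(chunks)
  if (is.null(authors) || nrow(authors) == 0L) {
    authors <- tibble::tibble(article_id = character(), position = integer(),
                              family = character(), given_full = character(),
                              initials = character(),
                              collective = character())
  }
  if (is.null(journals)) {
    ids <- unique(articles$journal_id)
    journals <- tibble::tibble(
      journal_id = ids, title = paste("Journal", ids),
      broad_subject_terms = rep(list("Medicine"), length(ids)),
      alias_of = NA_character_
    )
  }
  corpus(journals, articles, authors, window = window)
}

# n articles by the given author sets; ids generated automatically
arts_by <- function(journal, author_sets, start_id = 1, ...) {
  Map(function(i, aus) art(paste0(journal, "-", start_id + i - 1), journal,
                           authors = aus, ...),
      seq_along(author_sets), author_sets)
}

# random positive count vectors for Gini sweeps
random_count_vectors <- function(n_vectors, max_len = 500, max_count = 1000) {
  lapply(seq_len(n_vectors), function(i) {
    sample.int(max_count, sample(2:max_len, 1L), replace = TRUE)
  })
}

medline_fixture <- function() {
  system.file("extdata", "medline-sample.xml", package = "journalscreen",
              mustWork = TRUE)
}
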