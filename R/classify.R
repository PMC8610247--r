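#' Publication-type labels excluded from the research-article population
#'
#' Returns the 31 MEDLINE publication-type labels whose presence disqualifies
#' an article from counting as a research article (editorials, letters, news,
#' errata, and similar non-research material). The list ships as a plain-text
#' file under `inst/extdata/` so it is auditable, and can be overridden by
#' pointing `path` at a file of the same format (one label per line, `#`
#' comments ignored). Labels are compared case-sensitively against the
#' MEDLINE vocabulary; unknown labels neither qualify nor exclude.
#'
#' @param path Optional path to an alternative exclusion list.
#' @return Character vector of labels.
#' @export
research_exclusion_types <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "research-exclusion-types.txt",
                        package = "journalscreen", mustWork = TRUE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Which articles have at least one identified author?
#'
#' An "authored article" carries at least one identified author. Collective
#' (group) names count as identified authors by default; set
#' `include_collectives = FALSE` to treat articles whose only authors are
#' collectives as authorless, which matters when a collective byline such as
#' an editorial-office signature would otherwise dominate a journal's tally.
#'
#' @param x A [corpus()].
#' @param include_collectives Count collective names as authors? Default
#'   `TRUE`.
#' @return Logical vector aligned with `corpus_articles(x)`.
#' @export
is_authored <- function(x, include_collectives = TRUE) {
  stopifnot(inherits(x, "corpus"))
  au <- x$authors
  if (!include_collectives) au <- au[is.na(au$collective), , drop = FALSE]
  x$articles$article_id %in% au$article_id
}

#' Which articles are research articles?
#'
#' A research article (i) carries the publication type `"Journal Article"`,
#' (ii) has a non-empty abstract, and (iii) carries none of the excluded
#' publication-type labels of [research_exclusion_types()].
#'
#' @param x A [corpus()].
#' @param exclusions Character vector of disqualifying labels; defaults to
#'   the shipped list.
#' @return Logical vector aligned with `corpus_articles(x)`.
#' @export
is_research_article <- function(x, exclusions = research_exclusion_types()) {
  stopifnot(inherits(x, "corpus"))
  vapply(x$articles$pub_types, function(pt) "Journal Article" %in% pt &&
           !any(pt %in% exclusions), NA) &
    x$articles$has_abstract
}

#' Restrict a corpus to an analysis population
#'
#' The principal analysis runs on every authored article (`"all"`); the
#' sensitivity analysis runs on authored research articles only
#' (`"research"`). The research population is always a subset of the all
#' population.
#'
#' @inheritParams is_authored
#' @param population `"all"` or `"research"`.
#' @return A [corpus()] whose articles (and author rows) are the requested
#'   population, with a `population` attribute recording the label.
#' @export
build_population <- function(x, population = c("all", "research"),
                             include_collectives = TRUE) {
  stopifnot(inherits(x, "corpus"))
  population <- match.arg(population)
  keep <- is_authored(x, include_collectives)
  if (population == "research") keep <- keep & is_research_article(x)
  articles <- x$articles[keep, , drop = FALSE]
  authors <- x$authors[x$authors$article_id %in% articles$article_id, ,
                       drop = FALSE]
  out <- corpus(x$journals, articles, authors, x$window)
  attr(out, "population") <- population
  out
}
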