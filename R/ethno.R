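# Multi-response interview fields arrive as semicolon-separated strings
# ("urana;akuri;pauwi"); a list column is also accepted.
.split_multi <- function(x) {
  if (!length(x)) return(list())
  if (is.list(x)) return(lapply(x, function(v) as.character(v[nzchar(v)])))
  lapply(strsplit(ifelse(is.na(x), "", as.character(x)), ";", fixed = TRUE),
         function(v) trimws(v[nzchar(trimws(v))]))
}

#' Tally interview citations of game taxa
#'
#' Counts, per taxon, how often it is cited as a hunting target (h) and how
#' often it is the first-ranked preference (p). Vernacular names are mapped
#' to analysis taxa through `taxonomy_map`, which is how ambiguous names
#' (e.g. "savanna deer"/"forest deer" for the two brocket deer) are
#' aggregated at genus level. A respondent citing the same taxon several
#' times (directly or via synonyms mapping to one genus after a distinct
#' vernacular each) contributes one count per distinct vernacular mention,
#' but repeated identical mentions are counted once.
#'
#' @param interviews data frame with one row per respondent and columns
#'   `respondent_id`, `cited_taxa` (semicolon-separated), and optionally
#'   `ranked_preferences` (semicolon-separated, most preferred first).
#' @param taxonomy_map optional data frame `vernacular`, `taxon`; when NULL
#'   names are used as-is. Unmapped vernaculars are an error.
#' @return object of class `citation_counts`: named vectors `h` and `p`,
#'   totals `n`, `n_pref`, `N`, `N_pref`.
#' @export
tally_citations <- function(interviews, taxonomy_map = NULL) {
  stopifnot(is.data.frame(interviews),
            all(c("respondent_id", "cited_taxa") %in% names(interviews)))
  map_name <- function(v) {
    if (is.null(taxonomy_map)) return(v)
    idx <- match(v, taxonomy_map$vernacular)
    if (anyNA(idx))
      stop("unmapped vernacular name(s): ",
           paste(unique(v[is.na(idx)]), collapse = ", "))
    as.character(taxonomy_map$taxon)[idx]
  }
  cited <- .split_multi(interviews$cited_taxa)
  prefs <- if ("ranked_preferences" %in% names(interviews))
    .split_multi(interviews$ranked_preferences)
  else rep(list(character()), nrow(interviews))

  h <- integer(0); p <- integer(0); n_pref <- 0L; N_pref <- 0L
  add <- function(tab, taxa) {
    for (tx in taxa) tab[tx] <- (if (tx %in% names(tab)) tab[[tx]] else 0L) + 1L
    tab
  }
  for (i in seq_len(nrow(interviews))) {
    # one species list per respondent: repeated mentions of the same
    # vernacular count once; distinct vernaculars mapping to one genus
    # each count (the genus-aggregation rule)
    taxa_i <- map_name(unique(cited[[i]]))
    h <- add(h, taxa_i)
    pr <- unique(prefs[[i]])
    if (length(pr)) {
      if (!all(pr %in% cited[[i]]))
        stop("respondent ", interviews$respondent_id[i],
             ": ranked preference not among cited taxa")
      N_pref <- N_pref + 1L
      n_pref <- n_pref + length(pr)
      p <- add(p, map_name(pr[1]))
    }
  }
  structure(list(h = h, p = p, n = sum(h), n_pref = n_pref,
                 N = nrow(interviews), N_pref = N_pref),
            class = "citation_counts")
}

#' @export
print.citation_counts <- function(x, ...) {
  cat("Citation counts:", x$N, "respondents,", x$n, "target citations over",
      length(x$h), "taxa;", x$N_pref, "respondents with preferences\n")
  invisible(x)
}

#' Hunting importance index Hv
#'
#' Hv_taxon = (h / n) * N, where h is the number of times the taxon is
#' mentioned as a hunting target, n the total number of target citations
#' over all taxa, and N the number of respondents. Summed over distinct
#' taxa Hv totals N, a useful audit identity.
#'
#' @param counts a `citation_counts`.
#' @param taxon taxon name(s); default all tallied taxa.
#' @return named numeric vector of Hv values.
#' @export
hv <- function(counts, taxon = NULL) {
  stopifnot(inherits(counts, "citation_counts"))
  if (counts$n == 0) stop("no citations: Hv undefined")
  if (is.null(taxon)) taxon <- names(counts$h)
  h <- vapply(taxon, function(tx)
    if (tx %in% names(counts$h)) counts$h[[tx]] else 0L, numeric(1))
  h / counts$n * counts$N
}

#' Hunting preference index Pv
#'
#' Pv_taxon = (p / n_pref) * N_pref, computed only over respondents who
#' expressed at least one ranked preference: p is the number of times the
#' taxon is the first option, n_pref the total number of preference
#' citations, and N_pref the number of respondents with a preference.
#'
#' @inheritParams hv
#' @return named numeric vector of Pv values (0 when never first choice).
#' @export
pv <- function(counts, taxon = NULL) {
  stopifnot(inherits(counts, "citation_counts"))
  if (counts$n_pref == 0) stop("no preference citations: Pv undefined")
  if (is.null(taxon)) taxon <- names(counts$h)
  p <- vapply(taxon, function(tx)
    if (tx %in% names(counts$p)) counts$p[[tx]] else 0L, numeric(1))
  p / counts$n_pref * counts$N_pref
}

#' Per-taxon index table
#'
#' @param counts a `citation_counts`.
#' @return data frame `taxon`, `h`, `Hv`, `p`, `Pv` sorted by descending Hv;
#'   Pv is NA (left blank in reports) for taxa never cited as first choice.
#' @export
indices_table <- function(counts) {
  taxa <- names(counts$h)
  p <- vapply(taxa, function(tx)
    if (tx %in% names(counts$p)) counts$p[[tx]] else 0L, numeric(1))
  out <- data.frame(
    taxon = taxa,
    h = as.integer(counts$h),
    Hv = as.numeric(hv(counts)),
    p = as.integer(p),
    Pv = if (counts$n_pref > 0) as.numeric(pv(counts)) else NA_real_,
    stringsAsFactors = FALSE)
  out$Pv[out$p == 0] <- NA_real_
  out <- out[order(-out$Hv, out$taxon), ]
  rownames(out) <- NULL
  out
}
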