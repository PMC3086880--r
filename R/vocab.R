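#' Default species codes
#'
#' The method transfers pathway annotations among a configurable set of at
#' least two species. The default set covers the three metazoans the
#' curated pathway source spans: *Caenorhabditis elegans* (`CEL`),
#' *Drosophila melanogaster* (`DME`) and *Homo sapiens* (`HSA`).
#'
#' @return Character vector of species codes.
#' @export
#' @examples
#' default_species()
default_species <- function() c("CEL", "DME", "HSA")

#' Default signaling pathway vocabulary
#'
#' The eight canonical metazoan signaling pathways used throughout:
#' EGF/MAPK, TGF-beta, IGF/insulin, Notch, WNT, Hedgehog, JAK/STAT and
#' NHR (nuclear hormone receptor).
#'
#' @return Character vector of pathway names.
#' @export
default_pathways <- function() {
  c("EGF/MAPK", "TGF-beta", "IGF/insulin", "Notch",
    "WNT", "Hedgehog", "JAK/STAT", "NHR")
}

#' Default pathway-name synonym map
#'
#' Maps pathway names used by external resources onto the canonical
#' vocabulary, e.g. the ErbB, JNK and MAPK (sub)pathways of KEGG-style
#' resources all fold into EGF/MAPK. Users may extend or replace the map;
#' it is an ordinary two-column tibble.
#'
#' @return A tibble with columns `synonym` and `pathway`.
#' @export
#' @examples
#' default_pathway_synonyms()
default_pathway_synonyms <- function() {
  tibble::tribble(
    ~synonym,        ~pathway,
    "ErbB",          "EGF/MAPK",
    "JNK",           "EGF/MAPK",
    "MAPK",          "EGF/MAPK",
    "EGF",           "EGF/MAPK",
    "Ras/MAPK",      "EGF/MAPK",
    "TGF",           "TGF-beta",
    "TGF-b",         "TGF-beta",
    "TGF-beta",      "TGF-beta",
    "TGFbeta",       "TGF-beta",
    "insulin",       "IGF/insulin",
    "insulin/IGF-1", "IGF/insulin",
    "IGF",           "IGF/insulin",
    "IGF/Insulin",   "IGF/insulin",
    "Wnt",           "WNT",
    "Wingless",      "WNT",
    "WNT/Wingless",  "WNT",
    "Hh",            "Hedgehog",
    "JAK-STAT",      "JAK/STAT",
    "STAT",          "JAK/STAT",
    "NHR",           "NHR"
  )
}

#' Normalize protein/gene identifiers for comparison
#'
#' Identifiers are trimmed and case-folded for comparison while original
#' casing is preserved for output; worm, fly and human gene symbols follow
#' different casing conventions (`lin-12`, `numb`, `NUMB`) and the same
#' symbol may be printed in either case by different sources.
#' Normalization is idempotent.
#'
#' @param x Character vector of identifiers.
#' @return Character vector of normalized keys.
#' @export
#' @examples
#' norm_id(c(" Crb-1", "NOTCH2 "))
norm_id <- function(x) {
  tolower(trimws(as.character(x)))
}

#' Resolve pathway names through a synonym map
#'
#' Canonical names pass through unchanged (matched case-insensitively);
#' other names are looked up in the synonym map. Unresolvable names are
#' returned as `NA` with a warning, or raise an error when
#' `strict = TRUE`.
#'
#' @param x Character vector of pathway names.
#' @param vocabulary Canonical pathway vocabulary.
#' @param synonyms Synonym map as returned by [default_pathway_synonyms()].
#' @param strict Error on unresolvable names instead of warning?
#' @return Character vector of canonical pathway names (`NA` where
#'   unresolved).
#' @export
resolve_pathways <- function(x,
                             vocabulary = default_pathways(),
                             synonyms = default_pathway_synonyms(),
                             strict = FALSE) {
  key <- norm_id(x)
  canon <- vocabulary[match(key, norm_id(vocabulary))]
  miss <- is.na(canon) & !is.na(x)
  if (any(miss)) {
    syn <- synonyms$pathway[match(key[miss], norm_id(synonyms$synonym))]
    canon[miss] <- vocabulary[match(norm_id(syn), norm_id(vocabulary))]
  }
  bad <- unique(x[is.na(canon) & !is.na(x)])
  if (length(bad) > 0) {
    msg <- paste0("unresolvable pathway name(s): ",
                  paste(bad, collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  canon
}

#' Round a percentage to one decimal place
#'
#' All printed percentages use one decimal with round-half-even (banker's)
#' rounding, so repeated runs and independent reimplementations agree on
#' boundary cases.
#'
#' @param x Numeric vector of percentages.
#' @return Numeric vector rounded to one decimal.
#' @export
#' @examples
#' percent1(100 * 5 / 73)
percent1 <- function(x) round(x, 1)

#' Unweighted mean of per-species percentages
#'
#' The cross-species summary statistics report the unweighted arithmetic
#' mean of the per-species percentages, to one decimal. `NA` entries
#' (species for which a fraction is undefined) are dropped with a warning.
#'
#' @param x Numeric vector of per-species percentages.
#' @return Length-one numeric, the mean rounded to one decimal.
#' @export
#' @examples
#' coverage_mean(c(83.2, 67.5, 82.6))
coverage_mean <- function(x) {
  if (anyNA(x)) {
    warning("dropping undefined per-species fractions from the mean",
            call. = FALSE)
    x <- x[!is.na(x)]
  }
  percent1(mean(x))
}

split_list_field <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(v) trimws(v[nzchar(trimws(v))]))
}

join_list_field <- function(x) {
  vapply(x, function(v) paste(v, collapse = ";"), character(1))
}

split_pmids <- function(x) {
  lapply(split_list_field(x), function(v) sort(unique(as.integer(v))))
}
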