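#' Transliteration table for genus/epithet orthography
#'
#' Scientific names may only contain the letters A-Z, a-z and the hyphen.
#' Diacritics occasionally found in older literature are mapped to their
#' conventional ASCII spellings: the umlauts gain an 'e' (o-umlaut ->
#' "oe", as in Koeberlinia), while a diaeresis or accent on other vowels
#' simply marks pronunciation and is dropped to the base letter (Isoetes).
#' The table ships as a tab-delimited file under
#' `extdata/transliteration.tsv` so users can extend it.
#'
#' @param path optional path to an alternative two-column (`from`, `to`)
#'   tab-delimited table.
#' @return a data.frame with character columns `from` and `to`.
#' @export
#' @examples
#' head(transliteration_table())
transliteration_table <- function(path = NULL) {
  if (!is.null(path)) {
    tab <- read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    stopifnot(all(c("from", "to") %in% names(tab)))
    return(tab[c("from", "to")])
  }
  if (is.null(.taxscrub_env$translit)) {
    f <- system.file("extdata", "transliteration.tsv", package = "taxscrub")
    tab <- read.delim(f, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    .taxscrub_env$translit <- tab[c("from", "to")]
  }
  .taxscrub_env$translit
}

#' Normalize the orthography of a genus or epithet token
#'
#' Transliterates special characters via [transliteration_table()] and
#' drops any residual character outside `[A-Za-z-]` and the literal hybrid
#' suffix `_x`.  Idempotent.  Elements where a residual character had to
#' be dropped are flagged in the `"flagged"` attribute of the result.
#'
#' @param word character vector of name tokens.
#' @param table transliteration table (defaults to the shipped one).
#' @return character vector of cleaned tokens; attribute `flagged` is a
#'   logical vector marking elements that lost untransliterable characters.
#' @export
#' @examples
#' normalize_orthography(c("Isoëtes", "Köberlinia", "Draba"))
normalize_orthography <- function(word, table = transliteration_table()) {
  out <- enc2utf8(as.character(word))
  for (i in seq_len(nrow(table))) {
    out <- gsub(table$from[i], table$to[i], out, fixed = TRUE, useBytes = FALSE)
  }
  # protect the hybrid suffix, then drop anything non-alphabetic
  cleaned <- gsub("[^A-Za-z_x-]", "", out)
  flagged <- cleaned != out
  structure(cleaned, flagged = flagged)
}
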