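#' Canonicalize an author citation string
#'
#' Applies the backbone's authority conventions:
#' * spaces after single-letter initials are removed
#'   (`"C. F. W. Meissn."` -> `"C.F.W.Meissn."`),
#' * the space before a filial suffix (`f.`, `fil.`) is removed
#'   (`"Balf. f."` -> `"Balf.f."`),
#' * two authors are joined with `" & "`,
#' * three or more authors are truncated to the first author plus
#'   `" & al."`,
#' * `" ex "` clauses are preserved as part of a single author unit.
#'
#' The function is idempotent and maps the empty string to itself.
#'
#' @param auth character vector of raw author strings (may be empty).
#' @return character vector of canonical author strings.
#' @export
#' @examples
#' normalize_authority("C. F. W. Meissn.")   # "C.F.W.Meissn."
#' normalize_authority("Balf. f.")           # "Balf.f."
#' normalize_authority("A.One, B.Two & C.Three")  # "A.One & al."
normalize_authority <- function(auth) {
  vapply(as.character(auth), normalize_authority_one, character(1),
         USE.NAMES = FALSE)
}

normalize_authority_one <- function(auth) {
  if (is.na(auth)) return("")
  x <- gsub("\\s+", " ", trimws(auth))
  if (!nzchar(x)) return("")
  # collapse "A. B." runs: a lone uppercase initial followed by '.', a
  # space, then another capitalised token, loses the space.  Iterate
  # because matches may abut ("C. F. W. Meissn.").
  repeat {
    y <- gsub("(^|[^A-Za-z])([A-Z])\\. (?=[A-Z])", "\\1\\2.", x, perl = TRUE)
    if (identical(y, x)) break
    x <- y
  }
  # filial suffix: "Balf. f." / "Hook. fil." lose the space
  x <- gsub("\\. (f\\.|fil\\.)(?=$|[ ,])", ".\\1", x, perl = TRUE)
  authors <- split_authors(x)
  n <- length(authors)
  if (n == 0L) "" else if (n == 1L) authors[[1L]]
  else if (n == 2L) paste(authors[[1L]], "&", authors[[2L]])
  else paste(authors[[1L]], "& al.")
}

# split an author string into author units on "," and "&"; " ex " stays
# inside one unit.
split_authors <- function(x) {
  parts <- unlist(strsplit(x, "\\s*(,|&)\\s*", perl = TRUE))
  parts <- trimws(parts)
  parts[nzchar(parts)]
}
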