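#' Infraspecific rank markers recognised by the input grammar
#' @export
RANK_MARKERS <- c("subsp.", "var.", "forma", "ssp.", "f.", "subvar.", "subf.")

#' Standardize the raw form of a submitted name
#'
#' Collapses whitespace and rewrites hybrid annotations into the canonical
#' trailing `_x` marker: an `x ` or `x_` *preceding* the genus or the
#' epithet is moved to the end of that token
#' (`"x_Spartocytisus filipes"` -> `"Spartocytisus_x filipes"`,
#' `"Lycopodium x habereri"` -> `"Lycopodium habereri_x"`).
#' The multiplication sign U+00D7 sometimes used for hybrids is not part
#' of the grammar and is rejected with an error.
#'
#' @param raw a single name string.
#' @return the normalized name string.
#' @export
#' @examples
#' standardize_input("Lycopodium x habereri House")
standardize_input <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (grepl("\u00d7", raw, fixed = TRUE)) {
    stop("the Unicode multiplication sign (U+00D7) is not accepted as a ",
         "hybrid marker; use 'x' or '_x' instead", call. = FALSE)
  }
  x <- gsub("\\s+", " ", trimws(raw))
  if (!nzchar(x)) return("")
  toks <- strsplit(x, " ", fixed = TRUE)[[1L]]

  hybridize <- function(tok) {
    if (grepl("_x$", tok)) tok else paste0(tok, "_x")
  }
  # 'x'/'X' as its own token before the genus
  if (length(toks) >= 2L && toks[1L] %in% c("x", "X")) {
    toks <- toks[-1L]
    toks[1L] <- hybridize(toks[1L])
  } else if (grepl("^[xX]_.", toks[1L])) {
    toks[1L] <- hybridize(sub("^[xX]_", "", toks[1L]))
  }
  # 'x'/'X' before the epithet (token 2 of the remaining sequence)
  if (length(toks) >= 3L && toks[2L] %in% c("x", "X")) {
    toks <- toks[-2L]
    toks[2L] <- hybridize(toks[2L])
  } else if (length(toks) >= 2L && grepl("^[xX]_.", toks[2L])) {
    toks[2L] <- hybridize(sub("^[xX]_", "", toks[2L]))
  }
  paste(toks, collapse = " ")
}

#' Parse a standardized name into its components
#'
#' Splits on spaces: the first token is the genus, the second the epithet.
#' When the name has more than three tokens and the third is one of the
#' rank markers in [RANK_MARKERS] (matched case-insensitively), the fourth
#' token is the infraspecific epithet; every remaining token belongs to
#' the authority.  Otherwise all tokens after the epithet form the
#' authority.  Trailing `_x` marks are stripped into hybrid flags, genus
#' and epithet orthography is normalized via [normalize_orthography()],
#' and the authority is canonicalized via [normalize_authority()].
#'
#' @param x a name string (ideally already passed through
#'   [standardize_input()]; it is applied here defensively).
#' @return an object of class `parsed_name`: a list with elements
#'   `genus`, `genus_hybrid`, `epithet`, `epithet_hybrid`, `rank_marker`
#'   (`"none"` when absent), `infra_epithet`, `authority`, `warnings`.
#' @export
#' @examples
#' parse_name("Draba mollissima var. kusnezowii N.Busch")
parse_name <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- standardize_input(x)
  toks <- if (nzchar(x)) strsplit(x, " ", fixed = TRUE)[[1L]] else character(0)
  if (length(toks) < 2L) {
    stop("both the genus name and the epithet must be provided", call. = FALSE)
  }
  warnings <- character(0)

  strip_hybrid <- function(tok) {
    hy <- grepl("_x$", tok, ignore.case = TRUE)
    list(token = sub("_[xX]$", "", tok), hybrid = hy)
  }
  clean_token <- function(tok, what) {
    norm <- normalize_orthography(tok)
    if (attr(norm, "flagged")[1L]) {
      warnings <<- c(warnings,
                     sprintf("invalid character dropped from %s '%s'", what, tok))
    } else if (!identical(as.character(norm), tok)) {
      warnings <<- c(warnings,
                     sprintf("special character transliterated in %s '%s'", what, tok))
    }
    as.character(norm)
  }

  g <- strip_hybrid(toks[1L])
  genus <- clean_token(g$token, "genus")
  genus <- paste0(toupper(substr(genus, 1L, 1L)),
                  tolower(substr(genus, 2L, nchar(genus))))
  e <- strip_hybrid(toks[2L])
  epithet <- tolower(clean_token(e$token, "epithet"))

  rank <- "none"
  infra <- ""
  auth_toks <- character(0)
  if (length(toks) > 3L && tolower(toks[3L]) %in% RANK_MARKERS) {
    rank <- tolower(toks[3L])
    infra <- tolower(clean_token(toks[4L], "infraspecific epithet"))
    if (length(toks) > 4L) auth_toks <- toks[5:length(toks)]
  } else if (length(toks) >= 3L) {
    auth_toks <- toks[3:length(toks)]
    # a dangling rank marker with nothing after it cannot open an authority
    if (tolower(auth_toks[1L]) %in% RANK_MARKERS) {
      warnings <- c(warnings,
                    sprintf("dangling rank marker '%s' dropped", auth_toks[1L]))
      auth_toks <- auth_toks[-1L]
    }
  }
  authority <- normalize_authority(paste(auth_toks, collapse = " "))

  structure(
    list(genus = genus, genus_hybrid = g$hybrid,
         epithet = epithet, epithet_hybrid = e$hybrid,
         rank_marker = rank, infra_epithet = infra,
         authority = authority, warnings = warnings),
    class = "parsed_name")
}

#' Format a parsed name back into its canonical string
#'
#' Inverse of [parse_name()] on canonical names: single-space joined,
#' hybrid flags rendered as trailing `_x`, no trailing space when the
#' authority is empty.
#'
#' @param p a `parsed_name` (or a list with the same fields).
#' @return the canonical name string.
#' @export
format_name <- function(p) {
  g <- if (isTRUE(p$genus_hybrid)) paste0(p$genus, "_x") else p$genus
  e <- if (isTRUE(p$epithet_hybrid)) paste0(p$epithet, "_x") else p$epithet
  parts <- c(g, e)
  if (!is.null(p$rank_marker) && p$rank_marker != "none" &&
      nzchar(p$infra_epithet)) {
    parts <- c(parts, p$rank_marker, p$infra_epithet)
  }
  if (!is.null(p$authority) && nzchar(p$authority)) {
    parts <- c(parts, p$authority)
  }
  paste(parts, collapse = " ")
}

#' @export
print.parsed_name <- function(x, ...) {
  cat("<parsed_name> ", format_name(x), "\n", sep = "")
  cat("  genus:     ", x$genus, if (x$genus_hybrid) " (hybrid)", "\n", sep = "")
  cat("  epithet:   ", x$epithet, if (x$epithet_hybrid) " (hybrid)", "\n", sep = "")
  if (x$rank_marker != "none")
    cat("  infra:     ", x$rank_marker, " ", x$infra_epithet, "\n", sep = "")
  if (nzchar(x$authority))
    cat("  authority: ", x$authority, "\n", sep = "")
  if (length(x$warnings))
    cat("  warnings:  ", paste(x$warnings, collapse = "; "), "\n", sep = "")
  invisible(x)
}

# vectorized, tolerant parse used when loading reference tables: never
# errors; unparseable rows yield empty components plus a note.
parse_names_quiet <- function(x) {
  n <- length(x)
  out <- data.frame(
    genus = character(n), genus_hybrid = logical(n),
    epithet = character(n), epithet_hybrid = logical(n),
    rank_marker = rep("none", n), infra_epithet = character(n),
    authority = character(n), parse_note = character(n),
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    p <- tryCatch(parse_name(x[i]), error = function(e) conditionMessage(e))
    if (is.character(p)) {
      toks <- strsplit(trimws(x[i]), "\\s+")[[1L]]
      out$genus[i] <- if (length(toks)) toks[1L] else ""
      out$parse_note[i] <- p
    } else {
      out$genus[i] <- p$genus
      out$genus_hybrid[i] <- p$genus_hybrid
      out$epithet[i] <- p$epithet
      out$epithet_hybrid[i] <- p$epithet_hybrid
      out$rank_marker[i] <- p$rank_marker
      out$infra_epithet[i] <- p$infra_epithet
      out$authority[i] <- p$authority
      out$parse_note[i] <- paste(p$warnings, collapse = "; ")
    }
  }
  out
}
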