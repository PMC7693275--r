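#' Load a reference backbone table
#'
#' Reads a tab-delimited UTF-8 backbone file (header row, one record per
#' line), maps its columns and status vocabulary through a
#' [lcvp_dialect()], parses every name into its components, and indexes
#' the result by genus.  Row order is preserved; unmapped file columns
#' are retained untouched as extra columns.
#'
#' @param path path to the tab-delimited file.
#' @param dialect a `ref_dialect`; defaults to the shipped one.
#' @return a `ref_table`: a data.frame with canonical columns
#'   `input_name`, `status`, `accepted_name`, `family`, `order`,
#'   `tpl_comparison` plus parsed components (`genus`, `genus_hybrid`,
#'   `epithet`, `epithet_hybrid`, `rank_marker`, `infra_epithet`,
#'   `authority`, `parse_note`), with attributes `provenance` and
#'   `genus_index`.
#' @export
load_reference <- function(path, dialect = lcvp_dialect()) {
  if (!file.exists(path)) stop("reference file not found: ", path, call. = FALSE)
  raw <- read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character",
                    fileEncoding = "UTF-8")
  find_col <- function(field) {
    aliases <- dialect$columns[[field]]
    hit <- aliases[aliases %in% names(raw)]
    if (length(hit)) hit[1L] else NA_character_
  }
  required <- c("input_name", "status", "accepted_name")
  cols <- vapply(names(dialect$columns), find_col, character(1))
  missing <- required[is.na(cols[required])]
  if (length(missing)) {
    stop("format error: no column found for field(s) ",
         paste(sprintf("'%s' (looked for: %s)", missing,
                       vapply(dialect$columns[missing], paste,
                              character(1), collapse = ", ")),
               collapse = "; "), call. = FALSE)
  }

  status_raw <- trimws(raw[[cols[["status"]]]])
  mapped <- unname(dialect$status_map[tolower(status_raw)])
  bad <- unique(status_raw[is.na(mapped)])
  if (length(bad)) {
    stop("unmappable status value(s): ", paste(sQuote(bad), collapse = ", "),
         "; extend the dialect's status_map", call. = FALSE)
  }

  get_opt <- function(field) {
    if (is.na(cols[[field]])) character(nrow(raw)) else trimws(raw[[cols[[field]]]])
  }
  tab <- data.frame(
    input_name = trimws(raw[[cols[["input_name"]]]]),
    status = mapped,
    accepted_name = trimws(raw[[cols[["accepted_name"]]]]),
    family = get_opt("family"),
    order = get_opt("order"),
    tpl_comparison = get_opt("tpl_comparison"),
    stringsAsFactors = FALSE)
  tab <- cbind(tab, parse_names_quiet(tab$input_name))
  extras <- setdiff(names(raw), stats::na.omit(cols))
  if (length(extras)) tab <- cbind(tab, raw[extras])
  as_ref_table(tab, provenance = list(path = path, version = dialect$label))
}

# establish class + genus index on a canonical-column data.frame
as_ref_table <- function(tab, provenance = list(path = NA, version = NA),
                         truth = NULL) {
  rownames(tab) <- NULL
  class(tab) <- c("ref_table", "data.frame")
  attr(tab, "provenance") <- provenance
  if (!is.null(truth)) attr(tab, "truth") <- truth
  attr(tab, "genus_index") <- split(seq_len(nrow(tab)), tab$genus)
  tab
}

#' Genus index of a reference table
#'
#' @param table a `ref_table`.
#' @param rebuild recompute from scratch instead of using the cached
#'   index (the two are always identical; exposed for verification).
#' @return named list mapping genus to row indices.
#' @export
genus_index <- function(table, rebuild = FALSE) {
  if (rebuild || is.null(attr(table, "genus_index"))) {
    split(seq_len(nrow(table)), table$genus)
  } else {
    attr(table, "genus_index")
  }
}

#' Write a reference table back to a tab-delimited file
#'
#' Writes the canonical columns under the dialect's primary header names
#' so that `load_reference(write_reference(tab))` round-trips.
#'
#' @param table a `ref_table`.
#' @param path output path.
#' @param dialect dialect supplying the header names.
#' @return `path`, invisibly.
#' @export
write_reference <- function(table, path, dialect = lcvp_dialect()) {
  hdr <- vapply(dialect$columns, `[`, character(1), 1L)
  out <- data.frame(
    a = table$input_name, b = table$status, c = table$accepted_name,
    d = table$family, e = table$order, f = table$tpl_comparison,
    stringsAsFactors = FALSE)
  names(out) <- unname(hdr[c("input_name", "status", "accepted_name",
                             "family", "order", "tpl_comparison")])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.ref_table <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf("<ref_table> %d records, %d genera (%s)\n",
              nrow(x), length(genus_index(x)),
              if (is.null(prov$version) || is.na(prov$version)) "unversioned"
              else prov$version))
  tallies <- table(factor(x$status, c("accepted", "synonym", "unresolved")))
  cat(sprintf("  accepted: %d  synonym: %d  unresolved: %d\n",
              tallies[["accepted"]], tallies[["synonym"]],
              tallies[["unresolved"]]))
  invisible(x)
}
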