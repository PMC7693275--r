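#' Column/status dialect for reading backbone files
#'
#' A dialect tells [load_reference()] which file columns hold which record
#' fields and how the file's status vocabulary maps onto the canonical
#' `accepted` / `synonym` / `unresolved` enum.  Each field maps to a
#' vector of accepted header aliases (first one found wins); the shipped
#' default covers the headers used by the published v1.0.3 backbone
#' export and by the fixtures generated with [generate_reference()].
#'
#' @param columns named list: fields `input_name`, `status`,
#'   `accepted_name` (required at load time) and `family`, `order`,
#'   `tpl_comparison` (optional), each a character vector of header
#'   aliases.
#' @param status_map named character vector mapping (lower-cased) file
#'   status values to the canonical enum.
#' @param label free-text version label recorded in the table provenance.
#' @return a list of class `ref_dialect`.
#' @export
#' @examples
#' lcvp_dialect()$columns$status
lcvp_dialect <- function(columns = NULL, status_map = NULL,
                         label = "lcvp-1.0.3") {
  default_columns <- list(
    input_name     = c("Input_Taxon", "Input.Taxon", "Input Taxon", "InputTaxon"),
    status         = c("Status", "status"),
    accepted_name  = c("Output_Taxon", "Output.Taxon", "Output Taxon", "OutputTaxon"),
    family         = c("Family", "family"),
    order          = c("Order", "order"),
    tpl_comparison = c("PL_comparison", "PL.comparison", "TPL_comparison",
                       "TPL.comparison"))
  default_status <- c(
    "accepted"   = "accepted",
    "synonym"    = "synonym",
    "unresolved" = "unresolved",
    # editorial flavours seen in backbone exports
    "valid"      = "accepted",
    "invalid"    = "synonym",
    "comb.ined." = "synonym",
    "external"   = "unresolved",
    "blanks"     = "unresolved")
  if (!is.null(columns)) {
    default_columns[names(columns)] <- columns
  }
  if (!is.null(status_map)) {
    default_status[names(status_map)] <- status_map
  }
  structure(list(columns = default_columns, status_map = default_status,
                 label = label),
            class = "ref_dialect")
}

#' Read a dialect from a plain key-value config file
#'
#' Lines of the form `key = value`; keys `col.<field>` set column aliases
#' (comma-separated), keys `status.<file value>` set status mappings, and
#' `label` sets the version label.  Lines starting with `#` are ignored.
#'
#' @param path path to the config file.
#' @return a `ref_dialect`.
#' @export
read_dialect <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  columns <- list(); status <- character(0); label <- "custom"
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1L]]
    if (length(m) != 3L) stop("malformed dialect line: ", ln, call. = FALSE)
    key <- trimws(m[2L]); val <- trimws(m[3L])
    if (key == "label") {
      label <- val
    } else if (startsWith(key, "col.")) {
      columns[[sub("^col\\.", "", key)]] <- trimws(strsplit(val, ",")[[1L]])
    } else if (startsWith(key, "status.")) {
      status[tolower(sub("^status\\.", "", key))] <- val
    } else {
      stop("unknown dialect key: ", key, call. = FALSE)
    }
  }
  lcvp_dialect(columns = columns,
               status_map = if (length(status)) status else NULL,
               label = label)
}
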