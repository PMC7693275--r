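# fixed output schema of a result table; unresolved rows carry only
# Submitted_Name and Score
RESULT_COLUMNS <- c(
  "Submitted_Name", "Matched_Name", "Status", "Accepted_Taxon", "Order",
  "Family", "Genus", "Epithet", "Rank", "Infraspecific", "Authority",
  "Genus_Distance", "Epithet_Distance", "Infra_Distance",
  "Authority_Distance", "Total_Distance", "Ambiguous", "Score")

empty_result_row <- function(submitted, score) {
  data.frame(
    Submitted_Name = submitted, Matched_Name = "", Status = "",
    Accepted_Taxon = "", Order = "", Family = "", Genus = "", Epithet = "",
    Rank = "", Infraspecific = "", Authority = "",
    Genus_Distance = NA_integer_, Epithet_Distance = NA_integer_,
    Infra_Distance = NA_integer_, Authority_Distance = NA_integer_,
    Total_Distance = NA_integer_, Ambiguous = NA, Score = score,
    stringsAsFactors = FALSE)
}

result_row_from_match <- function(submitted, m, rec) {
  comp_d <- setNames(vapply(m$components, function(cm) cm$distance,
                            integer(1)),
                     vapply(m$components, function(cm) cm$component,
                            character(1)))
  data.frame(
    Submitted_Name = submitted,
    Matched_Name = rec$input_name,
    Status = rec$status,
    Accepted_Taxon = if (rec$status == "accepted") rec$input_name
                     else rec$accepted_name,
    Order = rec$order, Family = rec$family,
    Genus = rec$genus, Epithet = rec$epithet,
    Rank = ifelse(rec$rank_marker == "none", "", rec$rank_marker),
    Infraspecific = rec$infra_epithet, Authority = rec$authority,
    Genus_Distance = comp_d[["genus"]],
    Epithet_Distance = comp_d[["epithet"]],
    Infra_Distance = comp_d[["infra"]],
    Authority_Distance = comp_d[["authority"]],
    Total_Distance = m$total_distance,
    Ambiguous = m$ambiguous, Score = m$score,
    stringsAsFactors = FALSE)
}

#' Resolve a batch of raw name strings
#'
#' Each query is standardized, parsed and resolved with
#' [resolve_single()]; per-query failures (empty input, missing epithet,
#' rejected hybrid notation) become unresolved rows with an explanatory
#' score and never abort the batch.  Row order follows submission order;
#' with `cfg$return_all_ties` a query may yield several rows.  A warning
#' is emitted for batches larger than `cfg$batch_warn_threshold`.
#'
#' @param queries character vector of submitted names.
#' @param table a flattened `ref_table`.
#' @param cfg a [match_config()].
#' @return a `result_table` (data.frame with the documented column
#'   schema, see `RESULT_COLUMNS`).
#' @export
#' @examples
#' tab <- generate_reference(fixture_spec(n_genera = 3, seed = 1))
#' tab <- flatten_synonym_chains(tab)
#' resolve_names(tab$input_name[1], tab)
resolve_names <- function(queries, table, cfg = match_config()) {
  stopifnot(length(queries) >= 1L)
  if (length(queries) > cfg$batch_warn_threshold) {
    warning("batch of ", length(queries), " names exceeds the recommended ",
            cfg$batch_warn_threshold, "; expect long runtimes", call. = FALSE)
  }
  rows <- vector("list", length(queries))
  for (i in seq_along(queries)) {
    q <- queries[i]
    p <- tryCatch(parse_name(q), error = function(e) e)
    if (inherits(p, "error")) {
      score <- if (!nzchar(trimws(q))) {
        "empty input"
      } else if (grepl("U\\+00D7", conditionMessage(p))) {
        "hybrid marker U+00D7 rejected"
      } else if (length(strsplit(trimws(q), "\\s+")[[1L]]) < 2L) {
        "epithet missing"
      } else {
        paste0("unparsed: ", conditionMessage(p))
      }
      rows[[i]] <- empty_result_row(q, score)
      next
    }
    m <- resolve_single(p, table, cfg)
    if (is.null(m$record)) {
      rows[[i]] <- empty_result_row(q, m$score)
    } else if (cfg$return_all_ties && !is.null(m$candidates) &&
               nrow(m$candidates) > 1L) {
      tie_rows <- lapply(seq_len(nrow(m$candidates)), function(k) {
        result_row_from_match(q, m, m$candidates[k, , drop = FALSE])
      })
      rows[[i]] <- do.call(rbind, tie_rows)
    } else {
      rows[[i]] <- result_row_from_match(q, m, m$record)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("result_table", "data.frame")
  out
}

#' Write a result table to CSV
#'
#' RFC-4180-style CSV, UTF-8, header row, one line per result row;
#' empty cells encode both empty strings (character columns) and missing
#' values (distance and flag columns).  [read_results()] reproduces the
#' table exactly.
#'
#' @param rt a `result_table`.
#' @param path output file path (or `""` for stdout).
#' @return `path`, invisibly.
#' @export
write_results <- function(rt, path) {
  if (nzchar(path)) {
    utils::write.csv(rt, path, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8")
  } else {
    utils::write.csv(rt, stdout(), row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Read back a result table written by [write_results()]
#'
#' @param path CSV path.
#' @return a `result_table`.
#' @export
read_results <- function(path) {
  classes <- c(rep("character", 11L), rep("integer", 5L), "logical",
               "character")
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = classes, fileEncoding = "UTF-8")
  # empty cells in character columns come back as NA; the schema wants ""
  for (j in which(classes == "character")) {
    out[[j]][is.na(out[[j]])] <- ""
  }
  names(out) <- RESULT_COLUMNS
  class(out) <- c("result_table", "data.frame")
  out
}

#' @export
print.result_table <- function(x, ...) {
  cat(sprintf("<result_table> %d row(s)\n", nrow(x)))
  show <- utils::head(as.data.frame(x)[
    c("Submitted_Name", "Matched_Name", "Status", "Accepted_Taxon",
      "Total_Distance", "Score")], 10L)
  print(show)
  if (nrow(x) > 10L) cat("  ...\n")
  invisible(x)
}
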