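#' Validate the internal consistency of a backbone
#'
#' Checks that every synonym's cross-reference leads somewhere: reports
#' synonyms whose accepted name is absent from the table (dangling),
#' synonym chains (a synonym pointing at another synonym, i.e. the
#' accepted-name column has not been transitively closed), name cycles,
#' and duplicated name strings.  A table is valid iff all four lists are
#' empty.  Pure function: the table is not modified.
#'
#' @param table a `ref_table`.
#' @return a `validation_report`: list with `n_records`,
#'   `dangling_synonyms`, `chained_synonyms` (chains rendered as
#'   `"A -> B -> C"`), `cycles` (each a character vector of members),
#'   `duplicate_names`, and logical `valid`.
#' @export
validate_reference <- function(table) {
  n <- nrow(table)
  dup <- unique(table$input_name[duplicated(table$input_name)])

  idx <- match(table$accepted_name, table$input_name)
  is_syn <- table$status == "synonym"
  dangling <- table$input_name[is_syn &
                               (!nzchar(table$accepted_name) | is.na(idx))]

  chains <- character(0)
  cycles <- list()
  cycle_keys <- character(0)
  syn_rows <- which(is_syn & nzchar(table$accepted_name) & !is.na(idx))
  for (i in syn_rows) {
    path <- i
    j <- idx[i]
    in_cycle <- FALSE
    repeat {
      if (is.na(j)) break                      # dangles further down: reported there
      if (j %in% path) {                       # cycle
        in_cycle <- TRUE
        members <- sort(unique(table$input_name[path[which(path == j):length(path)]]))
        key <- paste(members, collapse = "\r")
        if (!key %in% cycle_keys) {
          cycle_keys <- c(cycle_keys, key)
          cycles[[length(cycles) + 1L]] <- members
        }
        break
      }
      path <- c(path, j)
      if (table$status[j] != "synonym") break
      j <- idx[j]
    }
    # the direct target being itself a synonym means an unflattened chain
    # (cycle members are reported as cycles only)
    if (!in_cycle && table$status[idx[i]] == "synonym") {
      chains <- c(chains, paste(table$input_name[path], collapse = " -> "))
    }
  }

  structure(
    list(n_records = n,
         dangling_synonyms = dangling,
         chained_synonyms = chains,
         cycles = cycles,
         duplicate_names = dup,
         valid = !length(dangling) && !length(chains) &&
                 !length(cycles) && !length(dup)),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d records: %s\n", x$n_records,
              if (x$valid) "valid" else "defects found"))
  cat(sprintf("  dangling synonyms: %d\n", length(x$dangling_synonyms)))
  cat(sprintf("  synonym chains:    %d\n", length(x$chained_synonyms)))
  cat(sprintf("  cycles:            %d\n", length(x$cycles)))
  cat(sprintf("  duplicate names:   %d\n", length(x$duplicate_names)))
  invisible(x)
}

#' Flatten synonym chains to their terminal accepted names
#'
#' Rewrites every synonym's accepted-name cross-reference so that it
#' points directly to a record with status `accepted`: if A is a synonym
#' of B and B turns out to be a synonym of C, A's accepted name becomes
#' C.  Synonyms whose chain ends nowhere (absent target, or a terminal
#' record that is itself unresolved) are demoted to `unresolved` with a
#' warning rather than aborting the run.  Cycles abort with an error
#' naming the members.  Idempotent; non-synonym records are untouched.
#'
#' @param table a `ref_table` (no cycles).
#' @return the flattened `ref_table`.
#' @export
flatten_synonym_chains <- function(table) {
  rep <- validate_reference(table)
  if (length(rep$cycles)) {
    stop("cannot flatten: synonym cycle(s) involving ",
         paste(vapply(rep$cycles, paste, character(1), collapse = " <-> "),
               collapse = "; "), call. = FALSE)
  }
  idx <- match(table$accepted_name, table$input_name)
  is_syn <- table$status == "synonym"
  demoted <- integer(0)
  for (i in which(is_syn)) {
    j <- idx[i]
    if (!nzchar(table$accepted_name[i]) || is.na(j)) {
      demoted <- c(demoted, i)
      next
    }
    hops <- 0L
    while (!is.na(j) && table$status[j] == "synonym" && hops < nrow(table)) {
      j <- idx[j]
      hops <- hops + 1L
    }
    if (is.na(j) || table$status[j] != "accepted") {
      demoted <- c(demoted, i)
    } else {
      table$accepted_name[i] <- table$input_name[j]
    }
  }
  if (length(demoted)) {
    nms <- table$input_name[demoted]
    table$status[demoted] <- "unresolved"
    table$accepted_name[demoted] <- ""
    warning(length(demoted), " synonym(s) with dangling accepted names ",
            "demoted to unresolved: ",
            paste(utils::head(nms, 5L), collapse = ", "),
            if (length(demoted) > 5L) ", ..." else "", call. = FALSE)
  }
  as_ref_table(table, provenance = attr(table, "provenance"),
               truth = attr(table, "truth"))
}
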