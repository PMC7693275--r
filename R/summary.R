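#' Summarize the information content of a backbone
#'
#' Counts records under a fixed partition of the status/rank/hybrid
#' space: every record is exactly one of a non-hybrid accepted name
#' (species rank or infraspecific), a natural hybrid (hybrid flag set,
#' status accepted), a synonym, or an unresolved name, so that
#' `total_names = accepted_incl_infraspecific + natural_hybrids +
#' synonyms + unresolved`.
#'
#' @param table a `ref_table`.
#' @return a `backbone_summary`: list with counts `total_names`,
#'   `accepted_species` (species rank, non-hybrid), `accepted_infraspecific`,
#'   `accepted_incl_infraspecific`, `natural_hybrids`, `synonyms`,
#'   `unresolved`, `genera_accepted`, `genera_all`, `families`, `orders`,
#'   and a data.frame `unresolved_by_genus` (`genus`, `unresolved`,
#'   `total`).
#' @export
summarize_backbone <- function(table) {
  hybrid <- table$genus_hybrid | table$epithet_hybrid
  acc <- table$status == "accepted"
  syn <- table$status == "synonym"
  unr <- table$status == "unresolved"
  infra <- table$rank_marker != "none"

  n_hyb <- sum(acc & hybrid)
  n_acc_sp <- sum(acc & !hybrid & !infra)
  n_acc_infra <- sum(acc & !hybrid & infra)

  ubg <- data.frame(genus = character(0), unresolved = integer(0),
                    total = integer(0), stringsAsFactors = FALSE)
  if (nrow(table)) {
    tot <- table(table$genus)
    unr_t <- table(factor(table$genus[unr], levels = names(tot)))
    keep <- unr_t > 0
    if (any(keep)) {
      ubg <- data.frame(genus = names(tot)[keep],
                        unresolved = as.integer(unr_t[keep]),
                        total = as.integer(tot[keep]),
                        stringsAsFactors = FALSE)
      ubg <- ubg[order(-ubg$unresolved), ]
      rownames(ubg) <- NULL
    }
  }

  structure(
    list(total_names = nrow(table),
         accepted_species = n_acc_sp,
         accepted_infraspecific = n_acc_infra,
         accepted_incl_infraspecific = n_acc_sp + n_acc_infra,
         natural_hybrids = n_hyb,
         synonyms = sum(syn),
         unresolved = sum(unr),
         genera_accepted = length(unique(table$genus[acc])),
         genera_all = length(unique(table$genus[nzchar(table$genus)])),
         families = length(unique(table$family[nzchar(table$family)])),
         orders = length(unique(table$order[nzchar(table$order)])),
         unresolved_by_genus = ubg),
    class = "backbone_summary")
}

#' @export
summary.ref_table <- function(object, ...) summarize_backbone(object)

#' @export
print.backbone_summary <- function(x, ...) {
  cat("<backbone_summary>\n")
  fields <- c("total_names", "accepted_species", "accepted_infraspecific",
              "accepted_incl_infraspecific", "natural_hybrids", "synonyms",
              "unresolved", "genera_accepted", "genera_all", "families",
              "orders")
  for (f in fields) {
    cat(sprintf("  %-28s %s\n", paste0(f, ":"),
                format(x[[f]], big.mark = ",")))
  }
  if (nrow(x$unresolved_by_genus)) {
    cat("  genera with unresolved names (top 5):\n")
    top <- utils::head(x$unresolved_by_genus, 5L)
    for (i in seq_len(nrow(top))) {
      cat(sprintf("    %s: %d of %d\n",
                  top$genus[i], top$unresolved[i], top$total[i]))
    }
  }
  invisible(x)
}

#' Flatten a backbone summary into a two-column data.frame
#'
#' Used by the CSV report writers.
#' @param x a `backbone_summary`.
#' @return data.frame with columns `statistic`, `value`.
#' @export
as.data.frame.backbone_summary <- function(x, ...) {
  fields <- setdiff(names(x), "unresolved_by_genus")
  data.frame(statistic = fields,
             value = vapply(x[fields], as.integer, integer(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}
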