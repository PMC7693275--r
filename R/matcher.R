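#' Levenshtein edit distance
#'
#' Unit-cost insertions, deletions and substitutions: the number of
#' letters that may disagree between a submitted and a matched name
#' component.  Vectorized with recycling; `edit_distance(a, "")` is
#' `nchar(a)`.
#'
#' @param a,b character vectors.
#' @return integer vector of distances.
#' @export
#' @examples
#' edit_distance("warscewiczii", "warszewiczii")  # 1
edit_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  as.integer(diag(utils::adist(a, b, costs = 1L)))
}

# distance of one string against many (no diag() waste)
dist_to_many <- function(x, ys) {
  as.integer(utils::adist(x, ys, costs = 1L)[1L, ])
}

#' Matching configuration
#'
#' Per-component Levenshtein thresholds for the staged resolver.  The
#' thresholds are the user-facing "number of letters that can disagree";
#' genus/epithet/infra default to 2.  Authority comparison defaults to
#' exact equality on canonical strings (`fuzzy_authority = FALSE`); an
#' authority mismatch is reported in the score but never vetoes a match.
#'
#' @param max_distance_genus,max_distance_epithet,max_distance_infra
#'   non-negative integer thresholds.
#' @param fuzzy_authority apply edit distance to the authority as well.
#' @param return_all_ties return every tied candidate instead of one row.
#' @param batch_warn_threshold warn when a batch exceeds this many names
#'   (large batches are legal but slow).
#' @return a list of class `match_config`.
#' @export
match_config <- function(max_distance_genus = 2L, max_distance_epithet = 2L,
                         max_distance_infra = 2L, fuzzy_authority = FALSE,
                         return_all_ties = FALSE,
                         batch_warn_threshold = 5000L) {
  stopifnot(max_distance_genus >= 0L, max_distance_epithet >= 0L,
            max_distance_infra >= 0L, batch_warn_threshold > 0L)
  structure(list(max_distance_genus = as.integer(max_distance_genus),
                 max_distance_epithet = as.integer(max_distance_epithet),
                 max_distance_infra = as.integer(max_distance_infra),
                 fuzzy_authority = isTRUE(fuzzy_authority),
                 return_all_ties = isTRUE(return_all_ties),
                 batch_warn_threshold = as.integer(batch_warn_threshold)),
            class = "match_config")
}

#' Candidate genera for a submitted genus
#'
#' All distinct reference genera within `max_distance_genus` of the
#' submitted genus, each with its distance.  An exact hit preempts the
#' fuzzy candidates: when the genus occurs verbatim, only it is returned.
#'
#' @param genus normalized genus string.
#' @param table a `ref_table`.
#' @param cfg a [match_config()].
#' @return data.frame with columns `genus`, `distance` (possibly empty).
#' @export
match_genus <- function(genus, table, cfg = match_config()) {
  ug <- names(genus_index(table))
  if (!length(ug)) {
    return(data.frame(genus = character(0), distance = integer(0)))
  }
  d <- dist_to_many(genus, ug)
  keep <- if (any(d == 0L)) d == 0L else d <= cfg$max_distance_genus
  out <- data.frame(genus = ug[keep], distance = d[keep],
                    stringsAsFactors = FALSE)
  out[order(out$distance, out$genus), , drop = FALSE]
}

#' Candidate records for a submitted epithet within candidate genera
#'
#' @param genus_candidates data.frame as returned by [match_genus()].
#' @param p a `parsed_name`.
#' @param table a `ref_table`.
#' @param cfg a [match_config()].
#' @return data.frame with columns `row` (row index into `table`),
#'   `genus_distance`, `epithet_distance`.
#' @export
match_epithet <- function(genus_candidates, p, table, cfg = match_config()) {
  gi <- genus_index(table)
  rows <- unlist(gi[genus_candidates$genus], use.names = FALSE)
  empty <- data.frame(row = integer(0), genus_distance = integer(0),
                      epithet_distance = integer(0))
  if (!length(rows)) return(empty)
  gd <- genus_candidates$distance[match(table$genus[rows],
                                        genus_candidates$genus)]
  # hybrid flags must agree for an exact component match; a mismatch
  # costs one extra edit (the marker is a marker, not orthography)
  gd <- gd + (table$genus_hybrid[rows] != isTRUE(p$genus_hybrid))
  keep_g <- if (any(gd == 0L)) gd == 0L else gd <= cfg$max_distance_genus
  rows <- rows[keep_g]; gd <- gd[keep_g]
  if (!length(rows)) return(empty)
  ed <- dist_to_many(p$epithet, table$epithet[rows]) +
    (table$epithet_hybrid[rows] != isTRUE(p$epithet_hybrid))
  keep <- if (any(ed == 0L)) ed == 0L else ed <= cfg$max_distance_epithet
  data.frame(row = rows[keep], genus_distance = gd[keep],
             epithet_distance = ed[keep])
}

#' Order candidate records and detect ambiguity
#'
#' Candidates are sorted by total distance, then by status priority
#' (accepted before synonym before unresolved), then by authority
#' agreement (a candidate whose authority matched the submitted one
#' outranks one whose did not), then lexicographically on the canonical
#' name.  The result is ambiguous when two or more candidates tie on the
#' first three keys.
#'
#' @param cands data.frame with columns `row`, `total`, `auth_pref`
#'   (0 when the authority agreed, 1 otherwise).
#' @param table a `ref_table`.
#' @param cfg a [match_config()].
#' @return list `ordered` (the reordered data.frame) and `ambiguous`.
#' @export
rank_candidates <- function(cands, table, cfg = match_config()) {
  prio <- c(accepted = 0L, synonym = 1L, unresolved = 2L)
  sp <- prio[table$status[cands$row]]
  nm <- table$input_name[cands$row]
  o <- order(cands$total, sp, cands$auth_pref, nm)
  cands <- cands[o, , drop = FALSE]
  sp <- sp[o]
  key <- paste(cands$total, sp, cands$auth_pref)
  list(ordered = cands, ambiguous = nrow(cands) >= 2L && key[1L] == key[2L])
}

component_match <- function(component, submitted, matched, distance, state) {
  list(component = component, submitted = submitted, matched = matched,
       distance = as.integer(distance), state = state)
}

score_string <- function(components) {
  paste(vapply(components, function(cm) {
    s <- if (cm$state == "fuzzy") sprintf("fuzzy(%d)", cm$distance) else cm$state
    paste0(cm$component, ":", s)
  }, character(1)), collapse = "|")
}

fail_result <- function(p, failed_at) {
  stages <- c("genus", "epithet", "infra", "authority")
  supplied <- c(TRUE, TRUE, p$rank_marker != "none", nzchar(p$authority))
  comps <- lapply(seq_along(stages), function(i) {
    state <- if (!supplied[i]) "not_supplied" else "unmatched"
    sub <- switch(stages[i], genus = p$genus, epithet = p$epithet,
                  infra = p$infra_epithet, authority = p$authority)
    component_match(stages[i], sub, "", NA_integer_, state)
  })
  structure(list(record = NULL, components = comps,
                 total_distance = NA_integer_, ambiguous = FALSE,
                 score = score_string(comps), candidates = NULL),
            class = "match_result")
}

#' Resolve one parsed name against a backbone
#'
#' Staged resolution in the grammar's order: genus first, then epithet,
#' then (when genus and epithet succeeded and the parts were supplied)
#' infraspecific epithet and authority.  At the genus, epithet and
#' infraspecific stages an exact hit suppresses all fuzzy candidates and
#' failure to find any candidate within the threshold fails the whole
#' resolution.  The authority never vetoes: when supplied it either
#' matches (exactly, or within edit distance if `fuzzy_authority`) or is
#' reported as unmatched in the score.  When the winning record is a
#' synonym the result also carries its accepted name, which after
#' [flatten_synonym_chains()] is itself an accepted record.
#'
#' @param p a `parsed_name` (or a string, parsed on the fly).
#' @param table a flattened `ref_table`.
#' @param cfg a [match_config()].
#' @return a `match_result`: list with `record` (one-row data.frame or
#'   `NULL`), `components`, `total_distance`, `ambiguous`, `score` and,
#'   when `cfg$return_all_ties`, `candidates` (rows of all tied records).
#' @export
resolve_single <- function(p, table, cfg = match_config()) {
  if (is.character(p)) p <- parse_name(p)
  stopifnot(inherits(p, "parsed_name"))

  g_cand <- match_genus(p$genus, table, cfg)
  if (!nrow(g_cand)) return(fail_result(p, "genus"))
  cand <- match_epithet(g_cand, p, table, cfg)
  if (!nrow(cand)) return(fail_result(p, "epithet"))

  # infraspecific stage
  infra_supplied <- p$rank_marker != "none" && nzchar(p$infra_epithet)
  if (infra_supplied) {
    idist <- dist_to_many(p$infra_epithet, table$infra_epithet[cand$row])
    keep <- if (any(idist == 0L)) idist == 0L else idist <= cfg$max_distance_infra
    cand <- cand[keep, , drop = FALSE]
    if (!nrow(cand)) return(fail_result(p, "infra"))
    cand$infra_distance <- idist[keep]
  } else {
    # prefer species-rank records when no infraspecific part was given
    at_rank <- table$rank_marker[cand$row] == "none"
    if (any(at_rank)) cand <- cand[at_rank, , drop = FALSE]
    cand$infra_distance <- 0L
  }

  # authority stage (never vetoes)
  auth_supplied <- nzchar(p$authority)
  if (auth_supplied) {
    adist_ <- dist_to_many(p$authority, table$authority[cand$row])
    if (cfg$fuzzy_authority) {
      cand$authority_distance <- adist_
      cand$auth_matched <- TRUE
    } else {
      cand$authority_distance <- ifelse(adist_ == 0L, 0L, NA_integer_)
      cand$auth_matched <- adist_ == 0L
    }
  } else {
    cand$authority_distance <- NA_integer_
    cand$auth_matched <- NA
  }
  cand$auth_pref <- if (auth_supplied) as.integer(!(cand$auth_matched %in% TRUE))
                    else 0L

  infra_part <- if (infra_supplied) cand$infra_distance else 0L
  auth_part <- ifelse(auth_supplied & cand$auth_matched %in% TRUE,
                      cand$authority_distance, 0L)
  cand$total <- cand$genus_distance + cand$epithet_distance + infra_part +
    auth_part

  ranked <- rank_candidates(cand, table, cfg)
  best <- ranked$ordered[1L, ]
  rec <- table[best$row, , drop = FALSE]

  state_of <- function(d) if (d == 0L) "exact" else "fuzzy"
  comps <- list(
    component_match("genus", p$genus, rec$genus, best$genus_distance,
                    state_of(best$genus_distance)),
    component_match("epithet", p$epithet, rec$epithet, best$epithet_distance,
                    state_of(best$epithet_distance)),
    if (infra_supplied) {
      component_match("infra", p$infra_epithet, rec$infra_epithet,
                      best$infra_distance, state_of(best$infra_distance))
    } else {
      component_match("infra", "", rec$infra_epithet, NA_integer_,
                      "not_supplied")
    },
    if (!auth_supplied) {
      component_match("authority", "", rec$authority, NA_integer_,
                      "not_supplied")
    } else if (best$auth_matched %in% TRUE) {
      component_match("authority", p$authority, rec$authority,
                      best$authority_distance,
                      state_of(best$authority_distance))
    } else {
      component_match("authority", p$authority, rec$authority, NA_integer_,
                      "unmatched")
    })

  ties <- NULL
  if (cfg$return_all_ties) {
    key <- paste(ranked$ordered$total,
                 table$status[ranked$ordered$row],
                 ranked$ordered$auth_pref)
    ties <- table[ranked$ordered$row[key == key[1L]], , drop = FALSE]
  }
  structure(list(record = rec, components = comps,
                 total_distance = as.integer(best$total),
                 ambiguous = ranked$ambiguous,
                 score = score_string(comps), candidates = ties),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  if (is.null(x$record)) {
    cat("<match_result> unresolved [", x$score, "]\n", sep = "")
  } else {
    cat("<match_result> ", x$record$input_name,
        " (", x$record$status, ")",
        if (x$ambiguous) " AMBIGUOUS", "\n",
        "  total distance ", x$total_distance, " [", x$score, "]\n", sep = "")
  }
  invisible(x)
}
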