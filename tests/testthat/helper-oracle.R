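# Independent oracles used across the suite.

# textbook dynamic-programming Levenshtein distance (independent of
# utils::adist, which backs the package implementation)
lev_dp <- function(a, b) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  na <- length(ca); nb <- length(cb)
  if (na == 0L) return(nb)
  if (nb == 0L) return(na)
  d <- matrix(0L, na + 1L, nb + 1L)
  d[, 1L] <- 0:na
  d[1L, ] <- 0:nb
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      cost <- if (ca[i] == cb[j]) 0L else 1L
      d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L,
                               d[i + 1L, j] + 1L,
                               d[i, j] + cost)
    }
  }
  d[na + 1L, nb + 1L]
}

# naive full-scan staged matcher: same thresholds and tie rules as
# resolve_single, written straight from the stage description with no
# shared code path (per-record scans, explicit preemption at each stage).
oracle_resolve <- function(p, tab, cfg = match_config()) {
  n <- nrow(tab)
  if (!n) return(NULL)

  # stage 1: genus, on distinct genus strings first (string preemption),
  # then per-record hybrid-flag penalty with its own preemption
  ug <- unique(tab$genus)
  dg_str <- as.integer(utils::adist(p$genus, ug)[1L, ])
  keep_g_str <- if (any(dg_str == 0L)) dg_str == 0L
                else dg_str <= cfg$max_distance_genus
  if (!any(keep_g_str)) return(NULL)
  ok_genus <- ug[keep_g_str]
  rows <- which(tab$genus %in% ok_genus)
  dg <- dg_str[match(tab$genus[rows], ug)] +
    as.integer(tab$genus_hybrid[rows] != isTRUE(p$genus_hybrid))
  keep <- if (any(dg == 0L)) dg == 0L else dg <= cfg$max_distance_genus
  rows <- rows[keep]; dg <- dg[keep]
  if (!length(rows)) return(NULL)

  # stage 2: epithet within surviving rows
  de <- as.integer(utils::adist(p$epithet, tab$epithet[rows])[1L, ]) +
    as.integer(tab$epithet_hybrid[rows] != isTRUE(p$epithet_hybrid))
  keep <- if (any(de == 0L)) de == 0L else de <= cfg$max_distance_epithet
  rows <- rows[keep]; dg <- dg[keep]; de <- de[keep]
  if (!length(rows)) return(NULL)

  # stage 3: infraspecific epithet
  infra_supplied <- p$rank_marker != "none" && nzchar(p$infra_epithet)
  if (infra_supplied) {
    di <- as.integer(utils::adist(p$infra_epithet,
                                  tab$infra_epithet[rows])[1L, ])
    keep <- if (any(di == 0L)) di == 0L else di <= cfg$max_distance_infra
    rows <- rows[keep]; dg <- dg[keep]; de <- de[keep]; di <- di[keep]
    if (!length(rows)) return(NULL)
  } else {
    sp_rank <- tab$rank_marker[rows] == "none"
    if (any(sp_rank)) {
      rows <- rows[sp_rank]; dg <- dg[sp_rank]; de <- de[sp_rank]
    }
    di <- rep(0L, length(rows))
  }

  # stage 4: authority (never vetoes)
  auth_supplied <- nzchar(p$authority)
  if (auth_supplied) {
    da_raw <- as.integer(utils::adist(p$authority, tab$authority[rows])[1L, ])
    if (cfg$fuzzy_authority) {
      da <- da_raw
      auth_pref <- rep(0L, length(rows))
    } else {
      da <- ifelse(da_raw == 0L, 0L, 0L)  # unmatched contributes nothing
      auth_pref <- as.integer(da_raw != 0L)
    }
  } else {
    da <- rep(0L, length(rows))
    auth_pref <- rep(0L, length(rows))
  }

  total <- dg + de + (if (infra_supplied) di else 0L) + da
  prio <- c(accepted = 0L, synonym = 1L, unresolved = 2L)[tab$status[rows]]
  o <- order(total, prio, auth_pref, tab$input_name[rows])
  best <- o[1L]
  list(row = rows[best], total = total[best],
       ambiguous = length(o) >= 2L &&
         total[o[1L]] == total[o[2L]] && prio[o[1L]] == prio[o[2L]] &&
         auth_pref[o[1L]] == auth_pref[o[2L]])
}

# convenience: a small flattened fixture shared by matcher tests
small_fixture <- function(seed = 7L, ...) {
  tab <- generate_reference(fixture_spec(seed = seed, ...))
  suppressWarnings(flatten_synonym_chains(tab))
}

# hand-built backbone from a compact description: a data.frame with
# columns name/status/accepted (full name strings)
toy_table <- function(df) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  n <- length(df$name)
  out <- data.frame(Input_Taxon = df$name, Status = df$status,
                    Output_Taxon = df$accepted,
                    Family = rep("Testaceae", n),
                    Order = rep("Testales", n))
  utils::write.table(out, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  load_reference(tmp)
}
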