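#' Specification for a synthetic backbone fixture
#'
#' The defaults emulate the composition of the published vascular-plant
#' backbone: roughly 64% of all names are synonyms and 5% unresolved,
#' about 12% of accepted names are infraspecific, and natural hybrids
#' make up about 2% of accepted species.  Chain and homonym parameters
#' exist to exercise flattening and ambiguity handling and default to
#' modest non-zero values.
#'
#' @param n_genera number of genera.
#' @param species_per_genus length-2 integer range of accepted species
#'   per genus (sampled uniformly).
#' @param synonym_fraction target fraction of the final table that is
#'   synonyms.
#' @param chain_fraction fraction of synonyms whose cross-reference
#'   points at another synonym before flattening (chain links).
#' @param infraspecific_fraction accepted infraspecific records per
#'   accepted species.
#' @param hybrid_fraction accepted natural hybrids per accepted species.
#' @param unresolved_fraction target fraction of the final table that is
#'   unresolved.
#' @param homonym_pairs number of accepted homonym pairs (same genus and
#'   epithet, different authority).
#' @param defects list with counts `dangling`, `cycles`, `duplicates` of
#'   injected defects.
#' @param seed RNG seed; the generator is a pure function of the spec.
#' @return a list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genera = 25L, species_per_genus = c(2L, 8L),
                         synonym_fraction = 0.64, chain_fraction = 0.10,
                         infraspecific_fraction = 0.12,
                         hybrid_fraction = 0.02,
                         unresolved_fraction = 0.05,
                         homonym_pairs = 2L,
                         defects = list(dangling = 0L, cycles = 0L,
                                        duplicates = 0L),
                         seed = 1L) {
  fr <- c(synonym_fraction, chain_fraction, infraspecific_fraction,
          hybrid_fraction, unresolved_fraction)
  stopifnot(all(fr >= 0), all(fr <= 1),
            synonym_fraction + unresolved_fraction < 1,
            n_genera >= 1L, length(species_per_genus) == 2L,
            species_per_genus[1L] >= 1L,
            species_per_genus[2L] >= species_per_genus[1L],
            homonym_pairs >= 0L)
  defects <- utils::modifyList(list(dangling = 0L, cycles = 0L,
                                    duplicates = 0L), defects)
  stopifnot(all(unlist(defects) >= 0L))
  structure(list(n_genera = as.integer(n_genera),
                 species_per_genus = as.integer(species_per_genus),
                 synonym_fraction = synonym_fraction,
                 chain_fraction = chain_fraction,
                 infraspecific_fraction = infraspecific_fraction,
                 hybrid_fraction = hybrid_fraction,
                 unresolved_fraction = unresolved_fraction,
                 homonym_pairs = as.integer(homonym_pairs),
                 defects = defects, seed = as.integer(seed)),
            class = "fixture_spec")
}

# --- pseudo-Latin word machinery -------------------------------------------

.onsets <- c("b", "c", "d", "f", "g", "h", "l", "m", "n", "p", "r", "s",
             "t", "v", "br", "cr", "dr", "gl", "pl", "st", "th", "ch")
.vowels <- c("a", "e", "i", "o", "u", "ae", "ia", "io")
.genus_suffix <- c("a", "us", "um", "ia", "ella", "opsis", "anthus", "aria")
.epithet_suffix <- c("a", "um", "us", "ensis", "iana", "ifolia", "oides",
                     "icola", "ii", "atum")

# sample from a vector even when it has length 1
resample <- function(x, size = 1L, ...) x[sample.int(length(x), size, ...)]

rand_word <- function(n_syl = 2L) {
  paste0(paste0(sample(.onsets, n_syl, replace = TRUE),
                sample(.vowels, n_syl, replace = TRUE), collapse = ""),
         collapse = "")
}

rand_unique_words <- function(n, suffixes, capitalize = FALSE,
                              hyphen_rate = 0, exclude = character(0)) {
  out <- character(0)
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    if (guard > 50L * n + 100L) stop("name space exhausted", call. = FALSE)
    w <- paste0(rand_word(sample(1:2, 1L)), sample(suffixes, 1L))
    if (hyphen_rate > 0 && runif(1) < hyphen_rate) {
      w <- paste0(w, "-", rand_word(1L))
    }
    if (capitalize) {
      w <- paste0(toupper(substr(w, 1, 1)), substr(w, 2, nchar(w)))
    }
    if (!w %in% out && !w %in% exclude) out <- c(out, w)
  }
  out
}

rand_surname <- function() {
  paste0(toupper(substr(rand_word(1L), 1, 1)),
         substr(rand_word(sample(1:2, 1L)), 2, 6), ".")
}

rand_author_unit <- function() {
  n_init <- sample(0:2, 1L, prob = c(0.4, 0.4, 0.2))
  inits <- if (n_init > 0) {
    paste0(paste0(sample(LETTERS, n_init, replace = TRUE), ".",
                  collapse = ""), collapse = "")
  } else ""
  paste0(inits, rand_surname())
}

rand_authority <- function() {
  r <- runif(1)
  if (r < 0.65) rand_author_unit()
  else if (r < 0.90) paste(rand_author_unit(), "&", rand_author_unit())
  else paste(rand_author_unit(), "& al.")
}

# --- generator --------------------------------------------------------------

#' Generate a synthetic reference backbone with known ground truth
#'
#' Builds a deterministic, pronounceable pseudo-Latin backbone table
#' according to a [fixture_spec()]: accepted species, accepted
#' infraspecific names, natural hybrids, homonym pairs, synonyms (a
#' configurable share of which form pre-flattening chains of length 2-5),
#' unresolved names, and injected defects (dangling synonym targets,
#' two-node cycles, duplicated rows).  Ground truth about every injection
#' is recorded in the `"truth"` attribute.
#'
#' @param spec a [fixture_spec()].
#' @return a `ref_table` with attribute `truth`: a list with elements
#'   `spec`, `counts` (the spec-implied summary counts), `flatten_map`
#'   (data.frame `synonym` / `terminal_accepted` for all intact
#'   synonyms), `chains` (character paths), `homonyms`, and `defects`.
#' @export
#' @examples
#' tab <- generate_reference(fixture_spec(n_genera = 3, seed = 42))
#' summary(tab)
generate_reference <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$seed)

  genera <- rand_unique_words(spec$n_genera, .genus_suffix, capitalize = TRUE)
  n_fam <- max(1L, ceiling(spec$n_genera / 3))
  fams <- paste0(rand_unique_words(n_fam, "ace"), "ae")
  fams <- paste0(toupper(substr(fams, 1, 1)), substr(fams, 2, nchar(fams)))
  n_ord <- max(1L, ceiling(n_fam / 2))
  ords <- rand_unique_words(n_ord, "ales", capitalize = TRUE)
  fam_of_genus <- sample(fams, spec$n_genera, replace = TRUE)
  ord_of_fam <- setNames(sample(ords, n_fam, replace = TRUE), fams)

  new_rec <- function(genus, epithet, status, accepted = "", rank = "none",
                      infra = "", authority = rand_authority(),
                      g_hyb = FALSE, e_hyb = FALSE) {
    p <- list(genus = genus, genus_hybrid = g_hyb, epithet = epithet,
              epithet_hybrid = e_hyb, rank_marker = rank,
              infra_epithet = infra, authority = authority)
    fam <- fam_of_genus[match(genus, genera)]
    if (is.na(fam)) fam <- sample(fams, 1L)
    data.frame(input_name = format_name(p), status = status,
               accepted_name = accepted, family = fam,
               order = unname(ord_of_fam[fam]), tpl_comparison = "",
               genus = genus, genus_hybrid = g_hyb, epithet = epithet,
               epithet_hybrid = e_hyb, rank_marker = rank,
               infra_epithet = infra, authority = authority,
               parse_note = "", stringsAsFactors = FALSE)
  }

  # accepted species
  recs <- list()
  used_binom <- character(0)
  word_pool <- character(0)   # every epithet-like word ever issued
  for (g in genera) {
    k <- resample(seq(spec$species_per_genus[1L],
                      spec$species_per_genus[2L]))
    eps <- rand_unique_words(k, .epithet_suffix, hyphen_rate = 0.03,
                             exclude = word_pool)
    word_pool <- c(word_pool, eps)
    for (e in eps) {
      if (paste(g, e) %in% used_binom) next
      used_binom <- c(used_binom, paste(g, e))
      recs[[length(recs) + 1L]] <- new_rec(g, e, "accepted")
    }
  }
  sp_rows <- seq_along(recs)
  n_sp <- length(sp_rows)

  # accepted infraspecific names attached to existing species
  n_infra <- round(spec$infraspecific_fraction * n_sp)
  if (n_infra > 0) {
    hosts <- resample(sp_rows, n_infra)
    infra_words <- rand_unique_words(n_infra, .epithet_suffix,
                                     exclude = word_pool)
    word_pool <- c(word_pool, infra_words)
    for (i in seq_len(n_infra)) {
      h <- recs[[hosts[i]]]
      recs[[length(recs) + 1L]] <-
        new_rec(h$genus, h$epithet, "accepted",
                rank = sample(RANK_MARKERS, 1L), infra = infra_words[i])
    }
  }

  # natural hybrids (species rank, hybrid flag on the epithet or genus)
  n_hyb <- round(spec$hybrid_fraction * n_sp)
  if (n_hyb > 0) {
    hyb_eps <- rand_unique_words(n_hyb, .epithet_suffix,
                                 exclude = word_pool)
    word_pool <- c(word_pool, hyb_eps)
    for (i in seq_len(n_hyb)) {
      g_hyb <- runif(1) < 0.2
      recs[[length(recs) + 1L]] <-
        new_rec(sample(genera, 1L), hyb_eps[i], "accepted",
                g_hyb = g_hyb, e_hyb = !g_hyb)
    }
  }

  # accepted homonym pairs: same binomial, different authority
  if (spec$homonym_pairs > n_sp) {
    stop("infeasible spec: homonym_pairs exceeds accepted species",
         call. = FALSE)
  }
  homonyms <- character(0)
  if (spec$homonym_pairs > 0) {
    hosts <- resample(sp_rows, spec$homonym_pairs)
    for (h in hosts) {
      r <- recs[[h]]
      repeat {
        au <- rand_authority()
        if (au != r$authority) break
      }
      recs[[length(recs) + 1L]] <-
        new_rec(r$genus, r$epithet, "accepted", authority = au)
      homonyms <- c(homonyms, paste(r$genus, r$epithet))
    }
  }

  acc_names <- vapply(recs, `[[`, character(1), "input_name")
  for (i in seq_along(recs)) recs[[i]]$accepted_name <- acc_names[i]
  n_acc <- length(recs)

  # synonyms and unresolved, sized so their share of the final table
  # approximates the spec fractions
  acc_frac <- 1 - spec$synonym_fraction - spec$unresolved_fraction
  n_syn <- round(n_acc * spec$synonym_fraction / acc_frac)
  n_unres <- round(n_acc * spec$unresolved_fraction / acc_frac)

  extra_words <- rand_unique_words(n_syn + n_unres, .epithet_suffix,
                                   hyphen_rate = 0.02, exclude = word_pool)
  word_pool <- c(word_pool, extra_words)
  make_extra <- function(i, status, accepted) {
    repeat {
      g <- sample(genera, 1L)
      if (!paste(g, extra_words[i]) %in% used_binom) break
      extra_words[i] <<- rand_unique_words(1L, .epithet_suffix,
                                           exclude = word_pool)
    }
    used_binom <<- c(used_binom, paste(g, extra_words[i]))
    new_rec(g, extra_words[i], status, accepted = accepted)
  }

  syn_start <- length(recs) + 1L
  for (i in seq_len(n_syn)) {
    recs[[length(recs) + 1L]] <-
      make_extra(i, "synonym", sample(acc_names, 1L))
  }
  syn_rows <- seq(syn_start, length.out = n_syn)

  # rewire a share of synonyms into chains of length 2-5 (pre-flattening
  # the cross-reference points at another synonym)
  chains <- character(0)
  n_links <- round(spec$chain_fraction * n_syn)
  link_budget <- n_links
  avail <- syn_rows
  while (link_budget > 0 && length(avail) >= 2L) {
    L <- min(sample(2:5, 1L), link_budget + 1L, length(avail))
    members <- resample(avail, L)
    avail <- setdiff(avail, members)
    for (j in seq_len(L - 1L)) {
      recs[[members[j]]]$accepted_name <- recs[[members[j + 1L]]]$input_name
    }
    # terminal member keeps its accepted target
    chains <- c(chains, paste(vapply(recs[members], `[[`, character(1),
                                     "input_name"), collapse = " -> "))
    link_budget <- link_budget - (L - 1L)
  }
  n_chain_links <- n_links - link_budget

  for (i in seq_len(n_unres)) {
    recs[[length(recs) + 1L]] <- make_extra(n_syn + i, "unresolved", "")
  }

  # --- injected defects ----------------------------------------------------
  plain_syn <- setdiff(syn_rows,
                       unlist(lapply(strsplit(chains, " -> "), function(x) {
                         which(vapply(recs, `[[`, character(1),
                                      "input_name") %in% x)
                       })))
  dangling_names <- character(0)
  if (spec$defects$dangling > 0) {
    if (length(plain_syn) < spec$defects$dangling) {
      stop("infeasible spec: not enough plain synonyms for dangling defects",
           call. = FALSE)
    }
    victims <- resample(plain_syn, spec$defects$dangling)
    for (k in seq_along(victims)) {
      recs[[victims[k]]]$accepted_name <-
        sprintf("Phantomus absentis%d Nob.", k)
      dangling_names <- c(dangling_names, recs[[victims[k]]]$input_name)
    }
  }

  cycle_names <- list()
  if (spec$defects$cycles > 0) {
    cyc_words <- rand_unique_words(2L * spec$defects$cycles, .epithet_suffix,
                                   exclude = word_pool)
    for (k in seq_len(spec$defects$cycles)) {
      g <- sample(genera, 1L)
      e1 <- cyc_words[2L * k - 1L]; e2 <- cyc_words[2L * k]
      a <- new_rec(g, e1, "synonym")
      b <- new_rec(g, e2, "synonym")
      a$accepted_name <- b$input_name
      b$accepted_name <- a$input_name
      recs[[length(recs) + 1L]] <- a
      recs[[length(recs) + 1L]] <- b
      cycle_names[[k]] <- sort(c(a$input_name, b$input_name))
    }
  }

  # duplicates clone clean accepted species rows so that the summary
  # bookkeeping stays exact and chain counting is unaffected
  duplicate_names <- character(0)
  if (spec$defects$duplicates > 0) {
    clean_acc <- which(vapply(recs, function(r) {
      r$status == "accepted" && r$rank_marker == "none" &&
        !r$genus_hybrid && !r$epithet_hybrid
    }, logical(1)))
    victims <- resample(clean_acc, spec$defects$duplicates)
    for (v in victims) {
      recs[[length(recs) + 1L]] <- recs[[v]]
      duplicate_names <- c(duplicate_names, recs[[v]]$input_name)
    }
  }

  tab <- do.call(rbind, recs)
  tab <- tab[sample(nrow(tab)), , drop = FALSE]

  # ground truth: spec-implied summary counts and the follow-the-pointers
  # closure for every intact synonym
  nm <- tab$input_name
  status <- tab$status
  term <- function(i, seen = integer(0)) {
    j <- match(tab$accepted_name[i], nm)
    if (is.na(j) || j %in% seen) return(NA_character_)
    if (status[j] == "accepted") return(nm[j])
    term(j, c(seen, i))
  }
  syn_idx <- which(status == "synonym" &
                   !nm %in% unlist(cycle_names) &
                   !nm %in% dangling_names &
                   !duplicated(nm))
  flatten_map <- data.frame(
    synonym = nm[syn_idx],
    terminal_accepted = vapply(syn_idx, term, character(1)),
    stringsAsFactors = FALSE)

  counts <- list(
    total_names = nrow(tab),
    accepted_species = n_sp + spec$homonym_pairs + spec$defects$duplicates,
    accepted_infraspecific = n_infra,
    natural_hybrids = n_hyb,
    synonyms = n_syn + 2L * spec$defects$cycles,
    unresolved = n_unres,
    chain_links = n_chain_links,
    genera_all = length(unique(tab$genus)))

  as_ref_table(tab,
               provenance = list(path = NA_character_,
                                 version = sprintf("fixture-seed%d", spec$seed)),
               truth = list(spec = spec, counts = counts,
                            flatten_map = flatten_map, chains = chains,
                            homonyms = homonyms,
                            defects = list(dangling = dangling_names,
                                           cycles = cycle_names,
                                           duplicates = duplicate_names)))
}
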