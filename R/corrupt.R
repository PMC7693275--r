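#' Corrupt one component of a reference name by k random edits
#'
#' Applies exactly `k` random single-character edits (substitution,
#' insertion or deletion over `a`-`z`) to the chosen component of a name
#' drawn from a reference table, verifies that the Levenshtein distance
#' between the true and the corrupted component equals `k`, and decides
#' whether the corrupted query still has a uniqueness margin: `margin_ok`
#' is `TRUE` when no other record could match it as well as the source
#' record does, i.e. when
#' * the corrupted component does not collide exactly with a different
#'   component value visible at its matching stage, and
#' * no record other than the source agrees with the query on all
#'   remaining name components while lying within `k` edits of the
#'   corrupted component (this also rules out homonym partners).
#'
#' Under those conditions, a staged resolver with thresholds >= `k`
#' must recover the source record.
#'
#' @param name full canonical name string present in `table`.
#' @param component one of `"genus"`, `"epithet"`, `"infra"`.
#' @param k number of edits (`0` returns the name unchanged); must not
#'   exceed the component length.
#' @param table the `ref_table` the name comes from.
#' @param seed RNG seed.
#' @return a `corruption_record`: list with `true_name`,
#'   `corrupted_name`, `component`, `n_edits`, `margin_ok`.
#' @export
corrupt_query <- function(name, component = c("genus", "epithet", "infra"),
                          k = 1L, table, seed = 1L) {
  component <- match.arg(component)
  stopifnot(k >= 0L)
  src <- which(table$input_name == name)
  if (!length(src)) stop("name not found in table: ", name, call. = FALSE)
  src <- src[1L]
  p <- list(genus = table$genus[src], genus_hybrid = table$genus_hybrid[src],
            epithet = table$epithet[src],
            epithet_hybrid = table$epithet_hybrid[src],
            rank_marker = table$rank_marker[src],
            infra_epithet = table$infra_epithet[src],
            authority = table$authority[src])
  true_val <- switch(component, genus = p$genus, epithet = p$epithet,
                     infra = p$infra_epithet)
  if (!nzchar(true_val)) {
    stop("component '", component, "' not present in ", name, call. = FALSE)
  }
  if (k > nchar(true_val)) {
    stop("k = ", k, " exceeds the length of the ", component, call. = FALSE)
  }

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)

  corrupted <- corrupt_word(true_val, k,
                            keep_first = component == "genus")
  new_p <- p
  if (component == "genus") new_p$genus <- corrupted
  if (component == "epithet") new_p$epithet <- corrupted
  if (component == "infra") new_p$infra_epithet <- corrupted

  structure(
    list(true_name = name,
         corrupted_name = format_name(new_p),
         component = component,
         n_edits = as.integer(k),
         margin_ok = margin_ok(table, src, p, component, corrupted, k)),
    class = "corruption_record")
}

# apply exactly k random edits so that the final edit distance is k
corrupt_word <- function(word, k, keep_first = FALSE, max_tries = 200L) {
  if (k == 0L) return(word)
  alphabet <- letters
  lo <- if (keep_first) 2L else 1L
  if (keep_first && nchar(word) - 1L < k) {
    stop("k exceeds the editable length of the word", call. = FALSE)
  }
  for (try in seq_len(max_tries)) {
    chars <- strsplit(word, "")[[1L]]
    for (e in seq_len(k)) {
      op <- sample(c("sub", "ins", "del"), 1L, prob = c(0.6, 0.2, 0.2))
      n <- length(chars)
      if (op == "del" && n > lo) {
        i <- sample(lo:n, 1L)
        chars <- chars[-i]
      } else if (op == "ins") {
        i <- sample(lo:(n + 1L), 1L)
        chars <- append(chars, sample(alphabet, 1L), after = i - 1L)
      } else {
        i <- sample(lo:n, 1L)
        repeat {
          ch <- sample(alphabet, 1L)
          if (ch != chars[i]) break
        }
        chars[i] <- ch
      }
    }
    out <- paste(chars, collapse = "")
    if (edit_distance(out, word) == k) return(out)
  }
  stop("could not construct a corruption at exact distance ", k,
       call. = FALSE)
}

# uniqueness margin of a corrupted component against the whole table
margin_ok <- function(table, src, p, component, corrupted, k) {
  comp_col <- switch(component, genus = "genus", epithet = "epithet",
                     infra = "infra_epithet")
  true_val <- switch(component, genus = p$genus, epithet = p$epithet,
                     infra = p$infra_epithet)

  # stage scope: which records are visible when the corrupted component
  # is being matched (earlier components are exact)
  scope <- switch(component,
    genus = rep(TRUE, nrow(table)),
    epithet = table$genus == p$genus,
    infra = table$genus == p$genus & table$epithet == p$epithet)

  vals <- table[[comp_col]][scope]
  if (any(vals == corrupted & vals != true_val)) return(FALSE)

  # competitor: another record matching the remaining supplied components
  # exactly, within k of the corrupted component
  others <- setdiff(seq_len(nrow(table)), src)
  same_rest <- switch(component,
    genus = table$epithet[others] == p$epithet &
            table$rank_marker[others] == p$rank_marker &
            table$infra_epithet[others] == p$infra_epithet,
    epithet = table$genus[others] == p$genus &
              table$rank_marker[others] == p$rank_marker &
              table$infra_epithet[others] == p$infra_epithet,
    infra = table$genus[others] == p$genus &
            table$epithet[others] == p$epithet)
  cand <- others[same_rest]
  if (!length(cand)) return(TRUE)
  d <- dist_to_many(corrupted, table[[comp_col]][cand])
  !any(d <= k)
}

#' Decorate a name with diacritics that transliterate back to themselves
#'
#' Sprinkles accent variants (which [normalize_orthography()] maps back
#' to the plain base letter) over the genus/epithet letters of a name, to
#' exercise the transliteration path without changing the canonical form.
#'
#' @param x character vector of canonical names.
#' @param rate per-letter decoration probability.
#' @param seed RNG seed.
#' @return character vector of decorated names.
#' @export
add_diacritics <- function(x, rate = 0.15, seed = 1L) {
  variants <- list(a = c("\u00e1", "\u00e0"), e = c("\u00e9", "\u00eb"),
                   i = c("\u00ed", "\u00ef"), o = c("\u00f3", "\u00f4"),
                   u = c("\u00fa", "\u00f9"), n = "\u00f1",
                   c = "\u00e7", y = "\u00fd")
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  vapply(x, function(nm) {
    toks <- strsplit(nm, " ", fixed = TRUE)[[1L]]
    for (t in seq_len(min(2L, length(toks)))) {
      chars <- strsplit(toks[t], "")[[1L]]
      for (i in seq_along(chars)) {
        v <- variants[[chars[i]]]
        if (!is.null(v) && runif(1) < rate) chars[i] <- sample(v, 1L)
      }
      toks[t] <- paste(chars, collapse = "")
    }
    paste(toks, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}
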