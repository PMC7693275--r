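#' Options for comparing two backbones
#'
#' @param max_orthography_distance names absent from the other table but
#'   within this Levenshtein distance (1 up to the maximum, computed on
#'   the concatenated genus + epithet with identical authority and
#'   infraspecific part) are classified as orthographic variants.
#' @return list of class `diff_options`.
#' @export
diff_options <- function(max_orthography_distance = 3L) {
  stopifnot(max_orthography_distance >= 1L)
  structure(list(max_orthography_distance = as.integer(max_orthography_distance)),
            class = "diff_options")
}

#' Compare two backbone tables
#'
#' Name presence is decided on the full canonical name string: every name
#' in the union of the two tables is exactly one of `identical` (present
#' in both), `only_in_a`, or `only_in_b`.  Status contrasts
#' (resolved/unresolved, accepted/synonym and synonym-target changes) are
#' computed over the shared names; author and orthography differences are
#' sought between the non-shared names (same genus+epithet+infraspecific
#' part with a different authority -> `different_author`; small edit
#' distance on genus+epithet with the same authority ->
#' `different_orthography`).
#'
#' @param a,b flattened `ref_table`s.
#' @param compare a [diff_options()].
#' @return a `backbone_diff`: counts plus per-category name lists.
#' @export
diff_backbones <- function(a, b, compare = diff_options()) {
  na <- a$input_name; nb <- b$input_name
  shared <- intersect(na, nb)
  only_a <- setdiff(na, nb)
  only_b <- setdiff(nb, na)

  ia <- match(shared, na); ib <- match(shared, nb)
  sa <- a$status[ia]; sb <- b$status[ib]

  res_a_unres_b <- shared[sa != "unresolved" & sb == "unresolved"]
  acc_a_syn_b <- shared[sa == "accepted" & sb == "synonym"]
  syn_a_acc_b <- shared[sa == "synonym" & sb == "accepted"]
  diff_syn <- shared[sa == "synonym" & sb == "synonym" &
                     a$accepted_name[ia] != b$accepted_name[ib]]

  # author / orthography variants among the non-shared names
  key_a <- match(only_a, na); key_b <- match(only_b, nb)
  binom_a <- paste(a$genus[key_a], a$epithet[key_a])
  binom_b <- paste(b$genus[key_b], b$epithet[key_b])
  infra_a <- paste(a$rank_marker[key_a], a$infra_epithet[key_a])
  infra_b <- paste(b$rank_marker[key_b], b$infra_epithet[key_b])
  auth_a <- a$authority[key_a]; auth_b <- b$authority[key_b]

  diff_author <- character(0)
  diff_orth <- character(0)
  if (length(only_a) && length(only_b)) {
    for (i in seq_along(only_a)) {
      same_name <- binom_b == binom_a[i] & infra_b == infra_a[i]
      if (any(same_name & auth_b != auth_a[i])) {
        diff_author <- c(diff_author, only_a[i])
        next
      }
      cand <- which(auth_b == auth_a[i] & infra_b == infra_a[i])
      if (length(cand)) {
        d <- utils::adist(binom_a[i], binom_b[cand])
        if (any(d >= 1L & d <= compare$max_orthography_distance)) {
          diff_orth <- c(diff_orth, only_a[i])
        }
      }
    }
  }

  structure(
    list(identical = length(shared),
         only_in_a = length(only_a),
         only_in_b = length(only_b),
         different_author = length(diff_author),
         different_synonym = length(diff_syn),
         different_orthography = length(diff_orth),
         resolved_in_a_unresolved_in_b = length(res_a_unres_b),
         accepted_in_a_synonym_in_b = length(acc_a_syn_b),
         synonym_in_a_accepted_in_b = length(syn_a_acc_b),
         names = list(identical = shared, only_in_a = only_a,
                      only_in_b = only_b, different_author = diff_author,
                      different_synonym = diff_syn,
                      different_orthography = diff_orth,
                      resolved_in_a_unresolved_in_b = res_a_unres_b,
                      accepted_in_a_synonym_in_b = acc_a_syn_b,
                      synonym_in_a_accepted_in_b = syn_a_acc_b)),
    class = "backbone_diff")
}

#' @export
print.backbone_diff <- function(x, ...) {
  cat("<backbone_diff>\n")
  for (f in setdiff(names(x), "names")) {
    cat(sprintf("  %-32s %d\n", paste0(f, ":"), x[[f]]))
  }
  invisible(x)
}

#' @rdname diff_backbones
#' @param x a `backbone_diff`.
#' @param ... unused.
#' @export
as.data.frame.backbone_diff <- function(x, ...) {
  fields <- setdiff(names(x), "names")
  data.frame(category = fields,
             count = vapply(x[fields], as.integer, integer(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}
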