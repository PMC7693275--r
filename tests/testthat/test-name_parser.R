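test_that("standardize_input rewrites hybrid annotations and whitespace", {
  expect_equal(standardize_input("x_Spartocytisus filipes Webb & Berthel."),
               "Spartocytisus_x filipes Webb & Berthel.")
  expect_equal(standardize_input("x Spartocytisus filipes"),
               "Spartocytisus_x filipes")
  expect_equal(standardize_input("Lycopodium x habereri House"),
               "Lycopodium habereri_x House")
  expect_equal(standardize_input("Lycopodium x_habereri House"),
               "Lycopodium habereri_x House")
  expect_equal(standardize_input("Hibiscus   vitifolius"),
               "Hibiscus vitifolius")
  # already canonical names are untouched
  expect_equal(standardize_input("Spartocytisus_x filipes"),
               "Spartocytisus_x filipes")
  expect_error(standardize_input("Crassocephalum × picridifolium"),
               "U\\+00D7")
})

test_that("parse_name decomposes the documented grammar", {
  p <- parse_name("Draba mollissima var. kusnezowii N.Busch")
  expect_equal(p$genus, "Draba")
  expect_equal(p$epithet, "mollissima")
  expect_equal(p$rank_marker, "var.")
  expect_equal(p$infra_epithet, "kusnezowii")
  expect_equal(p$authority, "N.Busch")

  p <- parse_name("Hibiscus rosa-sinensis L.")
  expect_equal(p$epithet, "rosa-sinensis")
  expect_equal(p$authority, "L.")

  p <- parse_name("Hibiscus vitifolius")
  expect_equal(p$genus, "Hibiscus")
  expect_equal(p$epithet, "vitifolius")
  expect_equal(p$authority, "")

  p <- parse_name("Spartocytisus_x filipes Webb & Berthel.")
  expect_true(p$genus_hybrid)
  expect_false(p$epithet_hybrid)
  expect_equal(p$authority, "Webb & Berthel.")

  expect_error(parse_name("Draba"), "genus name and the epithet")
  expect_error(parse_name(""), "genus name and the epithet")
})

test_that("rank markers are recognised only at token position 3 of 4+", {
  # third word not a rank marker: everything after the epithet is authority
  p <- parse_name("Aus bus subspecies cus")
  expect_equal(p$rank_marker, "none")
  expect_match(p$authority, "^subspecies")
  # rank marker is matched case-insensitively
  p <- parse_name("Aus bus VAR. cus L.")
  expect_equal(p$rank_marker, "var.")
  expect_equal(p$infra_epithet, "cus")
  # a 3-token name whose third token is a rank marker cannot carry an
  # infraspecific epithet; the dangling marker is dropped with a warning
  p <- parse_name("Aus bus var.")
  expect_equal(p$rank_marker, "none")
  expect_equal(p$authority, "")
  expect_true(any(grepl("dangling rank marker", p$warnings)))
  # the authority never starts with a rank token
  for (rk in RANK_MARKERS) {
    q <- parse_name(paste("Aus bus", rk, "cus", "Sm."))
    first_auth_word <- strsplit(q$authority, " ")[[1L]][1L]
    expect_false(isTRUE(first_auth_word %in% RANK_MARKERS))
  }
})

test_that("authority normalization reproduces the documented forms", {
  expect_equal(normalize_authority("C. F. W. Meissn."), "C.F.W.Meissn.")
  expect_equal(normalize_authority("C.F. W. Meissn."), "C.F.W.Meissn.")
  expect_equal(normalize_authority("C. F.W. Meissn."), "C.F.W.Meissn.")
  expect_equal(normalize_authority("C. F. W.Meissn."), "C.F.W.Meissn.")
  expect_equal(normalize_authority("Balf. f."), "Balf.f.")
  expect_equal(normalize_authority(
    "P.P.Ferrer, A.Navarro, P.Pérez, R.Roselló, Rosselló, M.Rosato & E.Laguna"),
    "P.P.Ferrer & al.")
  expect_equal(normalize_authority("Webb & Berthel."), "Webb & Berthel.")
  expect_equal(normalize_authority("Balf.f. & Kingdon-Ward"),
               "Balf.f. & Kingdon-Ward")
  expect_equal(normalize_authority("Benth. ex Hook. f."), "Benth. ex Hook.f.")
  expect_equal(normalize_authority(""), "")
})

test_that("authority and orthography normalization are idempotent", {
  raw <- c("C. F. W. Meissn.", "Balf. f.", "A.Gray & B. Sm.",
           "One, Two & Three", "L.", "Benth. ex Hook. f.",
           "Kingdon-Ward", "X. Y. Zed. & Q. R. Ess.")
  once <- normalize_authority(raw)
  expect_equal(normalize_authority(once), once)

  words <- c("Isoëtes", "Köberlinia", "Draba", "rosa-sinensis",
             "Übela", "señorita", "français")
  once <- as.character(normalize_orthography(words))
  expect_equal(as.character(normalize_orthography(once)), once)
})

test_that("orthography transliteration matches the documented table", {
  expect_equal(as.character(normalize_orthography("Isoëtes")), "Isoetes")
  expect_equal(as.character(normalize_orthography("Köberlinia")),
               "Koeberlinia")
  expect_equal(as.character(normalize_orthography("Draba")), "Draba")
  # residual non-alphabetic characters are dropped and flagged
  res <- normalize_orthography("abc9d")
  expect_equal(as.character(res), "abcd")
  expect_true(attr(res, "flagged")[1L])
})

test_that("format_name is the inverse of parse_name", {
  canon <- c("Draba mollissima var. kusnezowii N.Busch",
             "Hibiscus rosa-sinensis L.",
             "Spartocytisus_x filipes Webb & Berthel.",
             "Lycopodium habereri_x House",
             "Hibiscus vitifolius")
  for (s in canon) {
    expect_equal(format_name(parse_name(s)), s)
  }
  # no trailing space when the authority is empty
  expect_false(grepl(" $", format_name(parse_name("Aus bus"))))

  # parse(format(p)) recovers generator-produced parsed names
  tab <- generate_reference(fixture_spec(n_genera = 6, seed = 11))
  for (i in seq_len(nrow(tab))) {
    p <- parse_name(tab$input_name[i])
    expect_equal(p$genus, tab$genus[i])
    expect_equal(p$epithet, tab$epithet[i])
    expect_equal(p$rank_marker, tab$rank_marker[i])
    expect_equal(p$infra_epithet, tab$infra_epithet[i])
    expect_equal(p$authority, tab$authority[i])
    expect_equal(format_name(p), tab$input_name[i])
  }
})

test_that("diacritic-decorated queries parse to their canonical form", {
  tab <- generate_reference(fixture_spec(n_genera = 4, seed = 3))
  nms <- utils::head(tab$input_name, 25)
  dec <- add_diacritics(nms, rate = 0.4, seed = 9)
  expect_true(any(dec != nms))  # decoration actually happened
  for (i in seq_along(nms)) {
    expect_equal(format_name(parse_name(dec[i])), nms[i])
  }
})
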