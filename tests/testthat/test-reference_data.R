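test_that("load_reference reads a minimal well-formed file", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Input_Taxon\tStatus\tOutput_Taxon",
               "Aus bus L.\taccepted\tAus bus L.",
               "Aus cus Sm.\tsynonym\tAus bus L.",
               "Aus dus\tunresolved\t"),
             tmp)
  tab <- load_reference(tmp)
  expect_s3_class(tab, "ref_table")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$status, c("accepted", "synonym", "unresolved"))
  expect_equal(tab$genus, rep("Aus", 3))
  expect_equal(tab$authority[1:2], c("L.", "Sm."))
})

test_that("dialect contract: column and status mapping errors", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Taxon\tState\tTarget", "Aus bus\tAccepted\tAus bus"), tmp)
  expect_error(load_reference(tmp), "no column found.*input_name")

  # custom dialect maps the columns and the capitalised status value
  d <- lcvp_dialect(columns = list(input_name = "Taxon", status = "State",
                                   accepted_name = "Target"))
  tab <- load_reference(tmp, d)   # "Accepted" maps case-insensitively
  expect_equal(tab$status, "accepted")

  # an unmappable vocabulary entry names the offending values
  writeLines(c("Taxon\tState\tTarget", "Aus bus\tWeird\tAus bus"), tmp)
  expect_error(load_reference(tmp, d), "unmappable status.*Weird")
})

test_that("genus_index is consistent and covers all distinct genera", {
  tab <- generate_reference(fixture_spec(n_genera = 20, seed = 5))
  gi <- genus_index(tab)
  expect_equal(gi, genus_index(tab, rebuild = TRUE))
  expect_setequal(names(gi), unique(tab$genus))
  expect_equal(sort(unlist(gi, use.names = FALSE)), seq_len(nrow(tab)))
})

test_that("validate_reference reports chains, cycles, dangles, duplicates", {
  # valid two-record table
  tab <- toy_table(data.frame(
    name = c("Aus bus L.", "Aus cus Sm."),
    status = c("synonym", "accepted"),
    accepted = c("Aus cus Sm.", "Aus cus Sm.")))
  rep <- validate_reference(tab)
  expect_true(rep$valid)

  # A -> B -> C chain
  tab <- toy_table(data.frame(
    name = c("Aus alpha L.", "Aus beta L.", "Aus gamma L."),
    status = c("synonym", "synonym", "accepted"),
    accepted = c("Aus beta L.", "Aus gamma L.", "Aus gamma L.")))
  rep <- validate_reference(tab)
  expect_false(rep$valid)
  expect_equal(rep$chained_synonyms,
               "Aus alpha L. -> Aus beta L. -> Aus gamma L.")

  # two-node cycle
  tab <- toy_table(data.frame(
    name = c("Aus alpha L.", "Aus beta L."),
    status = c("synonym", "synonym"),
    accepted = c("Aus beta L.", "Aus alpha L.")))
  rep <- validate_reference(tab)
  expect_length(rep$cycles, 1L)
  expect_setequal(rep$cycles[[1L]], c("Aus alpha L.", "Aus beta L."))

  # dangling + duplicate
  tab <- toy_table(data.frame(
    name = c("Aus alpha L.", "Aus alpha L.", "Aus beta L."),
    status = c("accepted", "accepted", "synonym"),
    accepted = c("Aus alpha L.", "Aus alpha L.", "Gone missing L.")))
  rep <- validate_reference(tab)
  expect_equal(rep$dangling_synonyms, "Aus beta L.")
  expect_equal(rep$duplicate_names, "Aus alpha L.")
})

test_that("flatten_synonym_chains closes chains to accepted names", {
  tab <- toy_table(data.frame(
    name = c("Aus alpha L.", "Aus beta L.", "Aus gamma L."),
    status = c("synonym", "synonym", "accepted"),
    accepted = c("Aus beta L.", "Aus gamma L.", "Aus gamma L.")))
  ft <- flatten_synonym_chains(tab)
  expect_equal(ft$accepted_name[ft$input_name == "Aus alpha L."],
               "Aus gamma L.")
  expect_true(validate_reference(ft)$valid)
  # idempotence: second application is the identity
  expect_identical(flatten_synonym_chains(ft), ft)

  # cycles abort with the members named
  cyc <- toy_table(data.frame(
    name = c("Aus alpha L.", "Aus beta L."),
    status = c("synonym", "synonym"),
    accepted = c("Aus beta L.", "Aus alpha L.")))
  expect_error(flatten_synonym_chains(cyc), "Aus alpha L.")

  # dangling targets demote to unresolved with a warning
  dang <- toy_table(data.frame(
    name = c("Aus alpha L.", "Aus beta L."),
    status = c("accepted", "synonym"),
    accepted = c("Aus alpha L.", "Gone missing L.")))
  expect_warning(fd <- flatten_synonym_chains(dang), "demoted")
  expect_equal(fd$status[fd$input_name == "Aus beta L."], "unresolved")
})

test_that("chains injected by the generator flatten to their truth map", {
  tab <- generate_reference(fixture_spec(seed = 23, chain_fraction = 0.3))
  truth <- attr(tab, "truth")
  ft <- suppressWarnings(flatten_synonym_chains(tab))
  got <- ft$accepted_name[match(truth$flatten_map$synonym, ft$input_name)]
  expect_equal(got, truth$flatten_map$terminal_accepted)
  # every synonym now points at an accepted record
  idx <- match(ft$accepted_name[ft$status == "synonym"], ft$input_name)
  expect_true(all(ft$status[idx] == "accepted"))
  # record count is preserved
  expect_equal(nrow(ft), nrow(tab))
})

test_that("summarize counts a hand-built partition exactly", {
  # empty table
  empty <- toy_table(data.frame(name = character(0), status = character(0),
                                accepted = character(0)))
  s <- summarize_backbone(empty)
  expect_equal(s$total_names, 0L)
  expect_equal(s$accepted_species, 0L)

  # 10 accepted species, 2 hybrids, 5 synonyms, 1 unresolved
  sp <- sprintf("Aus %s L.", paste0("species", letters[1:10]))
  hyb <- c("Aus hybrida_x L.", "Bus_x notha L.")
  syn <- sprintf("Bus %s L.", paste0("syn", letters[1:5]))
  unr <- "Cus lost L."
  tab <- toy_table(data.frame(
    name = c(sp, hyb, syn, unr),
    status = c(rep("accepted", 12), rep("synonym", 5), "unresolved"),
    accepted = c(sp, hyb, rep(sp[1], 5), "")))
  s <- summarize_backbone(tab)
  expect_equal(s$total_names, 18L)
  expect_equal(s$accepted_species, 10L)
  expect_equal(s$natural_hybrids, 2L)
  expect_equal(s$synonyms, 5L)
  expect_equal(s$unresolved, 1L)
  expect_equal(s$accepted_incl_infraspecific +
                 s$natural_hybrids + s$synonyms + s$unresolved,
               s$total_names)
  expect_equal(s$genera_all, 3L)
  expect_equal(s$unresolved_by_genus$genus, "Cus")
})

test_that("summarize survives a write/load round trip", {
  tab <- generate_reference(fixture_spec(seed = 31))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_reference(tab, tmp)
  back <- load_reference(tmp)
  expect_equal(summarize_backbone(back)[1:11], summarize_backbone(tab)[1:11])
  expect_equal(back$input_name, tab$input_name)
})

test_that("diff_backbones classifies presence and contrast categories", {
  a <- generate_reference(fixture_spec(seed = 41, n_genera = 10))
  a <- suppressWarnings(flatten_synonym_chains(a))
  d <- diff_backbones(a, a)
  expect_equal(d$identical, nrow(a))
  for (f in c("only_in_a", "only_in_b", "different_author",
              "different_synonym", "different_orthography",
              "resolved_in_a_unresolved_in_b", "accepted_in_a_synonym_in_b",
              "synonym_in_a_accepted_in_b")) {
    expect_equal(d[[f]], 0L)
  }

  b0 <- toy_table(data.frame(name = character(0), status = character(0),
                             accepted = character(0)))
  one <- toy_table(data.frame(name = "Xus yus L.", status = "accepted",
                              accepted = "Xus yus L."))
  d <- diff_backbones(one, b0)
  expect_equal(d$only_in_a, 1L)
  expect_equal(d$identical, 0L)

  # author difference: same binomial, different authority
  a1 <- toy_table(data.frame(name = "Genus alba Sm.", status = "accepted",
                             accepted = "Genus alba Sm."))
  b1 <- toy_table(data.frame(name = "Genus alba L.", status = "accepted",
                             accepted = "Genus alba L."))
  d <- diff_backbones(a1, b1)
  expect_equal(d$different_author, 1L)
  expect_equal(d$different_orthography, 0L)

  # orthographic variant: small edit on the epithet, same authority
  b2 <- toy_table(data.frame(name = "Genus albus Sm.", status = "accepted",
                             accepted = "Genus albus Sm."))
  d <- diff_backbones(a1, b2)
  expect_equal(d$different_orthography, 1L)
  expect_equal(d$different_author, 0L)

  # status contrasts on shared names
  a2 <- toy_table(data.frame(
    name = c("Aus bus L.", "Aus cus L.", "Aus dus L."),
    status = c("accepted", "synonym", "accepted"),
    accepted = c("Aus bus L.", "Aus bus L.", "Aus dus L.")))
  b3 <- toy_table(data.frame(
    name = c("Aus bus L.", "Aus cus L.", "Aus dus L."),
    status = c("synonym", "accepted", "unresolved"),
    accepted = c("Aus cus L.", "Aus cus L.", "")))
  d <- diff_backbones(a2, b3)
  expect_equal(d$accepted_in_a_synonym_in_b, 1L)
  expect_equal(d$synonym_in_a_accepted_in_b, 1L)
  expect_equal(d$resolved_in_a_unresolved_in_b, 1L)
  expect_equal(d$identical, 3L)
})
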