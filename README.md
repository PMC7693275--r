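# taxscrub

Taxonomic name resolution ("taxon scrubbing") for vascular-plant
checklists: parse botanical name strings, match them — tolerating
spelling errors — against a reference backbone that maps every published
name to its status (*accepted*, *synonym*, *unresolved*) and its accepted
name, and validate, summarize and compare such backbone tables.

## Who this is for

Ecologists, biogeographers and database curators who assemble species
lists from heterogeneous sources and need them translated onto one
accepted nomenclature. Backbone maintainers who need to check a table's
internal consistency (do all synonyms lead to an accepted name?) or to
quantify how two backbone versions differ.

## What it does

**Name grammar.** A scientific name is parsed positionally:
`Genus epithet [rank infra] [authority]`, with ranks drawn from
`subsp. var. forma ssp. f. subvar. subf.` (only at token 3 of a ≥4-token
name), hybrid taxa marked by a trailing `_x` on the genus (intergeneric)
or epithet (interspecific). Loose hybrid annotations (`x Genus`,
`x_Genus`, `Genus x epithet`) are rewritten to the canonical marker; the
Unicode multiplication sign (U+00D7) is rejected. Authorities are
canonicalized: spaces inside initials removed (`C. F. W. Meissn.` →
`C.F.W.Meissn.`; `Balf. f.` → `Balf.f.`), two authors joined by `&`,
three or more truncated to `First & al.`. Genus/epithet diacritics are
transliterated (`Isoëtes` → `Isoetes`, `Köberlinia` → `Koeberlinia`).

**Staged fuzzy matching.** A query is resolved component-wise in the
grammar's order, using the Levenshtein distance d with per-component
thresholds t (default t = 2 for genus, epithet and infraspecific
epithet):

1. genus: candidates are all reference genera with d ≤ t_genus, an exact
   hit suppressing all fuzzy ones;
2. epithet: same rule inside the surviving genera;
3. infraspecific epithet and authority, if supplied — the authority never
   vetoes a match, it only breaks ties and is reported in the score.

Candidates are ranked by (total distance, status priority
accepted > synonym > unresolved, authority agreement, name); remaining
ties are flagged `Ambiguous` (homonyms submitted without an authority).
Every row of the output carries a per-component diagnostic `Score` such
as `genus:exact|epithet:fuzzy(1)|infra:not_supplied|authority:exact`;
unresolved queries keep only their submitted name and score.

**Backbone management.** `validate_reference()` reports dangling
synonyms, unflattened synonym chains (A→B→C), reference cycles and
duplicate names; `flatten_synonym_chains()` transitively closes every
synonym onto its terminal accepted name (if A is a synonym of B and B of
C, A's accepted name becomes C); `summarize_backbone()` counts names
under the partition accepted species / accepted infraspecific / natural
hybrids / synonyms / unresolved; `diff_backbones()` classifies the union
of two tables into identical / only-in-one names plus author,
orthography, synonym-target and status contrasts.

**Synthetic fixtures.** `generate_reference()` builds deterministic
pseudo-Latin backbones with known ground truth (chains, homonyms,
injected defects), and `corrupt_query()` produces queries at an exact
edit distance with a provable uniqueness margin — so matching quality is
testable without the real multi-hundred-thousand-row download.

## Worked example

```r
library(taxscrub)

tab <- flatten_synonym_chains(generate_reference(fixture_spec(seed = 2)))
tab
#> <ref_table> 433 records, 25 genera (fixture-seed2)
#>   accepted: 134  synonym: 277  unresolved: 22

cr <- corrupt_query(tab$input_name[7], "epithet", k = 1, tab, seed = 5)
rt <- resolve_names(c(cr$corrupted_name, "Zzz qqq"), tab)
rt
#> <result_table> 2 row(s)
#>                           Submitted_Name                           Matched_Name
#> 1 Niothiaia rayoides A.U.Fhevu. & R.Phi. Niothiaia raeoides A.U.Fhevu. & R.Phi.
#> 2                                Zzz qqq
#>    Status                           Accepted_Taxon Total_Distance
#> 1 synonym Tudraea guus ssp. raecioum K.Povo. & al.              1
#> 2                                                              NA
#>                                                                         Score
#> 1             genus:exact|epithet:fuzzy(1)|infra:not_supplied|authority:exact
#> 2 genus:unmatched|epithet:unmatched|infra:not_supplied|authority:not_supplied
```

Row 1: the single-letter typo `rayoides` was recovered at distance 1; the
matched record is a synonym, so the row also reports the accepted taxon
it resolves to (an infraspecific name in another genus, after chain
flattening). Row 2: nothing within the genus threshold — the row is empty
except for the submitted name and the score saying which stage failed.

`write_results(rt, "out.csv")` saves the table as UTF-8 CSV;
`read_results()` restores it losslessly.

## Command line

```sh
exec/taxscrub generate --seed 3 --out backbone.tsv
exec/taxscrub resolve --ref backbone.tsv "Hibiscus vitifolius" --out result.csv
exec/taxscrub validate --ref backbone.tsv
exec/taxscrub summarize --ref backbone.tsv
exec/taxscrub diff old.tsv new.tsv
```

Reference files are tab-delimited UTF-8 with a header row; column names
and status vocabulary are adapted via a dialect config
(`--dialect`, see `inst/extdata/lcvp-1.0.3.conf` for the shipped
default).

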