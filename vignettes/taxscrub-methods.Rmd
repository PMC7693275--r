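---
title: "Methods: name grammar, staged fuzzy matching, and backbone QC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: name grammar, staged fuzzy matching, and backbone QC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxscrub)
```

## The problem

Species lists compiled from heterogeneous literature carry three kinds of
noise: orthographic (typos, diacritics, inconsistent author spellings),
nomenclatural (the name used is a synonym of the currently accepted
name), and structural (a backbone whose synonym cross-references do not
actually terminate in accepted names). `taxscrub` addresses all three:
it standardizes and parses name strings, resolves them against a
reference backbone with per-component fuzzy matching, and audits the
backbone itself.

## The name grammar and its normalizations

A name is split on single spaces into positional components: token 1 is
the genus, token 2 the epithet (two-word genera/epithets must be
hyphenated, e.g. *Hibiscus rosa-sinensis*). When the name has **more
than three** tokens and token 3 is one of `subsp.`, `var.`, `forma`,
`ssp.`, `f.`, `subvar.`, `subf.` (case-insensitive), token 4 is the
infraspecific epithet; everything after the consumed tokens is the
authority. This is deliberately positional, not lexical: `f.` is a rank
marker at position 3 of a 4+-token name and an author suffix anywhere in
the authority ("Balf.f.").

Degenerate case: a 3-token name whose third token is a rank marker
("*Aus bus* var."). The grammar would make the marker an authority, but
an authority can never begin with a rank token; we drop the dangling
marker with a parse warning. Fewer than two tokens is an error — every
other parse problem is a warning so that batch jobs never abort.

Normalizations applied before matching:

* **Hybrid markers.** Natural hybrids are encoded by `_x` *after* the
  genus (intergeneric) or epithet (interspecific). Leading `x ` / `x_`
  annotations are rewritten into that form; the typographic
  multiplication sign U+00D7 is rejected outright rather than silently
  reinterpreted, because it is routinely confused with the letter x and
  corrupts downstream joins.
* **Orthography.** Genus and epithet may contain only `A–Za–z` and the
  hyphen. The transliteration table (`extdata/transliteration.tsv`,
  user-extensible) maps umlauts to digraphs (ö → oe, as in
  *Koeberlinia*) and accents/diaereses on other vowels to the base
  letter (*Isoëtes* → *Isoetes*). Residual non-alphabetic characters are
  dropped and flagged.
* **Authorities.** Spaces are removed after single-letter initials and
  before filial suffixes (`C. F. W. Meissn.` → `C.F.W.Meissn.`,
  `Balf. f.` → `Balf.f.`); two authors are joined with `&`; three or
  more become `First & al.`; `ex`-clauses stay inside one author unit.
  All three operations are idempotent, which the test suite verifies on
  random inputs — idempotence is what makes "normalize at load, compare
  normalized" sound.

`format_name()` inverts `parse_name()` on canonical strings, and the
suite checks both compositions on every generated fixture name.

## Staged fuzzy matching

Matching runs in the grammar's order with the Levenshtein distance
(unit-cost insert/delete/substitute, via `utils::adist`). "Letters that
may disagree" is implemented as Levenshtein rather than Hamming because
typos change word length, and rather than Damerau because transpositions
are rare in typeset botanical names and the simpler metric is easier to
reason about in the margin analysis below.

* **Stage order and veto.** Genus, then epithet, then (if supplied)
  infraspecific epithet must each find a candidate within their
  thresholds or the whole resolution fails. The authority, by contrast,
  is optional evidence: a mismatch is reported in the score
  (`authority:unmatched`) but never rejects the record.
* **Exact preemption.** At each vetoing stage a distance-0 hit discards
  all fuzzy candidates. Without this rule a verbatim name could be
  shadowed by a typo-neighbour with a better downstream component.
* **Hybrid flags.** `_x` is a marker, not spelling: a flag mismatch adds
  distance 1 and blocks exactness, so *Aus bus* still finds
  *Aus bus_x* — at a cost — when no flag-agreeing record exists.
* **Species preference.** When no infraspecific part is submitted,
  species-rank candidates preempt infraspecific ones (so *Hibiscus
  vitifolius* matches the species, not one of its varieties); if only
  infraspecific records exist they remain eligible, scored
  `infra:not_supplied`.
* **Defaults.** Thresholds default to 2 edits for genus, epithet and
  infraspecific epithet, authority matching to exact-on-canonical-form.
  The thresholds are user-set by design; 2 tolerates the common
  one-to-two-letter errors while keeping six-letter epithets from
  dissolving into their neighbours. They are deliberately conservative:
  enlarging a threshold can only add candidates (a property the suite
  tests), never lose an exact match.

**Ranking and ambiguity.** Candidates are ordered by total distance,
then status priority (accepted > synonym > unresolved), then authority
agreement, then name (a deterministic tie-break so results are invariant
under table row order). Ambiguity is a tie on the first three keys. The
authority key is the package's refinement of a two-key rule: roughly a
tenth of published plant names are homonyms — identical strings up to
the authority that denote different taxa — so when the user *does*
supply an authority it should disambiguate, and when they do not, the
tie is reported as `Ambiguous` rather than silently resolved
(`return_all_ties` then returns every tied record).

## Backbone QC

A backbone row maps a published name to a status and an accepted-name
cross-reference. `validate_reference()` reports four defect classes:
dangling synonyms (target absent), chains (target is itself a synonym —
the table has not been transitively closed), cycles, and duplicate name
strings; cycle members are reported as cycles only, not also as chains.
`flatten_synonym_chains()` performs the closure — every synonym ends at
a record with status accepted — and is idempotent; synonyms whose chain
terminates nowhere (or in an unresolved record) are demoted to
unresolved with a warning rather than aborting, because real backbone
exports contain such rows and QC should report, not crash. Cycles do
abort flattening: there is no defensible terminal name to assign.

`summarize_backbone()` uses a fixed partition — non-hybrid accepted
(species + infraspecific), natural hybrids (hybrid flag and accepted
status), synonyms, unresolved — chosen so the four classes sum exactly
to the record count, mirroring how published backbones report species,
infraspecific names and hybrids as separate headline numbers.

`diff_backbones()` decides presence on the full canonical string (each
name in the union is identical / only-in-A / only-in-B), computes status
contrasts on shared names, and looks for author variants (same
genus+epithet+infra, different authority) and orthographic variants
(edit distance 1–3 on the concatenated binomial, same authority and
infra) between the non-shared names. The 1–3 band is configurable
(`diff_options()`); published comparisons report an "orthographic
difference" category without stating a rule, so the bound is documented
rather than inherited.

## The synthetic world, and what a green test establishes

`generate_reference()` emulates the *composition* of a modern
vascular-plant backbone, not its content. Defaults: ~64% of names are
synonyms and ~5% unresolved (the published backbone has 846,279 of
1,315,562 and 63,072 respectively), ~12% of accepted names are
infraspecific (48,257 / 405,687), hybrids ~2% of accepted species
(6,160 / 351,180). Chain frequency is not published; the default (10% of
synonyms are chain links, chains of length 2–5) is a one-time choice
made to exercise flattening, not an estimate. Names are pronounceable
pseudo-Latin over ASCII; diacritics enter through `add_diacritics()` on
query strings only, since the stored canonical form forbids them.
Authorities are sampled across 1-, 2- and ≥3-author templates so the
`&`/`& al.` rules are exercised.

What the generator does **not** emulate: realistic name-frequency and
length distributions, genus-size skew, shared epithets across related
genera (our epithets are globally unique by construction, making the
synthetic matching problem *easier* than the real one), or plausible
literature citations. A green recovery test therefore establishes the
algorithmic guarantee below, not field performance on real floras.

**The recovery guarantee.** `corrupt_query()` applies exactly *k* edits
to one component and computes `margin_ok`: the corrupted component must
not collide exactly with a different value visible at its matching
stage, and no other record may agree on the remaining components while
lying within *k* edits of the corrupted component (this also excludes
homonym partners, since the authority is deliberately ignored here —
it cannot veto). Under `margin_ok`, k ≤ threshold, and a single
corrupted component, the staged resolver must return the source record;
the acceptance suite verifies 100% recovery over ≥500 such queries
across 5 seeds, and separately checks exact agreement with a naive
full-scan staged matcher on 1,000 mixed queries.

## Numerical and interface choices

* Determinism: every random operation (generator, corruption) takes an
  explicit seed and restores the caller's RNG state; resolution itself
  is deterministic and row-order invariant.
* Output CSV: fixed 18-column schema; unresolved rows are empty except
  `Submitted_Name` and `Score`; empty cells encode both `""` (character)
  and `NA` (distances/flags), and `read_results()` restores the table
  exactly.
* Dialects: file headers and status vocabulary are mapped through a
  small config (`lcvp_dialect()`, `read_dialect()`); the shipped default
  lists plausible header aliases for the published v1.0.3 export, but
  those exact headers are unverifiable without the download, so the
  mapping is user-overridable (and a missing column fails loudly, naming
  the field and the aliases tried).
* Batch size: submissions above 5,000 names warn (computation time), but
  are not refused.

## Known limitations

* Epithet variants that are *spellings* rather than typos (the
  *warscewiczii* / *warszewiczii* family) are matched fuzzily, not
  respelled editorially; the package transliterates characters but never
  rewrites epithets.
* Authority comparison is exact on canonical strings unless
  `fuzzy_authority` is enabled; abbreviation variants beyond the
  documented normalizations ("Linn." vs "L.") count as mismatches.
* No genus-synonym cross-walks, phonetic matching, or cultivar parsing;
  infraspecific rank markers are not compared (matching uses the
  infraspecific epithet only).
* `summarize_backbone()` on the real v1.0.3 download should reproduce its
  published headline counts, but that file is not bundled, so the claim
  is untested here (the loader's dialect is the part at risk).
```{r}
tab <- flatten_synonym_chains(generate_reference(fixture_spec(seed = 2)))
summary(tab)
```
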