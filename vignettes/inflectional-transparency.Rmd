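---
title: "Quantifying form–value transparency in Italian noun and adjective inflection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying form–value transparency in Italian noun and adjective inflection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(declentropy)
library(dplyr)
```

## The problem

Italian nouns and adjectives are obligatorily inflected for gender
(feminine/masculine) and number (singular/plural), and both values are fused
into a single final vowel: *gatto* "cat(M).SG", *gatta* "cat(F).SG",
*gatti* "cat(M).PL", *gatte* "cat(F).PL". Because essentially all of nominal
inflection is squeezed into the four vowels *-a, -e, -i, -o*, no ending maps
one-to-one onto a value combination: *-e* can be a feminine plural
(*rose*), a feminine singular (*tigre*) or a masculine singular (*fiore*).
Psycholinguistic work consistently finds that opaque form–value mappings
carry processing costs, but "transparent vs. opaque" is a categorical label;
this package quantifies the degree of transparency from corpus data.

The measure is Shannon entropy over a conditional distribution of forms. Fix
a conditioner — an inflectional ending, or a declensional class — and count
how the word forms carrying it distribute over the value categories. With
counts $c_v$ over categories $v$ and $p_v = c_v / \sum_w c_w$,

$$H = -\sum_{v:\,c_v>0} p_v \log_2 p_v \quad \text{(bits)},$$

with $0 \log 0 := 0$. $H = 0$ means the conditioner deterministically
signals one value combination (maximal transparency); the capacity is
$\log_2 k$ for $k$ populated categories. Counts are taken two ways: **types**
(each distinct word form counted once) and **tokens** (summed corpus
frequencies), since type-wise and token-wise transparency can diverge.

## Paradigms and declensional classes

The inflectional ending of an Italian noun or adjective is its last phoneme
and — thanks to the transparent orthography — its last character, so
`extract_ending()` simply strips the final character. Endings outside
`a/e/i/o` (invariable loans such as *blu* or *quiz*) take part in paradigm
construction but are reported in a remainder line, not in the four-ending
tables.

Paradigms are reconstructed by coupling the endings attested for one lemma
(`build_paradigms()`):

* **Nouns** have a two-cell paradigm (SG/PL); gender is a lexical property
  of the lemma, so nouns are grouped by (lemma, gender) — homographic
  lemma pairs such as *musicista* (M) / *musicista* (F) form two separate
  paradigms. Two lemma-level exceptions are coupled across genders: a
  lemma with exactly one singular and one plural of opposite genders (the
  gender-changing class *uovo*(M).SG / *uova*(F).PL, label `o_a`, keyed by
  the singular's gender), and a lemma with one singular and two plurals of
  distinct endings (the over-abundant `o_a_i` pattern, *braccio / braccia
  / bracci*).
* **Adjectives** agree with their noun, so gender is not lexical: each
  lemma has one four-cell paradigm (F.SG, F.PL, M.SG, M.PL).

Class labels couple the endings cell-wise: `o_i`, `a_e`, `e_i`, `a_i`,
`o_a` are the canonical noun classes; identical singular and plural forms
always win as `Inv` before any ending-pair reading; any other attested pair
(*sport/sports*, *corpus/corpora*) is `Other`; an unattested cell is
rendered `NA` (`o_NA`, `NA_i`), and such one-cell paradigms are excluded
from class-level entropy tables. Adjective labels concatenate a feminine
and a masculine part (`a_e o_i`, `e_i e_i`, `a_NA NA`, `NA o_i`, ...); a
gender with no attested cell collapses to a single `NA` token. Two label
decisions were genuinely open and are ours: a gender whose two cells share
one invariant form is rendered `Inv` in its slot, and an adjective whose
attested forms are all one surface form spanning both numbers is the class
`Inv` — the label grammar covers these mechanically, and we preferred an
explicit token over a degenerate `x_x` pair.

Noun class entropies are computed over the two genders (capacity 1 bit,
counting lemmas by their lemma-level gender key); adjective class and all
ending entropies are computed over the four value combinations (capacity
2 bits). One further choice: the plural tokens of a gender-changing `o_a`
paradigm are credited to the gender the plural is *attested* with, not to
the lemma's gender key, so token tables reflect what a reader of the corpus
actually encounters.

## Ambiguous forms and the counting policy

Within one part of speech, distinct annotation rows can share a surface
form: accidental lemma homography (*latte* M.SG "milk" / F.PL "tin cans"),
class intersection (*cameriere* = M.SG of `e_i` *and* F.PL of `a_e`),
invariance (*re*, and four-way *portavoce*). `detect_ambiguous_forms()`
pools all of these: any (form, POS) attested under two or more of the four
feature combinations is one ambiguity record, whatever its cause. Forms
shared only *across* POS (*manifesto* noun/adjective) are never ambiguous
here, because a POS-tagged corpus separates their counts.

A POS-level tagger cannot split a homograph's token count across feature
values, so the counting policy (`apply_counting_policy()`) is: **type**
tables use all entries (the annotation list does disambiguate types, one
per attested combination), while **token** tables use only non-ambiguous
forms, whose counts are exact. Whether published type tables included
ambiguous types is not fully documented in the literature this package
follows; we include them, flag the assumption in the run log, and note
that excluding them cannot reproduce the published type-table scale. Row
proportions in rendered tables are normalized within each row, after the
non-core (`OTHER`) endings have been moved to the remainder line.

## The synthetic-lexicon generator

Real corpus-derived lexica are large and license-encumbered;
`generate_lexicon()` produces seeded lexica with the structural features
the analysis relies on, plus exact ground truth, so every downstream stage
is testable:

* **Stems** are CV-alternating strings over a fixed 14-consonant /
  5-vowel alphabet, minimum length 3, ending in a consonant, unique by
  rejection sampling — so the appended ending character is always the
  final character, never stem material. No attempt is made at
  phonotactically valid Italian.
* **Classes** are drawn per [class_spec()]: noun lemmas take a gender by
  `p_masculine` and two cells per the label; `o_a` and `o_a_i` lemmas
  attest their plural(s) under the opposite gender as in the real classes;
  adjective lemmas fill four cells. `cell_dropout` removes each cell
  independently (a lemma keeps at least one cell), emulating the many
  defective paradigms of real corpora.
* **Frequencies** follow a Zipf law assigned over all surface forms
  jointly, `freq(rank) = max(1, round(freq_scale * rank^-s))`, mirroring a
  corpus-wide frequency list; homograph forms carry one undivided count
  into each of their entries, exactly as a POS-tagged merge would.
  Defaults `s = 1` (the classical Zipf exponent) and `freq_scale = 1e6`
  keep rounding negligible down to a few thousand forms; the nominal
  corpus size defaults to 1.9e9 tokens, the scale of the large web corpus
  the published frequencies come from.
* **Planted ambiguity**: at `ambiguity_rate`, masculine `e_i` lemmas and
  feminine `a_e` lemmas are paired to share a stem, forcing the
  *cameriere*-type F.PL–M.SG collision; `n_fourway` plants
  *portavoce*-type forms attested in all four combinations. Requests that
  exceed the available class pairs degrade with a warning. Structural
  ambiguity (invariant nouns, gender-syncretic adjective classes such as
  `e_i e_i`) arises on its own; `plant_ambiguity_report()` derives the
  complete expected record set from the generator's entry-level ground
  truth, which is what the detection tests compare against.

What passing on synthetic data does *not* show: the generator has clean
annotations (no tagging noise), no derivational morphology, no
morphophonological alternations (invisible at the final character anyway),
and no semantic structure, so recovery results speak to the pipeline's
correctness, not to annotation quality in real resources.

## Numerical and I/O choices

* Base-2 logarithms throughout; `0 log 0 = 0`; an all-zero count vector is
  an error, and empty table rows carry `H = NA`.
* Rendered tables print proportions and `H` to four decimals, rounding
  half away from zero; comparisons against published values use an
  absolute tolerance of `1e-4`, the printed precision.
* Forms are normalized to Unicode NFC and lower case before anything else,
  so composed and decomposed accented vowels (*città*) yield one entry and
  a stable final character.
* The standardized frequency is occurrences per million tokens,
  `token_freq * 1e6 / corpus_size` — the convention of the corpus
  literature; the source resource names the field without stating a
  formula.
* Input rows with unknown POS/gender/number codes or malformed
  frequencies are rejected and counted in a per-line report, never
  silently dropped; a rejection share above 50% (configurable) aborts as
  a dialect mismatch. Duplicate full-key rows have their frequencies
  summed with a warning, since sharded corpus exports split counts.
* Output row order and table orderings are deterministic (endings
  alphabetical, classes by descending total), so identical inputs produce
  byte-identical files.

## A worked example

```{r worked-example}
lex <- worked_example_lexicon()
paradigms <- build_paradigms(lex)
paradigms[, c("pos", "lemma", "gender_key", "class", "flags")]

detect_ambiguous_forms(lex, "noun")[, c("form", "pattern")]

out <- entropy_pipeline(lex)
out$tables$noun_ending_type
```

The over-abundant `o_a_i` class deserves a note: published tables print a
dash for its token entropy without explanation; this implementation
computes and reports the value like any other row.

## Problem sizes and limitations

The bundled test suite and the acceptance script run the pipeline at desk
scale — a few hundred to ~1,300 lemmas per synthetic lexicon, 1,000 lemmas
for the binomial gender-entropy check (ten seeds), 1,000 random count
vectors for the entropy property suite — sizes at which every check is
exact or tightly enveloped while the whole suite stays fast. The package
does not attempt: corpus construction, POS tagging or lemmatization
(annotations are taken as given); token-level disambiguation of homograph
counts (impossible under POS-level tagging); adjective grade morphology
beyond carrying a `grade` field; conditional-entropy or cue-validity
extensions. Full-resource headline figures (≈72k forms, 1,749 ambiguous
nouns) require the external corpus merge and are deliberately out of
scope; the entropies of the published per-row counts, which are fully
determined by the rows themselves, are reproduced exactly.
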