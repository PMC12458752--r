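---
title: "Methods: rule-based CRC and TNM extraction from clinical free text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based CRC and TNM extraction from clinical free text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crctnm)
```

This vignette is the package's own account of its method: the extraction
model and its assumptions, the parameters that matter, what the synthetic
generator does and does not emulate, the numerical choices, and the design
decisions taken where the problem was genuinely open.

## 1. The TNM extraction model

TNM staging is written with a closed vocabulary — a category letter (T, N,
M, V, R, L, Pn, G, SM, H), an optional prefix on T (`[acmpry]{1,3}`, e.g.
`yp`, `mr`), and a value from a small per-category set (`tnm_allowed_values()`).
That closure is the core assumption: explicit stages can be recovered by a
constrained grammar, while anything not written in letters and numbers
(implicit staging) is out of scope by design.

Extraction proceeds in five stages:

1. **Token scan.** One PCRE pass finds candidate tokens: optional lower-case
   prefix, category letter(s) (case-insensitive), up to two spaces, then one
   or more values joined by the multi-value separators. A token may be
   followed by a non-word character or directly by another token (`T1N0M0`),
   never by a stray digit — which is what makes `T12` (a vertebra) unmatchable.
   A token may start immediately after another token's value-final letter
   (`T1aN0`, `TisN0`, `TXN0`).
2. **Normalisation.** Letter O in value position becomes 0, `x` becomes `X`,
   substage letters are lower-cased, Haggitt Roman numerals (upper-case
   only) map to Arabic, and the result must sit in the category's allowed
   set or the value is dropped. `is` (carcinoma in situ) is accepted only
   without a gap: `Tis` is staging, "CT is unremarkable" is prose.
3. **Guards.** Plain unprefixed `T1`/`T2` with MRI vocabulary in the same
   sentence within ±30 characters ("weighted", "sequence", "signal",
   "FLAIR", plane names) are rejected, as are `T1`–`T4`/`L1` in vertebral
   context (anatomical words, or ranges such as `T1-T12` and `C7-T1`). Both
   term lists are configurable; guard context never crosses a sentence
   boundary.
4. **Phrase assembly.** Consecutive tokens merge while the text between
   them is at most 40 characters of whitespace/punctuation or a single
   bracketed comment (`T1a (solitary tumour) N0`); a sentence terminator
   ends the phrase. Letter-O values must sit immediately (≤ 2 spaces) next
   to another token — `T0 NO MX` keeps `NO`, a prose "No" never becomes N0.
   This adjacency rule is applied to every category, not only N: headers
   like "REFERRED TO" would otherwise produce a T0.
5. **Singleton anchoring.** A phrase covering a single category survives
   only with a staging cue ("staged as", "stage", "staging", "TNM") within
   30 characters before it. Disambiguating lone values is the known weak
   point of this family of methods, so the conservative default is to
   refuse them without a cue — this is also why bare `G2` grades are
   deliberately missed (grade is extracted only when phrase context or a
   cue supports it), and why grade sensitivity is expected to be poor on
   real reports.

**Aggregation.** The per-report output is the *maximum* per category under
a clinical severity ranking: `X` ranks below every informative value (so X
is reported only when it is all that was seen), and
`0 < is < 1 < 1a < 1b < 1c < 1d < 2 < … < 4d`; Haggitt Roman and Arabic
forms compare equal. The ranking is configurable (`tnm_config(ranking=)`)
because "maximum" is not otherwise defined for tokens; severity order is
the only defensible default. The reported T prefix is the one attached to
the token that supplied the T maximum; ties go to the last occurrence in
document order, matching the convention that conclusions restate staging.

### Ambiguities worth documenting

* `pN1` vs `Pn1`: the prefix grammar is lower-case-only, so exact-case
  `pN1` reads as prefix-p + N1 while `PN1`/`Pn1` read as perineural
  invasion. All-lower-case `pn1` is re-interpreted as perineural whenever
  the value fits Pn's allowed set (`{0,1,X}`) — `pn2` falls back to N2.
* Prefixes attach to T only by default (`allow_prefix_nm = TRUE` extends
  them to N/M); combinations outside the whitelist
  (`c, p, y, r, a, m, yp, mr, ymr, cp`) are dropped while the stage token
  is kept.
* Multi-value separators default to `/`, `,`, `or`. `-` is recognised but
  disabled: it collides head-on with vertebral ranges (`T1-T12`), and the
  documented dialect table only evidences `/`.

## 2. Modifier scoping and CRC detection

`scope_modifiers()` implements a ConText-style engine: a trigger term
projects a scope forward, backward, or both, until the first sentence
terminator (`.`, `;`, newline, the conjunction "but"), the rule's character
limit (default 120 forward / 60 backward, roughly one clinical sentence),
or the next trigger of the same modifier class projecting in the same
direction. A concept wholly inside a scope inherits the modifier. The
same-direction restriction keeps the engine monotone: adding triggers can
only add modifiers, which in turn guarantees that adding rules can only
flip a CRC call from positive to negative.

`classify_crc()` composes keyword matching with that engine: a tumour
keyword counts only when linked to a colorectal site in the same sentence
within 120 characters (compound terms like "colorectal cancer" are
self-sufficient), and a linked mention is excluded when any of the seven
modifier classes (negated, historical, general, non-definite, metastasis,
recurrence, treatment response) covers it. A report is positive when at
least one linked, unmodified mention survives; all mentions are returned
with 60-character context snippets for semi-manual review, which is the
intended precision lever in deployment.

The shipped lexicons (trigger terms, ~40 tumour terms, ~45 colorectal
sites, ~20 compound terms) are this package's own curation — the original
study's exact supplementary lists are not public — and are plain-text
files under `inst/extdata/lexicons/`, meant to be edited per site. A
mention scoped only by *metastasis* is secondary disease and is excluded;
the primary may still be asserted elsewhere in the report. Known
limitation inherited from the approach: reports implying CRC without
naming it (gene-test supplementaries) stay undetected, and a sentence like
"adenocarcinoma of the caecum with liver metastases" is over-excluded by
the bidirectional metastasis trigger; review of excluded phrases is the
mitigation.

## 3. The synthetic world

`generate_corpus()` emulates exactly the features the rule set is
sensitive to, no more: sectioned pathology (CLINICAL DETAILS / MACROSCOPY /
MICROSCOPY / CONCLUSION) and imaging (TECHNIQUE / FINDINGS / IMPRESSION)
reports; staging phrases rendered in the nine documentation dialects;
look-alike distractors placed where they occur in practice (sequence names
in TECHNIQUE); CRC mentions asserted or wrapped in a sampled modifier
template; implicit-staging prose ("no residual tumour…") with the implied
value recorded as gold but unwritten; and historical phrases under a
"Previously staged as" frame.

Defaults state the emulated world once: 50% pathology, staging information
in 50% of reports, 10% of staging implicit (the order of magnitude behind
the sensitivity losses reported for this method family), 5% historical,
60% CRC-positive, one distractor per report on average, uniform dialect
and modifier mixes. A single integer seed drives one stream; the caller's
RNG state is restored, and equal seeds give byte-identical corpora.

What a green synthetic test establishes: the grammar, guards, scoping and
metric arithmetic behave exactly as specified on every construct the
generator can emit. What it does not establish: performance on real
reports — real prose has misspellings, site-specific templates, richer
negation, and distractors beyond the bank. The generator is a correctness
harness, not a realism claim.

`enumerate_phrase_grammar()` is the deterministic counterpart: every
(category, written value) token under every applicable dialect transform,
paired with its expected parse (738 entries; the count is checked against
an independent closed form). The extractor must recover 100% of it, and
must extract exactly nothing from the distractor bank.

## 4. Evaluation arithmetic

Because a category can take many values, PPV and sensitivity are
*micro-averages*: counts are pooled across value classes before forming
the ratio (`ppv = ΣTP/(ΣTP+ΣFP)`, `sensitivity = ΣTP/(ΣTP+ΣFN)`), while
NPV and specificity are computed against the "no value detected" class
(`npv = TN/(TN+FN_none)`, `specificity = TN/(TN+FP_none)`). After
aggregation to maxima there is exactly one value per report and category,
so pooling over classes and over reports coincide. Undefined ratios (zero
denominator) are reported as missing and printed as "–".

Two scenarios bracket the treatment of non-current staging:
`explicit_only` scores the extractor on its actual contract (historical
retrievals correct, implicit stages not its job); `strict` scores it as a
user wanting current stages would (historical retrieval = false positive,
implicit miss = false negative), using the gold provenance flags.

Confidence intervals are 95% Wilson score intervals with the exact normal
quantile (not 1.96): rounding the quantile is the difference between
reproducing printed intervals to one decimal and missing them. Display
rounding is half-up to one decimal percent. The Wilson implementation is
the closed form; tests check it to 1e-9 against root-finding on the
score-test equality, plus the exact boundary behaviour at 0/n and n/n.

## 5. Numerical and engineering choices

* Spans are 0-based, half-open, in character units, everywhere — one
  convention for reported phrase offsets regardless of language.
* All randomness flows from explicit seeds; `parallel::mclapply` partitions
  reports (which are independent) and reassembles in input order, so worker
  count never changes a byte of output.
* Errors are typed conditions (`crctnm_config_error`,
  `crctnm_validation_error`, `crctnm_io_error`); the CLI maps them to exit
  code 1 and usage problems to 2.
* Degenerate inputs: empty text yields empty results (never an error);
  missing text is normalised to `""` with a warning so corpus size is
  deterministic; an empty trigger lexicon assigns no modifiers; an empty
  tumour lexicon classifies everything negative.

## 6. Known limitations

Explicit stages only; no TNM edition detection; no spell-checking beyond
O-for-zero; lexicon coverage is curated, not site-tuned; singleton values
without a cue are refused even when a human would accept them (precision
over recall, by design); the metastasis trigger can over-exclude primaries
described alongside their metastases. All of these are inspectable through
the phrase/keyword outputs the package retains for review.
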