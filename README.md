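# crctnm

Rule-based extraction of **colorectal cancer (CRC) status** and **explicitly
written TNM stages** from free-text imaging and histopathology reports.

## The problem

TNM staging (T = local tumour extent, N = regional nodal spread, M = distant
metastasis, plus V/L/Pn/R/G and the Kikuchi SM / Haggitt H levels) drives
prognosis and treatment in colorectal cancer, but in electronic health
records it usually lives in free text. Two things make naive pattern
matching fail:

* **Variation in documentation** — the same stage can be written `T1 N0 M0`,
  `T1N0M0`, `T 1 N0M0`, `t1 n0`, `T1/2/3 N0`, `ypT3 N1`, `T1a (solitary
  tumour) N0`, `NO` with a letter O for zero, or as a lone `Staged as T2`.
* **Look-alike false positives** — `T1` is also a T1-weighted MRI sequence
  and the first thoracic vertebra; `L1` is a lumbar level; `10 x 2 mm` and
  dates add more noise.

`crctnm` provides, for research pipelines and data-quality checks:

* `extract_tnm()` — finds staging phrases anywhere in a report, parses all
  the dialects above, rejects look-alikes via context guards, and reports the
  per-report **maximum** value per category (severity ranking: `X` below all
  informative values, `0 < is < 1 < 1a < … < 4d`), plus the supporting
  phrases with spans for review.
* `detect_crc()` — decides whether a report describes *current primary* CRC:
  tumour keywords linked to colorectal sites in-sentence, then ConText-style
  exclusion of mentions that are negated, historical, general, non-definite,
  or scoped to metastasis / recurrence / treatment response
  (`scope_modifiers()`, editable trigger lexicon).
* `generate_corpus()` — a seeded synthetic report generator with exhaustive
  gold (CRC status, per-category maxima, phrase spans, implicit/historical
  flags), so everything is testable without any clinical data.
* `evaluate_tnm()` / `evaluate_crc()` — micro-averaged PPV and sensitivity
  over value classes, NPV and specificity against the "no value detected"
  class, each with 95% Wilson score intervals
  (`wilson_interval()`), under two scenarios (`explicit_only` vs `strict`
  treatment of historical/implicit stages).

## Worked example

```r
library(crctnm)
report <- data.frame(
  report_id = "path-001", report_type = "pathology",
  text = paste("MICROSCOPY: Moderately differentiated adenocarcinoma of the",
               "sigmoid colon. CONCLUSION: R0 ypT3 L0 V1 N1 Mx."))

extract_tnm(report)$values
#>   report_id t_prefix t n m v r l   pn    g   sm    h n_phrases
#> 1  path-001       yp 3 1 X 1 0 0 <NA> <NA> <NA> <NA>         1

detect_crc(report)$status
#>   report_id crc_status n_included n_excluded
#> 1  path-001       TRUE          1          0

round(wilson_interval(94, 100), 3)
#> lower upper
#> 0.875 0.972
```

Reading the TNM row: the report stages a post-treatment (`y`), pathological
(`p`) T3 tumour with one nodal group involved (N1), metastasis not
assessable (MX), venous invasion present (V1), no lymphatic invasion (L0)
and clear resection margins (R0); grade, perineural invasion and the
Kikuchi/Haggitt levels were not reported, so their cells are empty. The CRC
row says one tumour mention survived modifier scoping ("adenocarcinoma"
linked to "sigmoid colon"), so the report describes current primary CRC.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "crctnm", package = "crctnm"))')
Rscript $CLI simulate    --n 1000 --seed 42 --output synth.csv --gold gold.csv
Rscript $CLI extract-tnm --input synth.csv --output tnm.csv [--phrases phrases.csv] [--workers 4]
Rscript $CLI detect-crc  --input synth.csv --output crc.csv
Rscript $CLI evaluate    --pred tnm.csv --gold gold.csv --task tnm --scenario explicit_only --output metrics.csv
```

All subcommands accept `--config cfg.yaml` (e.g. a `tnm:` section overriding
cues, separators, guard terms); outputs are byte-identical across worker
counts.

## Limitations

Only *explicit* stages (letters and numbers) are extracted — staging that is
merely inferable from prose is out of scope by design, as is TNM edition
detection and spell-checking beyond the O-for-zero correction. Grade is
extracted only when written with the letter G. Reports that imply CRC
without naming it (e.g. supplementary mismatch-repair gene-test reports)
are not detected. See `vignettes/crctnm-methods.Rmd` for the full model
description and design rationale.
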