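# entrainr

Neural entrainment and ERP analysis for statistical word-segmentation
EEG experiments, with a built-in synthetic-EEG simulator.

## The problem

A classic probe of statistical learning plays a continuous stream of
consonant–vowel syllables (250 ms each, 4 Hz) in which four trisyllabic
pseudo-words are concatenated semi-randomly: within a word the
syllable-to-syllable transitional probability (TP) is 1, across word
boundaries ≈ 1/3. If a listener — including a sleeping neonate — segments
the stream from the TP drops, the EEG develops a steady-state component
at the word rate (1/0.75 s = 1.333 Hz) on top of the syllable-rate
response (4 Hz). Isolated test triplets (Words A<sub>i</sub>B<sub>i</sub>C<sub>i</sub>,
Edge-words A<sub>i</sub>B<sub>i</sub>C<sub>k</sub>, Part-words
B<sub>i</sub>C<sub>i</sub>A<sub>k</sub>, Non-words
B<sub>i</sub>C<sub>i</sub>A<sub>i</sub>) then reveal *what* was encoded:
an early ERP difference between ABx and BCx triplets indicates
ordinal/first-syllable encoding, a heard-vs-unheard difference indicates
TP memory.

The package is for methodologists and EEG researchers who need this
pipeline as tested, reusable code: stimulus/schedule generation with
audited TP statistics; a controlled simulator so every stage is testable
without infant data; and the analysis stack —

* entrainment: 0.75 s epochs reshaped to 7.5 s (word and syllable rates
  land exactly on FFT bins 10 and 30), DSS denoising (30 PCA / 6 DSS
  components), evoked power, inter-trial coherence
  ITC(f) = |N⁻¹ Σᵢ e^{iφ(f,i)}|, and SNR z-scores against the 12 adjacent
  bins — a log-log power-law fit for power, a plain z-score for ITC —
  plus 120 s sliding-window learning curves;
* group statistics: electrode-wise one-sided t-tests with
  Benjamini–Hochberg FDR, one-way repeated-measures ANOVA with
  Bonferroni post-hocs;
* ERPs: 0.5–20 Hz filtering, [−1.50, 3.25] s epochs, baseline in the
  inter-stimulus silence, and spatio-temporal cluster-based permutation
  tests (paired t threshold α = 0.05, 3 cm electrode adjacency, minimum
  cluster size 2, 5000 within-subject sign-flip permutations, windows
  [0, 0.5] s and [0.5, 2.75] s), with per-block effect time courses.

See `vignettes/entrainment-methods.Rmd` for the full model description
and design rationale.

## Worked example

```r
library(entrainr)

lex <- build_lexicon("A")
lex$words
#> [1] "dinapo" "lutiva" "fobumi" "sazogu"

s <- generate_structured_stream(lex, 180, seed = 1)
audit_stream(s, lex)
#> <stream_audit> 1 stream(s)
#>   word counts:       60 60 60 60
#>   part-word counts:  20 20 20 20 20 20 20 20 20 20 20 19
#>   between-word TP (row-normalized): mean 0.333 sd 0.004 range [0.322, 0.339]
#>   between-word TP (occurrence):     mean 0.332 sd 0.005 range [0.317, 0.333]
```

Each word occurs exactly 60 times; every part-word (the 12 triplets
straddling a word boundary) occurs 18–21 times; and the occurrence-based
mean between-word TP is 0.332 — the audited properties of the published
stimulus set.

```r
sch <- build_session_schedule(lex, seed = 1)    # 128 test events, 8 blocks
mon <- make_montage(32, 6)                      # hemispheric lattice, cm
rec <- simulate_recording(sch, mon, simulation_config(seed = 42))
res <- condition_entrainment(rec, "Structured")
res
#> <spectral_result> Structured: 54 trials, 32 channels; mean SNR(power) word 1.25 / syl 5.43
```

With the default signal model (word-rate component ramping in after
~120 s of structured exposure) the Structured condition shows positive
word-rate SNR; `condition_entrainment(rec, "Random")` shows the syllable
rate only, and resting state neither. `sliding_entrainment()` returns the
learning curve; `cluster_permutation()` tests the ERP contrasts built by
`contrast_spec("abx-bcx")`.

The end-to-end demo (20 simulated subjects, TSV reports plus advisory
figures):

```r
run_demo_cohort(run_config(seed = 1), "demo_out")
```

A command-line interface with `audit`, `simulate`, `entrain`, `erp` and
`demo` subcommands is installed at `inst/cli/entrainr`.

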