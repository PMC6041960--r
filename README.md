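# kanjinet

A dual-pathway connectionist model of reading aloud for two-character
(kanji-like) words, built for researchers studying quasiregular
spelling-to-sound mappings and the semantic contribution to exception-word
reading (surface dyslexia).

The package simulates the full experiment: it generates a synthetic
quasiregular lexicon whose statistics match published two-kanji reading
materials, trains a continuous-time recurrent sigmoid network through a
developmental curriculum, deactivates a fraction of semantic units
(approximating anterior-temporal-lobe disruption), decodes the phonological
output by nearest neighbor, classifies errors (surface / semantic / other),
and tests the lesion × typicality interaction with a repeated-measures
ANOVA.

## Model

Four systems — visual input, phonetic input, semantic, phonetic output —
are fully bidirectionally connected through hidden layers (ventral pathway
via semantics, dorsal pathway via the phonetic input system). Each unit
follows

    s_i = Σ_j w_ji a_j,   x_i(t) = x_i(t-1) + 0.1 (s_i(t) − x_i(t-1)),
    a_i = 1 / (1 + exp(−x_i))

over 20 time steps per trial. Training is online backpropagation through
the unrolled dynamics with cross-entropy error, a zero-error radius of 0.1,
no momentum, weight decay, and error derivatives scaled by the square root
of word frequency. The curriculum runs a preliteracy phase (95% speaking,
5% repetition), freezes the production pathways into the phonetic output
layer, then a literacy phase (30% reading, 60% comprehension, 5% speaking,
5% repetition) with drilling of failed test items after every 2 epochs.

A word's condition is defined by its characters' pronunciation statistics:
*consistent* (single pronunciation), *typical* (both characters given their
most frequent pronunciation), *atypical* (both characters given a
non-modal pronunciation). The friends/neighbors ratio of a test word — the
fraction of same-position orthographic neighbors sharing its pronunciation
— averages 1.00 / 0.71 / 0.33 across the three conditions, as in the
published materials.

## Worked example

```r
library(kanjinet)

# synthetic lexicon: 300 characters, 1200 words, 20 test words per condition
lex <- generate_lexicon(seed = 1)
test_set_stats(lex)
#>    condition  n mean_ratio   sd_ratio mean_log10_freq
#> 2 consistent 20  1.0000000 0.00000000       0.7700367
#> 3    typical 20  0.7095238 0.06715383       0.7696256
#> 1   atypical 20  0.3303436 0.11918332       0.7703783
```

The three condition means reproduce the material statistics (1.00, 0.71,
0.33), and the mean log10 frequency of the 60 test words is 0.77
occurrences per million — low-frequency items, as in the human study.

```r
# one simulation: train, lesion 5% of semantic units 20 times, summarize
cfg <- default_config("desk", seed = 1)
res <- run_experiment(cfg)          # ~15 min for the 5-simulation battery
condition_means(res$summary)        # accuracy per condition x lesion status
res$anova_2x2$effects               # lesion x typicality repeated-measures F
```

`run_experiment()` writes (with `out_dir=`) the lexicon (TSV + JSON), one
checkpoint and training log per simulation, the battery CSV with
per-repetition accuracies and error rates, condition summaries, and the
ANOVA report.

## Command line

```sh
Rscript -e 'kanjinet::knet_main()' generate-lexicon --seed 1 --out runs/demo
Rscript -e 'kanjinet::knet_main()' train --seed 1 --out runs/demo --simulation 1
Rscript -e 'kanjinet::knet_main()' lesion --seed 1 --out runs/demo --fraction 0.05 --reps 20
Rscript -e 'kanjinet::knet_main()' score --seed 1 --out runs/demo
Rscript -e 'kanjinet::knet_main()' run-all --seed 1 --profile desk --out runs/demo
```

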