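# cytofocus

Semantic autofocus simulation and sharpness scoring for liquid-based
cytology (LBC) whole-slide scanning.

## The problem

LBC preparations (e.g. ThinPrep cervical samples stained for p16/Ki-67)
deposit cells inside a 22 mm circle as a thin but genuinely
three-dimensional layer: focus-point heights within one slide span up to
~30 µm, and coverslip dust forms a second, spurious focal plane that
general-purpose contrast autofocus happily locks onto. Multi-layer
(z-stack) scanning works around this at the cost of 15+ layers of data.
The alternative is a *master focus layer*: validate every focus point
semantically (is it actually an in-focus cell?), interpolate only the
valid heights into a focus map, scan a single layer, measure the
resulting sharpness objectively, and re-focus/re-scan what is still
blurry.

`cytofocus` implements that control stack in R, exercised against a
built-in virtual scanner, for scientists studying WSI autofocus
strategies:

* **Virtual slide simulator** — cells on a smooth 3-D focal surface, a
  disjoint dust plane, stain-faithful HSV colors, Gaussian defocus optics
  (`make_virtual_slide()`, `render_at()`, `make_focus_strip()`,
  `make_training_set()`).
* **Focus-point validity filters** — a focus strip is valid iff it has an
  object of at least a small nucleus' area (200 px at native 0.46 µm/px
  resolution), at least one Canny edge (threshold 0.07, σ 1.41), and at
  least 10 object pixels in one of four stain HSV classes
  (`classify_focus_point()`).
* **Slide sharpness scorer** — 4×4 region grid; per region up to 200
  detected cells; five sharpness features per cell (Canny edge count,
  mean gradient, difference to unsharp-masked and to blurred copies, a
  no-reference perceptual blur metric); an RBF-SVM (σ = 1) labels each
  cell in/out-of-focus; region score = % in focus; slide score = mean
  over cell-bearing regions (`train_sharpness_model()`, `score_slide()`).
* **Scan workflow** — detect the cell circle from the macro image, place
  12 focus points, require more than five valid points (≤ 5 focusing
  iterations, escalating 12 → 85 points), scan along the thin-plate
  focus map, score, re-focus out-of-focus regions, at most 7 scan
  rounds, else `not_scannable` (`run_workflow()`, `repeat_scan_cv()`).
* **Z-profile statistics** — dust/cell layer separation, descriptive
  stats, `layers_needed(range, spacing)` arithmetic.
* **Evaluation metrics** — contingency-table sensitivity/specificity/
  accuracy/PPV/NPV and the coefficient of variation.

## Worked example

```r
library(cytofocus)

## a published-style evaluation: metrics straight from counts
classification_metrics(contingency_table(tp = 1086, fn = 21,
                                         fp = 11, tn = 1177))
#> sensitivity specificity    accuracy         ppv         npv
#>    98.10298    99.07407    98.60566    98.99727    98.24708

coefficient_of_variation(c(98.07, 97.51, 97.41, 97.39, 97.15))
#> [1] 0.3506217
layers_needed(29.5, 2)   # z-stack layers a 29.5 um slide would need
#> [1] 15

## the full simulated scan
slide <- make_virtual_slide(seed = 5)          # 500 cells, 21 um surface
model <- train_sharpness_model(make_training_set(100, seed = 21), seed = 1)
session <- run_workflow(virtual_scanner(slide, seed = 5), model,
                        workflow_config(max_cells = 25, seed = 5))
session
#> scan session: completed after 1 focus iteration(s), 1 scan round(s)
#> final slide score: 100.0%

## a sparse slide is honestly refused
sparse <- make_virtual_slide(n_cells = 5, seed = 6)
run_workflow(virtual_scanner(sparse, seed = 6), model,
             workflow_config(seed = 6))
#> scan session: not_scannable after 15 focus iteration(s), 0 scan round(s)
```

A thin CLI wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","cytofocus.R",package="cytofocus"))')" \
    metrics --table 1086 21 11 1177
```

Subcommands: `generate`, `classify-focus`, `train-svm`, `score`,
`simulate-scan`, `zstats`, `metrics`.

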