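# protoseg

One-shot segmentation of brain tumors on single-modality MRI using a single
foreground prototype.

## The problem

Fully supervised tumor-segmentation networks need hundreds of expert-annotated
scans and transfer poorly to unseen classes. `protoseg` implements the
few-shot alternative: a model that segments a *query* scan given only a
handful of annotated *support* slices, trained episodically so that it learns
similarity rather than classes. It targets BraTS-style data — T2-weighted
NIfTI volumes of ~150 slices with integer labels 0/1/2/4 (background,
necrotic core, edema, enhancing tumor), merged into one whole-tumor class —
and ships a synthetic MRI-like volume generator so the entire pipeline is
testable without any external download.

## The method

Support and query slices pass through a shared convolutional encoder
f<sub>θ</sub> producing 256-channel feature grids at 1/8 resolution. Then:

* **Prototype** — masked average pooling over support foreground:
  ρ = Σ<sub>i,j</sub> χ<sup>s</sup>(i,j) η(i,j) / Σ<sub>i,j</sub> η(i,j),
  with η the binary foreground indicator. A single foreground prototype; no
  background prototype is ever formed.
* **Scoring** — scaled negative cosine (anomaly-style):
  R(i,j) = −α cos(χ<sup>q</sup>(i,j), ρ), α = 20. Perfect congruence scores
  −20, incongruence +20.
* **Soft threshold** — M(i,j) = 1 − σ(R(i,j) − β) with a *learned* scalar β;
  M = 0.5 exactly where R = β.
* **Losses** — class-weighted binary cross-entropy (foreground 1.0,
  background 0.2) plus a prototype-alignment regularizer that reverses the
  roles (the predicted query mask builds a query prototype that must segment
  the support): L = L<sub>seg</sub> + λ L<sub>PAR</sub>, λ = 1.
* **Training** — episodic SGD (momentum 0.9, lr 1e-3, 0.97 decay per 1000
  iterations, weight decay 5e-4), one episode per step, support and query
  drawn from the same case but different foreground-bearing slices.
* **Inference** — the median foreground slice of an annotated support scan
  yields one prototype; every slice of the query scan is scored against it
  and binarized at 0.5. Reported metrics: Dice 2|X∩Y|/(|X|+|Y|), IoU,
  precision, pooled in 3-D per scan, aggregated by 5-fold cross-validation.

The encoder is pluggable behind its (256-channel, stride-8) contract; the
built-in compact backbone (three stride-2 3×3 convolutions + a 1×1 projection,
with hand-written backpropagation verified against finite differences) keeps
everything runnable offline on one CPU.

## Worked example

Generate synthetic cases, preprocess them through the published chain
(clip 0.5% → resample to 21 slices → ROI crop → binarize labels →
256×256 standardization), train one-shot, and segment a held-out scan:

```r
library(protoseg)

cfg    <- synth_config()                              # 96x96x150 volumes
cases  <- lapply(1:8, function(i) generate_case(cfg, seed = 100 + i))
stacks <- lapply(cases, function(cs)
  preprocess_case(cs$volume, cs$label, id = cs$id))

fit <- train(stacks[1:6], train_config(iterations = 400, seed = 1))
tail(fit$history[, c("iteration", "l_seg", "l_par", "l_total", "beta")], 3)
#>     iteration       l_seg       l_par    l_total      beta
#> 398       398 0.012294641 0.010593827 0.02288847 -10.12392
#> 399       399 0.014639769 0.009590787 0.02423056 -10.12395
#> 400       400 0.009158262 0.006275881 0.01543414 -10.12398

sup <- stacks[[1]]
si  <- select_support_slice(sup$masks)                # median foreground slice
pred <- segment_query_volume(sup$images[si, , , ], sup$masks[si, , ],
                             stacks[[7]], fit$state)
unlist(compute_metrics(pred, stacks[[7]]$masks))
#>      dice       iou precision
#> 0.9748968 0.9510231 0.9621195
```

`l_total` is exactly `l_seg + λ·l_par` at every logged iteration; `beta`
drifts from its −10 initialization as the threshold is learned. The held-out
scan — all 21 slices, tumor-bearing or not — is segmented from a single
annotated slice of a *different* case; Dice 0.97 reflects the deliberately
separable synthetic contrast, not clinical difficulty (see the methods
vignette).

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/protoseg.R synth --n-cases 10 --seed 1 --out data/
Rscript inst/cli/protoseg.R train --data data/ --iterations 1000 --out run/
Rscript inst/cli/protoseg.R eval  --data data/ --k 5 --out run/eval/
```

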