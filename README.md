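# gaincam

Training a CNN lesion classifier on image labels alone gives it no reason to
look at the lesion: if a tongue depressor or stained teeth co-occur with
"suspicious" cases, the network may classify correctly while attending the
confounder, which is exactly the failure a clinician cannot accept from a
screening tool. **gaincam** implements guided-attention training for binary
lesion classifiers in R: the model's own Grad-CAM attention maps are made
part of the loss, supervised by the annotators' bounding boxes, so the
trained network both classifies and *looks at the right place*. The package
is aimed at researchers who want to study or teach attention-guided training
end to end — it ships its own reverse-mode differentiation engine, a compact
convolutional backbone, a synthetic confounded-lesion benchmark, and
quantitative attention-localization metrics, so every experiment runs on a
single CPU with no external model weights.

## The method

For an input image $I$ with class score $s^c$ and activation maps $f_{l,k}$
at conv layer $l$, the Grad-CAM attention map is

$$w^c_{l,k} = \mathrm{GAP}\!\left(\frac{\partial s^c}{\partial f_{l,k}}\right),
\qquad
A^c = \mathrm{ReLU}\!\left(\textstyle\sum_k w^c_{l,k} f_{l,k}\right),$$

upsampled to the image grid and min–max normalised. Three loss streams share
one set of network weights:

* **Classification** $L_{cl}$: softmax cross-entropy on $I$.
* **Attention mining** $L_{am}$: the attended region is softly erased,
  $I^{*c} = I - T(A^c)\odot I$ with
  $T(A^c) = 1/(1+e^{-w(A^c - \sigma)})$ ($\sigma = 0.20$, $w = 3.0$), and the
  surviving evidence for the true class is pushed to chance,
  $L_{am} = \lvert 0.5 - \sum_c s_c(I^{*c}) \rvert$.
* **Box supervision** $L_{bbox}$: mean squared error between $A^c$ and the
  binarised box mask $H^c$ (all-zero for nonsuspicious images),
  $L_{bbox} = \frac1n \sum_c (A^c - H^c)^2$.

The combined objective is
$L_{total} = \zeta L_{cl} + \alpha L_{am} + \beta L_{bbox}$ with defaults
$\zeta = 0.25$, $\alpha = 0.5$, $\beta = 360$, and the weights are updated
**once per iteration, only after all three streams** (the attention losses
need second-order gradient flow, which the built-in tape provides). Training
is two-stage: stage 1 is conventional SGD classification training (with the
affine augmentation policy and a 10× head learning-rate factor handed down
to 2×); stage 2 is the three-stream architecture at batch size 1.

## Worked example

```r
library(gaincam)

# a 200-image synthetic benchmark whose white "tongue-depressor" bar
# perfectly predicts the label (rho = 1), lesions annotated with boxes
r <- guidance_experiment(seed = 0)

round(c(baseline_acc  = r$baseline$accuracy,
        gain_acc      = r$gain$accuracy,
        baseline_eib  = r$baseline$mean_energy_in_box,
        gain_eib      = r$gain$mean_energy_in_box,
        delta         = r$delta_energy_in_box), 3)
#> baseline_acc     gain_acc baseline_eib     gain_eib        delta
#>        1.000        1.000        0.228        0.701        0.472
```

Both models classify the held-out test split perfectly, but the stage-1
baseline puts only 23% of its attention mass inside the annotated lesion
boxes (it attends the bar), while the guided model puts 70% there — the
guidance effect the method exists for. Individual pieces are available as
ordinary functions (`gradcam()`, `soft_threshold()`, `gain_iteration()`,
`compare_models()`, ...), and a command-line workflow is included:

```sh
Rscript inst/cli/gaincam.R generate --out data --n 200 --rho 1.0 --seed 0
Rscript inst/cli/gaincam.R train --manifest data/manifest.csv --stage both --out run
Rscript inst/cli/gaincam.R evaluate --manifest data/manifest.csv \
  --checkpoints run/checkpoint_stage1.rds,run/checkpoint_gain.rds --out eval
```

`evaluate` writes a comparison table (accuracy, sensitivity, specificity,
energy-in-box, thresholded IoU, pointing-game hit rate) and a side-by-side
attention-overlay panel (input | boxes | one column per model).

## Package layout

| Area | Functions |
| --- | --- |
| Data I/O | `load_manifest`, `write_manifest`, `split_dataset`, `oversample_minority`, `boxes_to_mask` |
| Augmentation | `augment_config`, `sample_transform`, `apply_transform`, `transform_boxes` |
| Attention | `capture_activations`, `neuron_importance`, `attention_map`, `upsample_normalize`, `gradcam` |
| Losses | `soft_threshold`, `apply_softmask`, `attention_mining_loss`, `bbox_loss`, `classification_loss`, `total_loss` |
| Training | `build_classifier`, `stage1_train`, `gain_iteration`, `stage2_train` |
| Synthetic data | `synth_config`, `generate_dataset`, `generate_worked_fixture` |
| Evaluation | `classification_metrics`, `attention_localization`, `localization_report`, `compare_models`, `guidance_experiment` |

The methods vignette (`vignettes/guided-attention.Rmd`) documents the model,
its hyperparameters, the synthetic benchmark's design, and the numerical
choices in detail.
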