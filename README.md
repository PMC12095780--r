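# gisegnet

Deep-learning tools, in R, for finding and classifying abnormalities in
gastrointestinal (GI) endoscopy images. The package implements two methods
end to end on CPU, with synthetic endoscopy-like data generators so that
every stage runs and is testable fully offline:

1. **GISegNet**, an encoder–decoder convolutional segmentation network built
   from parameter-efficient convolution primitives:
   - *asymmetric convolutions* that factor an `n × n` kernel into an
     `n × 1` followed by a `1 × n` kernel — `2n` weights per channel pair
     instead of `n²` (33% fewer at `n = 3`), optionally *atrous* (dilated)
     with per-axis rates so the receptive field grows as
     `[1 + (n−1)aₓ] · [1 + (n−1)a_y]` without extra weights, and optionally
     *depthwise* (per-channel, no channel mixing);
   - **EDR blocks** (Encoder-Decoder-Residual): a 1×1 projection with batch
     normalization and ReLU, two rounds of parallel dense-asymmetric (ACB)
     and depthwise-asymmetric (ADB) branches merged by addition, closed by a
     residual shortcut;
   - the **EHAAC** hybrid attention bottleneck: a spatial gate (ESAM) that
     sums `σ(δⁱ(F)) ⊙ δⁱ(F)` over dilated branches at rates {1, 6, 12, 18},
     a channel gate (ECAM) driven by global average pooling through a
     squeeze–excitation pair of linear maps, and a dilated fusion
     convolution over their sum;
   - a decoder of 2×2-stride transpose convolutions with additive skip
     connections and residual 3×3 refinement, and a 1×1 + sigmoid head.

   The default configuration (256×256×3 input, depth 4, widths
   24/32/71/88) counts exactly **648,457 trainable parameters**. Training
   uses Adam on binary cross-entropy with a reduce-on-plateau learning-rate
   schedule (0.01 down to 1e-5), and pixel metrics (accuracy, precision,
   recall, F1, Dice, IoU) are computed from per-pixel confusion counts.

2. A **hybrid classification pipeline** for the eight GI finding classes:
   pluggable feature extractors honouring the transformer contracts
   (DeiT3/MaxViT/ViT → 768 features, Swin → 1024; deterministic stub
   backbones included so no pretrained weights are ever needed), columnwise
   **feature fusion** (DeiT3+ViT = 1536, DeiT3+Swin = ViT+Swin = 1792, all
   three = 2560), **mRMR feature selection** (greedy
   maximal-relevance/minimal-redundancy ranking with mutual information on
   10 equal-frequency bins), and a **cubic-kernel SVM** (box constraint 1,
   one-vs-one) with stratified k-fold cross-validation.

The network core — dilated/asymmetric/depthwise convolutions, transpose
convolution, max-pooling, batch normalization, reverse-mode automatic
differentiation and Adam — is implemented in this package (Rcpp kernels plus
a small R autodiff tape), because these primitives are the method itself.
Tabular results come back as tibbles with `tidy()`/`glance()`/`autoplot()`
methods.

## Worked example

```r
library(gisegnet)

conv_param_count(kernel_spec(3), decomposed = FALSE)  # 9
conv_param_count(kernel_spec(3), decomposed = TRUE)   # 6  (33% fewer)
effective_receptive_field(kernel_spec(3, a_x = 6, a_y = 12))
#>   height width  area
#> 1     13    25   325

set.seed(1)
build_gisegnet(gisegnet_config())
#> <gisegnet_model> input 256x256x3, depth 4, widths (24, 32, 71, 88), 648,457 parameters

# train a small model on synthetic endoscopy-like scenes
set.seed(7)
tiny <- build_gisegnet(gisegnet_config(input_size = c(64L, 64L, 3L),
                                       depth = 3L, widths = c(4L, 8L, 16L)))
scenes <- gen_seg_arrays(seg_scene_params(n_images = 120, size = 64, seed = 7))
tiny <- train_segmentation(tiny, scenes,
                           train_protocol(epochs = 5, batch = 16,
                                          input = c(64, 64), seed = 7))
tiny$history[, c("epoch", "loss", "dice", "jaccard", "acc")]
#>   epoch  loss  dice jaccard   acc
#> 1     1 0.903 0.275   0.159 0.729
#> 2     2 0.367 0.550   0.380 0.852
#> 3     3 0.277 0.677   0.511 0.889
#> 4     4 0.214 0.759   0.611 0.912
#> 5     5 0.171 0.804   0.672 0.927

mask <- predict_mask(tiny, scenes$images[, , , 1])
seg_metrics(confusion_counts(mask, scenes$masks[, , 1, 1]))
#>     acc  prec   rec    f1  dice  miou
#> 1 0.935 0.621     1 0.766 0.766 0.621
```

Five epochs take the pooled training Dice from 0.28 to 0.80: the network is
learning the lesion geometry, and the per-image report shows the familiar
early-training signature (high recall, precision still catching up). The
classification half composes the same way:

```r
p <- feature_gen_params(n_per_class = 20,
                        dims_per_extractor = c(deit3_base_p16 = 64L,
                                               swin_base_p4w7 = 64L),
                        informative_frac = 0.25, duplicate_frac = 0,
                        class_sep = 3, synergy = TRUE, seed = 41)
sets <- gen_feature_dataset(p)
glance(crossval_accuracy(sets$deit3_base_p16, seed = 1))$accuracy  # 0.644
fused <- fuse(sets$deit3_base_p16, sets$swin_base_p4w7)
glance(crossval_accuracy(fused, seed = 1))$accuracy                # 1
top <- select_features(fused, mrmr_rank(fused, 24))
glance(crossval_accuracy(top, seed = 1))$accuracy                  # 1
```

In fusion-synergy mode one extractor separates only classes 0–3 and the
other only 4–7, so either alone plateaus near 64% while their fusion is
perfect — and mRMR keeps that accuracy with under a fifth of the columns.

A command-line interface wraps the same functions
(`inst/cli/gisegnet gen-data | train-seg | eval-seg | predict |
extract-features | fuse | select | classify | report`); every command
writes a JSON run manifest next to its outputs.

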