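# afmsnet

Attention-augmented 3D encoder-decoder networks for volumetric brain-lesion
segmentation, implemented natively in R with compiled tensor kernels and
exact reverse-mode gradients — no external deep-learning framework. The
package is aimed at methods researchers and engineers who need a fully
inspectable, CPU-testable reference implementation of this family of
architectures: every block, the training loss, and every evaluation metric
is unit-tested against independent scalar-loop oracles, and a seeded lesion
phantom generator stands in for clinical data.

## The model

Two encoder variants share an encoder-decoder backbone (stage widths
doubling from `base_channels`, 3×3×3 max pooling with stride 2 between
stages, transpose-convolution upsampling, and a 1×1×1 softmax head over K
classes):

* **SAEB** — a squeeze-and-excitation channel-attention block:
  conv3×3×3 → BN → global average pooling → 1×1×1 reduce (ratio r) → ReLU →
  1×1×1 restore → **softmax over channels**, giving attention weights
  A with A_c ≥ 0 and Σ_c A_c = 1 that rescale the normalized feature map
  before a final ReLU.
* **DAEB** — dual attention applied in parallel to a conv3×3×3 output T:
  a sigmoid channel map CA ∈ [0,1]^C from the pooled descriptor, and a
  sigmoid spatial map SA ∈ [0,1]^(H×W×D) from a 7×7×7 convolution of the
  concatenated channel-max and channel-mean maps; the output is
  T⊙CA + T⊙SA.
* **SegPath** — skip-connection refinement: n parallel iterations of
  ReLU(BN(conv1×1×1(x))) + ReLU(BN(conv3×3×3(x))), accumulated by addition
  (n = 0 is a plain skip).

Training minimizes the sum of weighted soft Dice,

    L_dice = 1 − (2 Σ_c Σ_i w_c G_ci P_ci + ε) / (Σ_c Σ_i w_c G_ci + Σ_c Σ_i w_c P_ci + ε),

and categorical focal loss,

    L_focal = − Σ_c Σ_i G_ci log(P_ci) (1 − P_ci)^γ,   γ = 1 by default,

with Adam (lr 1e-4) and an L2 weight penalty (5e-4). Evaluation reports
accuracy, precision, recall, DSC, IoU/mIoU and the average Hausdorff
distance at binarization threshold 0.5, per class and per nested region
(WT/TC/ET in the BraTS labeling). See `vignettes/afmsnet-methods.Rmd` for
the full account, including every numerical convention.

## Worked example

```r
library(afmsnet)

# one synthetic 2-channel phantom with a ~7-voxel lesion (4.3% foreground)
spec <- phantom_spec(grid = c(32, 32, 32), n_channels = 2, n_lesions = 1,
                     radii = c(6, 8), nested_factors = 1, noise_sd = 0.1, seed = 7)
rec <- normalize_volume(generate_phantom(spec))
foreground_fraction(rec)
#> [1] 0.04272461

# a miniature dual-attention network
net_spec <- network_spec("DAEB", n_stages = 2, base_channels = 4, n_classes = 2,
                         input_channels = 2, segpath_iterations = c(1, 1))
net <- build_network(net_spec, seed = 1)
net
#> <afms_spec> DAEB, 2 stages, widths 4/8/16, K=2, in=2, segpath=[1,1]
#>   trainable parameters: 16994

net <- train_network(net, list(rec), epochs = 80, lr = 1e-3, target_dsc = 0.95)
h <- attr(net, "history")
tail(h, 1)[, c("epoch", "train_loss", "train_dsc")]
#>   epoch train_loss train_dsc
#>      80      8098.     0.801

evaluate_network(net, list(rec))$macro
#>   unit    dsc_mean iou_mean accuracy_mean precision_mean recall_mean ahd_mean
#>   class_1    0.798    0.664         0.978          0.664       0.999    0.231
```

After 80 epochs the miniature network segments the lesion it was trained on
with DSC 0.80: recall is essentially 1 (every lesion voxel found) while
precision 0.66 shows the remaining error is over-segmentation at the lesion
boundary, the typical early-training signature. The average Hausdorff
distance of 0.23 voxels confirms the predicted boundary sits well under one
voxel from the truth on average. Longer training at the default lr 1e-4
drives the DSC above 0.9 (that run is part of the test suite).

A command-line driver wraps the same functions:

```sh
Rscript inst/cli/afms.R synth   --config run.yaml --out data/
Rscript inst/cli/afms.R train   --config run.yaml --manifest data/manifest.csv --out runs/
Rscript inst/cli/afms.R predict --config run.yaml --checkpoint runs/checkpoint.rds --volume v.nii.gz --out pred/
Rscript inst/cli/afms.R eval    --config run.yaml --checkpoint runs/checkpoint.rds --manifest data/manifest.csv --out eval/
```

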