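# attnmil

Weakly supervised, patient-level benign/malignant classification from
variable-sized bags of grayscale ultrasound-style images, using
dual-attention multiple-instance learning (MIL).

## The problem

An ultrasound examination yields a variable number of 2-D images per
patient, but the diagnostic label (histopathology) exists only per patient:
malignant if **any** nodule was confirmed malignant. Image-level labels are
usually unavailable, so the classifier must learn from bags: patient $i$
contributes a bag $B_i = \{x_{ij}\}_{j=1}^{n_i}$ with one label
$y_i \in \{0,1\}$, under the standard MIL assumption that a positive bag
contains at least one positive instance.

## The model

`attnmil` implements a dual-attention MIL classifier plus the two pooling
baselines it is compared against:

1. a convolutional backbone maps each instance to a spatial feature map
   $h_{ij} \in \mathbb{R}^{C\times H\times W}$ (34-layer residual network at
   production scale, a compact 4-block `tinycnn` for desk-scale work);
2. **spatial attention with residual refinement**: per instance,
   $\Psi_{12} = \mathrm{softmax}(\psi_1(h_{ij})^\top \psi_2(\tilde h_{ij})/\tau)$
   attends from every position to a 2× downsampled key/value map, and the
   context re-enters through a residual,
   $\psi_4(\Psi_{12}\,\psi_3(\tilde h_{ij})) + h_{ij}$;
3. **gated instance attention**: pooled instance vectors $v_{ij}$ are scored
   by $a_{ij} = w_c^\top(\tanh(W_a v_{ij}) \odot \sigma(W_b v_{ij}))$,
   softmax-normalised into weights $\alpha_{ij}$, and aggregated as
   $z_i = \sum_j \alpha_{ij} v_{ij}$;
4. a linear softmax head yields $p_i$, trained with mean cross-entropy on
   bag labels only.

The `meanpool`/`maxpool` baselines share the backbone and classifier and
replace both attention stages with an element-wise mean/max. The attention
weights double as an interpretability channel: `rank_instances()` orders a
patient's images by $\alpha$ and `export_gallery()` writes top/tail image
galleries.

Because no clinical data ship with the package, a synthetic generator
produces speckle-textured nodule cohorts with instance-level ground truth
(benign: smooth bright ellipse; malignant: irregular Fourier-modulated
boundary plus punctate bright spots, brightness-compensated so class is
carried by texture, not intensity). Every stage — layers, attention,
backprop, schedule, splits, metrics — is verified against independent
loop-based oracles and finite differences; see the methods vignette
(`vignettes/dual-attention-mil.Rmd`).

## Worked example

```r
library(attnmil)

# a synthetic cohort written to disk: 60 patients, half malignant
cfg  <- synth_config(n_patients = 60, seed = 1)
coh  <- generate_cohort(cfg, "cohort_demo")
coh$bags
#> <mil_bags> 60 patients (30 malignant), 466 images, bag sizes 3-12

# patient-level stratified split: 10% test, 5 folds on the rest
split_patients(coh$bags, test_frac = 0.1, k = 5, seed = 1)
#> <cohort_split> 60 patients: 6 test, 5 folds (val sizes 12/12/10/10/10); seed 1

# the reference experiment: 200 patients, tinycnn, 30 epochs (~1 min on CPU)
r <- synthetic_benchmark("dual_attention", seed = 1)
glance(r$fit)
#> # A tibble: 1 x 7
#>   variant  backbone epochs best_epoch best_val_auroc final_train_loss fold_index
#>   <chr>    <chr>     <int>      <int>          <dbl>            <dbl>      <int>
#> 1 dual_at~ tinycnn      30         23              1           0.0158          1

r$test_metrics
#> # A tibble: 1 x 10
#>   fold_index auroc auprc sensitivity specificity   ppv   npv threshold n_pos
#>        <int> <dbl> <dbl>       <dbl>       <dbl> <dbl> <dbl>     <dbl> <int>
#> 1         NA     1     1           1           1     1     1       0.5    10

# does the attention point at the right images? (planted ground truth)
r$localization
#> # A tibble: 1 x 3
#>   n_bags precision_at_1 mean_first_malignant_rank
#>    <int>          <dbl>                     <dbl>
#> 1     10              1                         0

r$rankings[[2]]
#> # A tibble: 7 x 6
#>   patient_id  rank instance  alpha image_path instance_label
#>   <chr>      <int>    <int>  <dbl> <chr>               <dbl>
#> 1 P011           1        7 0.547  <NA>                    1
#> 2 P011           2        4 0.260  <NA>                    1
#> 3 P011           3        5 0.114  <NA>                    0
#> 4 P011           4        1 0.0296 <NA>                    0
#> # i 3 more rows
```

`test_metrics` is held-out patient-level discrimination at the 0.5
operating point (this seed separates the 20 test patients perfectly;
across seeds the mean AUROC is ~0.95). The ranking shows the
interpretability channel doing its job: patient P011 has seven images of
which two were planted malignant, and those two receive the top attention
weights (alpha 0.55 and 0.26) — `precision_at_1 = 1` says the top-ranked
image was truly malignant in all ten positive test bags, against a 30%
witness-rate random baseline.

At full benchmark scale (200 patients, 30 epochs, three seeds;
`synthetic_benchmark()`), the dual-attention variant reaches mean held-out
AUROC ≈ 0.95 (≈ 0.99 when re-evaluated on a large fresh cohort), clearly
ahead of mean pooling, and its attention tops a truly malignant image in
≈ 97% of positive test bags (witness-rate random baseline: 30%). Max
pooling is an equally strong bag classifier on this synthetic task — the
planted cue is a single-instance punctate pattern, the regime max
aggregation is built for; see the methods vignette for why that comparison
does not transfer to artifact-prone real data.

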