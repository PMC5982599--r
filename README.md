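# melspect

Dual-modality multispectral reflectance analysis of pigmented skin
lesions: an R package and analysis workflow that discriminates melanomas
from benign nevi using two co-registered camera systems — a 12-bit
silicon CCD imaging eight LED bands from 414 to 995 nm (VIS-NIR,
1280x960 px) and a 16-bit InGaAs camera imaging six bands from 995 to
1613 nm (extended NIR, 320x256 px). The extended-NIR window reaches
deeper skin layers than silicon can see, which is where malignant
structural damage shows up.

It is written for researchers building or evaluating multispectral
skin-imaging pipelines. Patient image archives for this kind of paired
acquisition are not public, so the package includes a phantom generator
that simulates the full acquisition (calibration stacks, sensor noise,
inter-camera misregistration, class-dependent spectra and texture); the
whole chain is exercised and tested end to end on synthetic cohorts.

## Method

Per band, raw digital levels become reflectance against a gray reference
with dark-frame correction,

    R(i,j) = k * (I(i,j) - I_D(i,j)) / (I_N(i,j) - I_D(i,j)),

with the exposure time chosen so the mean digital level sits near half
the dynamic range. Four image variants are analyzed: R, R minus the mean
healthy-skin reflectance, absorbance A = -log10(R), and A minus the mean
skin absorbance. Lesions are segmented by quadrant-wise Otsu
thresholding of the 414 nm image (melanin contrast) and the mask is
transferred to the exNIR grid through a similarity transform.

Each (system, band, variant) image contributes seven first-order
histogram statistics — mean, max, min, population SD, and

    En  = sum_i P(i)^2
    Ep  = -sum_i P(i)^2 log2 P(i)^2
    mu3 = sum_i (i - mu)^3 P(i)^2

over an N = 256 bin in-mask histogram — 392 descriptors in total
(224 VIS-NIR + 168 exNIR). Per-descriptor benign intervals flag
malignancy; rules are ranked by melanomas caught and accumulated
greedily while each addition catches at least one new melanoma. The
selected descriptors are z-scored, decomposed by SVD into principal
components, and a linear soft-margin SVM on the best PC pair yields the
final sensitivity (true-positive rate over melanomas) and specificity
(true-negative rate over nevi).

The methods vignette (`vignettes/melspect-methods.Rmd`) documents the
models, defaults and design choices in detail.

## Worked example

Simulate a 14-lesion cohort and run the full pipeline at 1/8 of the
native camera resolutions:

```r
library(melspect)
out <- run_pipeline(run_config(out_dir = "results/demo",
                               n_nevi = 8, n_melanomas = 6,
                               resolution_scale = 1/8, seed = 42))
print(out$selection)
print(out$classification$report)
```

```
<selection_result: 1 rules accepted, 7 discarded>
  1. VISNIR.477.A.energy                cum. sensitivity 100.0%
<classification_report: TP 6 FN 0 TN 8 FP 0 | sensitivity 100.0%, specificity 100.0%>
```

Reading the output: of the eight shipped interval rules, the 477 nm
absorbance-energy rule alone already flags every planted melanoma on
this synthetic cohort, so the greedy pass discards the rest as
redundant; the PCA+SVM stage on the eight rule descriptors (here PC1 vs
PC2, with PC1 carrying 70% of the variance) separates the two classes
perfectly at the planted 3-sigma class gap — resubstitution figures, so
read them as "the chain recovers the planted signal", not as clinical
performance. The run directory collects every artifact: the descriptor
table (`descriptors.csv`), per-stage JSON reports, PC scores, and a PC
scatter plot with the decision boundary.

The numbered drivers under `analysis/` tell the same story at cohort
scale (39 nevi + 14 melanomas): `01_simulate.R` verifies the planted
spectral contrast (largest nevus-melanoma reflectance gap, 0.135, falls
in the 995-1350 nm window), `02_pipeline_descriptors.R` builds the
392-column descriptor table (segmentation Dice vs truth: 1.000 VIS-NIR,
0.990 exNIR transfer), `03_select_rules.R` compares shipped vs
cohort-fitted interval rules, and `04_classify.R` reports the final
boundary (sensitivity 100.0%, specificity 100.0% at the default planted
gap).

## Layout

```
R/                  package implementation (generator, calibration,
                    segmentation, descriptors, selection, classification,
                    pipeline orchestration)
analysis/           numbered narrative drivers writing under results/
scripts/            acceptance.R (reference-value reproduction)
tests/testthat/     unit, property and acceptance suites
vignettes/          methods vignette
```
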