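Package: noduleGAN
Title: GAN-Augmented Pretraining for Benign/Malignant Pulmonary Nodule
    Classification in CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying generative-adversarial data augmentation in
    small-sample pulmonary nodule classification. Provides a synthetic CT
    phantom generator (smooth benign nodules versus spiculated, optionally
    pleura-attached malignant nodules), volume-of-interest extraction sized
    to twice the nodule diameter, oblique-section and dihedral augmentation,
    a per-class Wasserstein GAN with weight clipping trained by RMSprop, an
    AlexNet-style convolutional classifier with a pretrain-on-generated /
    fine-tune-on-real protocol, and a case-level cross-validated evaluation
    harness with per-class accuracy and ROC/AUC. All networks run on a small
    built-in CPU training engine (im2col convolutions with Rcpp kernels).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
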