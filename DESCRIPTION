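Package: cinescar
Title: Contrast-Free Prediction of Myocardial Scar from Cine Cardiac MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting post-contrast myocardial-infarction information
    from contrast-free cine short-axis cardiac MR. Implements ground-truth
    preparation (trigger-time frame matching and mutual-information affine
    registration of late gadolinium enhancement images onto cine frames),
    engineered motion and texture features (Lucas-Kanade optical flow
    displacement, rate of myocardial area change, 2D shape / first-order / gray
    level run length radiomics with redundancy and significance filtering),
    channel-weighted Dice and class-weighted cross-entropy losses, classical
    classifiers (RBF support vector machine and decision tree) with permutation
    feature importance, a compact trainable UNet plus a canonical ResNet50
    architecture audit, and a synthetic contracting-annulus cine/LGE phantom
    generator so the whole pipeline can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    e1071,
    rpart,
    pROC,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
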