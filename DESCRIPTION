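Package: trajsel
Title: Deep-Learning Classification of Enzyme-Ligand MD Trajectory Descriptors
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Classifies short molecular-dynamics trajectories of
    enzyme-ligand complexes as containing the reactive or the non-reactive
    enantiomer from 15 geometric descriptor time series (distances, angles,
    dihedrals). Provides featurization of multi-model PDB trajectories into
    descriptor tensors, ligand-held-out dataset assembly, 1D/2D convolutional
    and LSTM network architectures with their training regimes implemented
    from first principles, class-activation and Grad-CAM saliency maps,
    per-channel ablation importance, latent-space visualisation by t-SNE,
    and a statistical trajectory emulator for end-to-end testing without an
    MD engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    arrow,
    cluster,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'utils.R'
    'dataset.R'
    'featurize.R'
    'tsne.R'
    'nn-lstm.R'
    'nn-core.R'
    'models.R'
    'interpret.R'
    'io.R'
    'synthetic.R'
    'pipeline.R'
    'trajsel-package.R'
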