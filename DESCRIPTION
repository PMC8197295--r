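Package: spotfts
Title: Snapshot Projection Optical Tomography with Fourier-Transform
    Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational pipeline for hyperspectral three-dimensional
    fluorescence imaging that combines snapshot projection optical
    tomography (SPOT) through a micro-lens array with Fourier-transform
    spectroscopy (FTS). Provides first-principles optics-geometry
    calculators (viewing angles, magnification, field of view,
    diffraction limits), per-pixel interferogram processing (signal
    masking, detrending, envelope centering, Norton-Beer apodization,
    non-uniform Fourier transform) with instrument-line-shape
    diagnostics, multi-view tomographic reconstruction (Richardson-Lucy
    deconvolution, Fourier-slice inverse projection, positivity
    refinement), a forward simulator generating synthetic interferogram
    stacks from labelled phantoms, and TIFF/YAML readers and writers
    with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    tiff,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
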