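Package: nucleoPulse
Title: Simulation and Quantification of Pulsatile Ribosomal-Gene
    Transcription in Nucleolar Image Stacks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying discontinuous (undulating) transcription of
    ribosomal genes in cold-synchronized human cells from 3D fluorescence
    microscopy. Provides a calibrated synthetic-data generator for per-cell
    nucleolar and nucleoplasmic intensity time courses and for confocal-like
    image stacks with ground truth; detection and sub-voxel quantification of
    FC/DFC transcription units (Gaussian fitting, FWHM, chi-square, integral
    intensities in spheres of fixed radii); Otsu-based segmentation of nuclei
    and nucleoli with per-region intensity measurements; and population
    fluctuation statistics (coefficient of variation, Fourier-amplitude
    periodogram on a period grid, dominant period with sampling-interval
    uncertainty, compartment correlation, fold changes, pooled Student's t).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    minpack.lm,
    rlang
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'otsu.R'
    'segmentation.R'
    'detection.R'
    'io.R'
    'kinetics.R'
    'nucleoPulse-package.R'
    'timecourse.R'
    'traces.R'
    'scene.R'
    'pipeline.R'
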