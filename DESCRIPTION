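Package: phenorosette
Title: High-Throughput Salt-Stress Phenotyping of Rosette Plants from
    Top-View Images and Chlorophyll Fluorescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-to-traits pipeline for quantifying early salt-stress
    responses in rosette plants (e.g. Arabidopsis thaliana) phenotyped on
    tray-based platforms.  Turns top-view tray RGB images into per-pot
    binary rosette masks, pixel areas and seven shape traits; builds a
    k-means hue palette from pooled rosette pixels and computes
    area-normalised hue abundances; extracts fluorescence levels (Fo, Fm,
    Fp, Ft, Fm') from pulse-amplitude-modulated chlorophyll-fluorescence
    traces under quenching-kinetics and light-curve protocols and derives
    quantum-yield and quenching parameters (Fv/Fm, PhiP, qP, qL, qN, NPQ,
    PhiNO, PhiNPQ, Rfd); fits two-interval linear growth rates and the
    shoot ion-independent tolerance (SIIT) index; and provides the
    statistical tail (ANOVA with Tukey letters, Mann-Whitney U with
    continuity correction, PCA, Ward clustering of accessions by trait
    profiles).  A synthetic-data generator with exact ground truth
    (rosette masks, hue maps, fluorescence parameters, growth rates)
    makes every stage testable without platform data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
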