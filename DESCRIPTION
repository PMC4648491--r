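Package: smartddpcr
Title: Droplet Digital PCR Assessment of Tumor Preferential Allelic Imbalance
Version: 1.0.0
Authors@R: person("smartddpcr", "developers", role = c("aut", "cre"),
    email = "maintainer@smartddpcr.example.org")
Description: Tools for measuring allelic imbalance (AI) at heterozygous SNP
    loci in tumor DNA with duplexed droplet digital PCR (ddPCR). Provides
    Poisson quantitation of droplet counts, a droplet-well simulator driven
    by mixtures of tumor clones, calibration of three-sigma AI thresholds
    from constitutional heterozygotes, an exact binomial test for
    preferential allelic imbalance (PAI), classification of the somatic
    copy state underlying AI (homozygous/hemizygous deletion, copy-neutral
    LOH, hyperdiploid gain) with clonal-fraction estimation, method
    agreement statistics (Lin's concordance correlation and Bland-Altman),
    and a scanner that intersects recurrent somatic copy-number alteration
    peaks with GWAS-catalog SNPs to nominate candidate PAI loci.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
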