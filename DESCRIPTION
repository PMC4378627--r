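Package: lipidremodel
Title: Targeted Glycerolipidomics of Phosphorus-Starvation Lipid Remodeling
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for targeted UPLC-MS glycerolipid profiling
    of phosphorus-starvation lipid remodeling. Implements library-based peak
    annotation with ppm mass tolerance and marker-based retention-time
    correction, isomer collapse into isobaric species, coefficient-of-
    variation-based normalization, quantification at the class, acyl-carbon
    group and species levels, triacylglycerol acyl-chain composition from
    all-ion-fragmentation scans, ANOVA and pairwise t-tests with compact
    letter displays, qPCR 40-minus-delta-CT expression analysis, and P1BS
    (GNATATNC) motif scanning of gene models. Ships a synthetic-data
    generator with planted ground truth emulating a two-organ, two-condition,
    multi-genotype study design, used for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
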