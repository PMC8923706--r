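Package: sexmarker
Title: Sex-Determination System Inference and Sex-Marker Design from
    Reduced-Representation Tags and Pooled Resequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers a species' genetic sex-determination system (XX/XY
    versus ZZ/ZW) from per-individual type-IIB restriction (2b-RAD) tag
    sets, screens male/female pooled resequencing variants for sex-biased
    SNP and InDel sites using GATK-style hard filters plus a pooled
    allele-frequency rule (homogametic pool homozygous, heterogametic
    pool heterozygous near 1:1), and designs and validates in silico
    allele-specific InDel PCR markers with a dominant presence/absence
    band. Ships a diploid population simulator that plants sex-linked and
    autosomal variants so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
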