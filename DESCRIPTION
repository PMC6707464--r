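Package: ychron
Title: Y-Chromosome Lineage Dating with the Rho Statistic
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dating splits in the human Y-chromosome phylogeny from
    jointly called haploid genotypes. Implements outgroup-based ancestral-allele
    polarization, per-sample branch-length calibration to correct
    haplogroup-specific mutation-accumulation heterogeneity, rho-statistic split
    time estimation with mutation-rate HPD confidence intervals, placement of
    query lineages by exclusive versus shared derived SNP profiles with
    recurrent-mutation flagging, and out-of-Africa migration-window arithmetic
    (lineage extancy timelines, faster-rate rescaling, introgression-date
    intersection). A synthetic genealogy and genotype simulator generates VCF
    call sets with known truth for validation, and a config-driven pipeline
    orchestrates the full analysis reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
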