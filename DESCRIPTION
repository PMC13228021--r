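Package: strainvar
Title: Comparative Genomic and Phenotypic Analysis of Yeast Strains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for strain-comparative genomics of
    Saccharomyces cerevisiae from short-read derived summaries: ploidy
    inference from allele-fraction modes at heterozygous sites,
    coverage-based whole-chromosome aneuploidy and segmental copy-number
    calling, loss-of-heterozygosity (LOH) segmentation with
    interstitial/terminal/uniparental-disomy classification and a
    mitotic-versus-meiotic positional statistic, SNV-based divergence-time
    estimation, detection of additional (horizontally acquired) genes by
    global-alignment percent identity, and phenotype-fermentation
    correlation analysis. A synthetic-genome simulator with full ground
    truth emits every input format the pipeline consumes, enabling
    parameter-recovery testing without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
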