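Package: aerotype
Title: Stratified Rate-Yield Fitness Landscapes from Proteome Allocation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained proteome-allocation model of Escherichia coli
    energy metabolism and the analysis pipeline around it: in-silico strain
    sampling over a temperature sweep, ATP-production accounting (including
    the fraction of ATP made by ATP synthase, f_ATPS), Gaussian-mixture
    fitting of the multimodal f_ATPS distribution, aero-type and nitro-type
    classification, electron-transport-chain knockout and nitrate
    experiments, rate-yield landscape statistics, and downstream expression
    statistics (TPM normalisation, phenotype-correlated gene selection,
    binomial enrichment, hierarchical clustering). Synthetic-data
    generators make every stage runnable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot,
    cluster,
    withr
Config/testthat/edition: 3
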