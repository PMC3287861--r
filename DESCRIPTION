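Package: kernelGxE
Title: Kernel Machine Tests for Gene-Environment Interaction in Gene-Based
    Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Gene-based association testing of quantitative traits with the
    least-squares kernel machine (LSKM). Builds polynomial, Gaussian and
    identity-in-state (IIS) similarity kernels over SNP sets, assembles six
    model formulations (baseline, burden-collapsed, interaction-only and joint
    gene-environment designs, with principal-component adjustment for
    population stratification), and tests the variance component H0: tau = 0
    with a score statistic whose null distribution is approximated by
    Satterthwaite moment matching, backed by an exact weighted-chi-square
    Monte Carlo oracle. Includes a GAW17-style simulator (rare variants,
    latent subpopulations, replicated phenotypes with a single
    gene-by-smoking interaction), a per-gene scan driver, Q-Q summaries with
    null confidence bands, empirical power tables and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation
Config/testthat/edition: 3
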