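Package: TriangulateMR
Title: Multi-Omics Triangulation of Drug Targets by Mendelian Randomization
        and Colocalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
        role = c("aut", "cre"))
Description: Tools for prioritizing plasma-protein and tissue-expression drug
        targets from GWAS and QTL summary statistics. Implements genetic
        instrument construction (cis-window restriction, greedy LD clumping,
        F-statistic filtering), a two-sample Mendelian randomization estimator
        suite with a full sensitivity battery (Wald ratio, inverse-variance
        weighting, MR-Egger, Cochran's Q, Steiger directionality, MR-PRESSO),
        DerSimonian-Laird meta-analysis across proteomic studies with
        Benjamini-Hochberg FDR control, Wakefield approximate-Bayes-factor
        colocalization for two traits and configuration-enumeration
        colocalization for three traits, phenome-wide mediation MR, a
        simplified bivariate LD score regression, and a staged filtration
        funnel that combines all of the above. A synthetic summary-statistic
        generator under the regression-with-summary-statistics model makes the
        whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), metafor, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
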