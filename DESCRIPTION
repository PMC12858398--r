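Package: screenselect
Title: Differential Drug-Sensitivity Meta-Analysis and Co-IP Interactome Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify lineage-selective compounds from multi-screen
    drug-sensitivity panels and to score protein interactomes from co-IP
    mass-spectrometry experiments. The screen pipeline fits log-logistic
    dose-response curves per cell line and compound, summarises each curve by
    the area above the curve (AAC), contrasts a target lineage against a
    background panel with a signed Wilcoxon rank-sum effect size, combines
    screens by a weighted meta-analysis that downweights screens with
    ineffective concentration windows, and tests compound-target sets with a
    permutation enrichment statistic. The proteomics pipeline quantile
    normalises protein intensities, classifies missing values as left-censored
    (MNAR) or random (MAR) by a detected-replicate rule, imputes them with a
    MinProb/maximum-likelihood mixture, fits an empirical-Bayes moderated t
    per protein, and downweights common contaminants with an average
    background-binding table. A synthetic-data module generates screen panels
    and intensity matrices with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea
Config/testthat/edition: 3
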