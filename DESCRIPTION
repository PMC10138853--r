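Package: svyconc
Title: Concentration-Index Inequality Analysis and Decomposition for Complex Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring and explaining socioeconomic inequality in
    binary health outcomes from stratified, clustered, weighted surveys.
    Ranks respondents by an ordinal equity stratifier (for example women's
    empowerment tertiles) using tie-aware weighted fractional ranks, computes
    the standard and Erreygers-normalized concentration indices with
    design-based (Taylor-linearized or cluster-bootstrap) uncertainty,
    draws concentration curves, and decomposes the Erreygers index into
    per-covariate elasticities, covariate concentration indices and percent
    contributions via a survey-weighted binomial-logit model with marginal
    effects. Includes preparation helpers for pooled multi-survey data
    (per-survey weight rescaling, distinct design identifiers, recoding of
    missing responses), SWPER-style empowerment-domain scoring from
    configurable loadings, and a synthetic two-stage stratified
    cluster-sample generator with enumerable ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    foreign
Config/testthat/edition: 3
RoxygenNote: 7.3.3
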