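Package: precda
Title: Predicting Candidate Disease-Related Circular RNAs by Network Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts candidate disease-related circular RNAs (circRNAs) by
    fusing circRNA expression similarity (Spearman rank correlation across
    cell types and tissues, max-combined over two expression sources and
    thresholded) with circRNA functional similarity (cosine similarity of
    disease-association score vectors built from a disease-disease similarity
    matrix) into a weighted heterogeneous circRNA-disease network, then
    ranking circRNAs per disease with the PersonalRank random walk with
    restart. Includes a cross-database hold-out validation scheme with
    per-disease ROC AUC, a threshold sweep, a cosine-only ablation, and a
    seeded synthetic-data generator with planted co-expression and
    co-disease modules so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
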