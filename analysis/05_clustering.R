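#!/usr/bin/env Rscript

# Stage 5: model-based clustering without population labels.
#
# Clusters the four-population colony means on the leading principal
# components explaining 95% of the variance, selecting the component
# count and covariance family by BIC, then cross-tabulates the chosen
# clusters against the (withheld) population labels.

library(wingmorph)

out <- file.path("results", "clustering")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cm <- utils::read.csv(file.path("results", "aligned",
                                "world_colony_means.csv"))
shape_cols <- grep("^[xy][0-9]+$", names(cm), value = TRUE)
pca <- shape_pca(as.matrix(cm[, shape_cols]))
m95 <- variance_threshold_components(pca$eigenvalues, 0.95)
message(sprintf("%d components explain 95%% of the variance", m95))

best <- select_model_bic(pca$scores[, seq_len(m95)], K_range = 1:9,
                         seed = 107)
utils::write.csv(best$bic_table, file.path(out, "bic_table.csv"),
                 row.names = FALSE)
message(sprintf("BIC selects K = %d (%s family)", best$K, best$family))

comp <- cluster_composition(best, cm$population)
write_matrix_csv(comp$counts, file.path(out, "composition.csv"))
message(sprintf("agreement with withheld population labels: %.3f",
                cluster_agreement(max.col(best$responsibilities),
                                  cm$population)))
print(comp$counts)
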