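#!/usr/bin/env Rscript

# Stage 4: geographic variation within one population.
#
# On the Mexico-like dataset: multivariate regression of colony-mean
# shape on latitude and longitude with residual-randomization permutation
# tests (latitude first, as the dominant axis of the generating
# gradient), and a regional discriminant comparison after splitting the
# latitude range into south / middle / north thirds. Also demonstrates
# transect chunking: single wings pooled into 10-wing samples along the
# dominant geographic axis.

library(wingmorph)

out <- file.path("results", "geography")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cm <- utils::read.csv(file.path("results", "aligned",
                                "mexico_colony_means.csv"))
shape_cols <- grep("^[xy][0-9]+$", names(cm), value = TRUE)
shapes <- as.matrix(cm[, shape_cols])

reg <- regress_shape_rrpp(shapes, cm[, c("latitude", "longitude")],
                          n_perm = 999, seed = 105)
utils::write.csv(reg$aov_table, file.path(out, "regression.csv"),
                 row.names = FALSE)
print(reg)

pca <- shape_pca(shapes, m_retain = 34)
conf <- loocv_lda(pca$scores, cm$region)
write_matrix_csv(conf$counts, file.path(out, "region_confusion.csv"))
message(sprintf("regional LOOCV success: %s",
                paste(sprintf("%s %.1f%%", conf$labels,
                              100 * conf$per_class_accuracy),
                      collapse = ", ")))

# transect chunking demo on single-wing collections
transect <- simulate_dataset(synthetic_config(
  n_populations = 1, colonies_per_population = 177, workers_per_colony = 1,
  lat_range = c(-35, -25), lon_range = c(-63, -58), seed = 106))
chunks <- chunk_transect(transect$dataset, 10)
message(sprintf("177 single wings -> %d samples; final sample has %d wings",
                length(unique(chunks)), min(table(chunks))))
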