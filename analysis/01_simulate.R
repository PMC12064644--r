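#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study datasets.
#
# Three datasets emulate the sampling designs the analysis supports:
#   mexico.csv  - one population sampled as colonies along a latitude
#                 gradient (12 workers per colony), for the
#                 shape-on-geography regression and regional comparison;
#   world.csv   - four diverged populations (colonies of 12), for
#                 discriminant classification, Mahalanobis distances,
#                 PCoA and clustering;
#   reference.csv - four widely separated populations standing in for
#                 the evolutionary lineages A, C, M and O, used to build
#                 the lineage reference panel.
# All are reproducible from the seeds written alongside.

library(wingmorph)

out <- file.path("results", "data")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

mexico <- simulate_dataset(synthetic_config(
  n_populations = 1, colonies_per_population = 245, workers_per_colony = 12,
  latitude_gradient = 0.01, lat_range = c(17, 19), lon_range = c(-94, -91),
  seed = 101))
write_landmarks_csv(mexico$dataset, file.path(out, "mexico.csv"))
message(sprintf("mexico.csv: %d wings, %d colonies",
                n_specimens(mexico$dataset),
                length(unique(mexico$dataset$meta$colony_id))))

world <- simulate_dataset(synthetic_config(
  n_populations = 4, colonies_per_population = 40, workers_per_colony = 12,
  pairwise_D = 7, seed = 102))
write_landmarks_csv(world$dataset, file.path(out, "world.csv"))
message(sprintf("world.csv: %d wings across %d populations",
                n_specimens(world$dataset), 4))

reference <- simulate_dataset(synthetic_config(
  n_populations = 4, colonies_per_population = 47, workers_per_colony = 10,
  pairwise_D = 8, latitude_gradient = 0, seed = 103))
write_landmarks_csv(reference$dataset, file.path(out, "reference.csv"))
message(sprintf("reference.csv: %d wings for the synthetic lineage panel",
                n_specimens(reference$dataset)))
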