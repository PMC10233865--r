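#!/usr/bin/env Rscript
# Stage 4: target expansion. Retrain node2vec on the full three-layer
# DS-CX-drug dataset, score every chemical-target non-edge, keep prediction
# values >= 0.5, restrict to herbal-chemical -> drug-target pairs, and
# tabulate the expansion report (new edges and newly covered chemicals per
# category, with expansion percentages).

suppressPackageStartupMessages(library(hetlink))
seed <- 1L
indir <- "results/net_tiny"

meta <- read_node_meta(file.path(indir, "nodes.tsv"))
layers <- list(
  CTC = read_edges_tsv(file.path(indir, "ctc_edges.tsv")),
  CCC = build_ccc_layer(read_fingerprints(file.path(indir, "fingerprints.tsv"))),
  PPI = build_ppi_layer(read_edges_tsv(file.path(indir, "ppi_pairs.tsv")),
                        meta = meta))
g <- assemble_dataset(layers, meta, spec = dataset_spec("DS-CX-drug"))

out <- run_predict(g, "node2vec", threshold = 0.5,
                   params = node2vec_params(dims = 64, epochs = 2),
                   seed = derive_seed(seed, "predict"), group = "DS-CX-drug")

cat(sprintf("retained %d predicted edges (>= 0.5), %d herbal-chemical -> drug-target\n",
            nrow(out$predictions), nrow(out$herbal_predictions)))
print(out$report, row.names = FALSE)

write_results_tsv(out$predictions[, c("chemical_id", "target_id",
                                      "prediction_value", "group")],
                  "results/predicted_edges.tsv", seed = seed)
jsonlite::write_json(out$report, "results/expansion_report.json",
                     dataframe = "rows", auto_unbox = TRUE, digits = NA)
cat("wrote results/predicted_edges.tsv and results/expansion_report.json\n")
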