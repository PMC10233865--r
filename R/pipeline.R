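# Stage drivers tying the modules together with a single master seed.
# Each stage derives its own sub-seed from (master seed, stage name), so
# stages are independently reproducible, and every output file carries the
# master seed in its comment header.

#' Derive a stage seed from the master seed
#'
#' Deterministic fan-out: each (stage, index) pair maps to its own 31-bit
#' seed so stages can be rerun in isolation.
#'
#' @param master integer master seed.
#' @param stage stage name.
#' @param index optional per-item index within the stage.
#' @return integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master, stage, index = 0L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 2654435) %% 2147480009 + h * 97 + index) %%
    2147483647L
}

#' Simulate a network and write it to disk
#'
#' @param config a [generator_config()].
#' @param outdir output directory.
#' @return the simulation list, invisibly (files under `outdir`).
#' @export
run_simulate <- function(config, outdir) {
  sim <- generate_hetnet(config)
  write_hetnet(sim, outdir)
  invisible(sim)
}

#' The three nested dataset graphs for one node population
#'
#' @param layers named list of `CTC`, `CCC`, `PPI` edge tables.
#' @param meta node metadata.
#' @param group optional group label (see [dataset_spec()]); `NULL` keeps
#'   all nodes.
#' @return named list of three `hetgraph`s: `CTC`, `CTC+CCC`, `CTC+CCC+PPI`.
#' @export
nested_datasets <- function(layers, meta, group = NULL) {
  specs <- list(`CTC` = c("CTC"),
                `CTC+CCC` = c("CTC", "CCC"),
                `CTC+CCC+PPI` = c("CTC", "CCC", "PPI"))
  lapply(specs, function(ls) {
    sp <- if (is.null(group)) NULL else dataset_spec(group, ls)
    assemble_dataset(layers[ls], meta, spec = sp)
  })
}

#' Evaluate an algorithm grid over datasets
#'
#' Runs [cross_validate()] for every (dataset, algorithm) cell and collects
#' the per-round and mean AUROC/AP scores.
#'
#' @param datasets named list of `hetgraph`s.
#' @param algorithms character vector of algorithm names.
#' @param spec a [split_spec()] (its seed is re-derived per cell so cells
#'   are independently reproducible).
#' @param params named list of per-algorithm parameter objects (optional).
#' @return list with `summary` (one row per cell: mean AUROC/AP) and
#'   `folds` (one row per cell and round).
#' @export
run_evaluate_grid <- function(datasets, algorithms = ALGORITHMS,
                              spec = split_spec(), params = list()) {
  bad <- setdiff(algorithms, ALGORITHMS)
  if (length(bad)) stop("unknown algorithm(s): ", paste(bad, collapse = ", "),
                        "; valid: ", paste(ALGORITHMS, collapse = ", "))
  summary <- folds <- list()
  for (ds in names(datasets)) {
    for (alg in algorithms) {
      cell_spec <- spec
      cell_spec$seed <- derive_seed(spec$seed, paste0(ds, "/", alg))
      res <- cross_validate(datasets[[ds]], alg, cell_spec,
                            params = params[[alg]])
      summary[[length(summary) + 1L]] <- data.frame(
        dataset = ds, algorithm = alg,
        mean_auroc = res$mean_auroc, mean_ap = res$mean_ap,
        stringsAsFactors = FALSE)
      folds[[length(folds) + 1L]] <- data.frame(
        dataset = ds, algorithm = alg, fold = seq_along(res$per_fold_auroc),
        auroc = res$per_fold_auroc, ap = res$per_fold_ap,
        stringsAsFactors = FALSE)
    }
  }
  list(summary = do.call(rbind, summary), folds = do.call(rbind, folds))
}

#' Write a results table as TSV with a seed-bearing comment header
#'
#' @param df data frame.
#' @param path output path.
#' @param seed master seed recorded in the header.
#' @export
write_results_tsv <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%d", as.integer(seed)), con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df)) {
    rows <- apply(df, 1L, function(r) paste(
      vapply(r, function(x) {
        if (is.na(suppressWarnings(as.numeric(x)))) as.character(x)
        else formatC(as.numeric(x), format = "g", digits = 12)
      }, ""), collapse = "\t"))
    writeLines(rows, con)
  }
  invisible(path)
}

#' End-to-end target expansion on one dataset
#'
#' Retrains the chosen algorithm on the full dataset graph (all edges; no
#' held-out split), predicts new edges at the prediction-value cut, filters
#' to herbal-chemical/drug-target pairs and tabulates the expansion report.
#'
#' @param graph the full dataset `hetgraph`.
#' @param algorithm algorithm name (index scorers are calibrated so their
#'   scores read as probabilities).
#' @param threshold prediction-value cut.
#' @param candidates candidate universe (see [predict_new_edges()]).
#' @param params optional algorithm parameters.
#' @param seed master seed for embedding training and negative sampling.
#' @param group optional group label copied onto records.
#' @return list with `predictions`, `herbal_predictions` and `report`.
#' @export
run_predict <- function(graph, algorithm = "node2vec", threshold = 0.5,
                        candidates = "chem-target", params = NULL,
                        seed = 1L, group = NA_character_) {
  # labeled training pairs: all edges as positives plus matched negatives
  pos <- graph$edges[, c("u", "v")]
  neg <- with_local_seed(derive_seed(seed, "negatives"),
                         sample_nonedges(graph, nrow(pos), "any", character(0)))
  train_pairs <- data.frame(u = c(pos$u, neg$u), v = c(pos$v, neg$v),
                            label = c(rep(1L, nrow(pos)),
                                      rep(0L, length(neg$u))),
                            stringsAsFactors = FALSE)
  if (algorithm == "node2vec") {
    if (is.null(params)) params <- node2vec_params()
    params$seed <- derive_seed(seed, "embedding")
  }
  scorer <- suppressWarnings(
    train_scorer(graph, algorithm, train_pairs = train_pairs, params = params,
                 calibrate = !algorithm %in% c("node2vec", "SC")))
  predictions <- predict_new_edges(graph, scorer, threshold = threshold,
                                   candidates = candidates, group = group)
  herbal <- filter_herbal_to_drugtarget(predictions, graph$nodes)
  list(predictions = predictions, herbal_predictions = herbal,
       report = expansion_report(graph, predictions))
}
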