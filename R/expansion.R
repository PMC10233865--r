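# Target expansion: retrain the chosen scorer on the full dataset graph,
# score candidate non-edges, keep those at or above the prediction-value
# cut (0.5 by default), restrict to herbal-chemical -> drug-target pairs,
# and tabulate expansion counts and percentages.

#' Predict new edges on the full graph
#'
#' Scores candidate non-edges with a probability-type scorer and retains
#' those with prediction value at or above the threshold. The default
#' candidate universe is chemical-target pairs (the connections analyzed
#' downstream); `candidates = "all"` also scores chemical-chemical and
#' target-target non-edges for total-edge accounting.
#'
#' @param graph the full dataset `hetgraph` the scorer was trained on.
#' @param scorer a probability-type `edge_scorer` (classifier-backed, or an
#'   index scorer trained with `calibrate = TRUE`).
#' @param threshold prediction-value cut in `(0, 1)`.
#' @param candidates `"chem-target"` or `"all"`.
#' @param group optional group label copied onto the records.
#' @return `data.frame` with columns `chemical_id`, `target_id` (`NA` for
#'   non-chemical-target pairs), `u`, `v`, `pair_type`, `prediction_value`,
#'   `group`, sorted by decreasing prediction value.
#' @export
predict_new_edges <- function(graph, scorer, threshold = 0.5,
                              candidates = c("chem-target", "all"),
                              group = NA_character_) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("config error: threshold must lie in (0, 1)")
  }
  candidates <- match.arg(candidates)
  if (!scorer$algorithm %in% c("node2vec", "SC") && !isTRUE(scorer$calibrated)) {
    stop("scorer must produce probabilities; calibrate index scorers first")
  }
  role <- stats::setNames(graph$nodes$role, graph$nodes$node_id)
  chems <- graph$nodes$node_id[graph$nodes$role == "chemical"]
  targs <- graph$nodes$node_id[graph$nodes$role == "target"]
  if (candidates == "chem-target") {
    cand <- expand.grid(u = chems, v = targs, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  } else {
    ids <- graph$nodes$node_id
    i <- utils::combn(length(ids), 2L)
    cand <- data.frame(u = ids[i[1, ]], v = ids[i[2, ]],
                       stringsAsFactors = FALSE)
  }
  cand <- cand[!(pair_key(cand$u, cand$v) %in%
                   pair_key(graph$edges$u, graph$edges$v)), , drop = FALSE]
  if (!nrow(cand)) {
    return(data.frame(chemical_id = character(), target_id = character(),
                      u = character(), v = character(),
                      pair_type = character(), prediction_value = numeric(),
                      group = character(), stringsAsFactors = FALSE))
  }
  pv <- predict(scorer, cand)
  keep <- pv >= threshold
  cand <- cand[keep, , drop = FALSE]
  pv <- pv[keep]
  ru <- role[cand$u]; rv <- role[cand$v]
  ptype <- ifelse(ru != rv, "chem-target",
                  ifelse(ru == "chemical", "chem-chem", "target-target"))
  chem <- ifelse(ptype == "chem-target",
                 ifelse(ru == "chemical", cand$u, cand$v), NA_character_)
  targ <- ifelse(ptype == "chem-target",
                 ifelse(ru == "chemical", cand$v, cand$u), NA_character_)
  out <- data.frame(chemical_id = chem, target_id = targ,
                    u = cand$u, v = cand$v, pair_type = ptype,
                    prediction_value = pv, group = group,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$prediction_value, out$u, out$v), , drop = FALSE]
  rownames(out) <- NULL
  out
}

is_herbal <- function(origins) {
  vapply(strsplit(origins, ";", fixed = TRUE),
         function(s) any(s %in% c("DS", "CX")), logical(1))
}

is_drug_tagged <- function(origins) {
  vapply(strsplit(origins, ";", fixed = TRUE),
         function(s) "drug" %in% s, logical(1))
}

#' Keep only herbal-chemical to drug-target predictions
#'
#' Retains chemical-target records whose chemical carries a herb origin
#' (`DS` and/or `CX`) and whose target is a drug target (origin includes
#' `drug`).
#'
#' @param records prediction records from [predict_new_edges()].
#' @param meta node metadata covering all record endpoints.
#' @return the filtered records.
#' @export
filter_herbal_to_drugtarget <- function(records, meta) {
  if (!nrow(records)) return(records)
  ct <- records[records$pair_type == "chem-target", , drop = FALSE]
  miss <- setdiff(unique(c(ct$chemical_id, ct$target_id)), meta$node_id)
  if (length(miss)) stop("unknown node(s) in records: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  orig <- stats::setNames(meta$origins, meta$node_id)
  keep <- is_herbal(orig[ct$chemical_id]) & is_drug_tagged(orig[ct$target_id])
  out <- ct[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

expansion_pct <- function(expanded, original) {
  if (original == 0) stop("expansion percentage undefined: zero original count")
  round(100 * expanded / original, 2)
}

#' Expansion accounting from precomputed counts
#'
#' @param categories `data.frame` with columns `category`, `original`,
#'   `expanded`.
#' @return same table with an `expansion_pct` column,
#'   `round(100 * expanded / original, 2)`.
#' @export
expansion_report_from_counts <- function(categories) {
  categories$expansion_pct <- mapply(expansion_pct, categories$expanded,
                                     categories$original)
  categories
}

herbal_drugtarget_ctc_count <- function(graph) {
  role <- stats::setNames(graph$nodes$role, graph$nodes$node_id)
  orig <- stats::setNames(graph$nodes$origins, graph$nodes$node_id)
  e <- graph$edges[graph$edges$layer == "CTC", , drop = FALSE]
  if (!nrow(e)) return(0L)
  chem <- ifelse(role[e$u] == "chemical", e$u, e$v)
  targ <- ifelse(role[e$u] == "chemical", e$v, e$u)
  sum(is_herbal(orig[chem]) & is_drug_tagged(orig[targ]))
}

#' Expansion report for one dataset
#'
#' Tabulates, per category, the original count in the graph, the expanded
#' (newly predicted) count, and the expansion percentage: total edges (any
#' retained prediction), herbal-chemical-drug-target edges, total chemical
#' nodes (chemicals gaining at least one predicted chemical-target edge)
#' and herbal chemical nodes (herbal chemicals gaining at least one
#' herbal-to-drug-target edge).
#'
#' @param graph the original dataset `hetgraph`.
#' @param predictions retained records from [predict_new_edges()].
#' @param meta node metadata (defaults to the graph's node table).
#' @return `data.frame` with columns `category`, `original`, `expanded`,
#'   `expansion_pct`.
#' @export
expansion_report <- function(graph, predictions, meta = graph$nodes) {
  herb_pred <- filter_herbal_to_drugtarget(predictions, meta)
  ct_pred <- predictions[predictions$pair_type == "chem-target", , drop = FALSE]
  chems <- meta$node_id[meta$role == "chemical"]
  herb_chems <- chems[is_herbal(meta$origins[match(chems, meta$node_id)])]
  counts <- data.frame(
    category = c("total_edges", "herbal_chemical_drug_target_edges",
                 "total_chemical_nodes", "herbal_chemical_nodes"),
    original = c(nrow(graph$edges),
                 herbal_drugtarget_ctc_count(graph),
                 length(chems),
                 length(herb_chems)),
    expanded = c(nrow(predictions),
                 nrow(herb_pred),
                 length(unique(ct_pred$chemical_id)),
                 length(unique(herb_pred$chemical_id))),
    stringsAsFactors = FALSE)
  expansion_report_from_counts(counts)
}
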