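#' @useDynLib hetlink, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

LAYERS <- c("CTC", "CCC", "PPI")
GROUPS <- c("DS-drug", "CX-drug", "DS-CX-drug")

#' Node metadata table
#'
#' Builds the per-node metadata table used throughout the pipeline. Each node
#' is either a chemical (a small molecule) or a target (a protein), and
#' carries a non-empty set of origin tags: `DS` (Salvia miltiorrhiza, Danshen)
#' or `CX` (Ligusticum chuanxiong, Chuanxiong) for herbal provenance, and
#' `drug` for approved-drug provenance. A chemical present in both herbs
#' carries both herb tags; a target carries the union of the tags of the
#' chemicals known to bind it.
#'
#' @param node_id character vector of opaque node identifiers (unique).
#' @param role character vector, each `"chemical"` or `"target"`.
#' @param origins character vector of semicolon-separated origin tags drawn
#'   from `DS`, `CX`, `drug`; must be non-empty for every node.
#' @param display_name optional character vector of human-readable names.
#' @return A `data.frame` with columns `node_id`, `role`, `origins` (and
#'   `display_name` when supplied).
#' @export
node_meta <- function(node_id, role, origins, display_name = NULL) {
  node_id <- as.character(node_id)
  if (anyDuplicated(node_id)) stop("duplicate node_id in metadata")
  role <- as.character(role)
  if (!all(role %in% c("chemical", "target"))) {
    stop("role must be 'chemical' or 'target'")
  }
  origins <- as.character(origins)
  tags <- strsplit(origins, ";", fixed = TRUE)
  if (any(lengths(tags) == 0L) || any(origins == "")) {
    stop("every node needs at least one origin tag")
  }
  bad <- setdiff(unique(unlist(tags)), c("DS", "CX", "drug"))
  if (length(bad)) stop("unknown origin tag(s): ", paste(bad, collapse = ", "))
  out <- data.frame(node_id = node_id, role = role, origins = origins,
                    stringsAsFactors = FALSE)
  if (!is.null(display_name)) out$display_name <- as.character(display_name)
  out
}

origin_sets <- function(meta) {
  s <- strsplit(meta$origins, ";", fixed = TRUE)
  names(s) <- meta$node_id
  s
}

canonical_pairs <- function(u, v) {
  u <- as.character(u); v <- as.character(v)
  a <- pmin(u, v); b <- pmax(u, v)
  data.frame(u = a, v = b, stringsAsFactors = FALSE)
}

pair_key <- function(u, v) paste(pmin(u, v), pmax(u, v), sep = "\r")

#' Layered edge table
#'
#' Normalizes an edge table into the canonical layered form: undirected, no
#' self-loops, endpoints sorted lexicographically, symmetric duplicates
#' collapsed keeping the maximum score. Layers are `CTC` (chemical-target),
#' `CCC` (chemical-chemical similarity) and `PPI` (protein-protein).
#'
#' @param u,v character vectors of endpoint node ids.
#' @param layer single layer label or vector (`CTC`, `CCC` or `PPI`).
#' @param score optional numeric scores in `[0, 1]` (similarity or confidence);
#'   `NA` when absent.
#' @return `data.frame` with columns `u`, `v`, `layer`, `score`.
#' @export
layered_edges <- function(u, v, layer, score = NA_real_) {
  if (length(u) == 0L) {
    return(data.frame(u = character(), v = character(), layer = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  if (!all(layer %in% LAYERS)) stop("layer must be one of CTC, CCC, PPI")
  p <- canonical_pairs(u, v)
  keep <- p$u != p$v
  e <- data.frame(u = p$u[keep], v = p$v[keep],
                  layer = rep_len(as.character(layer), length(u))[keep],
                  score = rep_len(as.numeric(score), length(u))[keep],
                  stringsAsFactors = FALSE)
  # dedupe within layer, keeping the max score (NA treated as lowest)
  key <- paste(e$layer, e$u, e$v, sep = "\r")
  o <- order(key, -ifelse(is.na(e$score), -Inf, e$score))
  e <- e[o, , drop = FALSE]
  e <- e[!duplicated(key[o]), , drop = FALSE]
  rownames(e) <- NULL
  e
}

#' Layered heterogeneous network
#'
#' Assembles a simple undirected graph over chemical and target nodes with
#' layer-labeled edges and validates the layer typing: every `CTC` edge joins
#' a chemical to a target, every `CCC` edge two chemicals, every `PPI` edge
#' two targets. Isolated nodes are retained.
#'
#' @param nodes node metadata from [node_meta()].
#' @param edges edge table from [layered_edges()] (or rbind of several).
#' @return An object of class `hetgraph` with elements `nodes`, `edges` and a
#'   precomputed adjacency list `adj` (neighbors ignoring layer).
#' @export
hetgraph <- function(nodes, edges) {
  edges <- layered_edges(edges$u, edges$v, edges$layer, edges$score)
  missing <- setdiff(unique(c(edges$u, edges$v)), nodes$node_id)
  if (length(missing)) {
    stop("edge endpoint(s) not in node table: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  role <- stats::setNames(nodes$role, nodes$node_id)
  ru <- role[edges$u]; rv <- role[edges$v]
  ok <- (edges$layer == "CTC" & ru != rv) |
        (edges$layer == "CCC" & ru == "chemical" & rv == "chemical") |
        (edges$layer == "PPI" & ru == "target" & rv == "target")
  if (!all(ok)) {
    i <- which(!ok)[1]
    stop(sprintf("role violation: %s edge %s(%s) -- %s(%s)",
                 edges$layer[i], edges$u[i], ru[i], edges$v[i], rv[i]))
  }
  g <- structure(list(nodes = nodes, edges = edges,
                      adj = build_adjacency(nodes$node_id, edges)),
                 class = "hetgraph")
  g
}

build_adjacency <- function(node_ids, edges) {
  adj <- stats::setNames(vector("list", length(node_ids)), node_ids)
  for (i in seq_along(adj)) adj[[i]] <- character(0)
  if (nrow(edges)) {
    nb <- split(c(edges$v, edges$u), c(edges$u, edges$v))
    nb <- lapply(nb, function(x) sort(unique(x)))
    adj[names(nb)] <- nb
  }
  adj
}

#' Neighbors of a node, ignoring layer labels
#' @param graph a `hetgraph`.
#' @param x node id.
#' @return character vector of neighbor ids (sorted, possibly empty).
#' @export
het_neighbors <- function(graph, x) {
  if (!x %in% names(graph$adj)) stop("unknown node: ", x)
  graph$adj[[x]]
}

#' @export
print.hetgraph <- function(x, ...) {
  s <- het_summary(x)
  cat(sprintf("hetgraph: %d nodes (%d chemicals, %d targets), %d edges\n",
              s$n_nodes, s$n_chemicals, s$n_targets, s$n_edges))
  for (l in LAYERS) cat(sprintf("  %s: %d\n", l, s$edges_by_layer[[l]]))
  invisible(x)
}

#' Node and edge bookkeeping for a layered network
#'
#' Counts nodes by role and edges by layer; the totals satisfy
#' `n_nodes = n_chemicals + n_targets` and `n_edges = sum(edges_by_layer)`.
#'
#' @param graph a `hetgraph`.
#' @return list with `n_nodes`, `n_chemicals`, `n_targets`, `n_edges`, and
#'   named integer vector `edges_by_layer`.
#' @export
het_summary <- function(graph) {
  byl <- stats::setNames(integer(length(LAYERS)), LAYERS)
  if (nrow(graph$edges)) {
    t <- table(factor(graph$edges$layer, levels = LAYERS))
    byl[names(t)] <- as.integer(t)
  }
  list(n_nodes = nrow(graph$nodes),
       n_chemicals = sum(graph$nodes$role == "chemical"),
       n_targets = sum(graph$nodes$role == "target"),
       n_edges = nrow(graph$edges),
       edges_by_layer = byl)
}

#' Tanimoto coefficient between two fingerprint bit sets
#'
#' The standard 2D chemical-similarity measure: the ratio of shared set bits
#' to the union of set bits, `|A ∩ B| / |A ∪ B|`.
#'
#' @param a,b integer vectors of set-bit positions (each treated as a set).
#' @return similarity in `[0, 1]`; symmetric in its arguments.
#' @export
tanimoto <- function(a, b) {
  a <- unique(as.integer(a)); b <- unique(as.integer(b))
  if (length(a) == 0L && length(b) == 0L) {
    stop("tanimoto undefined for two empty fingerprints")
  }
  n_int <- length(intersect(a, b))
  n_int / (length(a) + length(b) - n_int)
}

#' Chemical-chemical similarity layer from fingerprints
#'
#' Connects every pair of chemicals whose fingerprint Tanimoto similarity
#' reaches the threshold (0.6 by default, the usual cut for "structurally
#' similar" in fingerprint screening). Pairwise similarities are computed via
#' a sparse bit-matrix cross-product, so the cost is driven by shared bits
#' rather than the full n^2 scan.
#'
#' @param fps named list: chemical id -> integer vector of set-bit positions.
#' @param threshold minimum Tanimoto similarity, in `(0, 1]`.
#' @return edge table (layer `CCC`) with the similarity in `score`.
#' @export
build_ccc_layer <- function(fps, threshold = 0.6) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  ids <- names(fps)
  if (is.null(ids) || anyDuplicated(ids)) stop("fps must be uniquely named by chemical_id")
  sizes <- lengths(lapply(fps, unique))
  if (any(sizes == 0L)) {
    warning("empty fingerprint(s): ",
            paste(ids[sizes == 0L], collapse = ", "))
  }
  n <- length(fps)
  if (n < 2L) return(layered_edges(character(), character(), "CCC"))
  bits <- lapply(fps, function(x) unique(as.integer(x)))
  all_bits <- sort(unique(unlist(bits)))
  m <- Matrix::sparseMatrix(
    i = rep.int(seq_len(n), lengths(bits)),
    j = match(unlist(bits), all_bits),
    x = 1, dims = c(n, max(1L, length(all_bits))))
  inter <- Matrix::tcrossprod(m)
  inter <- as(inter, "TsparseMatrix")
  keep <- inter@i < inter@j   # upper triangle, 0-based indices
  i <- inter@i[keep] + 1L; j <- inter@j[keep] + 1L
  ninter <- inter@x[keep]
  sim <- ninter / (sizes[i] + sizes[j] - ninter)
  sel <- sim >= threshold
  layered_edges(ids[i[sel]], ids[j[sel]], "CCC", score = sim[sel])
}

#' Protein-protein interaction layer from scored pairs
#'
#' Keeps target pairs whose interaction confidence score meets the threshold
#' (0.9 and above by default, the high-confidence cut of STRING-style scores),
#' drops self-pairs, and collapses symmetric duplicates keeping the maximum
#' score.
#'
#' @param pairs `data.frame` with columns `u`, `v`, `score` (scores in `[0,1]`).
#' @param threshold minimum confidence to keep an edge.
#' @param meta optional node metadata; when given, non-target endpoints raise
#'   a role-violation error.
#' @return edge table (layer `PPI`).
#' @export
build_ppi_layer <- function(pairs, threshold = 0.9, meta = NULL) {
  if (nrow(pairs) == 0L) return(layered_edges(character(), character(), "PPI"))
  if (any(pairs$score < 0 | pairs$score > 1, na.rm = TRUE)) {
    stop("PPI scores must lie in [0, 1]")
  }
  if (!is.null(meta)) {
    role <- stats::setNames(meta$role, meta$node_id)
    ends <- unique(c(pairs$u, pairs$v))
    bad <- ends[is.na(role[ends]) | role[ends] != "target"]
    if (length(bad)) stop("PPI endpoint is not a target: ",
                          paste(utils::head(bad, 5), collapse = ", "))
  }
  keep <- pairs$score >= threshold & pairs$u != pairs$v
  layered_edges(pairs$u[keep], pairs$v[keep], "PPI", score = pairs$score[keep])
}

#' Chemical-target activity layer
#'
#' Deduplicated undirected chemical-target edges from activity records.
#'
#' @param records `data.frame` with columns `chemical_id`, `target_id`.
#' @param meta optional node metadata; when given, records whose endpoints do
#'   not have the chemical/target roles raise a role-violation error.
#' @return edge table (layer `CTC`).
#' @export
build_ctc_layer <- function(records, meta = NULL) {
  if (nrow(records) == 0L) return(layered_edges(character(), character(), "CTC"))
  if (!is.null(meta)) {
    role <- stats::setNames(meta$role, meta$node_id)
    if (any(role[as.character(records$chemical_id)] != "chemical", na.rm = FALSE) ||
        any(is.na(role[as.character(records$chemical_id)]))) {
      stop("role violation: CTC record with non-chemical (or unknown) chemical_id")
    }
    if (any(role[as.character(records$target_id)] != "target", na.rm = FALSE) ||
        any(is.na(role[as.character(records$target_id)]))) {
      stop("role violation: CTC record with non-target (or unknown) target_id")
    }
  }
  layered_edges(records$chemical_id, records$target_id, "CTC")
}

#' Dataset specification: a group and a layer set
#'
#' The study design crosses three herb-drug groups (`DS-drug`, `CX-drug`,
#' `DS-CX-drug`) with three nested layer sets: activity edges only (`CTC`),
#' activity plus chemical similarity (`CTC`,`CCC`), and all three layers
#' (`CTC`,`CCC`,`PPI`).
#'
#' @param group one of `"DS-drug"`, `"CX-drug"`, `"DS-CX-drug"`.
#' @param layers subset of `c("CTC","CCC","PPI")`; must contain `CTC` and be
#'   one of the three nested sets above.
#' @return list with class `dataset_spec`.
#' @export
dataset_spec <- function(group, layers = LAYERS) {
  if (!group %in% GROUPS) stop("group must be one of ", paste(GROUPS, collapse = ", "))
  layers <- unique(as.character(layers))
  valid <- list(c("CTC"), c("CTC", "CCC"), c("CTC", "CCC", "PPI"))
  if (!any(vapply(valid, function(v) setequal(v, layers), logical(1)))) {
    stop("layers must be one of {CTC}, {CTC,CCC}, {CTC,CCC,PPI}")
  }
  structure(list(group = group, layers = layers[order(match(layers, LAYERS))]),
            class = "dataset_spec")
}

group_tags <- function(group) {
  switch(group,
         "DS-drug" = c("DS", "drug"),
         "CX-drug" = c("CX", "drug"),
         "DS-CX-drug" = c("DS", "CX", "drug"),
         stop("unknown group: ", group))
}

#' Assemble a dataset graph from per-layer edge tables
#'
#' Merges the requested layers into one `hetgraph`. When a group is given
#' (via `spec`), nodes are filtered first: a chemical enters the group iff
#' its origin set intersects the group's tags, and a target enters via an
#' incident CTC edge with a selected chemical; CCC and PPI edges are then
#' restricted to the selected nodes. Because the layers are type-disjoint
#' (chemical-target, chemical-chemical, target-target), the assembled edge
#' count always equals the sum of the included per-layer counts.
#'
#' @param layers named list of edge tables, names among `CTC`, `CCC`, `PPI`.
#' @param meta node metadata covering all endpoints.
#' @param spec optional [dataset_spec()]; when `NULL`, all nodes in `meta` and
#'   all provided layers are used as-is.
#' @return a `hetgraph`.
#' @export
assemble_dataset <- function(layers, meta, spec = NULL) {
  wanted <- if (is.null(spec)) names(layers) else spec$layers
  if (!"CTC" %in% wanted || is.null(layers[["CTC"]])) {
    stop("invalid dataset spec: the CTC layer is required")
  }
  if (!all(wanted %in% names(layers))) {
    stop("requested layer(s) not provided: ",
         paste(setdiff(wanted, names(layers)), collapse = ", "))
  }
  ctc <- layers[["CTC"]]
  if (is.null(spec)) {
    nodes <- meta
    keep_layers <- layers[wanted]
  } else {
    tags <- group_tags(spec$group)
    os <- origin_sets(meta)
    in_group <- vapply(os, function(s) length(intersect(s, tags)) > 0, logical(1))
    chems <- meta$node_id[meta$role == "chemical" & in_group[meta$node_id]]
    role <- stats::setNames(meta$role, meta$node_id)
    cu <- ifelse(role[ctc$u] == "chemical", ctc$u, ctc$v)
    tu <- ifelse(role[ctc$u] == "chemical", ctc$v, ctc$u)
    sel <- cu %in% chems
    targs <- sort(unique(tu[sel]))
    keep_ids <- c(chems, targs)
    nodes <- meta[meta$node_id %in% keep_ids, , drop = FALSE]
    rownames(nodes) <- NULL
    keep_layers <- lapply(layers[wanted], function(e) {
      e[e$u %in% keep_ids & e$v %in% keep_ids, , drop = FALSE]
    })
    keep_layers[["CTC"]] <- ctc[sel, , drop = FALSE]
  }
  hetgraph(nodes, do.call(rbind, keep_layers))
}
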