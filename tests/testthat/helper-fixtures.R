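# Fixtures and independent oracles shared across the suite.

# small typed graph: chemicals A..., targets T...; edges typed by role pair
random_typed_graph <- function(n, p, seed) {
  set.seed(seed)
  roles <- sample(c("chemical", "target"), n, replace = TRUE)
  ids <- sprintf("%s%02d", ifelse(roles == "chemical", "c", "t"), seq_len(n))
  meta <- node_meta(ids, roles, rep("drug", n))
  pr <- utils::combn(n, 2L)
  keep <- stats::runif(ncol(pr)) < p
  u <- ids[pr[1, keep]]; v <- ids[pr[2, keep]]
  ru <- roles[pr[1, keep]]; rv <- roles[pr[2, keep]]
  layer <- ifelse(ru != rv, "CTC", ifelse(ru == "chemical", "CCC", "PPI"))
  hetgraph(meta, layered_edges(u, v, layer))
}

# all-chemical graph from an explicit edge list (for hand-worked examples)
chem_graph <- function(edge_pairs, extra_nodes = character()) {
  ids <- sort(unique(c(unlist(edge_pairs), extra_nodes)))
  meta <- node_meta(ids, rep("chemical", length(ids)), rep("drug", length(ids)))
  if (length(edge_pairs)) {
    u <- vapply(edge_pairs, `[`, "", 1L)
    v <- vapply(edge_pairs, `[`, "", 2L)
    hetgraph(meta, layered_edges(u, v, "CCC"))
  } else {
    hetgraph(meta, layered_edges(character(), character(), "CCC"))
  }
}

pkey <- function(u, v) paste(pmin(u, v), pmax(u, v))

adjacency_matrix <- function(graph) {
  ids <- graph$nodes$node_id
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(graph$edges)) {
    ui <- match(graph$edges$u, ids); vi <- match(graph$edges$v, ids)
    A[cbind(ui, vi)] <- 1; A[cbind(vi, ui)] <- 1
  }
  A
}

# matrix-route oracles for the neighborhood indices (independent of the
# adjacency-list implementations in the package)
oracle_aa <- function(graph, u, v) {
  A <- adjacency_matrix(graph)
  deg <- rowSums(A)
  w <- ifelse(deg > 1, 1 / log(deg), 0)   # deg<=1 nodes can't be common nbrs
  M <- A %*% diag(w, nrow(A)) %*% A
  M[cbind(match(u, rownames(A)), match(v, rownames(A)))]
}

oracle_jaccard <- function(graph, u, v) {
  A <- adjacency_matrix(graph)
  inter <- (A %*% A)[cbind(match(u, rownames(A)), match(v, rownames(A)))]
  deg <- rowSums(A)
  un <- deg[u] + deg[v] - inter
  ifelse(un == 0, 0, inter / un)
}

oracle_pa <- function(graph, u, v) {
  deg <- rowSums(adjacency_matrix(graph))
  as.numeric(deg[u] * deg[v])
}

# threshold-sweep oracle for average precision (explicit counting at each
# distinct threshold, no ranking shortcuts)
oracle_ap <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  prev_r <- 0; ap <- 0
  for (t in th) {
    tp <- sum(scores >= t & labels == 1)
    fp <- sum(scores >= t & labels == 0)
    p <- tp / (tp + fp)
    r <- tp / sum(labels == 1)
    ap <- ap + (r - prev_r) * p
    prev_r <- r
  }
  ap
}

# exhaustive pair-counting oracle for AUROC (ties count one half)
oracle_auroc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

trapezoid_area <- function(xy) {
  sum(diff(xy$fpr) * (utils::head(xy$tpr, -1) + utils::tail(xy$tpr, -1)) / 2)
}

# k distinct synthetic edges of one layer over disjoint endpoint pools
synth_layer <- function(k, layer, lhs_prefix, rhs_prefix = lhs_prefix) {
  if (lhs_prefix == rhs_prefix) {
    n <- ceiling((1 + sqrt(1 + 8 * k)) / 2)
    pr <- utils::combn(n, 2L)[, seq_len(k), drop = FALSE]
    layered_edges(sprintf("%s%05d", lhs_prefix, pr[1, ]),
                  sprintf("%s%05d", lhs_prefix, pr[2, ]), layer)
  } else {
    n_rhs <- ceiling(k / 40)
    idx <- seq_len(k) - 1L
    layered_edges(sprintf("%s%05d", lhs_prefix, idx %% 40L + 1L),
                  sprintf("%s%05d", rhs_prefix, idx %/% 40L + 1L), layer)
  }
}
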