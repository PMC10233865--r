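# Evaluation protocol: each round (a "fold") re-splits the edge set
# 6:3:1 into train/validation/test positives, samples an equal number of
# verified non-edges per partition, trains on the training graph and scores
# the held-out pairs. Classical 10-fold partitioning cannot produce a 6:3:1
# split, so "tenfold cross validation" is realized as 10 independently
# reseeded resampling rounds, which preserves both stated facts.

#' Split-and-evaluation specification
#'
#' @param train_frac,val_frac,test_frac positive fractions summing to 1
#'   (default 6:3:1). The validation split is reserved for hyperparameter
#'   selection and never used to fit the final classifier.
#' @param folds number of independent resampling rounds.
#' @param neg_ratio negatives sampled per positive in each partition.
#' @param candidate_universe `"any"` samples negatives from all node pairs
#'   (matching graph-level evaluation over all edge types);
#'   `"chem-target"` restricts to chemical-target pairs.
#' @param seed master seed; round r uses `seed + r`.
#' @return list of class `split_spec`.
#' @export
split_spec <- function(train_frac = 0.6, val_frac = 0.3, test_frac = 0.1,
                       folds = 10L, neg_ratio = 1,
                       candidate_universe = c("any", "chem-target"),
                       seed = 1L) {
  stopifnot(train_frac > 0, val_frac > 0, test_frac > 0,
            abs(train_frac + val_frac + test_frac - 1) < 1e-9,
            folds >= 2, neg_ratio > 0)
  candidate_universe <- match.arg(candidate_universe)
  structure(as.list(environment()), class = "split_spec")
}

sample_nonedges <- function(graph, n_needed, universe, forbidden_keys) {
  ids <- graph$nodes$node_id
  chems <- graph$nodes$node_id[graph$nodes$role == "chemical"]
  targs <- graph$nodes$node_id[graph$nodes$role == "target"]
  edge_keys <- pair_key(graph$edges$u, graph$edges$v)
  got_u <- character(0); got_v <- character(0)
  taken <- character(0)
  guard <- 0L
  while (length(got_u) < n_needed) {
    guard <- guard + 1L
    if (guard > 200L) stop("unable to sample enough non-edges")
    m <- max(16L, 2L * (n_needed - length(got_u)))
    if (universe == "chem-target") {
      u <- sample(chems, m, replace = TRUE)
      v <- sample(targs, m, replace = TRUE)
    } else {
      u <- sample(ids, m, replace = TRUE)
      v <- sample(ids, m, replace = TRUE)
    }
    ok <- u != v
    u <- u[ok]; v <- v[ok]
    key <- pair_key(u, v)
    ok <- !(key %in% edge_keys) & !(key %in% forbidden_keys) &
          !(key %in% taken) & !duplicated(key)
    u <- u[ok]; v <- v[ok]; key <- key[ok]
    keep <- seq_len(min(length(u), n_needed - length(got_u)))
    got_u <- c(got_u, u[keep]); got_v <- c(got_v, v[keep])
    taken <- c(taken, key[keep])
  }
  list(u = got_u, v = got_v, keys = taken)
}

#' Split a graph's edges 6:3:1 and sample negatives
#'
#' Edges are partitioned uniformly at random into train/validation/test
#' positives at the spec's fractions (rounded so the partitions are exact on
#' multiples of ten). The training graph retains only the training edges
#' (over all nodes, so held-out endpoints stay addressable). Negatives are
#' sampled uniformly from verified non-edges of the *full* graph at
#' `neg_ratio` per positive, disjoint across partitions.
#'
#' @param graph a `hetgraph` with at least 10 edges.
#' @param spec a [split_spec()].
#' @param fold integer round index (affects the seed; default 1).
#' @return list with `train_graph` and `sets`: named list of
#'   `data.frame(u, v, label)` for `train`, `val`, `test`.
#' @export
split_edges <- function(graph, spec = split_spec(), fold = 1L) {
  n <- nrow(graph$edges)
  if (n < 10L) stop("graph must have at least 10 edges to split")
  with_local_seed(as.integer(spec$seed) + as.integer(fold), {
    perm <- sample.int(n)
    n_test <- max(1L, round(spec$test_frac * n))
    n_val <- max(1L, round(spec$val_frac * n))
    n_train <- n - n_test - n_val
    idx <- list(train = perm[seq_len(n_train)],
                val = perm[n_train + seq_len(n_val)],
                test = perm[n_train + n_val + seq_len(n_test)])
    train_graph <- hetgraph(graph$nodes, graph$edges[idx$train, , drop = FALSE])
    forbidden <- character(0)
    sets <- list()
    for (part in names(idx)) {
      pos <- graph$edges[idx[[part]], c("u", "v"), drop = FALSE]
      nneg <- round(spec$neg_ratio * nrow(pos))
      neg <- sample_nonedges(graph, nneg, spec$candidate_universe, forbidden)
      forbidden <- c(forbidden, neg$keys)
      s <- data.frame(
        u = c(pos$u, neg$u), v = c(pos$v, neg$v),
        label = c(rep(1L, nrow(pos)), rep(0L, length(neg$u))),
        stringsAsFactors = FALSE)
      # shuffle rows so tie-broken metrics cannot reward input order
      s <- s[sample.int(nrow(s)), , drop = FALSE]
      rownames(s) <- NULL
      sets[[part]] <- s
    }
    deg_tr <- degrees(train_graph)
    for (part in c("val", "test")) {
      s <- sets[[part]]
      lonely <- s$label == 1L & deg_tr[s$u] == 0L & deg_tr[s$v] == 0L
      if (any(lonely)) {
        warning(sum(lonely), " ", part,
                " positive(s) with both endpoints isolated in the training graph")
      }
    }
    list(train_graph = train_graph, sets = sets)
  })
}

#' Average precision over a ranked threshold sweep
#'
#' `AP = sum_n (R_n - R_{n-1}) P_n` with precision `P_n` and recall `R_n`
#' evaluated after each prediction in the ranking (stable sort on
#' descending score, so ties keep input order).
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels (at least one positive).
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(scores, labels) {
  labels <- as.integer(labels)
  npos <- sum(labels == 1L)
  if (npos == 0L) stop("average precision undefined without positives")
  o <- order(-scores)            # radix order: stable for ties
  l <- labels[o]
  tp <- cumsum(l)
  precision <- tp / seq_along(l)
  recall <- tp / npos
  sum(diff(c(0, recall)) * precision)
}

#' Area under the ROC curve
#'
#' The probability that a uniformly drawn positive is ranked above a
#' uniformly drawn negative, with ties counted one half — computed as the
#' normalized Mann-Whitney U statistic via mean ranks.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUROC in `[0, 1]` (0.5 = chance).
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L) stop("AUROC undefined with a single class")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' ROC curve points
#'
#' Threshold sweep over the distinct scores, from the strictest call
#' (nothing positive) to the laxest (everything positive); both coordinates
#' are non-decreasing from (0,0) to (1,1).
#'
#' @inheritParams auroc
#' @return `data.frame` with columns `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L) stop("ROC undefined with a single class")
  o <- order(-scores)
  s <- scores[o]; l <- labels[o]
  last_of_block <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(l)[last_of_block]
  fp <- cumsum(1L - l)[last_of_block]
  data.frame(fpr = c(0, fp / nneg), tpr = c(0, tp / npos))
}

#' Repeated 6:3:1 cross-validation of one algorithm on one dataset
#'
#' Runs `spec$folds` independent resampling rounds: split, train on the
#' training graph, score the held-out test pairs, and compute AUROC and
#' average precision. The validation split is held out for optional
#' hyperparameter selection and is not used here by default. Deterministic
#' under the spec's master seed (single-threaded).
#'
#' @param graph the dataset `hetgraph`.
#' @param algorithm one of `"node2vec"`, `"AA"`, `"JS"`, `"PA"`, `"SC"`.
#' @param spec a [split_spec()].
#' @param params algorithm parameters (see [train_scorer()]).
#' @param operator edge-feature operator for classifier-backed algorithms.
#' @return list of class `eval_result`: `algorithm`, `per_fold_auroc`,
#'   `per_fold_ap`, `mean_auroc`, `mean_ap`, and `roc_points` pooled over
#'   the rounds' test scores.
#' @export
cross_validate <- function(graph, algorithm, spec = split_spec(),
                           params = NULL, operator = "hadamard") {
  aurocs <- aps <- numeric(spec$folds)
  pooled_scores <- pooled_labels <- list()
  for (f in seq_len(spec$folds)) {
    sp <- suppressWarnings(split_edges(graph, spec, fold = f))
    fold_params <- params
    if (algorithm == "node2vec") {
      if (is.null(fold_params)) fold_params <- node2vec_params()
      fold_params$seed <- (as.integer(spec$seed) %% 1000003L) * 1000L + f
    } else if (algorithm == "SC" && is.null(fold_params)) {
      fold_params <- spectral_params()
    }
    scorer <- suppressWarnings(
      train_scorer(sp$train_graph, algorithm,
                   train_pairs = sp$sets$train, params = fold_params,
                   operator = operator))
    sc <- suppressWarnings(predict(scorer, sp$sets$test))
    lab <- sp$sets$test$label
    aurocs[f] <- tryCatch(auroc(sc, lab), error = function(e) {
      stop("fold ", f, ": ", conditionMessage(e))
    })
    aps[f] <- tryCatch(average_precision(sc, lab), error = function(e) {
      stop("fold ", f, ": ", conditionMessage(e))
    })
    pooled_scores[[f]] <- sc; pooled_labels[[f]] <- lab
  }
  structure(list(algorithm = algorithm,
                 per_fold_auroc = aurocs, per_fold_ap = aps,
                 mean_auroc = mean(aurocs), mean_ap = mean(aps),
                 roc_points = roc_curve(unlist(pooled_scores),
                                        unlist(pooled_labels))),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("%s: mean AUROC %.3f, mean AP %.3f over %d rounds\n",
              x$algorithm, x$mean_auroc, x$mean_ap, length(x$per_fold_auroc)))
  invisible(x)
}
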