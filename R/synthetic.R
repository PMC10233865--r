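# Planted-block generator for heterogeneous chemical-target networks.
#
# The analysis assumes that structurally similar chemicals share targets and
# that interacting proteins share ligands; both are shared-latent-group
# statements, so the generator plants a block structure: chemicals and
# targets are assigned to latent blocks, chemical-target edges are denser
# within blocks, fingerprints inherit noisy per-block bit signatures (so the
# Tanimoto cut concentrates chemical-chemical edges within blocks), and
# protein-pair confidence scores are drawn high within blocks and low across
# them (so the 0.9 cut keeps mostly intra-block protein pairs).

with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Configuration for the planted-block network generator
#'
#' Defaults emulate the scale of a curated herb-drug network: ~400 chemicals,
#' ~1000 targets and a chemical-target layer in the low thousands of edges,
#' with 8 latent blocks supplying the cross-layer signal.
#'
#' @param n_chem number of chemicals.
#' @param n_targ number of protein targets.
#' @param n_blocks number of latent blocks shared by chemicals and targets.
#' @param ctc_p_in,ctc_p_out Bernoulli edge probabilities for chemical-target
#'   pairs within / across blocks (`ctc_p_in > ctc_p_out`).
#' @param fp_len fingerprint length in bits.
#' @param fp_block_bits number of signature bits owned by each block.
#' @param fp_noise per-bit flip probability applied to a chemical's block
#'   signature.
#' @param ppi_mu_in,ppi_mu_out means of the clipped Normal(mu, 0.05)
#'   confidence scores for intra-/inter-block protein pairs.
#' @param ppi_emit_min protein pairs with sampled score below this floor are
#'   not recorded (they cannot enter the network at any high-confidence cut).
#' @param herb_fraction fraction of chemicals tagged as herbal (DS and/or CX);
#'   the rest are drug chemicals.
#' @param seed RNG seed; every draw in [generate_hetnet()] derives from it.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_chem = 400L, n_targ = 1000L, n_blocks = 8L,
                             ctc_p_in = 0.08, ctc_p_out = 0.002,
                             fp_len = 256L, fp_block_bits = 40L,
                             fp_noise = 0.05,
                             ppi_mu_in = 0.92, ppi_mu_out = 0.4,
                             ppi_emit_min = 0.6,
                             herb_fraction = 0.1, seed = 1L) {
  stopifnot(ctc_p_in > ctc_p_out, ppi_mu_in > ppi_mu_out,
            ctc_p_in >= 0, ctc_p_in <= 1, ctc_p_out >= 0,
            herb_fraction >= 0, herb_fraction <= 1,
            fp_noise >= 0, fp_noise <= 1,
            n_blocks >= 1, fp_block_bits <= fp_len)
  structure(as.list(environment()), class = "generator_config")
}

#' Small generator profile for fast runs
#'
#' 40 chemicals, 100 targets, 4 blocks, with within-/across-block edge
#' probabilities chosen so the chemical-target layer lands near 350 edges —
#' a 10x scale-down of the default profile that keeps the planted signal
#' strong enough for link prediction.
#'
#' @param seed RNG seed.
#' @param ... overrides passed to [generator_config()].
#' @return a `generator_config`.
#' @export
tiny_config <- function(seed = 1L, ...) {
  generator_config(n_chem = 40L, n_targ = 100L, n_blocks = 4L,
                   ctc_p_in = 0.28, ctc_p_out = 0.02, seed = seed, ...)
}

#' Generate a planted-block heterogeneous chemical-target network
#'
#' @param config a [generator_config()].
#' @return list with `meta` (node metadata), `fps` (fingerprints),
#'   `ctc_records` (chemical-target activity records), `ppi_pairs` (scored
#'   protein pairs), `blocks` (named integer vector of ground-truth block
#'   assignments) and `config`.
#' @export
generate_hetnet <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  nc <- as.integer(config$n_chem); nt <- as.integer(config$n_targ)
  nb <- as.integer(config$n_blocks)
  intra <- sum(outer(tabulate(rep_len(seq_len(nb), nc), nb),
                     tabulate(rep_len(seq_len(nb), nt), nb)) *
               diag(nb))
  expected <- intra * config$ctc_p_in + (nc * nt - intra) * config$ctc_p_out
  if (expected < 10) stop("config error: expected CTC edge count below 10")
  with_local_seed(config$seed, {
    chem_ids <- sprintf("C%04d", seq_len(nc))
    targ_ids <- sprintf("T%04d", seq_len(nt))
    bc <- sample(rep_len(seq_len(nb), nc))
    bt <- sample(rep_len(seq_len(nb), nt))
    names(bc) <- chem_ids; names(bt) <- targ_ids

    # chemical-target activity: planted-partition Bernoulli draws
    same <- outer(bc, bt, "==")
    p <- ifelse(same, config$ctc_p_in, config$ctc_p_out)
    hit <- matrix(stats::runif(nc * nt) < p, nc, nt)
    idx <- which(hit, arr.ind = TRUE)
    ctc_records <- data.frame(chemical_id = chem_ids[idx[, 1]],
                              target_id = targ_ids[idx[, 2]],
                              stringsAsFactors = FALSE)

    # fingerprints: per-block signatures with per-bit flip noise
    sig <- lapply(seq_len(nb), function(b)
      sort(sample.int(config$fp_len, config$fp_block_bits)))
    fps <- lapply(seq_len(nc), function(i) {
      mask <- logical(config$fp_len)
      mask[sig[[bc[i]]]] <- TRUE
      flip <- stats::runif(config$fp_len) < config$fp_noise
      which(xor(mask, flip))
    })
    names(fps) <- chem_ids

    # protein-pair confidence scores: clipped normals, high within blocks
    pr <- utils::combn(nt, 2L)
    mu <- ifelse(bt[pr[1, ]] == bt[pr[2, ]], config$ppi_mu_in, config$ppi_mu_out)
    sc <- pmin(1, pmax(0, stats::rnorm(length(mu), mu, 0.05)))
    keep <- sc >= config$ppi_emit_min
    ppi_pairs <- data.frame(u = targ_ids[pr[1, keep]],
                            v = targ_ids[pr[2, keep]],
                            score = sc[keep], stringsAsFactors = FALSE)

    # origins: herb_fraction of chemicals are herbal (DS, CX or both),
    # the rest are drug chemicals; targets inherit the union of the origins
    # of their activity partners, defaulting to drug when unattached
    n_herb <- round(config$herb_fraction * nc)
    herb_idx <- sample.int(nc, n_herb)
    chem_orig <- rep("drug", nc)
    if (n_herb > 0) {
      chem_orig[herb_idx] <- sample(c("DS", "CX", "DS;CX"), n_herb,
                                    replace = TRUE, prob = c(.45, .45, .10))
    }
    names(chem_orig) <- chem_ids
    co_sets <- strsplit(chem_orig, ";", fixed = TRUE)
    names(co_sets) <- chem_ids
    targ_orig <- vapply(targ_ids, function(t) {
      nb_chems <- ctc_records$chemical_id[ctc_records$target_id == t]
      tags <- sort(unique(unlist(co_sets[nb_chems])))
      if (!length(tags)) "drug" else paste(tags, collapse = ";")
    }, "")
    meta <- node_meta(c(chem_ids, targ_ids),
                      c(rep("chemical", nc), rep("target", nt)),
                      c(chem_orig, targ_orig))
    list(meta = meta, fps = fps, ctc_records = ctc_records,
         ppi_pairs = ppi_pairs, blocks = c(bc, bt), config = config)
  })
}

#' Write a generated network to a directory of plain-text files
#'
#' Emits `nodes.tsv`, `ctc_edges.tsv`, `ppi_pairs.tsv`, `fingerprints.tsv`
#' and `truth_blocks.tsv`, each with a comment header recording the seed.
#'
#' @param sim output of [generate_hetnet()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_hetnet <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hdr <- sprintf("seed=%d", sim$config$seed)
  write_node_meta(sim$meta, file.path(dir, "nodes.tsv"), header = hdr)
  write_edges_tsv(build_ctc_layer(sim$ctc_records),
                  file.path(dir, "ctc_edges.tsv"), header = hdr)
  write_edges_tsv(layered_edges(sim$ppi_pairs$u, sim$ppi_pairs$v, "PPI",
                                sim$ppi_pairs$score),
                  file.path(dir, "ppi_pairs.tsv"), header = hdr)
  write_fingerprints(sim$fps, file.path(dir, "fingerprints.tsv"), header = hdr)
  con <- file(file.path(dir, "truth_blocks.tsv"), "w")
  writeLines(c(paste0("# ", hdr),
               paste(names(sim$blocks), sim$blocks, sep = "\t")), con)
  close(con)
  invisible(dir)
}

#' Build the three evidence layers from a generated (or loaded) network
#'
#' @param sim list with `meta`, `fps`, `ctc_records`, `ppi_pairs`.
#' @param tanimoto_threshold Tanimoto cut for the chemical similarity layer.
#' @param ppi_threshold confidence cut for the protein interaction layer.
#' @return named list of edge tables `CTC`, `CCC`, `PPI`.
#' @export
build_layers <- function(sim, tanimoto_threshold = 0.6, ppi_threshold = 0.9) {
  list(CTC = build_ctc_layer(sim$ctc_records, meta = sim$meta),
       CCC = build_ccc_layer(sim$fps, threshold = tanimoto_threshold),
       PPI = build_ppi_layer(sim$ppi_pairs, threshold = ppi_threshold,
                             meta = sim$meta))
}
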