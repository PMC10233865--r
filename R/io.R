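# Plain-text interchange formats: per-layer edge TSVs, a node-metadata TSV
# and a fingerprint file (comma-separated set-bit indices). All files allow
# '#'-prefixed comment headers, which the writers use to record the seed.

read_tsv_commented <- function(path, col.names) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) {
    return(stats::setNames(as.data.frame(replicate(length(col.names),
                                                   character(0),
                                                   simplify = FALSE)),
                           col.names))
  }
  utils::read.delim(text = lines, header = FALSE, col.names = col.names,
                    colClasses = "character", quote = "")
}

#' Read a layered edge-list TSV
#'
#' Columns `u  v  layer  score` (score optional/empty); `#` comments allowed.
#' @param path file path.
#' @return canonical edge table (see [layered_edges()]).
#' @export
read_edges_tsv <- function(path) {
  raw <- readLines(path)
  raw <- raw[!startsWith(raw, "#") & nzchar(raw)]
  if (!length(raw)) return(layered_edges(character(), character(), "CTC"))
  parts <- strsplit(raw, "\t", fixed = TRUE)
  u <- vapply(parts, `[`, "", 1L)
  v <- vapply(parts, `[`, "", 2L)
  layer <- vapply(parts, `[`, "", 3L)
  score <- suppressWarnings(as.numeric(vapply(parts, function(p)
    if (length(p) >= 4L) p[4L] else NA_character_, "")))
  layered_edges(u, v, layer, score)
}

#' Write a layered edge-list TSV
#' @param edges edge table.
#' @param path file path.
#' @param header optional character vector of comment lines (written with `#`).
#' @export
write_edges_tsv <- function(edges, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  if (nrow(edges)) {
    sc <- ifelse(is.na(edges$score), "", formatC(edges$score, format = "g",
                                                 digits = 10))
    writeLines(paste(edges$u, edges$v, edges$layer, sc, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a node-metadata TSV (`node_id  role  origins`)
#' @param path file path.
#' @return metadata `data.frame` (see [node_meta()]).
#' @export
read_node_meta <- function(path) {
  d <- read_tsv_commented(path, c("node_id", "role", "origins"))
  node_meta(d$node_id, d$role, d$origins)
}

#' Write a node-metadata TSV
#' @param meta metadata table.
#' @param path file path.
#' @param header optional comment lines.
#' @export
write_node_meta <- function(meta, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(meta$node_id, meta$role, meta$origins, sep = "\t"), con)
  invisible(path)
}

#' Read a fingerprint file (`chemical_id  b1,b2,...`)
#' @param path file path.
#' @return named list of integer set-bit vectors.
#' @export
read_fingerprints <- function(path) {
  d <- read_tsv_commented(path, c("chemical_id", "bits"))
  fps <- lapply(strsplit(d$bits, ",", fixed = TRUE), function(x) {
    x <- x[nzchar(x)]
    sort(unique(as.integer(x)))
  })
  names(fps) <- d$chemical_id
  fps
}

#' Write a fingerprint file
#' @param fps named list of integer set-bit vectors.
#' @param path file path.
#' @param header optional comment lines.
#' @export
write_fingerprints <- function(fps, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(names(fps),
                   vapply(fps, function(b) paste(sort(unique(as.integer(b))),
                                                 collapse = ","), ""),
                   sep = "\t"), con)
  invisible(path)
}

#' Convert SMILES to atom-pair fingerprint bit sets
#'
#' Convenience bridge for users with structures rather than precomputed
#' fingerprints; requires the ChemmineR toolkit. The pipeline itself is
#' chemistry-toolkit-agnostic and consumes plain bit sets.
#'
#' @param smiles named character vector of SMILES strings.
#' @return named list of integer set-bit vectors.
#' @export
smiles_to_fingerprints <- function(smiles) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("ChemmineR is required for SMILES input; supply bit sets instead")
  }
  sdf <- ChemmineR::smiles2sdf(smiles)
  ap <- ChemmineR::sdf2ap(sdf)
  fp <- ChemmineR::desc2fp(ap, descnames = 1024, type = "FPset")
  m <- as.matrix(fp)
  out <- apply(m, 1L, function(r) which(r > 0), simplify = FALSE)
  names(out) <- names(smiles)
  out
}
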