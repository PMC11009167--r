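# Shared fixture builders and independent brute-force oracles.

# toy call matrix from dense alt/ref integer matrices
toy_vcm <- function(alt, ref = NULL, barcodes = NULL, sites = NULL) {
  alt <- as.matrix(alt)
  if (is.null(ref)) ref <- matrix(0, nrow(alt), ncol(alt))
  if (is.null(barcodes)) barcodes <- sprintf("b%02d", seq_len(nrow(alt)))
  if (is.null(sites))
    sites <- tibble::tibble(chrom = paste0("chr", seq_len(ncol(alt))),
                            pos = 100L + seq_len(ncol(alt)),
                            ref = "A", alt = "T")
  variant_call_matrix(Matrix::Matrix(alt, sparse = TRUE),
                      Matrix::Matrix(as.matrix(ref), sparse = TRUE),
                      barcodes, sites)
}

toy_alignment <- function(seqs) {
  states <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(states) <- names(seqs) %||% sprintf("c%02d", seq_along(seqs))
  sites <- tibble::tibble(chrom = paste0("chr", seq_len(ncol(states))),
                          pos = seq_len(ncol(states)) + 10L,
                          ref = "A", alt = "T")
  cell_alignment(states, sites)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force per-entry filter oracle on dense matrices
oracle_filter <- function(alt, germline_drop = logical(ncol(alt)),
                          min_umis = 8, min_barcodes = 4) {
  alt <- as.matrix(alt)
  alt <- alt[, !germline_drop, drop = FALSE]
  for (i in seq_len(nrow(alt))) for (j in seq_len(ncol(alt)))
    if (alt[i, j] > 0 && alt[i, j] < min_umis) alt[i, j] <- 0
  keep <- vapply(seq_len(ncol(alt)),
                 function(j) sum(alt[, j] >= min_umis) >= min_barcodes, TRUE)
  alt[, keep, drop = FALSE]
}

# brute-force double-loop p-distance oracle
oracle_p_distance <- function(states) {
  n <- nrow(states)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    comp <- 0; diff <- 0
    for (s in seq_len(ncol(states))) {
      a <- states[i, s]; b <- states[j, s]
      if (a != "?" && b != "?") {
        comp <- comp + 1
        if (a != b) diff <- diff + 1
      }
    }
    d[i, j] <- if (comp > 0) diff / comp else 0
  }
  dimnames(d) <- list(rownames(states), rownames(states))
  d
}

# naive O(n^3) UPGMA oracle with the same tie-break (smallest i, then j);
# returns the implied tip-tip cophenetic matrix (2 x merge height)
oracle_upgma_cophenetic <- function(dm) {
  n <- nrow(dm)
  D <- as.matrix(dm)
  members <- as.list(seq_len(n))
  size <- rep(1, n)
  active <- rep(TRUE, n)
  coph <- matrix(0, n, n, dimnames = dimnames(dm))
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i >= j || !active[i] || !active[j]) next
      if (D[i, j] < bestd) { bestd <- D[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    for (a in members[[i]]) for (b in members[[j]])
      coph[a, b] <- coph[b, a] <- bestd
    for (z in seq_len(n)) {
      if (!active[z] || z == i || z == j) next
      D[i, z] <- D[z, i] <- (size[i] * D[z, i] + size[j] * D[z, j]) /
        (size[i] + size[j])
    }
    members[[i]] <- c(members[[i]], members[[j]])
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
  }
  coph
}

# random binary rooted tree with positive branch lengths
rand_tree <- function(n, seed) {
  set.seed(seed)
  t <- ape::rtree(n)
  t$edge.length <- t$edge.length + 0.05
  t
}

# igraph-based patristic distance oracle over all vertices
oracle_dist_all <- function(t, weighted = TRUE) {
  g <- igraph::graph_from_edgelist(t$edge, directed = FALSE)
  w <- if (weighted) t$edge.length else rep(1, nrow(t$edge))
  igraph::distances(g, weights = w)
}

# random feature table + metadata for model-layer tests (no trees involved)
rand_cohort <- function(n_samples, n_reps, seed, signal = TRUE) {
  set.seed(seed)
  ids <- sprintf("S%03d", seq_len(n_samples))
  md <- tibble::tibble(sample_id = ids,
                       age = runif(n_samples, 21, 82),
                       sex = sample(c("F", "M"), n_samples, replace = TRUE))
  ft <- tibble::tibble(sample_id = rep(ids, each = n_reps),
                       replicate_id = rep(seq_len(n_reps), n_samples))
  for (m in metric_catalog()$metric) ft[[m]] <- rnorm(n_samples * n_reps)
  if (signal) {
    age_rep <- md$age[match(ft$sample_id, md$sample_id)]
    ft$tipRootPatr <- 0.05 * age_rep + rnorm(nrow(ft), sd = 0.3)
    ft$mMaxEigen <- -0.03 * age_rep + rnorm(nrow(ft), sd = 0.3)
  }
  list(features = ft, metadata = md)
}
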