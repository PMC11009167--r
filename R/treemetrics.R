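#' @keywords internal
pvar <- function(x) mean((x - mean(x))^2)   # population variance

# adjacency (weighted by branch length or unit) over all tree vertices;
# the root edge, when present, is not part of the tree graph
tree_adjacency <- function(t, weighted = TRUE) {
  m <- length(t$tip.label) + t$Nnode
  A <- matrix(0, m, m)
  w <- if (weighted) t$edge.length else rep(1, nrow(t$edge))
  A[t$edge] <- w
  A[t$edge[, c(2, 1)]] <- w
  A
}

graph_laplacian <- function(A) diag(rowSums(A)) - A

#' Spectral tree-shape features (Group I)
#'
#' Features of two spectral transforms of a tree: the modified graph
#' Laplacian `MGL = diag(rowSums(P)) - P`, where `P` is the all-vertices
#' patristic distance matrix (a distance Laplacian, positive semi-definite),
#' and the ordinary graph Laplacians of the tree graph (branch-length
#' weighted for `lmax_graph`, unweighted for `AC_2`).
#'
#' Returned values: `mMaxEigen` (largest MGL eigenvalue), `mMax_eigengap`
#' (largest difference between consecutive descending MGL eigenvalues — a
#' heuristic for modality in the division structure), `eigengap_pos`
#' (1-based position of that gap), `spec_skewness` and `spec_kurtosis`
#' (population skewness / excess kurtosis of the MGL spectrum),
#' `spec_entropy` (Shannon entropy of the spectrum normalized to sum one),
#' `AC_2` (algebraic connectivity: second-smallest eigenvalue of the
#' unweighted Laplacian) and `lmax_graph` (largest eigenvalue of the
#' weighted Laplacian).
#'
#' @param t a `phylo` tree with at least 3 tips.
#' @return Named numeric vector of 8 values.
#' @export
spectral_features <- function(t) {
  if (length(t$tip.label) < 3) tc_abort("need at least 3 tips", "metrics")
  P <- ape::dist.nodes(t)
  MGL <- diag(rowSums(P)) - P
  ev <- eigen(MGL, symmetric = TRUE, only.values = TRUE)$values  # descending
  gaps <- ev[-length(ev)] - ev[-1]
  m2 <- pvar(ev)
  ctr <- ev - mean(ev)
  skew <- if (m2 > 0) mean(ctr^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean(ctr^4) / m2^2 - 3 else 0
  evp <- pmax(ev, 0)
  s <- sum(evp)
  ent <- if (s > 0) { p <- evp / s; -sum(ifelse(p > 0, p * log(p), 0)) } else 0
  L0 <- graph_laplacian(tree_adjacency(t, weighted = FALSE))
  ev0 <- eigen(L0, symmetric = TRUE, only.values = TRUE)$values
  Lw <- graph_laplacian(tree_adjacency(t, weighted = TRUE))
  evw <- eigen(Lw, symmetric = TRUE, only.values = TRUE)$values
  c(mMaxEigen = ev[1], mMax_eigengap = max(gaps),
    eigengap_pos = as.numeric(which.max(gaps)),
    spec_skewness = skew, spec_kurtosis = kurt, spec_entropy = ent,
    AC_2 = ev0[length(ev0) - 1L], lmax_graph = evw[1])
}

#' Branch-length statistics (Group II)
#'
#' Aggregate statistics of the edge length distribution: total, mean, median,
#' population variance, maximum, Shannon entropy of lengths normalized to
#' sum one, and the internal-to-terminal length ratio (0 with a warning when
#' the terminal sum is zero).
#'
#' @param t a `phylo` tree with at least one edge.
#' @return Named numeric vector of 7 values.
#' @export
branch_stats <- function(t) {
  b <- t$edge.length
  if (length(b) == 0) tc_abort("tree has no edges", "metrics")
  tot <- sum(b)
  ent <- if (tot > 0) { p <- b / tot; -sum(ifelse(p > 0, p * log(p), 0)) } else 0
  n_tip <- length(t$tip.label)
  internal <- t$edge[, 2] > n_tip
  int_sum <- sum(b[internal]); ext_sum <- sum(b[!internal])
  if (ext_sum == 0) {
    warning("terminal branch length sum is 0; bl_int_ext_ratio set to 0")
    ratio <- 0
  } else ratio <- int_sum / ext_sum
  c(bl_total = tot, bl_mean = mean(b), bl_median = median(b),
    bl_var = pvar(b), bl_max = max(b), bl_entropy = ent,
    bl_int_ext_ratio = ratio)
}

# topological tip depths (edges from root)
tip_depths_topo <- function(t) {
  n <- length(t$tip.label)
  d <- integer(n + t$Nnode)
  for (nd in postorder_nodes(t)) {
    kids <- t$edge[t$edge[, 1] == nd, 2]
    d[kids] <- d[nd] + 1L
  }
  d[seq_len(n)]
}

#' Classical imbalance and shape statistics (Group III)
#'
#' Well-known phylogenetic statistics: normalized Colless imbalance,
#' normalized Sackin index (mean topological tip depth), normalized cherry
#' count, the Pybus–Harvey gamma statistic, treeness (internal / total branch
#' length), the B1 and B2 balance indices and the maximum topological depth.
#' Non-binary nodes are resolved arbitrarily with zero-length edges (with a
#' warning). On non-ultrametric trees gamma uses the mean tip depth as the
#' present.
#'
#' @param t a binary rooted `phylo` tree with at least 4 tips.
#' @return Named numeric vector of 8 values.
#' @export
classical_stats <- function(t) {
  n <- length(t$tip.label)
  if (n < 4) tc_abort("need at least 4 tips", "metrics")
  if (!ape::is.binary.phylo(t)) {
    warning("non-binary nodes resolved arbitrarily with zero-length edges")
    t <- ape::multi2di(t)
    t$edge.length[is.na(t$edge.length)] <- 0
  }
  desc <- edge_tip_descendants(t)
  n_below <- vapply(desc, length, 1L)
  # per internal node: tips below each of its two children
  colless <- 0
  for (nd in (n + 1L):(n + t$Nnode)) {
    es <- which(t$edge[, 1] == nd)
    colless <- colless + abs(n_below[es[1]] - n_below[es[2]])
  }
  colless_norm <- colless / ((n - 1) * (n - 2) / 2)
  depths <- tip_depths_topo(t)
  sackin_norm <- sum(depths) / n
  is_tip <- t$edge[, 2] <= n
  kids_tips <- tapply(is_tip, t$edge[, 1], sum)
  cherries <- sum(kids_tips == 2)
  cherries_norm <- cherries / floor(n / 2)
  gamma <- ph_gamma(t)
  b <- t$edge.length
  tot <- sum(b)
  treeness <- if (tot > 0) sum(b[!is_tip]) / tot else 0
  # B1: internal non-root nodes, reciprocal of max topological tip depth below
  node_depth <- integer(n + t$Nnode)
  for (nd in postorder_nodes(t)) {
    kids <- t$edge[t$edge[, 1] == nd, 2]
    node_depth[kids] <- node_depth[nd] + 1L
  }
  max_below <- integer(n + t$Nnode)
  max_below[seq_len(n)] <- 0L
  for (nd in rev(postorder_nodes(t))) {
    if (nd <= n) next
    kids <- t$edge[t$edge[, 1] == nd, 2]
    max_below[nd] <- max(max_below[kids] + 1L)
  }
  root <- n + 1L
  internal_nonroot <- setdiff((n + 1L):(n + t$Nnode), root)
  B1 <- sum(1 / max_below[internal_nonroot])
  p_k <- 2^(-depths)
  B2 <- -sum(p_k * log(p_k))
  c(colless_norm = colless_norm, sackin_norm = sackin_norm,
    cherries_norm = cherries_norm, gamma_stat = gamma, treeness = treeness,
    B1 = B1, B2 = B2, max_depth_topo = max(depths))
}

# Pybus-Harvey gamma from node times; present = mean tip depth when the tree
# is not ultrametric
ph_gamma <- function(t) {
  n <- length(t$tip.label)
  depth <- ape::node.depth.edgelength(t)
  u <- sort(depth[(n + 1L):(n + t$Nnode)])       # internal node times, root = 0
  Tp <- mean(depth[seq_len(n)])                  # the present
  times <- c(u, Tp)                              # u_1 = 0 (root) .. u_{n-1}, present
  g <- diff(times)                               # g_k for k = 2..n
  kg <- (2:n) * g
  Tg <- sum(kg)
  if (Tg <= 0) return(0)
  Ti <- cumsum(kg)                               # T_i for i = 2..n
  inner <- sum(Ti[seq_len(n - 2)])               # i = 2..n-1
  (inner / (n - 2) - Tg / 2) / (Tg * sqrt(1 / (12 * (n - 2))))
}

#' Tip-distance statistics (Group IV)
#'
#' Summary statistics of the tip-tip patristic distance matrix (mean,
#' population variance and maximum over unordered pairs), the total-length
#' normalized mean `tipDistNorm`, and mean / population variance of
#' root-to-tip patristic distances (`tipRootPatr`, `tipRootPatr_var`).
#'
#' @param t a `phylo` tree with at least 2 tips.
#' @return Named numeric vector of 6 values.
#' @export
tipdist_stats <- function(t) {
  n <- length(t$tip.label)
  if (n < 2) tc_abort("need at least 2 tips", "metrics")
  depth <- ape::node.depth.edgelength(t)
  root_tip <- depth[seq_len(n)]
  ct <- ape::cophenetic.phylo(t)
  pairs <- ct[upper.tri(ct)]
  tot <- sum(t$edge.length)
  if (tot == 0) {
    warning("total branch length is 0; tipDistNorm set to 0")
    tdn <- 0
  } else tdn <- mean(pairs) / tot
  c(tipDist_mean = mean(pairs), tipDist_var = pvar(pairs),
    tipDist_max = max(pairs), tipDistNorm = tdn,
    tipRootPatr = mean(root_tip), tipRootPatr_var = pvar(root_tip))
}

#' Powergraph features (Group V)
#'
#' Laplacian spectrum of the square of the unweighted tree graph (vertices
#' adjacent iff their graph distance is at most 2 edges): largest eigenvalue
#' `pg_lmax` and second-smallest (algebraic connectivity) `pg_AC2`.
#'
#' @param t a `phylo` tree with at least 3 tips.
#' @return Named numeric vector of 2 values.
#' @export
powergraph_features <- function(t) {
  if (length(t$tip.label) < 3) tc_abort("need at least 3 tips", "metrics")
  A <- tree_adjacency(t, weighted = FALSE)
  A2 <- ((A %*% A + A) > 0) * 1
  diag(A2) <- 0
  ev <- eigen(graph_laplacian(A2), symmetric = TRUE, only.values = TRUE)$values
  c(pg_lmax = ev[1], pg_AC2 = ev[length(ev) - 1L])
}

#' The 31-metric tree-shape feature vector
#'
#' Concatenates the five feature groups — spectral (I, 8 values),
#' branch-length (II, 7), classical (III, 8), tip-distance (IV, 6) and
#' powergraph (V, 2) — into one named vector of 31 tree-shape metrics.
#' All metrics are invariant to tip-label permutation and child-order
#' rotation; deterministic.
#'
#' @param t a binary rooted `phylo` tree with at least 4 tips.
#' @param tree_id,sample_id,replicate_id optional identifiers attached as
#'   attributes.
#' @return A `tree_features` named numeric vector of length 31 with a
#'   `group` attribute.
#' @examples
#' tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1.5,d:0.5):1);")
#' compute_features(tr)[c("tipRootPatr", "colless_norm")]
#' @export
compute_features <- function(t, tree_id = NULL, sample_id = NULL,
                             replicate_id = NULL) {
  vals <- c(spectral_features(t), branch_stats(t), classical_stats(t),
            tipdist_stats(t), powergraph_features(t))
  stopifnot(length(vals) == 31, !anyDuplicated(names(vals)))
  structure(vals, group = metric_catalog()$group,
            tree_id = tree_id, sample_id = sample_id,
            replicate_id = replicate_id, class = "tree_features")
}

#' Catalogue of the 31 tree metrics
#'
#' @return Tibble with columns `metric` and `group` (I-V) in canonical order.
#' @export
metric_catalog <- function() {
  tibble::tibble(
    metric = c("mMaxEigen", "mMax_eigengap", "eigengap_pos", "spec_skewness",
               "spec_kurtosis", "spec_entropy", "AC_2", "lmax_graph",
               "bl_total", "bl_mean", "bl_median", "bl_var", "bl_max",
               "bl_entropy", "bl_int_ext_ratio",
               "colless_norm", "sackin_norm", "cherries_norm", "gamma_stat",
               "treeness", "B1", "B2", "max_depth_topo",
               "tipDist_mean", "tipDist_var", "tipDist_max", "tipDistNorm",
               "tipRootPatr", "tipRootPatr_var",
               "pg_lmax", "pg_AC2"),
    group = rep(c("I", "II", "III", "IV", "V"), c(8, 7, 8, 6, 2)))
}

#' @exportS3Method base::print
print.tree_features <- function(x, ...) {
  cat("<tree_features> 31 metrics")
  if (!is.null(attr(x, "sample_id")))
    cat(" [", attr(x, "sample_id"), "/", attr(x, "replicate_id"), "]", sep = "")
  cat("\n")
  print(unclass(setNames(as.numeric(x), names(x))))
  invisible(x)
}

#' @export
tidy.tree_features <- function(x, ...) {
  tibble::tibble(metric = names(x), group = attr(x, "group"),
                 value = as.numeric(x))
}

#' Feature table for a set of trees
#'
#' Computes [compute_features()] for every tree and assembles a tidy table,
#' one row per tree, with identifier columns followed by the 31 metrics.
#'
#' @param trees list of `phylo` trees.
#' @param sample_id,replicate_id vectors recycled along `trees`.
#' @return Tibble with columns `sample_id`, `replicate_id` and the 31 metrics.
#' @export
compute_feature_table <- function(trees, sample_id = "S001",
                                  replicate_id = seq_along(trees)) {
  sample_id <- rep_len(sample_id, length(trees))
  replicate_id <- rep_len(replicate_id, length(trees))
  rows <- purrr::map(seq_along(trees), function(i) {
    v <- compute_features(trees[[i]])
    dplyr::bind_cols(tibble::tibble(sample_id = sample_id[i],
                                    replicate_id = replicate_id[i]),
                     tibble::as_tibble_row(setNames(as.numeric(v), names(v))))
  })
  dplyr::bind_rows(rows)
}
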