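#' Pairwise p-distances between cells
#'
#' For each pair of cells, the proportion of sites at which both carry an
#' informative state (`A` or `R`) and the states differ — the "raw"
#' substitution model with pairwise deletion of missing data. Pairs with zero
#' comparable sites get distance 0; their count is reported in a warning
#' ("complete" deletion, which drops every site with any `?`, is available
#' behind `deletion`).
#'
#' @param a a [cell_alignment()] with at least two cells.
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return A symmetric numeric matrix with zero diagonal, barcode dimnames.
#' @export
p_distance <- function(a, deletion = c("pairwise", "complete")) {
  stopifnot(inherits(a, "cell_alignment"))
  deletion <- match.arg(deletion)
  if (length(a$cells) < 2) tc_abort("need at least 2 cells", "pdist")
  st <- a$states
  if (deletion == "complete") {
    keep <- colSums(st == "?") == 0
    st <- st[, keep, drop = FALSE]
  }
  XA <- (st == "A") * 1
  XR <- (st == "R") * 1
  eq <- tcrossprod(XA) + tcrossprod(XR)
  comp <- tcrossprod(XA + XR)
  diffn <- comp - eq
  d <- matrix(0, nrow(st), nrow(st), dimnames = list(a$cells, a$cells))
  pos <- comp > 0
  d[pos] <- diffn[pos] / comp[pos]
  n_empty <- (sum(!pos) - sum(!pos & row(pos) == col(pos))) / 2
  if (n_empty > 0)
    warning(sprintf("%d cell pair(s) had no comparable sites; distance set to 0",
                    n_empty))
  diag(d) <- 0
  d
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomerative clustering: the closest pair of clusters is
#' merged at height d/2 and distances to the merged cluster are size-weighted
#' averages. Ties are broken by the smallest (row, column) index pair in the
#' current label order, so results are reproducible across platforms. The
#' output is a rooted, binary, ultrametric `phylo` tree.
#'
#' @param dm symmetric numeric matrix with tip labels as dimnames (e.g. from
#'   [p_distance()]).
#' @return An ape `phylo` object.
#' @examples
#' dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
#'              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' ape::write.tree(upgma(dm))
#' @export
upgma <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 2) tc_abort("need at least 2 tips", "upgma")
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-12, check.attributes = FALSE)))
    tc_abort("distance matrix is not symmetric", "upgma")
  labels <- rownames(dm) %||% paste0("t", seq_len(n))

  D <- dm
  diag(D) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  height <- numeric(n)          # current height of cluster at each slot
  node_of <- seq_len(n)         # phylo node id occupying each slot
  # internal node for merge step s is 2n - s, so the last merge is root n+1
  edge <- matrix(0L, 2L * (n - 1L), 2L)
  edge_len <- numeric(2L * (n - 1L))
  ne <- 0L
  for (s in seq_len(n - 1L)) {
    # column-major which.min finds, among tied pairs (i < j), the smallest i
    # then the smallest j: pair (i, j) is first met at (row j, col i)
    k <- which.min(D)
    j <- ((k - 1L) %% n) + 1L
    i <- ((k - 1L) %/% n) + 1L
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    h <- D[i, j] / 2
    node <- 2L * n - s
    for (child in c(i, j)) {
      ne <- ne + 1L
      edge[ne, ] <- c(node, node_of[child])
      edge_len[ne] <- max(h - height[child], 0)
    }
    # size-weighted average linkage update into slot i
    z <- which(active & seq_len(n) != i & seq_len(n) != j)
    if (length(z))
      D[i, z] <- D[z, i] <- (size[i] * D[z, i] + size[j] * D[z, j]) /
        (size[i] + size[j])
    active[j] <- FALSE
    D[j, ] <- Inf; D[, j] <- Inf; D[i, i] <- Inf
    size[i] <- size[i] + size[j]
    height[i] <- h
    node_of[i] <- node
  }
  tr <- structure(list(edge = edge, edge.length = edge_len,
                       tip.label = labels, Nnode = n - 1L),
                  class = "phylo")
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

#' Write / read trees in Newick format
#'
#' The writer serializes with 15 significant digits so branch lengths
#' round-trip to 1e-12 relative accuracy; labels containing characters
#' outside `[A-Za-z0-9.-]` are single-quoted. The reader wraps
#' [ape::read.tree()] with a bracket-balance pre-check that reports the
#' character offset of the first structural error.
#'
#' @param t an ape `phylo` tree.
#' @param path file path.
#' @return `path` invisibly for the writer; a `phylo` for the reader.
#' @export
write_newick <- function(t, path) {
  writeLines(newick_string(t), path)
  invisible(path)
}

newick_string <- function(t) {
  stopifnot(inherits(t, "phylo"))
  n <- length(t$tip.label)
  quote_lab <- function(x) {
    bad <- grepl("[^A-Za-z0-9.-]", x)
    x[bad] <- paste0("'", gsub("'", "''", x[bad]), "'")
    x
  }
  labs <- quote_lab(t$tip.label)
  children <- split(seq_len(nrow(t$edge)), t$edge[, 1])
  strs <- character(n + t$Nnode)
  ord <- rev(postorder_nodes(t))   # children before parents
  for (nd in ord) {
    if (nd <= n) { strs[nd] <- labs[nd]; next }
    es <- children[[as.character(nd)]]
    parts <- vapply(es, function(e) {
      paste0(strs[t$edge[e, 2]], ":",
             format(t$edge.length[e], digits = 15, scientific = FALSE,
                    trim = TRUE))
    }, "")
    strs[nd] <- paste0("(", paste(parts, collapse = ","), ")")
  }
  root <- setdiff(t$edge[, 1], t$edge[, 2])[1]
  out <- strs[root]
  if (!is.null(t$root.edge))
    out <- paste0(out, ":", format(t$root.edge, digits = 15,
                                   scientific = FALSE, trim = TRUE))
  paste0(out, ";")
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  in_quote <- FALSE
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  for (k in seq_along(chars)) {
    ch <- chars[k]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0)
        tc_abort(sprintf("Newick parse error: unmatched ')' at character %d", k),
                 "newick")
    }
  }
  if (depth != 0)
    tc_abort(sprintf("Newick parse error: %d unclosed '(' at character %d",
                     depth, length(chars)), "newick")
  if (!grepl(";\\s*$", txt))
    tc_abort(sprintf("Newick parse error: missing terminal ';' at character %d",
                     nchar(txt)), "newick")
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) tc_abort("Newick parse error at character 1", "newick")
  unquote_lab <- function(x) {
    q <- grepl("^'.*'$", x)
    x[q] <- gsub("''", "'", sub("^'(.*)'$", "\\1", x[q]))
    x
  }
  tr$tip.label <- unquote_lab(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- unquote_lab(tr$node.label)
  tr
}

#' Infer UPGMA trees for all pseudo-replicates of a sample
#'
#' Maps [p_distance()] then [upgma()] over a list of pseudo-replicate
#' alignments; failures are re-signalled with the replicate index.
#'
#' @param alignments list of [cell_alignment()] objects.
#' @return List of `phylo` trees, one per replicate.
#' @export
infer_sample_trees <- function(alignments) {
  lapply(seq_along(alignments), function(r) {
    tryCatch(upgma(p_distance(alignments[[r]])),
             error = function(e) tc_abort(
               sprintf("replicate %d: %s", r, conditionMessage(e)), "phylo"))
  })
}

#' Is a tree ultrametric?
#'
#' Checks that all root-to-tip path lengths agree to a relative tolerance.
#'
#' @param t a `phylo` tree.
#' @param rtol relative tolerance (default 1e-9).
#' @return Logical scalar.
#' @export
is_ultrametric <- function(t, rtol = 1e-9) {
  n <- length(t$tip.label)
  depths <- ape::node.depth.edgelength(t)[seq_len(n)]
  rng <- max(depths) - min(depths)
  rng <= rtol * max(max(depths), 1e-300)
}
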