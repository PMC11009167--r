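#' Simulation configuration for synthetic cohorts
#'
#' Bundles and validates every knob of the cohort simulator. The generative
#' model is a discrete-generation birth process: a founder cell divides for
#' `divisions_base + divisions_per_year * age` generations, each division
#' drops `Poisson(mu_div)` new variants onto one daughter (infinite sites),
#' the population is capped by resampling once it exceeds a working pool, and
#' with probability `clone_rate_per_year * age` (capped at 1) a single lineage
#' acquires a fitness advantage that biases survival from its origin onward —
#' the discrete analogue of a division-rate advantage, and the mechanism that
#' makes tree imbalance grow with age. Observation noise is per-(cell, site)
#' Poisson UMI depth with Bernoulli dropout.
#'
#' @param n_samples number of samples in the cohort.
#' @param age_range length-2 numeric, lower/upper chronological age in years.
#' @param cells_per_sample tips per truth tree (cells recovered per sample).
#' @param divisions_base founder-to-sample-cell divisions at age 0.
#' @param divisions_per_year additional divisions per year of age.
#' @param mu_div mean new somatic variants per division (Poisson).
#' @param clone_rate_per_year per-year probability that a driver clone arises.
#' @param clone_advantage multiplicative survival weight of driver-clone cells.
#' @param depth_mean mean UMIs covering a site in a cell (Poisson).
#' @param dropout probability that a covered site yields zero UMIs.
#' @param sex_assignment optional character vector (`"F"`/`"M"`) of length
#'   `n_samples`; `NULL` draws sexes at random.
#' @param seed integer master seed; every stream is derived from it.
#' @return A validated `sim_config` list.
#' @examples
#' cfg <- sim_config(n_samples = 2, cells_per_sample = 50, seed = 1)
#' @export
sim_config <- function(n_samples = 18,
                       age_range = c(21, 82),
                       cells_per_sample = 1400,
                       divisions_base = 30,
                       divisions_per_year = 1.0,
                       mu_div = 0.3,
                       clone_rate_per_year = 0.01,
                       clone_advantage = 2.0,
                       depth_mean = 12,
                       dropout = 0.6,
                       sex_assignment = NULL,
                       seed = 1L) {
  stopifnot(length(age_range) == 2)
  if (age_range[1] > age_range[2])
    tc_abort("age_range must satisfy low <= high", "config")
  num <- c(n_samples = n_samples, cells_per_sample = cells_per_sample,
           divisions_base = divisions_base,
           divisions_per_year = divisions_per_year, mu_div = mu_div,
           clone_rate_per_year = clone_rate_per_year,
           clone_advantage = clone_advantage, depth_mean = depth_mean,
           dropout = dropout)
  if (any(!is.finite(num)) || any(num < 0))
    tc_abort("all rates and counts must be finite and non-negative", "config")
  if (cells_per_sample < 3)
    tc_abort("cells_per_sample must be at least 3", "config")
  if (dropout > 1)
    tc_abort("dropout is a probability and must be <= 1", "config")
  if (!is.null(sex_assignment)) {
    if (length(sex_assignment) != n_samples ||
        !all(sex_assignment %in% c("F", "M")))
      tc_abort("sex_assignment must be 'F'/'M' of length n_samples", "config")
  }
  structure(list(
    n_samples = as.integer(n_samples), age_range = as.numeric(age_range),
    cells_per_sample = as.integer(cells_per_sample),
    divisions_base = divisions_base, divisions_per_year = divisions_per_year,
    mu_div = mu_div, clone_rate_per_year = clone_rate_per_year,
    clone_advantage = clone_advantage, depth_mean = depth_mean,
    dropout = dropout, sex_assignment = sex_assignment,
    seed = as.integer(seed)), class = "sim_config")
}

#' Simulate one sample's true cell lineage tree
#'
#' Runs the discrete-generation birth process for one individual and returns
#' the genealogy of `cells_per_sample` uniformly sampled cells, collapsed to a
#' binary tree whose branch lengths are the number of somatic variants that
#' arose on each edge. Mutations respect infinite sites: every variant is born
#' on exactly one edge and is carried by exactly the tips below that edge.
#'
#' Uses the current RNG state; callers wanting reproducibility should
#' `set.seed()` first (as [simulate_cohort()] does per sample).
#'
#' @param age chronological age in years.
#' @param cfg a [sim_config()].
#' @return A `truth_record` list: `tree` (an ape `phylo` with integer branch
#'   lengths and a `root.edge` of variants shared by all cells),
#'   `per_cell_mutations` (named list of integer variant ids per tip),
#'   `variant_carriers` (list of tip-index vectors per variant), `n_variants`,
#'   `age`, and `n_divisions` (divisions ancestral to the sampled cells, root
#'   edge included).
#' @examples
#' set.seed(1)
#' tr <- simulate_lineage(40, sim_config(cells_per_sample = 20, seed = 1))
#' ape::Ntip(tr$tree)
#' @export
simulate_lineage <- function(age, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (age < cfg$age_range[1] || age > cfg$age_range[2])
    tc_abort("age outside cfg$age_range", "config")
  n_tip <- cfg$cells_per_sample
  G <- max(round(cfg$divisions_base + cfg$divisions_per_year * age),
           ceiling(log2(n_tip)))
  n_pool <- max(4L * n_tip, 8L)

  # optional driver clone: origin generation chosen uniformly
  p_clone <- min(1, cfg$clone_rate_per_year * age)
  clone_gen <- if (runif(1) < p_clone) sample.int(G, 1) else 0L

  parents <- vector("list", G)   # index into previous generation
  muts <- vector("list", G)      # new-variant count at each birth
  prev_n <- 1L
  clone_prev <- FALSE
  for (g in seq_len(G)) {
    n2 <- 2L * prev_n
    parent_full <- rep(seq_len(prev_n), each = 2L)
    m_div <- rpois(prev_n, cfg$mu_div)
    which_d <- sample.int(2L, prev_n, replace = TRUE)
    muts_full <- integer(n2)
    muts_full[2L * seq_len(prev_n) - 2L + which_d] <- m_div
    clone_full <- rep(clone_prev, each = 2L)
    if (g == clone_gen) clone_full[sample.int(n2, 1)] <- TRUE
    if (n2 > n_pool) {
      w <- ifelse(clone_full, cfg$clone_advantage, 1)
      if (all(w == 0)) w <- rep(1, n2)
      keep <- sort(sample.int(n2, n_pool, prob = w))
    } else keep <- seq_len(n2)
    parents[[g]] <- parent_full[keep]
    muts[[g]] <- muts_full[keep]
    clone_prev <- clone_full[keep]
    prev_n <- length(keep)
  }

  tips <- sort(sample.int(prev_n, n_tip))
  labels <- sprintf("cell%05d", seq_len(n_tip))

  # collapse the sampled genealogy bottom-up into Newick; each parent has at
  # most two daughters so merges are binary
  cur_cell <- tips
  cur_str <- labels
  cur_len <- muts[[G]][tips]
  anc_sum <- n_tip  # sum over generations 1..G of ancestral-cell counts
  if (G > 1) for (g in G:2) {
    par <- parents[[g]][cur_cell]
    ord <- order(par)
    par <- par[ord]; cur_str <- cur_str[ord]; cur_len <- cur_len[ord]
    first <- !duplicated(par)
    idx1 <- which(first)
    nxt_str <- character(length(idx1)); nxt_len <- numeric(length(idx1))
    for (k in seq_along(idx1)) {
      i <- idx1[k]
      if (i < length(par) && !first[i + 1L]) {
        nxt_str[k] <- paste0("(", cur_str[i], ":", cur_len[i], ",",
                             cur_str[i + 1L], ":", cur_len[i + 1L], ")")
        nxt_len[k] <- 0
      } else {
        nxt_str[k] <- cur_str[i]
        nxt_len[k] <- cur_len[i]
      }
    }
    cur_cell <- par[idx1]
    g_muts <- muts[[g - 1L]][cur_cell]
    nxt_len <- nxt_len + g_muts
    anc_sum <- anc_sum + length(idx1)
    cur_str <- nxt_str
    cur_len <- nxt_len
  }
  # generation 1 -> founder
  if (length(cur_str) == 2L) {
    root_str <- paste0("(", cur_str[1], ":", cur_len[1], ",",
                       cur_str[2], ":", cur_len[2], ")")
    root_len <- 0
  } else {
    root_str <- cur_str[1]
    root_len <- cur_len[1]
  }
  tree <- ape::read.tree(text = paste0(root_str, ":", root_len, ";"))
  if (is.null(tree$root.edge)) tree$root.edge <- root_len

  # divisions with >=1 sampled descendant: every ancestral cell at
  # generations 0..G-1 divides exactly once
  rec <- truth_from_tree(tree, labels, age)
  rec$n_divisions <- anc_sum - n_tip + 1L
  rec
}

# assign variant ids to edges (branch lengths are integer mutation counts)
# and derive per-cell and per-variant carrier sets
truth_from_tree <- function(tree, labels, age) {
  n_tip <- length(tree$tip.label)
  m_edge <- round(tree$edge.length)
  desc <- edge_tip_descendants(tree)
  n_root <- round(tree$root.edge %||% 0)
  total <- sum(m_edge) + n_root
  variant_carriers <- vector("list", total)
  per_tip <- vector("list", n_tip)
  for (i in seq_len(n_tip)) per_tip[[i]] <- integer(0)
  nxt <- 1L
  if (n_root > 0) {
    ids <- nxt:(nxt + n_root - 1L); nxt <- nxt + n_root
    for (v in ids) variant_carriers[[v]] <- seq_len(n_tip)
    for (i in seq_len(n_tip)) per_tip[[i]] <- c(per_tip[[i]], ids)
  }
  for (e in seq_along(m_edge)) {
    if (m_edge[e] == 0) next
    ids <- nxt:(nxt + m_edge[e] - 1L); nxt <- nxt + m_edge[e]
    tips_e <- desc[[e]]
    for (v in ids) variant_carriers[[v]] <- tips_e
    for (i in tips_e) per_tip[[i]] <- c(per_tip[[i]], ids)
  }
  names(per_tip) <- tree$tip.label
  structure(list(tree = tree, per_cell_mutations = per_tip,
                 variant_carriers = variant_carriers, n_variants = total,
                 age = age, sex = NA_character_, sample_id = NA_character_),
            class = "truth_record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tip indices below each edge, postorder accumulation
edge_tip_descendants <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  kids <- vector("list", n_tip + n_node)
  for (e in seq_len(nrow(tree$edge)))
    kids[[tree$edge[e, 1]]] <- c(kids[[tree$edge[e, 1]]], e)
  tipset <- vector("list", n_tip + n_node)
  po <- rev(postorder_nodes(tree))  # children before parents
  for (nd in po) {
    if (nd <= n_tip) { tipset[[nd]] <- nd; next }
    s <- integer(0)
    for (e in kids[[nd]]) s <- c(s, tipset[[tree$edge[e, 2]]])
    tipset[[nd]] <- s
  }
  lapply(seq_len(nrow(tree$edge)), function(e) tipset[[tree$edge[e, 2]]])
}

# nodes ordered root -> leaves (parents before children)
postorder_nodes <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  out <- integer(n); out[1] <- root; filled <- 1L
  children <- split(tree$edge[, 2], tree$edge[, 1])
  i <- 1L
  while (i <= filled) {
    kids <- children[[as.character(out[i])]]
    if (!is.null(kids)) {
      out[(filled + 1L):(filled + length(kids))] <- kids
      filled <- filled + length(kids)
    }
    i <- i + 1L
  }
  out[seq_len(filled)]
}

#' Observe a truth record as noisy UMI count matrices
#'
#' Converts true per-cell variant carriage into sparse alternative/reference
#' UMI count matrices. Each (cell, site) receives `Poisson(depth_mean)` total
#' UMIs, zeroed with probability `dropout`; a carrier's UMIs all support the
#' alternative allele, a non-carrier's the reference. Site annotations
#' (chrom, pos, ref, alt) are synthesized deterministically from variant ids.
#'
#' @param truth a `truth_record` from [simulate_lineage()].
#' @param cfg the [sim_config()] used to generate it.
#' @return A [variant_call_matrix()].
#' @examples
#' set.seed(1)
#' cfg <- sim_config(cells_per_sample = 20, seed = 1)
#' m <- observe_umis(simulate_lineage(40, cfg), cfg)
#' dim(m$alt_umis)
#' @export
observe_umis <- function(truth, cfg) {
  stopifnot(inherits(truth, "truth_record"), inherits(cfg, "sim_config"))
  n_cell <- length(truth$per_cell_mutations)
  n_var <- truth$n_variants
  barcodes <- names(truth$per_cell_mutations)
  sites <- synth_sites(n_var)
  if (n_var == 0) {
    z <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n_cell, 0))
    return(variant_call_matrix(z, z, barcodes, sites))
  }
  carrier_i <- unlist(truth$variant_carriers, use.names = FALSE)
  carrier_j <- rep.int(seq_len(n_var),
                       vapply(truth$variant_carriers, length, 1L))
  carrier <- Matrix::sparseMatrix(i = carrier_i, j = carrier_j, x = TRUE,
                                  dims = c(n_cell, n_var))
  # chunk over sites to bound dense scratch memory
  ai <- aj <- ax <- ri <- rj <- rx <- list(); nb <- 0L
  block <- max(1L, floor(5e6 / n_cell))
  for (s0 in seq(1L, n_var, by = block)) {
    s1 <- min(n_var, s0 + block - 1L)
    nc <- (s1 - s0 + 1L) * n_cell
    depth <- rpois(nc, cfg$depth_mean)
    if (cfg$dropout > 0)
      depth[rbinom(nc, 1L, cfg$dropout) == 1L] <- 0L
    nz <- which(depth > 0L)
    if (length(nz) == 0) next
    i <- ((nz - 1L) %% n_cell) + 1L
    j <- ((nz - 1L) %/% n_cell) + s0
    is_alt <- as.logical(carrier[cbind(i, j)])
    nb <- nb + 1L
    ai[[nb]] <- i[is_alt]; aj[[nb]] <- j[is_alt]; ax[[nb]] <- depth[nz][is_alt]
    ri[[nb]] <- i[!is_alt]; rj[[nb]] <- j[!is_alt]; rx[[nb]] <- depth[nz][!is_alt]
  }
  alt <- Matrix::sparseMatrix(i = unlist(ai), j = unlist(aj),
                              x = as.numeric(unlist(ax)),
                              dims = c(n_cell, n_var))
  ref <- Matrix::sparseMatrix(i = unlist(ri), j = unlist(rj),
                              x = as.numeric(unlist(rx)),
                              dims = c(n_cell, n_var))
  variant_call_matrix(alt, ref, barcodes, sites)
}

# deterministic synthetic site annotations, unique (chrom, pos)
synth_sites <- function(n_var) {
  if (n_var == 0)
    return(tibble::tibble(chrom = character(0), pos = integer(0),
                          ref = character(0), alt = character(0)))
  bases <- c("A", "C", "G", "T")
  chrom <- paste0("chr", ((seq_len(n_var) - 1L) %% 22L) + 1L)
  pos <- 10000L + ((seq_len(n_var) - 1L) %/% 22L + 1L) * 10L
  ref <- bases[((seq_len(n_var) - 1L) %% 4L) + 1L]
  alt <- bases[(seq_len(n_var) %% 4L) + 1L]
  tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt)
}

#' Simulate a full synthetic cohort
#'
#' Draws ages uniformly over `cfg$age_range` (or uses `ages`), assigns sexes,
#' and runs [simulate_lineage()] + [observe_umis()] per sample on independent
#' deterministic RNG streams derived from `cfg$seed`, so changing one sample's
#' stream leaves the others untouched. Optionally writes everything to disk:
#' per sample `alt.mtx`, `ref.mtx`, `barcodes.tsv`, `variants.csv`, a truth
#' tree in Newick and true carriage as CSV, plus a cohort `metadata.csv`.
#'
#' @param cfg a [sim_config()].
#' @param ages optional explicit numeric ages (length `n_samples`).
#' @param out_dir optional directory to write cohort files into.
#' @return List with `matrices` (list of [variant_call_matrix()]), `truth`
#'   (list of `truth_record`), and `metadata` (tibble sample_id, age, sex).
#' @examples
#' co <- simulate_cohort(sim_config(n_samples = 2, cells_per_sample = 20,
#'                                  age_range = c(30, 60), seed = 7))
#' co$metadata
#' @export
simulate_cohort <- function(cfg, ages = NULL, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_samples
  set.seed(cfg$seed)
  if (is.null(ages)) {
    ages <- runif(n, cfg$age_range[1], cfg$age_range[2])
  } else {
    stopifnot(length(ages) == n)
    if (n > 0 && (min(ages) < cfg$age_range[1] || max(ages) > cfg$age_range[2]))
      tc_abort("explicit ages outside cfg$age_range", "config")
  }
  sexes <- cfg$sex_assignment %||%
    (if (n > 0) sample(c("F", "M"), n, replace = TRUE) else character(0))
  ids <- if (n > 0) sprintf("S%03d", seq_len(n)) else character(0)
  metadata <- tibble::tibble(sample_id = ids, age = ages, sex = sexes)

  matrices <- vector("list", n); truth <- vector("list", n)
  names(matrices) <- names(truth) <- ids
  for (i in seq_len(n)) {
    set.seed(sample_seed(cfg$seed, i))
    rec <- simulate_lineage(ages[i], cfg)
    rec$sample_id <- ids[i]; rec$sex <- sexes[i]
    truth[[i]] <- rec
    matrices[[i]] <- observe_umis(rec, cfg)
  }
  out <- list(matrices = matrices, truth = truth, metadata = metadata)
  if (!is.null(out_dir)) write_cohort(out, out_dir)
  out
}

# per-sample derived stream, kept under 2^31
sample_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + i * 7919) %% 2147483647)
}

write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    tc_abort(paste0("cannot create output directory: ", out_dir), "io")
  utils::write.csv(cohort$metadata, file.path(out_dir, "metadata.csv"),
                   row.names = FALSE)
  for (id in names(cohort$matrices)) {
    sdir <- file.path(out_dir, id)
    dir.create(sdir, showWarnings = FALSE)
    write_call_matrix(cohort$matrices[[id]], sdir)
    rec <- cohort$truth[[id]]
    write_newick(rec$tree, file.path(sdir, "truth_tree.nwk"))
    carriage <- tibble::tibble(
      barcode = rep(names(rec$per_cell_mutations),
                    vapply(rec$per_cell_mutations, length, 1L)),
      variant_id = unlist(rec$per_cell_mutations, use.names = FALSE))
    utils::write.csv(carriage, file.path(sdir, "truth_carriage.csv"),
                     row.names = FALSE)
  }
  invisible(out_dir)
}

#' @exportS3Method base::print
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_samples, " samples, ages ",
      x$age_range[1], "-", x$age_range[2], ", ",
      x$cells_per_sample, " cells/sample\n", sep = "")
  cat("  divisions: ", x$divisions_base, " + ", x$divisions_per_year,
      "/yr; mu_div=", x$mu_div, "; clone ", x$clone_rate_per_year,
      "/yr x", x$clone_advantage, "\n", sep = "")
  cat("  depth_mean=", x$depth_mean, ", dropout=", x$dropout,
      ", seed=", x$seed, "\n", sep = "")
  invisible(x)
}
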