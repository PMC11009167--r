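test_that("spectral features match direct small-matrix eigendecompositions", {
  # 2-tip unit-branch tree: the tree graph is a path on 3 vertices
  path3 <- ape::read.tree(text = "(a:1,b:1);")
  L0 <- treeclock:::graph_laplacian(treeclock:::tree_adjacency(path3, FALSE))
  expect_equal(sort(eigen(L0, symmetric = TRUE)$values), c(0, 1, 3))
  # independent check of every eigen feature via igraph distances
  for (seed in c(2, 13)) {
    t <- rand_tree(12, seed)
    sf <- spectral_features(t)
    P <- oracle_dist_all(t, weighted = TRUE)
    MGL <- diag(rowSums(P)) - P
    ev <- sort(eigen(MGL, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    expect_equal(sf[["mMaxEigen"]], ev[1], tolerance = 1e-8)
    gaps <- ev[-length(ev)] - ev[-1]
    expect_equal(sf[["mMax_eigengap"]], max(gaps), tolerance = 1e-8)
    expect_equal(sf[["eigengap_pos"]], which.max(gaps))
    evp <- pmax(ev, 0)                 # clamp fp-negative near-zero modes
    p <- evp / sum(evp)
    expect_equal(sf[["spec_entropy"]],
                 -sum(ifelse(p > 0, p * log(p), 0)), tolerance = 1e-8)
    A0 <- (oracle_dist_all(t, weighted = FALSE) == 1) * 1
    ev0 <- sort(eigen(diag(rowSums(A0)) - A0, symmetric = TRUE,
                      only.values = TRUE)$values)
    expect_equal(sf[["AC_2"]], ev0[2], tolerance = 1e-8)
  }
})

test_that("spectral features scale correctly with branch lengths", {
  t <- rand_tree(10, 4)
  t2 <- t; t2$edge.length <- t$edge.length * 3.7
  a <- spectral_features(t); b <- spectral_features(t2)
  expect_equal(b[["mMaxEigen"]], 3.7 * a[["mMaxEigen"]], tolerance = 1e-9)
  expect_equal(b[["mMax_eigengap"]], 3.7 * a[["mMax_eigengap"]],
               tolerance = 1e-9)
  expect_equal(b[["lmax_graph"]], 3.7 * a[["lmax_graph"]], tolerance = 1e-9)
  expect_equal(b[["AC_2"]], a[["AC_2"]])   # topology-only
  expect_error(spectral_features(ape::read.tree(text = "(a:1,b:1);")),
               "at least 3")
})

test_that("branch statistics match a flat per-edge oracle", {
  t <- rand_tree(10, 6)
  bs <- branch_stats(t)
  b <- t$edge.length
  expect_equal(bs[["bl_total"]], sum(b))
  expect_equal(bs[["bl_mean"]], mean(b))
  expect_equal(bs[["bl_median"]], median(b))
  expect_equal(bs[["bl_var"]], mean((b - mean(b))^2))
  expect_equal(bs[["bl_max"]], max(b))
  p <- b / sum(b)
  expect_equal(bs[["bl_entropy"]], -sum(p * log(p)))
  internal <- t$edge[, 2] > ape::Ntip(t)
  expect_equal(bs[["bl_int_ext_ratio"]], sum(b[internal]) / sum(b[!internal]))
  # uniform lengths maximize entropy at log(m), zero variance
  u <- t; u$edge.length <- rep(2, nrow(t$edge))
  bu <- branch_stats(u)
  expect_equal(bu[["bl_entropy"]], log(nrow(t$edge)))
  expect_equal(bu[["bl_var"]], 0)
})

test_that("classical statistics are exact on 4-tip shapes", {
  bal <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  cs <- classical_stats(bal)
  expect_equal(cs[["colless_norm"]], 0)
  expect_equal(cs[["cherries_norm"]], 1)   # 2 cherries / floor(4/2)
  expect_equal(cs[["sackin_norm"]], 2)     # all tips at depth 2
  expect_equal(cs[["max_depth_topo"]], 2)
  cat4 <- ape::read.tree(text = "(((a:1,b:1):1,c:2):1,d:3);")
  cs2 <- classical_stats(cat4)
  # Colless raw |1-3| + |1-2| + |1-1| = 3, normalized by (n-1)(n-2)/2 = 3
  expect_equal(cs2[["colless_norm"]], 1)
  expect_equal(cs2[["cherries_norm"]], 0.5)
  # B2 by hand: depths 3,3,2,1 -> -sum(2^-d log 2^-d)
  p <- 2^(-c(3, 3, 2, 1))
  expect_equal(cs2[["B2"]], -sum(p * log(p)))
  # B1: internal non-root nodes have max depths below of 1 and 2
  expect_equal(cs2[["B1"]], 1 + 1 / 2)
})

test_that("gamma statistic agrees with ape on ultrametric trees", {
  for (seed in c(1, 8, 15)) {
    set.seed(seed)
    t <- ape::rcoal(20)
    expect_equal(classical_stats(t)[["gamma_stat"]], ape::gammaStat(t),
                 tolerance = 1e-9)
  }
})

test_that("tip-distance statistics match an all-pairs path oracle", {
  t <- rand_tree(12, 9)
  td <- tipdist_stats(t)
  n <- ape::Ntip(t)
  D <- oracle_dist_all(t, weighted = TRUE)[seq_len(n), seq_len(n)]
  pairs <- D[upper.tri(D)]
  expect_equal(td[["tipDist_mean"]], mean(pairs), tolerance = 1e-10)
  expect_equal(td[["tipDist_var"]], mean((pairs - mean(pairs))^2),
               tolerance = 1e-10)
  expect_equal(td[["tipDist_max"]], max(pairs), tolerance = 1e-10)
  expect_equal(td[["tipDistNorm"]], mean(pairs) / sum(t$edge.length),
               tolerance = 1e-10)
  # 2-tip hand case
  t2 <- ape::read.tree(text = "(a:0.2,b:0.2);")
  td2 <- tipdist_stats(t2)
  expect_equal(td2[["tipDist_mean"]], 0.4)
  expect_equal(td2[["tipDist_max"]], 0.4)
  expect_equal(td2[["tipDistNorm"]], 1)
  # ultrametric: tipRootPatr = height, zero variance
  set.seed(30)
  u <- ape::rcoal(10)
  tdu <- tipdist_stats(u)
  expect_equal(tdu[["tipRootPatr_var"]], 0, tolerance = 1e-12)
  expect_equal(tdu[["tipRootPatr"]],
               max(ape::node.depth.edgelength(u)), tolerance = 1e-10)
})

test_that("powergraph features: path becomes a triangle; connectivity grows", {
  # tree graph of a 2-tip tree is a path on 3 vertices; its square is K3
  t2 <- ape::read.tree(text = "(a:1,b:1);")
  A <- treeclock:::tree_adjacency(t2, weighted = FALSE)
  A2 <- ((A %*% A + A) > 0) * 1; diag(A2) <- 0
  ev <- sort(eigen(diag(rowSums(A2)) - A2, symmetric = TRUE)$values)
  expect_equal(ev, c(0, 3, 3))
  # squaring a graph never lowers algebraic connectivity
  for (seed in 1:10) {
    t <- rand_tree(sample(5:15, 1), 100 + seed)
    pg <- powergraph_features(t)
    sf <- spectral_features(t)
    expect_gte(pg[["pg_AC2"]], sf[["AC_2"]] - 1e-10)
  }
})

test_that("the catalogue has 31 uniquely named metrics incl. the named six", {
  cat31 <- metric_catalog()
  expect_equal(nrow(cat31), 31)
  expect_false(anyDuplicated(cat31$metric) > 0)
  expect_equal(unname(table(cat31$group)[c("I", "II", "III", "IV", "V")]),
               c(8, 7, 8, 6, 2), ignore_attr = TRUE)
  expect_true(all(c("tipDistNorm", "mMax_eigengap", "mMaxEigen", "AC_2",
                    "tipRootPatr") %in% cat31$metric))
  t <- rand_tree(16, 3)
  fv <- compute_features(t)
  expect_length(fv, 31)
  expect_identical(names(fv), cat31$metric)
  expect_true(all(is.finite(fv)))
})

test_that("features are invariant to tip permutation and rotation", {
  t <- rand_tree(16, 44)
  fv <- compute_features(t)
  rot <- ape::rotateConstr(t, sample(t$tip.label))
  expect_equal(as.numeric(compute_features(rot)), as.numeric(fv),
               tolerance = 1e-8)
  # relabeling tips leaves all 31 metrics unchanged
  perm <- t
  perm$tip.label <- t$tip.label[sample(ape::Ntip(t))]
  expect_equal(as.numeric(compute_features(perm)), as.numeric(fv),
               tolerance = 1e-8)
})

test_that("feature tables have one row per tree and tidy output", {
  trees <- lapply(1:5, function(k) rand_tree(10, 200 + k))
  tab <- compute_feature_table(trees, sample_id = "S42")
  expect_equal(dim(tab), c(5, 33))
  expect_equal(tab$replicate_id, 1:5)
  td <- tidy(compute_features(trees[[1]]))
  expect_equal(nrow(td), 31)
  expect_identical(unique(td$group), c("I", "II", "III", "IV", "V"))
})

test_that("age signal reaches the feature layer on a simulated cohort", {
  cfg <- sim_config(n_samples = 30, cells_per_sample = 200,
                    age_range = c(21, 82), seed = 77)
  co <- simulate_cohort(cfg)
  rows <- lapply(seq_len(30), function(i) {
    f <- filter_variants(co$matrices[[i]])
    a <- encode_alignment(f)
    tr <- suppressWarnings(upgma(p_distance(a)))
    compute_feature_table(list(tr), sample_id = co$metadata$sample_id[i])
  })
  tab <- dplyr::bind_rows(rows)
  g14 <- metric_catalog()$metric[metric_catalog()$group %in% c("I", "IV")]
  cors <- vapply(g14, function(m) {
    v <- tab[[m]]
    if (stats::sd(v) == 0) return(0)
    abs(cor(co$metadata$age, v))
  }, 1.0)
  expect_gte(max(cors), 0.5)
})
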