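test_that("exact kNN graphs match the all-pairs oracle", {
  x <- withr::with_seed(41, matrix(rnorm(60 * 4), ncol = 4))
  k <- 5L
  g <- knn_graph(x, k = k, metric = "euclidean", mode = "exact")
  d <- as.matrix(dist(x))
  for (i in sample(60, 15)) {
    oracle <- order(d[i, ], seq_len(60))
    oracle <- setdiff(oracle, i)[1:k]
    # each oracle neighbour pair must be an edge (symmetrized union)
    for (j in oracle) {
      expect_true(any(g$edges$i == min(i, j) & g$edges$j == max(i, j)))
    }
  }
  # weights are the metric distances
  expect_equal(g$edges$w,
               d[cbind(g$edges$i, g$edges$j)])
  expect_error(knn_graph(x, k = 60), "smaller than n")
  expect_error(knn_graph(x[1, , drop = FALSE], k = 1), "at least 2")
})

test_that("simple geometric neighbour relations hold", {
  # 3 points on a line: the middle point is nearest neighbour of both ends
  x <- matrix(c(0, 1, 2), ncol = 1)
  g <- knn_graph(x, k = 1)
  expect_true(all(c("1 2", "2 3") %in% paste(g$edges$i, g$edges$j)))
  expect_false("1 3" %in% paste(g$edges$i, g$edges$j))
  # duplicated points produce a zero-weight edge
  y <- matrix(c(0, 0, 5, 9), ncol = 1)
  gy <- knn_graph(y, k = 1)
  expect_true(any(gy$edges$i == 1 & gy$edges$j == 2 & gy$edges$w == 0))
})

test_that("tanimoto kNN graphs use 1 - similarity as distance", {
  fps <- list(c(1L, 2L, 3L), c(1L, 2L, 3L), c(1L, 9L), c(7L, 8L))
  attr(fps, "n_bits") <- 16L
  g <- knn_graph(fps, k = 1, metric = "tanimoto")
  expect_true(all(g$edges$w >= 0 & g$edges$w <= 1))
  # identical fingerprints at distance zero
  expect_true(any(g$edges$i == 1 & g$edges$j == 2 & g$edges$w == 0))
})

test_that("approximate kNN reaches high recall against exact", {
  x <- withr::with_seed(43, matrix(rnorm(400 * 8), ncol = 8))
  exact <- knn_graph(x, k = 6, mode = "exact")
  approx <- knn_graph(x, k = 6, mode = "approximate", seed = 2)
  expect_gte(knn_recall(approx, exact), 0.9)
  expect_error(knn_graph(list(1L, 2L), k = 1, metric = "tanimoto",
                         mode = "approximate"), "euclidean")
})

test_that("the MST has n-1 edges, is a tree, and matches an independent oracle", {
  x <- withr::with_seed(44, matrix(rnorm(80 * 3), ncol = 3))
  g <- knn_graph(x, k = 8)
  t <- min_spanning_tree(g)
  expect_equal(nrow(t$edges), 79L)
  expect_true(is_spanning_tree(80L, t$edges))
  # same edge set, independent Kruskal implementation
  oracle <- kruskal_oracle(80L, g$edges)
  expect_equal(sum(t$edges$w), oracle$weight)
  # complete-graph cross-check against vegan's spanning tree
  gc <- knn_graph(x, k = 79)
  tc <- min_spanning_tree(gc)
  expect_equal(sum(tc$edges$w), sum(vegan::spantree(dist(x))$dist))
})

test_that("disconnected neighbour graphs are bridged by one minimal edge", {
  # two far groups; k=1 keeps them in separate components
  x <- matrix(c(0, 0.1, 0.2, 100, 100.1, 100.2), ncol = 1)
  g <- knn_graph(x, k = 1)
  t <- min_spanning_tree(g)
  expect_equal(t$n_bridges, 1L)
  expect_true(is_spanning_tree(6L, t$edges))
  # the bridge is the minimum inter-group pair (3 <-> 4)
  expect_true(any(t$edges$i == 3 & t$edges$j == 4))
})

test_that("tree layouts are deterministic with distinct coordinates", {
  x <- withr::with_seed(45, matrix(rnorm(40 * 3), ncol = 3))
  t <- min_spanning_tree(knn_graph(x, k = 4))
  c1 <- layout_tree(t, seed = 9)
  c2 <- layout_tree(t, seed = 9)
  expect_identical(c1, c2)
  expect_false(identical(c1, layout_tree(t, seed = 10)))
  expect_true(all(is.finite(c1)))
  expect_equal(nrow(unique(c1)), 40L)
  # single node sits at the origin
  one <- structure(list(n = 1L, edges = data.frame(i = integer(0),
                                                   j = integer(0),
                                                   w = numeric(0))),
                   class = "spanning_tree")
  expect_equal(layout_tree(one), matrix(c(0, 0), 1,
                                        dimnames = list(NULL, c("x", "y"))))
})

test_that("a path lays out with adjacent nodes closer than its endpoints", {
  t <- min_spanning_tree(knn_graph(matrix(as.numeric(1:5), ncol = 1),
                                   k = 1))
  co <- layout_tree(t, seed = 1)
  d <- as.matrix(dist(co))
  adjacent <- max(d[1, 2], d[2, 3], d[3, 4], d[4, 5])
  expect_lt(adjacent, d[1, 5])
})

test_that("primary maps conserve representatives and link cluster ids", {
  fx <- quality_fixture()
  reps_idx <- seq(1, 600, by = 40)  # stand-in representatives
  meta <- data.frame(id = reps_idx, cluster = seq_along(reps_idx),
                     smiles = paste0("mol", reps_idx))
  tm <- build_primary(fx$b$x[reps_idx, ], meta, k = 4, seed = 3)
  expect_equal(tm$n, length(reps_idx))
  expect_equal(nrow(tm$edges), tm$n - 1L)
  expect_true(is_spanning_tree(tm$n, tm$edges))
  expect_identical(tm$nodes$cluster, meta$cluster)
  expect_error(build_primary(fx$b$x[1, , drop = FALSE], meta[1, ]),
               "at least 2")
})

test_that("primary topology is invariant to input permutation", {
  fx <- quality_fixture()
  idx <- seq(1, 600, by = 60)
  meta <- data.frame(id = idx, cluster = seq_along(idx),
                     smiles = paste0("m", idx))
  tm1 <- build_primary(fx$b$x[idx, ], meta, k = 3, seed = 1)
  perm <- withr::with_seed(5, sample(length(idx)))
  tm2 <- build_primary(fx$b$x[idx[perm], ], meta[perm, ], k = 3, seed = 1)
  expect_setequal(edge_key(tm1$edges, tm1$nodes$id),
                  edge_key(tm2$edges, tm2$nodes$id))
})

test_that("secondary maps handle singletons, duplicates and conservation", {
  lib <- test_library()
  fps <- lib$ecfp[1:12]
  attr(fps, "n_bits") <- attr(lib$ecfp, "n_bits")
  meta <- data.frame(id = 1:12, smiles = lib$smiles[1:12])
  tm <- build_secondary(fps, meta, cluster_id = 3L, k = 4, seed = 2)
  expect_equal(tm$n, 12L)
  expect_equal(nrow(tm$edges), 11L)
  expect_equal(unique(tm$nodes$cluster), 3L)
  # singleton cluster: one node, no edges
  one <- build_secondary(fps[1], meta[1, ], cluster_id = 9L)
  expect_equal(one$n, 1L)
  expect_equal(nrow(one$edges), 0L)
  # duplicated molecules are joined by a zero-weight tree edge
  dup_fps <- fps[c(1, 1, 5, 8)]
  attr(dup_fps, "n_bits") <- attr(lib$ecfp, "n_bits")
  dup <- build_secondary(dup_fps, data.frame(id = 1:4,
                                             smiles = rep("x", 4)),
                         cluster_id = 1L, k = 2, seed = 1)
  expect_true(any(dup$edges$i == 1 & dup$edges$j == 2 & dup$edges$w == 0))
})

test_that("atlas assembly validates links and conservation", {
  fx <- quality_fixture()
  idx <- c(1, 101, 201)
  meta <- data.frame(id = idx, cluster = 1:3, smiles = paste0("m", idx))
  primary <- build_primary(fx$b$x[idx, ], meta, k = 2, seed = 1)
  lib <- test_library()
  mk_sec <- function(cid, members) {
    fps <- lib$ecfp[members]
    attr(fps, "n_bits") <- attr(lib$ecfp, "n_bits")
    build_secondary(fps, data.frame(id = members,
                                    smiles = lib$smiles[members]),
                    cluster_id = cid, k = 2, seed = 1)
  }
  secs <- list(mk_sec(1L, 1:3), mk_sec(2L, 4:8), mk_sec(3L, 9:10))
  atlas <- assemble_atlas(primary, secs, n_total = 10L)
  expect_s3_class(atlas, "nested_atlas")
  expect_equal(atlas$manifest$cluster_sizes, c(3L, 5L, 2L))
  # wrong total, missing and duplicated secondaries are all rejected
  expect_error(assemble_atlas(primary, secs, n_total = 11L), "dataset")
  expect_error(assemble_atlas(primary, secs[1:2], n_total = 8L),
               "missing secondary.*3")
  expect_error(assemble_atlas(primary, c(secs, secs[1]), n_total = 13L),
               "duplicated")
})

test_that("atlas bundles round-trip through the JSON format", {
  fx <- quality_fixture()
  idx <- c(1, 101)
  meta <- data.frame(id = idx, cluster = 1:2, smiles = paste0("m", idx))
  primary <- build_primary(fx$b$x[idx, ], meta, k = 1, seed = 1)
  lib <- test_library()
  fps1 <- lib$ecfp[1:4]; attr(fps1, "n_bits") <- 2048L
  fps2 <- lib$ecfp[5:6]; attr(fps2, "n_bits") <- 2048L
  secs <- list(
    build_secondary(fps1, data.frame(id = 1:4, smiles = lib$smiles[1:4]),
                    cluster_id = 1L, k = 2, seed = 1),
    build_secondary(fps2, data.frame(id = 5:6, smiles = lib$smiles[5:6]),
                    cluster_id = 2L, k = 1, seed = 1))
  atlas <- assemble_atlas(primary, secs, n_total = 6L)
  dir <- tempfile("atlas")
  write_atlas(atlas, dir)
  back <- read_atlas(dir)
  expect_equal(back$manifest, atlas$manifest)
  expect_equal(back$primary$nodes$id, atlas$primary$nodes$id)
  expect_equal(back$secondaries[["1"]]$edges, atlas$secondaries[["1"]]$edges)
  unlink(dir, recursive = TRUE)
})
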