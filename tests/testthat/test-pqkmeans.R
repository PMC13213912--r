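# shared small code set for the clustering tests
pqk_fixture <- function(n = 400, k_blobs = 4, seed = 21) {
  cache_get(paste0("pqk", n, k_blobs, seed), function() {
    b <- generate_mqn_blobs(n, k = k_blobs, spread = 1,
                            separation = 8 * sqrt(42), seed = seed)
    cb <- pq_codebook(b$x, L = 64, seed = seed)
    tb <- pq_sd_tables(cb)
    list(blobs = b, codebook = cb, tables = tb,
         codes = pq_encode(b$x, cb))
  })
}

test_that("well separated code blobs are recovered up to label permutation", {
  fx <- pqk_fixture()
  fit <- pq_kmeans(fx$codes, k = 4, tables = fx$tables, seed = 1)
  expect_equal(mclust::adjustedRandIndex(fit$labels, fx$blobs$labels), 1)
})

test_that("the objective is non-increasing and zero when k equals n", {
  fx <- pqk_fixture()
  fit <- pq_kmeans(fx$codes, k = 4, tables = fx$tables, seed = 2)
  expect_true(all(diff(fit$objective) <= 1e-9))
  distinct <- fx$codes[!duplicated(fx$codes), , drop = FALSE][1:30, ]
  fit_n <- pq_kmeans(distinct, k = 30, tables = fx$tables, seed = 3)
  expect_equal(fit_n$objective[length(fit_n$objective)], 0)
})

test_that("fit is deterministic in the seed and validates n >= k", {
  fx <- pqk_fixture()
  f1 <- pq_kmeans(fx$codes, k = 4, tables = fx$tables, seed = 7)
  f2 <- pq_kmeans(fx$codes, k = 4, tables = fx$tables, seed = 7)
  expect_identical(f1$centroids, f2$centroids)
  expect_identical(f1$labels, f2$labels)
  expect_error(pq_kmeans(fx$codes[1:3, ], k = 5, tables = fx$tables),
               "n >= k")
})

test_that("centroid update equals the exhaustive per-subspace scan", {
  fx <- pqk_fixture(n = 120, k_blobs = 3, seed = 22)
  labels <- fx$blobs$labels
  centroids <- fx$codes[c(1L, 50L, 100L), , drop = FALSE]
  upd <- nestedtmap:::centroid_update(fx$codes, labels, 3L, fx$tables,
                                      centroids)
  for (cl in 1:3) {
    members <- fx$codes[labels == cl, , drop = FALSE]
    for (j in 1:6) {
      # oracle: total squared table distance from every candidate codeword
      cost <- vapply(0:63, function(cand) {
        sum(fx$tables$tables[[j]][cand + 1L, members[, j] + 1L])
      }, numeric(1))
      expect_identical(upd$centroids[cl, j], which.min(cost) - 1L)
    }
  }
})

test_that("degenerate clusters keep sensible centroids", {
  fx <- pqk_fixture(n = 120, k_blobs = 3, seed = 22)
  # single-member cluster: centroid is that member's code
  labels <- rep(1L, nrow(fx$codes))
  labels[5L] <- 2L
  cent <- fx$codes[c(1L, 5L), , drop = FALSE]
  upd <- nestedtmap:::centroid_update(fx$codes, labels, 2L, fx$tables, cent)
  expect_identical(upd$centroids[2L, ], fx$codes[5L, ])
  # cluster of identical codes: centroid equals that code
  same <- fx$codes[rep(7L, 10L), , drop = FALSE]
  upd2 <- nestedtmap:::centroid_update(same, rep(1L, 10L), 1L, fx$tables,
                                       same[1L, , drop = FALSE])
  expect_identical(upd2$centroids[1L, ], fx$codes[7L, ])
  # empty cluster: centroid unchanged and flagged unpopulated
  upd3 <- nestedtmap:::centroid_update(same, rep(1L, 10L), 2L, fx$tables,
                                       rbind(same[1L, ], fx$codes[9L, ]))
  expect_identical(upd3$centroids[2L, ], fx$codes[9L, ])
  expect_identical(upd3$populated, c(TRUE, FALSE))
})

test_that("streaming assignment matches brute force and any batch split", {
  fx <- pqk_fixture()
  fit <- pq_kmeans(fx$codes, k = 4, tables = fx$tables, seed = 4)
  one <- predict(fit, fx$codes, fx$tables, batch_size = 10000L)
  two <- predict(fit, fx$codes, fx$tables, batch_size = 37L)
  expect_identical(one, two)
  # brute-force nearest-centroid oracle on a subset
  for (i in sample(nrow(fx$codes), 40)) {
    d <- pq_symmetric_distance(fx$codes[rep(i, 4), ], fit$centroids,
                               fx$tables)
    expect_identical(one$label[i], which.min(d))
    expect_equal(one$sd[i], min(d))
  }
  # a code equal to a centroid code is assigned to it with SD 0
  probe <- predict(fit, fit$centroids, fx$tables)
  expect_equal(probe$sd, rep(0, 4))
  expect_identical(probe$label, 1:4)
})

test_that("every molecule gets exactly one label and sizes conserve n", {
  fx <- pqk_fixture()
  fit <- pq_kmeans(fx$codes, k = 4, tables = fx$tables, seed = 5)
  a <- predict(fit, fx$codes, fx$tables)
  expect_length(a$label, nrow(fx$codes))
  expect_true(all(a$label %in% 1:4))
  expect_true(all(a$sd >= 0))
  expect_equal(sum(tabulate(a$label, 4)), nrow(fx$codes))
})

test_that("compaction drops empty clusters and preserves counts", {
  fx <- pqk_fixture()
  fit <- pq_kmeans(fx$codes, k = 4, tables = fx$tables, seed = 6)
  a <- predict(fit, fx$codes, fx$tables)
  # all populated: identity mapping
  comp <- compact_clusters(fit, a)
  expect_identical(comp$mapping, 1:4)
  expect_identical(comp$assignment$label, a$label)
  # force an empty cluster by dropping one label's members
  keep <- a$label != 2L
  a3 <- a[keep, ]
  comp3 <- compact_clusters(fit, a3)
  expect_equal(comp3$model$k, 3L)
  expect_identical(sort(unique(comp3$assignment$label)), 1:3)
  expect_equal(nrow(comp3$assignment), sum(keep))
})

test_that("representatives minimize SD to the centroid with stable ties", {
  fx <- pqk_fixture()
  fit <- pq_kmeans(fx$codes, k = 4, tables = fx$tables, seed = 8)
  a <- predict(fit, fx$codes, fx$tables)
  comp <- compact_clusters(fit, a)
  reps <- select_representatives(fx$codes, comp$assignment, comp$model,
                                 fx$tables)
  expect_equal(nrow(reps), comp$model$k)
  for (r in seq_len(nrow(reps))) {
    cl <- reps$cluster[r]
    members <- which(comp$assignment$label == cl)
    sds <- pq_symmetric_distance(
      fx$codes[members, , drop = FALSE],
      comp$model$centroids[rep(cl, length(members)), , drop = FALSE],
      fx$tables)
    # argmin oracle with lowest-id tie-break
    best <- min(sds)
    expect_equal(reps$sd[r], best)
    expect_identical(reps$id[r], members[which(sds <= best + 1e-12)][1L])
    expect_true(all(reps$sd[r] <= sds + 1e-12))
  }
  # singleton cluster yields its only member
  a_small <- data.frame(label = c(1L, 1L, 2L), sd = 0)
  fit_small <- fit
  fit_small$k <- 2L
  fit_small$centroids <- fit$centroids[1:2, , drop = FALSE]
  reps_small <- select_representatives(fx$codes[1:3, , drop = FALSE],
                                       a_small, fit_small, fx$tables)
  expect_identical(reps_small$id[reps_small$cluster == 2L], 3L)
})
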