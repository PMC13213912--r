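test_that("default codebook geometry covers 42-dim MQN input", {
  x <- random_count_vectors(400, seed = 1)
  cb <- pq_codebook(x, L = 256, seed = 1)
  expect_equal(cb$m, 6L)
  expect_equal(cb$d_sub, 7L)
  expect_equal(cb$L, 256L)
  expect_length(cb$codewords, 6L)
  expect_true(all(vapply(cb$codewords, function(cw) {
    all(dim(cw) == c(256L, 7L))
  }, logical(1))))
  # 6-byte codes, 7-fold compression
  codes <- pq_encode(x, cb)
  expect_equal(ncol(codes), 6L)
  expect_true(all(codes >= 0L & codes <= 255L))
  expect_equal(cb$dim / cb$m, 7)
})

test_that("codebook training is deterministic and validates inputs", {
  x <- random_count_vectors(300, seed = 2)
  cb1 <- pq_codebook(x, L = 32, seed = 9)
  cb2 <- pq_codebook(x, L = 32, seed = 9)
  expect_identical(cb1$codewords, cb2$codewords)
  expect_error(pq_codebook(x, m = 5), "not divisible")
  expect_error(pq_codebook(x[1:10, ], L = 32), "at least L")
})

test_that("a sample with exactly L distinct subvector values is learned losslessly", {
  # k-means fixed point: codewords land on the distinct values
  base <- matrix(sample(0:7, 8 * 42, replace = TRUE), nrow = 8)
  x <- base[rep(1:8, 25), , drop = FALSE]
  cb <- pq_codebook(x, L = 8, iters = 20, seed = 4)
  rec <- pq_decode(pq_encode(x, cb), cb)
  expect_equal(max(abs(rec - x)), 0, tolerance = 1e-12)
})

test_that("reconstruction error is non-increasing in codebook size", {
  x <- random_count_vectors(600, seed = 3)
  err <- vapply(c(2L, 4L, 8L), function(L) {
    cb <- pq_codebook(x, L = L, seed = 5)
    rec <- pq_decode(pq_encode(x, cb), cb)
    mean(sqrt(rowSums((x - rec)^2)))
  }, numeric(1))
  expect_true(all(diff(err) <= 1e-9))
})

test_that("encoding matches an exhaustive nearest-codeword scan", {
  x <- random_count_vectors(150, seed = 6)
  cb <- pq_codebook(x, L = 16, seed = 7)
  codes <- pq_encode(x, cb)
  # brute-force oracle: per subspace, scan all codewords directly
  for (j in 1:6) {
    cols <- ((j - 1) * 7 + 1):(j * 7)
    for (i in sample(150, 25)) {
      d <- apply(cb$codewords[[j]], 1, function(cw) {
        sum((x[i, cols] - cw)^2)
      })
      expect_identical(codes[i, j], which.min(d) - 1L)
    }
  }
})

test_that("encoding in batches equals encoding in one pass", {
  x <- random_count_vectors(230, seed = 8)
  cb <- pq_codebook(x, L = 32, seed = 9)
  expect_identical(pq_encode(x, cb, batch_size = 7L),
                   pq_encode(x, cb, batch_size = 10000L))
  expect_identical(predict(cb, x), pq_encode(x, cb))
  expect_error(pq_encode(x[, 1:20], cb), "dimension")
})

test_that("decode is the codeword concatenation and a fixed point of encode", {
  x <- random_count_vectors(100, seed = 10)
  cb <- pq_codebook(x, L = 16, seed = 11)
  # a vector assembled from codewords round-trips exactly
  idx <- c(3L, 0L, 15L, 7L, 1L, 9L)
  v <- unlist(lapply(1:6, function(j) cb$codewords[[j]][idx[j] + 1L, ]))
  expect_identical(pq_encode(matrix(v, nrow = 1), cb)[1, ], idx)
  expect_equal(pq_decode(idx, cb)[1, ], v)
  # decode then re-encode returns the same codes
  codes <- pq_encode(x, cb)
  expect_identical(pq_encode(pq_decode(codes, cb), cb), codes)
  # reconstruction error equals the per-subspace quantization error summed
  rec <- pq_decode(codes, cb)
  per_sub <- sapply(1:6, function(j) {
    cols <- ((j - 1) * 7 + 1):(j * 7)
    rowSums((x[, cols] - cb$codewords[[j]][codes[, j] + 1L, ])^2)
  })
  expect_equal(sqrt(rowSums((x - rec)^2)), sqrt(rowSums(per_sub)))
  expect_error(pq_decode(c(0L, 0L, 16L, 0L, 0L, 0L), cb), "range")
})

test_that("SD tables are symmetric, zero-diagonal squared codeword distances", {
  x <- random_count_vectors(200, seed = 12)
  cb <- pq_codebook(x, L = 16, seed = 13)
  tb <- pq_sd_tables(cb)
  for (j in 1:6) {
    tab <- tb$tables[[j]]
    expect_equal(diag(tab), rep(0, 16))
    expect_equal(tab, t(tab))
    expect_true(all(tab >= 0))
    # spot-check against direct codeword distances
    for (a in c(1L, 5L)) for (b in c(2L, 16L)) {
      expect_equal(tab[a, b],
                   sum((cb$codewords[[j]][a, ] - cb$codewords[[j]][b, ])^2))
    }
  }
})

test_that("symmetric distance matches the direct codeword formula", {
  x <- random_count_vectors(120, seed = 14)
  cb <- pq_codebook(x, L = 16, seed = 15)
  tb <- pq_sd_tables(cb)
  codes <- pq_encode(x, cb)
  a <- codes[1:40, ]
  b <- codes[41:80, ]
  sd_tab <- pq_symmetric_distance(a, b, tb)
  # oracle: sqrt of summed squared codeword distances, no tables
  sd_direct <- sqrt(rowSums((pq_decode(a, cb) - pq_decode(b, cb))^2))
  expect_equal(sd_tab, sd_direct)
  # metric basics
  expect_equal(pq_symmetric_distance(codes[1, ], codes[1, ], tb), 0)
  expect_equal(pq_symmetric_distance(a, b, tb),
               pq_symmetric_distance(b, a, tb))
})

test_that("SD is exact for codeword-exact vectors", {
  x <- random_count_vectors(90, seed = 16)
  cb <- pq_codebook(x, L = 8, seed = 17)
  tb <- pq_sd_tables(cb)
  codes <- pq_encode(x, cb)
  exact <- pq_decode(codes, cb)  # codeword-exact by construction
  d_true <- sqrt(rowSums((exact[1:30, ] - exact[31:60, ])^2))
  d_sd <- pq_symmetric_distance(codes[1:30, ], codes[31:60, ], tb)
  expect_equal(d_sd, d_true)
})

test_that("binary code shards round-trip through the byte format", {
  codes <- matrix(sample(0:255, 60, replace = TRUE), ncol = 6)
  tmp <- tempfile(fileext = ".bin")
  write_pq_codes(codes, tmp)
  expect_identical(file.size(tmp), as.double(nrow(codes) * 6))
  back <- read_pq_codes(tmp, m = 6L)
  expect_identical(back, matrix(as.integer(codes), ncol = 6))
  unlink(tmp)
})
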