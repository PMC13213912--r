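#' @title Product quantization of MQN vectors
#'
#' @description A 42-dimensional MQN vector is split into \code{m = 6}
#' contiguous subvectors of dimension 7. For each subspace a codebook of
#' \code{L = 256} codewords is learned by k-means (k-means++ initialization,
#' Euclidean distance, 20 iterations) on a training subsample, and every
#' vector is then encoded as the m-tuple of nearest-codeword indices — a
#' 6-byte code, a 7-fold compression of the 42-entry vector. Distances
#' between codes are computed with the symmetric distance (SD): precomputed
#' L x L squared codeword-distance tables are summed per subspace and the
#' square root taken, so SD is unit-compatible with Euclidean distance on
#' the original vectors and exact whenever both vectors are codeword-exact.
#' @name pq
NULL

# greedy k-means++ initialization over rows of x under squared Euclidean
# distance: each step samples several candidates from the D^2 distribution
# and keeps the one minimizing the resulting potential
kmeanspp_init <- function(x, L) {
  n <- nrow(x)
  n_cand <- 2L + as.integer(floor(log(L)))
  centers <- matrix(0, nrow = L, ncol = ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- dist2_cross(x, centers[1L, , drop = FALSE])[, 1L]
  for (j in seq_len(L - 1L)) {
    tot <- sum(d2)
    cand <- if (tot <= 0) {
      sample.int(n, n_cand, replace = TRUE)
    } else {
      sample.int(n, n_cand, replace = TRUE, prob = d2 / tot)
    }
    cand_d2 <- dist2_cross(x, x[cand, , drop = FALSE])
    pot <- colSums(pmin(cand_d2, d2))
    best <- which.min(pot)
    centers[j + 1L, ] <- x[cand[best], ]
    d2 <- pmin(d2, cand_d2[, best])
  }
  centers
}

# Lloyd iterations with fixed count; empty clusters are re-seeded from the
# point farthest from its current center
lloyd_kmeans <- function(x, centers, iters) {
  n <- nrow(x)
  L <- nrow(centers)
  assign_d2 <- NULL
  labels <- NULL
  for (it in seq_len(iters)) {
    d2 <- dist2_cross(x, centers)
    labels <- argmin_rows(d2)
    assign_d2 <- d2[cbind(seq_len(n), labels)]
    counts <- tabulate(labels, nbins = L)
    sums <- rowsum(x, labels, reorder = FALSE)
    filled <- sort(unique(labels))
    centers[filled, ] <- sums[as.character(filled), , drop = FALSE] /
      counts[filled]
    empty <- which(counts == 0L)
    if (length(empty) > 0L) {
      far <- order(assign_d2, decreasing = TRUE)
      take <- far[seq_along(empty)]
      centers[empty, ] <- x[take, , drop = FALSE]
    }
  }
  list(centers = centers, labels = labels, withinss = sum(assign_d2))
}

#' Train a product-quantization codebook
#'
#' Splits the input dimension into \code{m} contiguous subspaces and learns,
#' independently for each, a codebook of \code{L} centroids by k-means with
#' k-means++ initialization, Euclidean (L2) distance and a fixed number of
#' Lloyd iterations. Empty clusters are re-seeded from the farthest point.
#' The result is fully determined by \code{seed}.
#'
#' @param x numeric matrix of training vectors (rows), e.g. an MQN matrix
#'   from [compute_mqn()]. \code{ncol(x)} must be divisible by \code{m}.
#' @param m number of subspaces (6 for 42-dimensional MQN input).
#' @param L codewords per subspace; at most 256 so each index fits one byte.
#' @param iters Lloyd iterations per subspace.
#' @param seed integer training seed.
#' @return an object of class \code{"pq_codebook"}: list with \code{m},
#'   \code{L}, \code{d_sub}, \code{dim}, \code{codewords} (list of m
#'   L x d_sub matrices), \code{seed}.
#' @export
pq_codebook <- function(x, m = 6L, L = 256L, iters = 20L, seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  m <- stopifnot_scalar_count(m, "m")
  L <- stopifnot_scalar_count(L, "L")
  d <- ncol(x)
  if (d %% m != 0L) {
    stop(sprintf("input dimension %d is not divisible by m = %d", d, m),
         call. = FALSE)
  }
  if (L > 256L) stop("L must be at most 256 (one byte per index)",
                     call. = FALSE)
  if (nrow(x) < L) {
    stop(sprintf(paste("training sample has %d vectors but L = %d codewords",
                       "are requested; supply at least L training vectors"),
                 nrow(x), L), call. = FALSE)
  }
  d_sub <- d %/% m
  codewords <- with_seed(seed, {
    lapply(seq_len(m), function(j) {
      cols <- ((j - 1L) * d_sub + 1L):(j * d_sub)
      xs <- x[, cols, drop = FALSE]
      fit <- lloyd_kmeans(xs, kmeanspp_init(xs, L), iters)
      unname(fit$centers)
    })
  })
  structure(list(m = m, L = L, d_sub = d_sub, dim = d,
                 codewords = codewords, iters = as.integer(iters),
                 seed = as.integer(seed)),
            class = "pq_codebook")
}

#' @export
print.pq_codebook <- function(x, ...) {
  cat(sprintf(paste0("Product-quantization codebook: %d-dim vectors -> ",
                     "%d subspaces of dim %d, %d codewords each\n"),
              x$dim, x$m, x$d_sub, x$L))
  cat(sprintf("  code size: %d bytes  (compression factor %.3g)\n",
              x$m, x$dim / x$m))
  cat(sprintf("  trained with %d Lloyd iterations, seed %d\n",
              x$iters, x$seed))
  invisible(x)
}

check_codebook <- function(codebook) {
  if (!inherits(codebook, "pq_codebook")) {
    stop("'codebook' must be a pq_codebook object", call. = FALSE)
  }
}

check_codes <- function(codes, codebook) {
  codes <- as.matrix(codes)
  if (ncol(codes) != codebook$m) {
    stop("codes have ", ncol(codes), " columns; codebook expects m = ",
         codebook$m, call. = FALSE)
  }
  if (nrow(codes) > 0L &&
      (min(codes) < 0L || max(codes) >= codebook$L)) {
    stop("code indices out of range [0, L-1]", call. = FALSE)
  }
  storage.mode(codes) <- "integer"
  codes
}

#' Encode vectors into PQ codes
#'
#' Assigns each contiguous subvector to its nearest codeword by Euclidean
#' distance (lowest index on ties), processing rows in batches so peak
#' memory is set by \code{batch_size}, not by the input size.
#'
#' @param x numeric matrix of vectors, \code{ncol(x) == codebook$dim}.
#' @param codebook a [pq_codebook()] object.
#' @param batch_size rows encoded per batch.
#' @return integer matrix of codes (n x m, 0-based indices in [0, L-1]).
#' @export
pq_encode <- function(x, codebook, batch_size = 8192L) {
  check_codebook(codebook)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != codebook$dim) {
    stop("vectors have dimension ", ncol(x), "; codebook expects ",
         codebook$dim, call. = FALSE)
  }
  n <- nrow(x)
  m <- codebook$m
  d_sub <- codebook$d_sub
  codes <- matrix(0L, nrow = n, ncol = m)
  start <- 1L
  while (start <= n) {
    end <- min(start + as.integer(batch_size) - 1L, n)
    rows <- start:end
    for (j in seq_len(m)) {
      cols <- ((j - 1L) * d_sub + 1L):(j * d_sub)
      d2 <- dist2_cross(x[rows, cols, drop = FALSE],
                        codebook$codewords[[j]])
      codes[rows, j] <- argmin_rows(d2) - 1L
    }
    start <- end + 1L
  }
  codes
}

#' @rdname pq_encode
#' @param object a \code{pq_codebook}.
#' @param newdata matrix of vectors to encode.
#' @param ... passed to [pq_encode()].
#' @export
predict.pq_codebook <- function(object, newdata, ...) {
  pq_encode(newdata, object, ...)
}

#' Decode PQ codes back to vectors
#'
#' Reconstructs each vector as the concatenation of its indexed codewords.
#' The reconstruction error of a vector equals its Euclidean distance to
#' that concatenation; it is zero iff the vector is codeword-exact.
#'
#' @param codes integer code matrix (n x m, 0-based) or a single code vector.
#' @param codebook a [pq_codebook()] object.
#' @return numeric matrix (n x dim).
#' @export
pq_decode <- function(codes, codebook) {
  check_codebook(codebook)
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = 1L)
  codes <- check_codes(codes, codebook)
  out <- matrix(0, nrow = nrow(codes), ncol = codebook$dim)
  d_sub <- codebook$d_sub
  for (j in seq_len(codebook$m)) {
    cols <- ((j - 1L) * d_sub + 1L):(j * d_sub)
    out[, cols] <- codebook$codewords[[j]][codes[, j] + 1L, , drop = FALSE]
  }
  out
}

#' Precompute symmetric-distance lookup tables
#'
#' For each subspace, the L x L matrix of squared Euclidean distances
#' between codewords. These tables make the symmetric distance between two
#' codes a sum of m table lookups.
#'
#' @param codebook a [pq_codebook()] object.
#' @return object of class \code{"pq_sd_tables"}: list of m symmetric
#'   L x L matrices with zero diagonals, plus the codebook geometry.
#' @export
pq_sd_tables <- function(codebook) {
  check_codebook(codebook)
  tables <- lapply(codebook$codewords, function(cw) {
    t2 <- dist2_cross(cw, cw)
    t2 <- (t2 + t(t2)) / 2  # enforce exact symmetry against round-off
    diag(t2) <- 0
    t2
  })
  structure(list(tables = tables, m = codebook$m, L = codebook$L),
            class = "pq_sd_tables")
}

check_tables <- function(tables) {
  if (!inherits(tables, "pq_sd_tables")) {
    stop("'tables' must come from pq_sd_tables()", call. = FALSE)
  }
}

#' Symmetric distance between PQ codes
#'
#' SD(a, b) = sqrt( sum_j T_j[a_j, b_j] ) where T_j holds squared Euclidean
#' distances between the codewords of subspace j. It is symmetric, zero for
#' identical codes, and equals the true Euclidean distance whenever both
#' vectors are codeword-exact.
#'
#' @param a,b codes: integer vectors of length m or n x m matrices (paired
#'   row-wise when both are matrices of equal height).
#' @param tables a [pq_sd_tables()] object.
#' @return numeric vector of distances.
#' @export
pq_symmetric_distance <- function(a, b, tables) {
  check_tables(tables)
  if (is.null(dim(a))) a <- matrix(a, nrow = 1L)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1L)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  stopifnot(nrow(a) == nrow(b), ncol(a) == tables$m, ncol(b) == tables$m)
  s <- numeric(nrow(a))
  for (j in seq_len(tables$m)) {
    s <- s + tables$tables[[j]][cbind(a[, j] + 1L, b[, j] + 1L)]
  }
  sqrt(pmax(s, 0))
}

# all-pairs squared SD between two code sets: |A| x |B| matrix
sd2_cross <- function(a, b, tables) {
  s <- matrix(0, nrow = nrow(a), ncol = nrow(b))
  for (j in seq_len(tables$m)) {
    s <- s + tables$tables[[j]][a[, j] + 1L, b[, j] + 1L, drop = FALSE]
  }
  s
}

#' Write / read PQ code shards
#'
#' Codes persist as one unsigned byte per subspace index in a flat binary
#' shard, with a JSON sidecar manifest recording the geometry, seed, counts
#' and shard order.
#'
#' @param codes integer code matrix (0-based indices).
#' @param path output file for the binary shard.
#' @return \code{path}, invisibly.
#' @export
write_pq_codes <- function(codes, path) {
  if (max(c(-1L, codes)) > 255L || min(c(0L, codes)) < 0L) {
    stop("codes must be in [0, 255] for byte serialization", call. = FALSE)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(t(codes)), con)
  invisible(path)
}

#' @rdname write_pq_codes
#' @param m code length (bytes per molecule).
#' @export
read_pq_codes <- function(path, m) {
  bytes <- readBin(path, what = "raw", n = file.size(path))
  if (length(bytes) %% m != 0L) {
    stop("shard length is not a multiple of m = ", m, call. = FALSE)
  }
  matrix(as.integer(bytes), ncol = m, byrow = TRUE)
}
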