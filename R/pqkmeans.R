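#' @title PQk-Means: clustering directly on PQ codes
#'
#' @description A k-means-like Lloyd alternation that never leaves code
#' space. Assignment uses the symmetric distance (SD) through the L x L
#' lookup tables; the centroid update works per cluster and per subspace:
#' the member indices in a subspace are histogrammed and the histogram is
#' multiplied against the subspace's squared-distance table, giving for
#' every candidate codeword the total squared distance to all members —
#' the argmin (lowest index on ties) becomes the centroid's index in that
#' subspace. Because squared SD decomposes additively over subspaces this
#' update is the exact minimizer, so the objective (sum of squared SD to
#' assigned centroids) is non-increasing across iterations.
#' @name pqkmeans
NULL

# greedy k-means++ over codes under squared SD: several D^2-sampled
# candidates per step, keeping the one that minimizes the potential
kmeanspp_codes <- function(codes, k, tables) {
  n <- nrow(codes)
  n_cand <- 2L + as.integer(floor(log(k)))
  picks <- integer(k)
  picks[1L] <- sample.int(n, 1L)
  d2 <- sd2_cross(codes, codes[picks[1L], , drop = FALSE], tables)[, 1L]
  for (j in seq_len(k - 1L)) {
    tot <- sum(d2)
    cand <- if (tot <= 0) sample.int(n, n_cand, replace = TRUE) else
      sample.int(n, n_cand, replace = TRUE, prob = d2 / tot)
    cand_d2 <- sd2_cross(codes, codes[cand, , drop = FALSE], tables)
    pot <- colSums(pmin(cand_d2, d2))
    best <- which.min(pot)
    picks[j + 1L] <- cand[best]
    d2 <- pmin(d2, cand_d2[, best])
  }
  codes[picks, , drop = FALSE]
}

# exact per-subspace centroid update via index histograms
centroid_update <- function(codes, labels, k, tables, centroids) {
  m <- tables$m
  L <- tables$L
  counts <- tabulate(labels, nbins = k)
  populated <- counts > 0L
  new_c <- centroids
  for (j in seq_len(m)) {
    # hist[c, l]: number of members of cluster c whose j-th index is l
    hist <- matrix(0, nrow = k, ncol = L)
    tab <- table(factor(labels, levels = seq_len(k)),
                 factor(codes[, j], levels = 0:(L - 1L)))
    hist[] <- as.numeric(tab)
    cost <- hist %*% tables$tables[[j]]  # k x L total squared distance
    best <- argmin_rows(cost) - 1L
    new_c[populated, j] <- best[populated]
  }
  list(centroids = new_c, populated = populated)
}

#' Fit a PQk-Means clustering model
#'
#' Lloyd-style alternation on PQ codes: SD assignment, exact per-subspace
#' centroid update. Initialization is k-means++ in code space under SD.
#' Iterations stop at \code{iters} or as soon as the assignment stabilizes.
#' Clusters that lose all members keep their previous centroid and are
#' flagged unpopulated (they are dropped later by [compact_clusters()],
#' after full assignment). Deterministic for a fixed seed.
#'
#' @param codes integer code matrix (n x m, 0-based), e.g. from
#'   [pq_encode()]; a training subsample at scale.
#' @param k requested number of clusters (\code{k <= n}).
#' @param tables [pq_sd_tables()] built from the same codebook.
#' @param iters maximum Lloyd iterations.
#' @param seed integer seed for initialization.
#' @return object of class \code{"pq_kmeans"}: \code{centroids} (k x m
#'   integer matrix), \code{k}, \code{labels} (training assignment, 1-based),
#'   \code{objective} (per-iteration sum of squared SD, non-increasing),
#'   \code{populated} (logical k), \code{iters_run}, \code{seed}.
#' @export
pq_kmeans <- function(codes, k, tables, iters = 20L, seed = 1L) {
  check_tables(tables)
  codes <- check_codes(codes, structure(list(m = tables$m, L = tables$L),
                                        class = "pq_codebook"))
  k <- stopifnot_scalar_count(k, "k")
  n <- nrow(codes)
  if (n < k) {
    stop(sprintf("cannot fit %d clusters on %d codes (need n >= k)", k, n),
         call. = FALSE)
  }
  centroids <- with_seed(seed, kmeanspp_codes(codes, k, tables))
  labels_prev <- NULL
  objective <- numeric(0)
  populated <- rep(TRUE, k)
  labels <- NULL
  for (it in seq_len(iters)) {
    d2 <- sd2_cross(codes, centroids, tables)
    labels <- argmin_rows(d2)
    objective <- c(objective, sum(d2[cbind(seq_len(n), labels)]))
    if (!is.null(labels_prev) && identical(labels, labels_prev)) break
    labels_prev <- labels
    upd <- centroid_update(codes, labels, k, tables, centroids)
    centroids <- upd$centroids
    populated <- upd$populated
  }
  structure(list(centroids = centroids, k = k, labels = labels,
                 objective = objective, populated = populated,
                 iters_run = length(objective), seed = as.integer(seed)),
            class = "pq_kmeans")
}

#' @export
print.pq_kmeans <- function(x, ...) {
  cat(sprintf("PQk-Means model: %d centroids (%d populated on training data)\n",
              x$k, sum(x$populated)))
  cat(sprintf("  %d iterations, objective %.4g -> %.4g\n",
              x$iters_run, x$objective[1L],
              x$objective[length(x$objective)]))
  invisible(x)
}

#' Assign PQ codes to the nearest centroids
#'
#' Streams the codes through in batches of \code{batch_size}, labelling each
#' with its nearest centroid under SD (lowest centroid index on ties), so
#' the result is identical for any batch partition and peak memory is set
#' by the batch size.
#'
#' @param object a fitted [pq_kmeans()] model.
#' @param codes integer code matrix to assign.
#' @param tables [pq_sd_tables()] from the same codebook.
#' @param batch_size rows per batch.
#' @param ... unused.
#' @return data.frame with columns \code{label} (1-based cluster index) and
#'   \code{sd} (symmetric distance to the assigned centroid).
#' @export
predict.pq_kmeans <- function(object, codes, tables, batch_size = 65536L,
                              ...) {
  check_tables(tables)
  codes <- check_codes(codes, structure(list(m = tables$m, L = tables$L),
                                        class = "pq_codebook"))
  n <- nrow(codes)
  label <- integer(n)
  sdist <- numeric(n)
  start <- 1L
  while (start <= n) {
    end <- min(start + as.integer(batch_size) - 1L, n)
    rows <- start:end
    d2 <- sd2_cross(codes[rows, , drop = FALSE], object$centroids, tables)
    lab <- argmin_rows(d2)
    label[rows] <- lab
    sdist[rows] <- sqrt(pmax(d2[cbind(seq_along(rows), lab)], 0))
    start <- end + 1L
  }
  data.frame(label = label, sd = sdist)
}

#' Drop unpopulated clusters and re-index densely
#'
#' After full assignment not every learned centroid need be populated; this
#' drops empty clusters, renumbers the survivors 1..k' preserving order, and
#' remaps the labels. The mapping is retained for traceability.
#'
#' @param model a [pq_kmeans()] model.
#' @param assignment data.frame from \code{predict()} (columns label, sd).
#' @return list with \code{model} (compacted, \code{populated} all TRUE,
#'   attribute \code{mapping}: old index per new cluster), \code{assignment}
#'   (labels remapped), \code{mapping}.
#' @export
compact_clusters <- function(model, assignment) {
  stopifnot(inherits(model, "pq_kmeans"))
  sizes <- tabulate(assignment$label, nbins = model$k)
  keep <- which(sizes > 0L)
  remap <- integer(model$k)
  remap[keep] <- seq_along(keep)
  new_model <- model
  new_model$centroids <- model$centroids[keep, , drop = FALSE]
  new_model$k <- length(keep)
  new_model$populated <- rep(TRUE, length(keep))
  new_model$labels <- NULL
  attr(new_model, "mapping") <- keep
  new_assignment <- assignment
  new_assignment$label <- remap[assignment$label]
  list(model = new_model, assignment = new_assignment, mapping = keep)
}

#' Select per-cluster representative molecules
#'
#' The representative of a cluster is the member whose PQ code has minimal
#' SD to the cluster centroid; ties resolve to the lowest molecule id.
#'
#' @param codes integer code matrix of all members (row i = molecule id i,
#'   or supply \code{ids}).
#' @param assignment data.frame (label, sd) aligned with \code{codes}; a
#'   compacted assignment from [compact_clusters()].
#' @param model the compacted [pq_kmeans()] model.
#' @param tables [pq_sd_tables()] object.
#' @param ids optional molecule ids (defaults to row numbers).
#' @return data.frame with one row per populated cluster: \code{cluster},
#'   \code{id}, \code{sd}.
#' @export
select_representatives <- function(codes, assignment, model, tables,
                                   ids = seq_len(nrow(codes))) {
  check_tables(tables)
  stopifnot(nrow(codes) == nrow(assignment), length(ids) == nrow(codes))
  sdist <- pq_symmetric_distance(codes,
                                 model$centroids[assignment$label, ,
                                                 drop = FALSE],
                                 tables)
  ord <- order(assignment$label, sdist, ids)
  first <- ord[!duplicated(assignment$label[ord])]
  out <- data.frame(cluster = assignment$label[first], id = ids[first],
                    sd = sdist[first])
  out[order(out$cluster), , drop = FALSE]
}
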