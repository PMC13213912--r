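#' @title Cluster quality diagnostics
#'
#' @description Diagnostics mirroring the standard checks for PQ-compressed
#' clustering of molecule libraries: agreement between the symmetric
#' distance and the true Euclidean distance to a reference molecule;
#' within- versus between-cluster distance sampling (a small fixed design:
#' all pairs among a few molecules drawn from a few clusters); pairwise
#' distance heatmaps blocked by cluster; per-cluster dispersion of the
#' physicochemical descriptor panel (CV, IQR, range summarized by 5th /
#' median / 95th percentiles across clusters); and the cluster size
#' distribution.
#' @name quality
NULL

metric_fun <- function(metric, tables = NULL) {
  switch(metric,
    euclidean_mqn = function(x, codes, i, j) {
      sqrt(rowSums((x[i, , drop = FALSE] - x[j, , drop = FALSE])^2))
    },
    manhattan_mqn = function(x, codes, i, j) {
      rowSums(abs(x[i, , drop = FALSE] - x[j, , drop = FALSE]))
    },
    sd_pq = {
      if (is.null(tables)) stop("metric 'sd_pq' needs 'tables'",
                                call. = FALSE)
      function(x, codes, i, j) {
        pq_symmetric_distance(codes[i, , drop = FALSE],
                              codes[j, , drop = FALSE], tables)
      }
    },
    stop("unknown metric: ", metric, call. = FALSE)
  )
}

#' Symmetric distance versus Euclidean distance to a reference
#'
#' For every sample vector, pairs the true Euclidean distance to a
#' reference vector with the SD between the corresponding PQ codes, and
#' summarizes their agreement (Pearson correlation, least-squares slope
#' through the origin).
#'
#' @param x numeric matrix of sample vectors.
#' @param codebook a [pq_codebook()] object.
#' @param reference a single vector (defaults to the first row of x).
#' @param tables optional precomputed [pq_sd_tables()].
#' @return data.frame with columns \code{euclidean}, \code{sd}; attributes
#'   \code{pearson} and \code{slope}.
#' @export
sd_vs_euclidean <- function(x, codebook, reference = x[1L, ],
                            tables = pq_sd_tables(codebook)) {
  check_codebook(codebook)
  x <- as.matrix(x)
  ref <- matrix(as.numeric(reference), nrow = 1L)
  eu <- sqrt(dist2_cross(x, ref))[, 1L]
  codes <- pq_encode(x, codebook)
  ref_code <- pq_encode(ref, codebook)
  sdist <- pq_symmetric_distance(codes, ref_code, tables)
  out <- data.frame(euclidean = eu, sd = sdist)
  keep <- stats::sd(eu) > 0 && stats::sd(sdist) > 0
  attr(out, "pearson") <- if (keep) stats::cor(eu, sdist) else NA_real_
  attr(out, "slope") <- if (sum(eu^2) > 0) sum(eu * sdist) / sum(eu^2)
                        else NA_real_
  out
}

sample_design <- function(labels, n_clusters, n_per_cluster, seed) {
  sizes <- table(labels)
  eligible <- as.integer(names(sizes)[sizes >= n_per_cluster])
  if (length(eligible) < n_clusters) {
    stop(sprintf(paste("need at least %d clusters with >= %d members;",
                       "only %d available"),
                 n_clusters, n_per_cluster, length(eligible)),
         call. = FALSE)
  }
  with_seed(seed, {
    picked <- sort(sample(eligible, n_clusters))
    members <- lapply(picked, function(cl) {
      ids <- which(labels == cl)
      sort(sample(ids, n_per_cluster))
    })
    list(clusters = picked, members = members)
  })
}

#' Within- versus between-cluster distance summary
#'
#' Samples \code{n_clusters} clusters and \code{n_per_cluster} molecules
#' from each (seeded), then computes exhaustively all pairwise distances
#' among the sampled molecules: pairs inside a sampled cluster are
#' "within", pairs across different sampled clusters are "between".
#'
#' @param labels integer cluster label per molecule (1-based).
#' @param metric one of \code{"euclidean_mqn"}, \code{"manhattan_mqn"},
#'   \code{"sd_pq"}.
#' @param x MQN matrix (needed for the MQN metrics).
#' @param codes PQ code matrix (needed for \code{sd_pq}).
#' @param tables [pq_sd_tables()] (needed for \code{sd_pq}).
#' @param n_clusters,n_per_cluster sampling design.
#' @param seed sampling seed; the summary is a pure function of
#'   (data, labels, seed).
#' @return object of class \code{"distance_sample_summary"}: a one-row
#'   data.frame (metric, within_mean, within_sd, between_mean, between_sd,
#'   n_within, n_between) with the sample design attached as an attribute.
#' @export
sample_cluster_distances <- function(labels, metric = c("euclidean_mqn",
                                                        "manhattan_mqn",
                                                        "sd_pq"),
                                     x = NULL, codes = NULL, tables = NULL,
                                     n_clusters = 100L, n_per_cluster = 10L,
                                     seed = 1L) {
  metric <- match.arg(metric)
  f <- metric_fun(metric, tables)
  design <- sample_design(labels, n_clusters, n_per_cluster, seed)
  ids <- unlist(design$members)
  grp <- rep(seq_along(design$members), each = n_per_cluster)
  pairs <- utils::combn(length(ids), 2L)
  i <- ids[pairs[1L, ]]
  j <- ids[pairs[2L, ]]
  within <- grp[pairs[1L, ]] == grp[pairs[2L, ]]
  d <- f(x, codes, i, j)
  out <- data.frame(metric = metric,
                    within_mean = mean(d[within]),
                    within_sd = stats::sd(d[within]),
                    between_mean = mean(d[!within]),
                    between_sd = stats::sd(d[!within]),
                    n_within = sum(within),
                    n_between = sum(!within))
  attr(out, "design") <- c(list(n_clusters = n_clusters,
                                n_per_cluster = n_per_cluster,
                                seed = seed), design)
  class(out) <- c("distance_sample_summary", class(out))
  out
}

#' Pairwise-distance heatmap matrix blocked by cluster
#'
#' Builds the full symmetric pairwise distance matrix over
#' \code{n_clusters * n_per_cluster} sampled molecules, ordered by cluster
#' blocks (so diagonal blocks hold within-cluster distances).
#'
#' @inheritParams sample_cluster_distances
#' @return numeric matrix with attributes \code{block} (cluster id per
#'   row/column) and \code{design}.
#' @export
distance_heatmap <- function(labels, metric = c("euclidean_mqn",
                                                "manhattan_mqn", "sd_pq"),
                             x = NULL, codes = NULL, tables = NULL,
                             n_clusters = 25L, n_per_cluster = 10L,
                             seed = 1L) {
  metric <- match.arg(metric)
  f <- metric_fun(metric, tables)
  design <- sample_design(labels, n_clusters, n_per_cluster, seed)
  ids <- unlist(design$members)
  nm <- length(ids)
  idx <- expand.grid(a = seq_len(nm), b = seq_len(nm))
  d <- f(x, codes, ids[idx$a], ids[idx$b])
  mat <- matrix(d, nrow = nm, ncol = nm)
  mat <- (mat + t(mat)) / 2
  diag(mat) <- 0
  attr(mat, "block") <- rep(design$clusters, each = n_per_cluster)
  attr(mat, "design") <- design
  mat
}

#' Per-cluster descriptor dispersion statistics
#'
#' For every cluster with at least \code{min_cluster_size} members and every
#' descriptor of the panel, computes the coefficient of variation (CV =
#' sd/mean), the interquartile range and the range (max - min), then
#' summarizes each statistic by its 5th, 50th and 95th percentiles across
#' clusters (linear interpolation between order statistics). Clusters with
#' zero mean for a descriptor are excluded from that descriptor's CV (and
#' counted), since a vanishing mean makes CV uninformative.
#'
#' @param panel data.frame of per-molecule descriptors (see
#'   [compute_panel()]).
#' @param labels integer cluster label per molecule.
#' @param min_cluster_size smallest cluster entering the statistics.
#' @return object of class \code{"dispersion_stats"}: data.frame with one
#'   row per descriptor x statistic (cv, iqr, range) and columns p5,
#'   median, p95; attribute \code{cv_excluded} counts zero-mean exclusions.
#' @export
dispersion_stats <- function(panel, labels, min_cluster_size = 2L) {
  stopifnot(nrow(panel) == length(labels))
  sizes <- table(labels)
  keep_cl <- as.integer(names(sizes)[sizes >= min_cluster_size])
  rows <- list()
  excluded <- integer(0)
  for (desc in names(panel)) {
    v <- panel[[desc]]
    per_cl <- lapply(keep_cl, function(cl) {
      vals <- v[labels == cl]
      c(mean = mean(vals), sd = stats::sd(vals),
        iqr = stats::IQR(vals, type = 7), range = diff(range(vals)))
    })
    per_cl <- do.call(rbind, per_cl)
    nz <- per_cl[, "mean"] != 0
    excluded[desc] <- sum(!nz)
    cv <- per_cl[nz, "sd"] / per_cl[nz, "mean"]
    qs <- function(vals) {
      if (length(vals) == 0L) return(c(NA_real_, NA_real_, NA_real_))
      stats::quantile(vals, c(0.05, 0.5, 0.95), type = 7, names = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      descriptor = desc,
      statistic = c("cv", "iqr", "range"),
      rbind(qs(cv), qs(per_cl[, "iqr"]), qs(per_cl[, "range"]))
    )
  }
  out <- do.call(rbind, rows)
  names(out)[3:5] <- c("p5", "median", "p95")
  rownames(out) <- NULL
  attr(out, "cv_excluded") <- excluded
  attr(out, "n_clusters") <- length(keep_cl)
  class(out) <- c("dispersion_stats", class(out))
  out
}

#' Cluster size distribution
#'
#' @param labels integer cluster label per molecule (compacted, 1-based).
#' @return list with \code{sizes} (sorted decreasing) and \code{summary}
#'   (mean, sd, min, max, and the central 95\% interval).
#' @export
cluster_size_distribution <- function(labels) {
  sizes <- sort(as.integer(table(labels)), decreasing = TRUE)
  list(sizes = sizes,
       summary = c(mean = mean(sizes),
                   sd = if (length(sizes) > 1L) stats::sd(sizes) else 0,
                   min = min(sizes), max = max(sizes),
                   q2.5 = unname(stats::quantile(sizes, 0.025, type = 7)),
                   q97.5 = unname(stats::quantile(sizes, 0.975, type = 7))))
}
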