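#' @title Tree-maps: kNN graph -> minimum spanning tree -> 2D layout
#'
#' @description A tree-map organizes a set of molecules by computing a
#' k-nearest-neighbour graph under a chemical metric, reducing it to its
#' minimum spanning tree, and drawing a deterministic 2D embedding of that
#' tree. The primary map is built over cluster representatives in MQN space
#' (Euclidean); each secondary map is built over one cluster's members in
#' ECFP4 space (Tanimoto distance = 1 - similarity). Primary and secondary
#' maps are linked by cluster id into a nested atlas. Coordinates are
#' presentation only; the contractual outputs are the tree topology and
#' determinism under a fixed seed.
#' @name tmap
NULL

# distances between item subsets under the graph metric.
# items: numeric matrix (euclidean) or list of on-bit vectors (tanimoto)
item_distances <- function(items, metric, i_idx, j_idx) {
  if (metric == "euclidean") {
    sqrt(dist2_cross(items[i_idx, , drop = FALSE],
                     items[j_idx, , drop = FALSE]))
  } else {
    sub <- tanimoto_matrix(c(items[i_idx], items[j_idx]),
                           n_bits = attr(items, "n_bits"))
    1 - sub[seq_along(i_idx), length(i_idx) + seq_along(j_idx),
            drop = FALSE]
  }
}

n_items <- function(items) {
  if (is.list(items)) length(items) else nrow(items)
}

# full pairwise distance matrix (exact mode / bridging)
full_distance_matrix <- function(items, metric) {
  if (metric == "euclidean") {
    d <- sqrt(dist2_cross(items, items))
    d <- (d + t(d)) / 2
    diag(d) <- 0
    d
  } else {
    1 - tanimoto_matrix(items)
  }
}

knn_from_rowdist <- function(drow, self, k) {
  ord <- order(drow, seq_along(drow))  # distance, then index: deterministic
  ord <- ord[ord != self]
  ord[seq_len(k)]
}

#' Build a k-nearest-neighbour graph
#'
#' For each item, its k nearest neighbours under the metric (ties broken by
#' lowest index), symmetrized by keeping an edge if either endpoint lists
#' the other. Exact mode is the reference contract (all-pairs scan);
#' approximate mode (euclidean only) searches candidates along seeded
#' random projections and is assessed by neighbour recall against exact.
#'
#' @param items numeric matrix of vectors (euclidean) or a fingerprint list
#'   from [compute_ecfp4()] (tanimoto).
#' @param k neighbours per node; \code{k < n}.
#' @param metric \code{"euclidean"} or \code{"tanimoto"}.
#' @param mode \code{"exact"} or \code{"approximate"}.
#' @param seed seed for the approximate search.
#' @param n_projections,window approximate-mode tuning: number of random
#'   projections and candidate window (in units of k) per side.
#' @return object of class \code{"knn_graph"}: list with \code{n}, \code{k},
#'   \code{metric}, \code{mode}, \code{edges} (data.frame i, j, w with
#'   i < j), and the items (for exact component bridging downstream).
#' @export
knn_graph <- function(items, k = 10L, metric = c("euclidean", "tanimoto"),
                      mode = c("exact", "approximate"), seed = 1L,
                      n_projections = 12L, window = 6L) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  n <- n_items(items)
  if (n < 2L) stop("need at least 2 items for a kNN graph", call. = FALSE)
  k <- stopifnot_scalar_count(k, "k")
  if (k >= n) stop(sprintf("k = %d must be smaller than n = %d", k, n),
                   call. = FALSE)
  if (mode == "approximate" && metric != "euclidean") {
    stop("approximate mode is implemented for the euclidean metric only",
         call. = FALSE)
  }
  nbrs <- if (mode == "exact") {
    d <- full_distance_matrix(items, metric)
    lapply(seq_len(n), function(i) knn_from_rowdist(d[i, ], i, k))
  } else {
    knn_approx_euclidean(items, k, seed, n_projections, window)
  }
  from <- rep(seq_len(n), each = k)
  to <- unlist(nbrs)
  a <- pmin(from, to)
  b <- pmax(from, to)
  keep <- !duplicated(cbind(a, b))
  a <- a[keep]
  b <- b[keep]
  w <- vapply(seq_along(a), function(e) {
    item_distances(items, metric, a[e], b[e])[1L, 1L]
  }, numeric(1))
  ord <- order(a, b)
  structure(list(n = n, k = k, metric = metric, mode = mode,
                 edges = data.frame(i = a[ord], j = b[ord], w = w[ord]),
                 items = items),
            class = "knn_graph")
}

# approximate kNN for euclidean items: candidates from windows along
# seeded random projections, exact distances among candidates
knn_approx_euclidean <- function(items, k, seed, n_projections, window) {
  n <- nrow(items)
  d <- ncol(items)
  with_seed(seed, {
    cand <- vector("list", n)
    for (p in seq_len(n_projections)) {
      u <- stats::rnorm(d)
      u <- u / sqrt(sum(u^2))
      proj <- as.numeric(items %*% u)
      ord <- order(proj, seq_len(n))
      pos <- integer(n)
      pos[ord] <- seq_len(n)
      half <- window * k
      for (i in seq_len(n)) {
        lo <- max(1L, pos[i] - half)
        hi <- min(n, pos[i] + half)
        cand[[i]] <- c(cand[[i]], ord[lo:hi])
      }
    }
    lapply(seq_len(n), function(i) {
      cc <- setdiff(sort(unique(cand[[i]])), i)
      dd <- item_distances(items, "euclidean", i, cc)[1L, ]
      cc[order(dd, seq_along(cc))][seq_len(min(k, length(cc)))]
    })
  })
}

#' Neighbour recall of an approximate kNN graph against the exact one
#'
#' @param approx,exact \code{knn_graph} objects over the same items.
#' @return fraction of exact edges present in the approximate graph.
#' @export
knn_recall <- function(approx, exact) {
  key <- function(g) paste(g$edges$i, g$edges$j)
  mean(key(exact) %in% key(approx))
}

#' Minimum spanning tree of a neighbour graph
#'
#' Extracts the MST of the kNN graph. If the graph is disconnected, the
#' components are first joined through the minimum-distance inter-component
#' pair, found by exact search over component members under the graph's own
#' metric, so the result is always one tree with n - 1 edges.
#'
#' @param graph a [knn_graph()] object.
#' @return object of class \code{"spanning_tree"}: list with \code{n} and
#'   \code{edges} (data.frame i, j, w; exactly n - 1 rows), plus a count of
#'   bridging edges added.
#' @export
min_spanning_tree <- function(graph) {
  stopifnot(inherits(graph, "knn_graph"))
  edges <- graph$edges
  n <- graph$n
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$i, to = edges$j),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(g)
  n_bridges <- 0L
  while (comp$no > 1L) {
    members1 <- which(comp$membership == 1L)
    rest <- which(comp$membership != 1L)
    d <- item_distances(graph$items, graph$metric, members1, rest)
    hit <- arrayInd(which.min(d), dim(d))
    i <- members1[hit[1L]]
    j <- rest[hit[2L]]
    edges <- rbind(edges, data.frame(i = min(i, j), j = max(i, j),
                                     w = d[hit]))
    n_bridges <- n_bridges + 1L
    g <- igraph::add_edges(g, c(i, j))
    comp <- igraph::components(g)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$i, to = edges$j, weight = edges$w),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  mstg <- igraph::mst(g, weights = igraph::E(g)$weight)
  el <- igraph::as_edgelist(mstg, names = TRUE)
  i <- pmin(as.integer(el[, 1L]), as.integer(el[, 2L]))
  j <- pmax(as.integer(el[, 1L]), as.integer(el[, 2L]))
  w <- igraph::E(mstg)$weight
  ord <- order(i, j)
  structure(list(n = n,
                 edges = data.frame(i = i[ord], j = j[ord], w = w[ord]),
                 n_bridges = n_bridges),
            class = "spanning_tree")
}

#' Deterministic 2D layout of a spanning tree
#'
#' Radial embedding: the tree is rooted at its highest-degree node (lowest
#' index on ties); each node sits at radius equal to its depth, inside an
#' angular wedge proportional to its subtree's leaf count, with a small
#' seeded angular jitter that never leaves the wedge. Distinct nodes are
#' guaranteed distinct coordinates and the drawing's edges are exactly the
#' tree edges. Coordinates are presentation, not a distance embedding.
#'
#' @param tree a [min_spanning_tree()] result.
#' @param seed jitter seed; same seed, same coordinates bit-for-bit.
#' @return n x 2 numeric matrix of coordinates.
#' @export
layout_tree <- function(tree, seed = 1L) {
  stopifnot(inherits(tree, "spanning_tree"))
  n <- tree$n
  if (n == 1L) return(matrix(c(0, 0), nrow = 1L,
                             dimnames = list(NULL, c("x", "y"))))
  adj <- vector("list", n)
  for (e in seq_len(nrow(tree$edges))) {
    i <- tree$edges$i[e]
    j <- tree$edges$j[e]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  deg <- lengths(adj)
  root <- which.max(deg)  # lowest index on ties
  # BFS to get parent/depth/children in deterministic order
  parent <- integer(n)
  depth <- integer(n)
  order_bfs <- integer(n)
  visited <- logical(n)
  queue <- root
  visited[root] <- TRUE
  ptr <- 0L
  while (length(queue) > 0L) {
    v <- queue[1L]
    queue <- queue[-1L]
    ptr <- ptr + 1L
    order_bfs[ptr] <- v
    nb <- sort(adj[[v]])
    nb <- nb[!visited[nb]]
    visited[nb] <- TRUE
    parent[nb] <- v
    depth[nb] <- depth[v] + 1L
    queue <- c(queue, nb)
  }
  children <- vector("list", n)
  for (v in order_bfs) if (v != root) {
    children[[parent[v]]] <- c(children[[parent[v]]], v)
  }
  # subtree leaf counts, bottom-up in reverse BFS order
  leaves <- rep(1L, n)
  for (v in rev(order_bfs)) {
    if (length(children[[v]]) > 0L) leaves[v] <- sum(leaves[children[[v]]])
  }
  jitter <- with_seed(seed, stats::runif(n, -0.25, 0.25))
  a_lo <- numeric(n)
  a_hi <- numeric(n)
  a_lo[root] <- 0
  a_hi[root] <- 2 * pi
  coords <- matrix(0, nrow = n, ncol = 2,
                   dimnames = list(NULL, c("x", "y")))
  for (v in order_bfs) {
    width <- a_hi[v] - a_lo[v]
    if (v != root) {
      ang <- (a_lo[v] + a_hi[v]) / 2 + jitter[v] * width
      coords[v, ] <- depth[v] * c(cos(ang), sin(ang))
    }
    kids <- children[[v]]
    if (length(kids) > 0L) {
      frac <- leaves[kids] / sum(leaves[kids])
      cuts <- a_lo[v] + width * cumsum(c(0, frac))
      a_lo[kids] <- cuts[-length(cuts)]
      a_hi[kids] <- cuts[-1L]
    }
  }
  coords
}

#' Build the primary tree-map over cluster representatives
#'
#' Euclidean kNN graph on the representatives' MQN vectors, reduced to its
#' MST and laid out in 2D. Node metadata carries the molecule id, SMILES,
#' the linking cluster id, and colour channels from the descriptor panel
#' (ring count, aromatic atom count, heavy atom count, molecular weight).
#'
#' @param mqn MQN matrix of the representatives (one row per cluster).
#' @param meta data.frame with columns \code{id}, \code{cluster},
#'   \code{smiles} aligned with \code{mqn} rows.
#' @param panel descriptor panel data.frame aligned with \code{mqn} rows
#'   (optional; NA colour channels when absent).
#' @param k neighbours for the kNN graph (clamped to n - 1).
#' @param seed layout seed.
#' @param mode kNN mode, see [knn_graph()].
#' @return object of class \code{"treemap"}: list with \code{level}
#'   ("primary"), \code{cluster_id} (NA), \code{n}, \code{nodes}
#'   (data.frame node, id, cluster, smiles, x, y, colour channels),
#'   \code{edges}.
#' @export
build_primary <- function(mqn, meta, panel = NULL, k = 10L, seed = 1L,
                          mode = "exact") {
  mqn <- as.matrix(mqn)
  n <- nrow(mqn)
  if (n < 2L) stop("primary tree-map needs at least 2 representatives",
                   call. = FALSE)
  stopifnot(nrow(meta) == n)
  build_treemap(items = mqn, metric = "euclidean", meta = meta,
                panel = panel, k = k, seed = seed, mode = mode,
                level = "primary", cluster_id = NA_integer_)
}

#' Build a secondary tree-map of one cluster's members
#'
#' Tanimoto kNN graph on the members' ECFP4 fingerprints, reduced to its
#' MST and laid out in 2D. A single-member cluster yields a one-node map.
#'
#' @param fps fingerprint list from [compute_ecfp4()] for the members.
#' @param meta data.frame with columns \code{id}, \code{smiles} aligned
#'   with \code{fps}.
#' @param cluster_id the cluster this map represents.
#' @param panel optional aligned descriptor panel for colour channels.
#' @param k,seed,mode as in [build_primary()].
#' @return a \code{"treemap"} object with \code{level = "secondary"}.
#' @export
build_secondary <- function(fps, meta, cluster_id, panel = NULL, k = 10L,
                            seed = 1L, mode = "exact") {
  n <- length(fps)
  stopifnot(n >= 1L, nrow(meta) == n)
  meta$cluster <- cluster_id
  build_treemap(items = fps, metric = "tanimoto", meta = meta,
                panel = panel, k = k, seed = seed, mode = mode,
                level = "secondary", cluster_id = cluster_id)
}

build_treemap <- function(items, metric, meta, panel, k, seed, mode,
                          level, cluster_id) {
  n <- n_items(items)
  channels <- c("rings", "aromatic_atoms", "HAC", "MW")
  colour <- if (!is.null(panel)) {
    panel[intersect(channels, names(panel))]
  } else {
    as.data.frame(setNames(rep(list(rep(NA_real_, n)), length(channels)),
                           channels))
  }
  if (n == 1L) {
    nodes <- data.frame(node = 1L, id = meta$id,
                        cluster = meta$cluster, smiles = meta$smiles,
                        x = 0, y = 0, colour,
                        stringsAsFactors = FALSE)
    return(structure(list(level = level, cluster_id = cluster_id, n = 1L,
                          nodes = nodes,
                          edges = data.frame(i = integer(0), j = integer(0),
                                             w = numeric(0))),
                     class = "treemap"))
  }
  k_eff <- min(as.integer(k), n - 1L)
  graph <- knn_graph(items, k = k_eff, metric = metric, mode = mode,
                     seed = seed)
  tree <- min_spanning_tree(graph)
  coords <- layout_tree(tree, seed = seed)
  nodes <- data.frame(node = seq_len(n), id = meta$id,
                      cluster = meta$cluster, smiles = meta$smiles,
                      x = coords[, 1L], y = coords[, 2L], colour,
                      stringsAsFactors = FALSE)
  structure(list(level = level, cluster_id = cluster_id, n = n,
                 nodes = nodes, edges = tree$edges),
            class = "treemap")
}

#' @export
print.treemap <- function(x, ...) {
  cat(sprintf("%s tree-map: %d nodes, %d edges%s\n", x$level, x$n,
              nrow(x$edges),
              if (!is.na(x$cluster_id)) sprintf(" (cluster %d)",
                                                x$cluster_id) else ""))
  invisible(x)
}

#' Plot a tree-map
#'
#' Draws tree edges and nodes, optionally coloured by a metadata channel.
#'
#' @param x a \code{"treemap"} object.
#' @param colour_by node column used for colouring (default "rings").
#' @param ... passed to \code{plot.default}.
#' @export
plot.treemap <- function(x, colour_by = "rings", ...) {
  nodes <- x$nodes
  graphics::plot(nodes$x, nodes$y, type = "n", asp = 1,
                 xlab = "", ylab = "",
                 main = sprintf("%s tree-map (n = %d)", x$level, x$n), ...)
  if (nrow(x$edges) > 0L) {
    graphics::segments(nodes$x[x$edges$i], nodes$y[x$edges$i],
                       nodes$x[x$edges$j], nodes$y[x$edges$j],
                       col = "grey70")
  }
  col <- if (colour_by %in% names(nodes) &&
             any(is.finite(nodes[[colour_by]]))) {
    v <- nodes[[colour_by]]
    grDevices::hcl.colors(16L)[cut(v, 16L, labels = FALSE)]
  } else "steelblue"
  graphics::points(nodes$x, nodes$y, pch = 19, cex = 0.6, col = col)
  invisible(x)
}

#' Assemble a nested atlas from a primary map and its secondaries
#'
#' Validates the linkage: every primary node's cluster id must resolve to
#' exactly one secondary map, with no duplicates or dangling links, and the
#' secondary node counts must sum to the dataset size (every molecule in
#' exactly one secondary map).
#'
#' @param primary a primary \code{"treemap"}.
#' @param secondaries list of secondary \code{"treemap"} objects.
#' @param n_total total number of (valid) molecules in the dataset.
#' @return object of class \code{"nested_atlas"}: list with \code{primary},
#'   \code{secondaries} (named by cluster id), \code{manifest}.
#' @export
assemble_atlas <- function(primary, secondaries, n_total) {
  stopifnot(inherits(primary, "treemap"), primary$level == "primary")
  cids <- vapply(secondaries, function(s) as.integer(s$cluster_id),
                 integer(1))
  if (anyDuplicated(cids)) {
    stop("duplicated secondary cluster id(s): ",
         paste(unique(cids[duplicated(cids)]), collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(primary$nodes$cluster, cids)
  if (length(missing) > 0L) {
    stop("missing secondary map(s) for cluster(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(cids, primary$nodes$cluster)
  if (length(extra) > 0L) {
    stop("secondary map(s) with no primary node: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  sizes <- vapply(secondaries, function(s) s$n, integer(1))
  if (sum(sizes) != n_total) {
    stop(sprintf("secondary maps hold %d molecules but dataset has %d",
                 sum(sizes), n_total), call. = FALSE)
  }
  names(secondaries) <- as.character(cids)
  manifest <- list(n_total = as.integer(n_total),
                   n_clusters = length(secondaries),
                   cluster_ids = sort(cids),
                   cluster_sizes = as.integer(sizes[order(cids)]))
  structure(list(primary = primary, secondaries = secondaries,
                 manifest = manifest),
            class = "nested_atlas")
}

#' @export
print.nested_atlas <- function(x, ...) {
  cat(sprintf("Nested atlas: %d molecules in %d clusters\n",
              x$manifest$n_total, x$manifest$n_clusters))
  cat(sprintf("  primary map: %d representatives; secondary sizes %d-%d\n",
              x$primary$n, min(x$manifest$cluster_sizes),
              max(x$manifest$cluster_sizes)))
  invisible(x)
}

treemap_to_list <- function(tm) {
  list(level = tm$level,
       cluster_id = if (is.na(tm$cluster_id)) NULL else tm$cluster_id,
       n = tm$n, nodes = tm$nodes, edges = tm$edges)
}

treemap_from_list <- function(lst) {
  nodes <- as.data.frame(lst$nodes)
  edges <- as.data.frame(lst$edges)
  if (nrow(edges) == 0L) {
    edges <- data.frame(i = integer(0), j = integer(0), w = numeric(0))
  }
  structure(list(level = lst$level,
                 cluster_id = if (is.null(lst$cluster_id)) NA_integer_
                              else as.integer(lst$cluster_id),
                 n = as.integer(lst$n), nodes = nodes, edges = edges),
            class = "treemap")
}

#' Write / read a nested atlas bundle
#'
#' The atlas persists as a directory: \code{primary.json},
#' \code{secondary/<cluster_id>.json} (nodes with id, SMILES, coordinates
#' and colour channels; edges with endpoint pairs and weights) and
#' \code{manifest.json}. Reading the bundle back reproduces the manifest
#' exactly.
#'
#' @param atlas a \code{"nested_atlas"}.
#' @param dir output directory (created if needed).
#' @return \code{dir} invisibly (write); a \code{"nested_atlas"} (read).
#' @export
write_atlas <- function(atlas, dir) {
  stopifnot(inherits(atlas, "nested_atlas"))
  dir.create(file.path(dir, "secondary"), recursive = TRUE,
             showWarnings = FALSE)
  jsonlite::write_json(treemap_to_list(atlas$primary),
                       file.path(dir, "primary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  for (cid in names(atlas$secondaries)) {
    jsonlite::write_json(treemap_to_list(atlas$secondaries[[cid]]),
                         file.path(dir, "secondary",
                                   paste0(cid, ".json")),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  }
  jsonlite::write_json(atlas$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  manifest$cluster_ids <- as.integer(manifest$cluster_ids)
  manifest$cluster_sizes <- as.integer(manifest$cluster_sizes)
  manifest$n_total <- as.integer(manifest$n_total)
  manifest$n_clusters <- as.integer(manifest$n_clusters)
  primary <- treemap_from_list(
    jsonlite::read_json(file.path(dir, "primary.json"),
                        simplifyVector = TRUE))
  files <- list.files(file.path(dir, "secondary"), pattern = "\\.json$",
                      full.names = TRUE)
  secondaries <- lapply(files, function(f) {
    treemap_from_list(jsonlite::read_json(f, simplifyVector = TRUE))
  })
  cids <- vapply(secondaries, function(s) s$cluster_id, integer(1))
  secondaries <- secondaries[order(cids)]
  names(secondaries) <- as.character(sort(cids))
  structure(list(primary = primary, secondaries = secondaries,
                 manifest = manifest),
            class = "nested_atlas")
}
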