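# shared fixtures, cached so the RDKit backend runs once per batch

.cache <- new.env(parent = emptyenv())

cache_get <- function(key, maker) {
  if (!exists(key, envir = .cache)) assign(key, maker(), envir = .cache)
  get(key, envir = .cache)
}

# reference molecules used across descriptor tests
ref_smiles <- c(benzene = "c1ccccc1", cyclohexane = "C1CCCCC1",
                ethane = "CC", decane = "CCCCCCCCCC",
                methane = "C", methanol = "CO")

ref_descriptors <- function() {
  cache_get("ref", function() {
    tmp <- tempfile(fileext = ".smi")
    writeLines(unname(ref_smiles), tmp)
    on.exit(unlink(tmp))
    d <- describe_smiles_file(tmp)
    d$names <- names(ref_smiles)
    d
  })
}

# a small synthetic library with MQN + panel, shared by pq/quality tests
test_library <- function() {
  cache_get("lib300", function() {
    smiles <- generate_smiles_library(300, seed = 42)
    tmp <- tempfile(fileext = ".smi")
    writeLines(smiles, tmp)
    on.exit(unlink(tmp))
    d <- describe_smiles_file(tmp)
    list(smiles = smiles, mqn = d$mqn, panel = d$panel, ecfp = d$ecfp)
  })
}

# labelled blobs + trained codebook + codes, shared by several files
quality_fixture <- function() {
  cache_get("quality_fx", function() {
    b <- generate_mqn_blobs(600, k = 6, spread = 1,
                            separation = 8 * sqrt(42), seed = 31)
    cb <- pq_codebook(b$x, L = 64, seed = 31)
    tb <- pq_sd_tables(cb)
    list(b = b, cb = cb, tb = tb, codes = pq_encode(b$x, cb))
  })
}

# one shared end-to-end pipeline run, reused across test files
pipeline_fixture <- function() {
  cache_get("pipe_fx", function() {
    root <- tempfile("pipe")
    dir.create(root)
    input <- file.path(root, "library.smi")
    generate_smiles_library(350, seed = 71, path = input)
    cfg <- pipeline_config(input, file.path(root, "out"),
                           shard_size = 100L, k = 6L, L = 64L,
                           codebook_sample = 1e6, fit_sample = 1e6,
                           knn_k = 5L, seed = 17L,
                           quality_clusters = 4L, quality_per_cluster = 6L)
    res <- suppressMessages(run_pipeline(cfg))
    list(root = root, cfg = cfg, res = res)
  })
}

# deterministic random count-vector sample (MQN-shaped, well spread)
random_count_vectors <- function(n, d = 42L, seed = 1L) {
  withr::with_seed(seed, {
    matrix(rpois(n * d, lambda = 4), nrow = n)
  })
}

# independent Kruskal MST oracle with union-find
kruskal_oracle <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(v) {
    while (parent[v] != v) v <- parent[v]
    v
  }
  ord <- order(edges$w, edges$i, edges$j)
  total <- 0
  taken <- 0L
  for (e in ord) {
    ri <- find(edges$i[e])
    rj <- find(edges$j[e])
    if (ri != rj) {
      parent[ri] <- rj
      total <- total + edges$w[e]
      taken <- taken + 1L
    }
  }
  list(weight = total, n_edges = taken)
}

# union-find connectivity/acyclicity check on a claimed tree
is_spanning_tree <- function(n, edges) {
  if (nrow(edges) != n - 1L) return(FALSE)
  parent <- seq_len(n)
  find <- function(v) {
    while (parent[v] != v) v <- parent[v]
    v
  }
  for (e in seq_len(nrow(edges))) {
    ri <- find(edges$i[e]); rj <- find(edges$j[e])
    if (ri == rj) return(FALSE)  # cycle
    parent[ri] <- rj
  }
  length(unique(vapply(seq_len(n), find, integer(1)))) == 1L
}

# edge set as canonical id-pair strings (for permutation-invariance checks)
edge_key <- function(edges, ids = NULL) {
  i <- edges$i; j <- edges$j
  if (!is.null(ids)) { i <- ids[i]; j <- ids[j] }
  sort(paste(pmin(i, j), pmax(i, j)))
}
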