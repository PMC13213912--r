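#' @title Sharded streaming pipeline: shuffle -> MQN -> PQ -> PQk-Means ->
#'   atlas
#'
#' @description The end-to-end workflow runs in stages that communicate
#' only through artifacts persisted under the output directory, so each
#' stage is independently re-runnable and peak memory per stage is bounded
#' by the configured shard and batch sizes:
#' \enumerate{
#'   \item \code{shuffle}: seeded permutation of the input SMILES lines,
#'     re-sharded (removes ordering effects from pre-sorted inputs);
#'   \item \code{descriptors}: per-shard MQN / ECFP4 / panel computation,
#'     skipping (and counting) unparseable SMILES;
#'   \item \code{pq}: codebook training on a subsample, then streaming
#'     encoding of all molecules into binary code shards;
#'   \item \code{cluster}: PQk-Means fit on a subsample, streaming
#'     assignment of everything, compaction of empty clusters,
#'     representative selection;
#'   \item \code{atlas}: primary tree-map over representatives (MQN),
#'     secondary tree-maps per cluster (ECFP4), assembled and validated.
#' }
#' A JSON run manifest records counts, seeds and artifact checksums per
#' stage; molecule counts must reconcile across stages.
#' @name pipeline
NULL

#' Build a pipeline configuration
#'
#' Defaults mirror the method's standard settings: m = 6 subspaces,
#' L = 256 codewords, 20 codebook iterations, k = 100,000 clusters at
#' scale (set k to suit the dataset). All stage seeds derive from the
#' single \code{seed} unless given explicitly.
#'
#' @param input character vector of SMILES line files (".gz" accepted).
#' @param output_dir directory for all artifacts.
#' @param shard_size lines per shard after shuffling.
#' @param m,L,codebook_iters,codebook_sample,codebook_seed PQ settings.
#' @param k,fit_sample,fit_iters,fit_seed PQk-Means settings.
#' @param batch_size rows per encoding/assignment batch.
#' @param knn_k neighbours for tree-map graphs.
#' @param layout_seed tree layout seed.
#' @param n_bits ECFP4 folded length.
#' @param seed master seed.
#' @param quality_clusters,quality_per_cluster sampling design for the
#'   quality stage.
#' @return a \code{"pipeline_config"} list.
#' @export
pipeline_config <- function(input, output_dir,
                            shard_size = 1000L,
                            m = 6L, L = 256L, codebook_iters = 20L,
                            codebook_sample = 50e6, codebook_seed = NULL,
                            k = 100000L, fit_sample = 1e9,
                            fit_iters = 20L, fit_seed = NULL,
                            batch_size = 65536L, knn_k = 10L,
                            layout_seed = NULL, n_bits = 2048L,
                            seed = 1L,
                            quality_clusters = 10L,
                            quality_per_cluster = 10L) {
  cfg <- list(input = input, output_dir = output_dir,
              shard_size = stopifnot_scalar_count(shard_size, "shard_size"),
              m = stopifnot_scalar_count(m, "m"),
              L = stopifnot_scalar_count(L, "L"),
              codebook_iters = stopifnot_scalar_count(codebook_iters,
                                                      "codebook_iters"),
              codebook_sample = codebook_sample,
              codebook_seed = if (is.null(codebook_seed)) seed + 101L
                              else as.integer(codebook_seed),
              k = stopifnot_scalar_count(k, "k"),
              fit_sample = fit_sample,
              fit_iters = stopifnot_scalar_count(fit_iters, "fit_iters"),
              fit_seed = if (is.null(fit_seed)) seed + 202L
                         else as.integer(fit_seed),
              batch_size = stopifnot_scalar_count(batch_size, "batch_size"),
              knn_k = stopifnot_scalar_count(knn_k, "knn_k"),
              layout_seed = if (is.null(layout_seed)) seed + 303L
                            else as.integer(layout_seed),
              n_bits = stopifnot_scalar_count(n_bits, "n_bits"),
              seed = as.integer(seed),
              quality_clusters = as.integer(quality_clusters),
              quality_per_cluster = as.integer(quality_per_cluster))
  stopifnot(cfg$codebook_sample >= 1, cfg$fit_sample >= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

manifest_path <- function(cfg) file.path(cfg$output_dir, "manifest.json")

read_manifest <- function(cfg) {
  p <- manifest_path(cfg)
  if (!file.exists(p)) return(list(stages = list()))
  jsonlite::read_json(p, simplifyVector = FALSE)
}

update_manifest <- function(cfg, stage, info) {
  man <- read_manifest(cfg)
  man$package_version <- as.character(utils::packageVersion("nestedtmap"))
  man$config <- cfg[setdiff(names(cfg), c("input", "output_dir"))]
  man$config$input <- as.character(cfg$input)
  man$stages[[stage]] <- info
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(man, manifest_path(cfg), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(man)
}

file_checksums <- function(paths) {
  md5 <- tools::md5sum(paths)
  as.list(setNames(unname(md5), basename(paths)))
}

read_lines_any <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

shard_paths <- function(cfg) {
  sort(list.files(file.path(cfg$output_dir, "01_shards"),
                  pattern = "^shard_[0-9]+\\.smi$", full.names = TRUE))
}

descriptor_paths <- function(cfg) {
  sort(list.files(file.path(cfg$output_dir, "02_descriptors"),
                  pattern = "^shard_[0-9]+\\.tsv$", full.names = TRUE))
}

code_paths <- function(cfg) {
  sort(list.files(file.path(cfg$output_dir, "03_pq"),
                  pattern = "^codes_shard_[0-9]+\\.bin$", full.names = TRUE))
}

#' Shuffle and re-shard the input SMILES files
#'
#' Applies a seeded permutation to the concatenated input lines (removing
#' any ordering of the source files, which often come sorted by heavy atom
#' count) and writes them back in shards of \code{shard_size} lines. Lines
#' are brought to a canonical (sorted) order before the permutation, so
#' the shard content is a pure function of the line multiset and the seed:
#' pre-sorted and arbitrarily ordered inputs yield identical shards. The
#' multiset of lines is preserved exactly.
#'
#' @param cfg a [pipeline_config()].
#' @return shard paths, invisibly.
#' @export
stage_shuffle <- function(cfg) {
  lines <- unlist(lapply(cfg$input, read_lines_any))
  lines <- lines[nzchar(trimws(lines))]
  lines <- sort(lines, method = "radix")  # canonical order first
  perm <- with_seed(cfg$seed, sample.int(length(lines)))
  lines <- lines[perm]
  dir <- file.path(cfg$output_dir, "01_shards")
  unlink(dir, recursive = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  starts <- seq(1L, length(lines), by = cfg$shard_size)
  paths <- character(length(starts))
  for (s in seq_along(starts)) {
    rows <- starts[s]:min(starts[s] + cfg$shard_size - 1L, length(lines))
    paths[s] <- file.path(dir, sprintf("shard_%04d.smi", s))
    writeLines(lines[rows], paths[s])
  }
  update_manifest(cfg, "shuffle",
                  list(n_lines = length(lines), n_shards = length(paths),
                       seed = cfg$seed, checksums = file_checksums(paths)))
  invisible(paths)
}

#' Compute descriptors for every shard
#'
#' Runs the RDKit backend once per shard, producing a TSV with canonical
#' SMILES, the 42 MQN counts, the physicochemical panel and ECFP4 on-bits.
#' Unparseable SMILES are kept flagged invalid and counted; they carry no
#' descriptors and are excluded from every later stage.
#'
#' @param cfg a [pipeline_config()].
#' @return descriptor shard paths, invisibly.
#' @export
stage_descriptors <- function(cfg) {
  shards <- shard_paths(cfg)
  if (length(shards) == 0L) stop("no shards found; run stage_shuffle first",
                                 call. = FALSE)
  dir <- file.path(cfg$output_dir, "02_descriptors")
  unlink(dir, recursive = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts <- data.frame(shard = basename(shards), n = 0L, n_valid = 0L)
  paths <- character(length(shards))
  for (s in seq_along(shards)) {
    tab <- run_descriptor_backend(shards[s],
                                  what = c("mqn", "ecfp", "panel"),
                                  n_bits = cfg$n_bits)
    paths[s] <- file.path(dir, sprintf("shard_%04d.tsv", s))
    utils::write.table(tab, paths[s], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    counts$n[s] <- nrow(tab)
    counts$n_valid[s] <- sum(tab$valid == "1")
    message(sprintf("descriptors %s: %d parsed, %d skipped",
                    basename(shards[s]), counts$n_valid[s],
                    counts$n[s] - counts$n_valid[s]))
  }
  update_manifest(cfg, "descriptors",
                  list(n = sum(counts$n), n_valid = sum(counts$n_valid),
                       n_skipped = sum(counts$n) - sum(counts$n_valid),
                       n_bits = cfg$n_bits,
                       per_shard = counts,
                       checksums = file_checksums(paths)))
  invisible(paths)
}

read_descriptor_shard <- function(path, n_bits) {
  tab <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                           colClasses = "character", check.names = FALSE)
  parse_backend_table(tab, n_bits = n_bits)
}

# stack the valid molecules of all descriptor shards; global ids are
# sequential over valid molecules in shard order
gather_descriptors <- function(cfg, what = c("mqn", "ecfp", "panel")) {
  paths <- descriptor_paths(cfg)
  if (length(paths) == 0L) {
    stop("no descriptor shards; run stage_descriptors first", call. = FALSE)
  }
  mqn <- list(); ecfp <- list(); panel <- list(); smiles <- list()
  for (p in paths) {
    d <- read_descriptor_shard(p, cfg$n_bits)
    ok <- d$records$valid
    smiles[[p]] <- d$records$smiles[ok]
    if ("mqn" %in% what) mqn[[p]] <- d$mqn[ok, , drop = FALSE]
    if ("panel" %in% what) panel[[p]] <- d$panel[ok, , drop = FALSE]
    if ("ecfp" %in% what) ecfp[[p]] <- d$ecfp[ok]
  }
  out <- list(smiles = unlist(smiles, use.names = FALSE))
  out$id <- seq_along(out$smiles)
  if ("mqn" %in% what) out$mqn <- do.call(rbind, mqn)
  if ("panel" %in% what) out$panel <- do.call(rbind, panel)
  if ("ecfp" %in% what) {
    out$ecfp <- do.call(c, ecfp)
    attr(out$ecfp, "n_bits") <- cfg$n_bits
  }
  out
}

write_codebook_json <- function(codebook, path) {
  jsonlite::write_json(
    list(m = codebook$m, L = codebook$L, d_sub = codebook$d_sub,
         dim = codebook$dim, iters = codebook$iters, seed = codebook$seed,
         codewords = codebook$codewords),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_codebook_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cw_list <- if (is.array(j$codewords) && length(dim(j$codewords)) == 3L) {
    # jsonlite simplifies the list of m equally-shaped L x d_sub matrices
    # into an m x L x d_sub array
    lapply(seq_len(dim(j$codewords)[1L]),
           function(jj) matrix(j$codewords[jj, , ],
                               nrow = dim(j$codewords)[2L]))
  } else {
    lapply(j$codewords, function(cw) {
      matrix(as.numeric(unlist(cw)), nrow = as.integer(j$L))
    })
  }
  structure(list(m = as.integer(j$m), L = as.integer(j$L),
                 d_sub = as.integer(j$d_sub), dim = as.integer(j$dim),
                 codewords = cw_list,
                 iters = as.integer(j$iters), seed = as.integer(j$seed)),
            class = "pq_codebook")
}

#' Train the PQ codebook (stage)
#'
#' Trains on a seeded uniform subsample of at most \code{codebook_sample}
#' valid MQN vectors and persists the codebook as JSON.
#'
#' @param cfg a [pipeline_config()].
#' @return the \code{pq_codebook}, invisibly.
#' @export
stage_pq_fit <- function(cfg) {
  data <- gather_descriptors(cfg, what = "mqn")
  n <- nrow(data$mqn)
  take <- min(n, floor(cfg$codebook_sample))
  rows <- with_seed(cfg$codebook_seed, sort(sample.int(n, take)))
  codebook <- pq_codebook(data$mqn[rows, , drop = FALSE], m = cfg$m,
                          L = cfg$L, iters = cfg$codebook_iters,
                          seed = cfg$codebook_seed)
  dir <- file.path(cfg$output_dir, "03_pq")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "codebook.json")
  write_codebook_json(codebook, path)
  update_manifest(cfg, "pq_fit",
                  list(n_train = take, m = codebook$m, L = codebook$L,
                       seed = cfg$codebook_seed,
                       checksums = file_checksums(path)))
  invisible(codebook)
}

#' Encode all molecules into PQ code shards (stage)
#'
#' Encodes the valid molecules of each descriptor shard in batches of
#' \code{batch_size} and writes one binary code shard (m bytes per
#' molecule) per input shard, plus a JSON sidecar manifest.
#'
#' @param cfg a [pipeline_config()].
#' @return code shard paths, invisibly.
#' @export
stage_pq_encode <- function(cfg) {
  codebook <- read_codebook_json(file.path(cfg$output_dir, "03_pq",
                                           "codebook.json"))
  paths <- descriptor_paths(cfg)
  dir <- file.path(cfg$output_dir, "03_pq")
  out <- character(length(paths))
  counts <- integer(length(paths))
  for (s in seq_along(paths)) {
    d <- read_descriptor_shard(paths[s], cfg$n_bits)
    mqn <- d$mqn[d$records$valid, , drop = FALSE]
    codes <- pq_encode(mqn, codebook, batch_size = cfg$batch_size)
    out[s] <- file.path(dir, sprintf("codes_shard_%04d.bin", s))
    write_pq_codes(codes, out[s])
    counts[s] <- nrow(codes)
  }
  sidecar <- file.path(dir, "codes_manifest.json")
  jsonlite::write_json(list(m = codebook$m, L = codebook$L,
                            d_sub = codebook$d_sub,
                            seed = codebook$seed,
                            count = sum(counts),
                            shards = basename(out),
                            shard_counts = counts),
                       sidecar, auto_unbox = TRUE, digits = NA)
  update_manifest(cfg, "pq_encode",
                  list(n_codes = sum(counts), bytes_per_code = codebook$m,
                       checksums = file_checksums(c(out, sidecar))))
  invisible(out)
}

gather_codes <- function(cfg) {
  side <- jsonlite::read_json(file.path(cfg$output_dir, "03_pq",
                                        "codes_manifest.json"),
                              simplifyVector = TRUE)
  do.call(rbind, lapply(code_paths(cfg), read_pq_codes,
                        m = as.integer(side$m)))
}

#' Fit the PQk-Means model (stage)
#'
#' Fits \code{k} centroids on a seeded uniform subsample of at most
#' \code{fit_sample} PQ codes and persists the model.
#'
#' @param cfg a [pipeline_config()].
#' @return the \code{pq_kmeans} model, invisibly.
#' @export
stage_cluster_fit <- function(cfg) {
  codebook <- read_codebook_json(file.path(cfg$output_dir, "03_pq",
                                           "codebook.json"))
  tables <- pq_sd_tables(codebook)
  codes <- gather_codes(cfg)
  n <- nrow(codes)
  if (n < cfg$k) {
    stop(sprintf("k = %d clusters requested but only %d valid molecules",
                 cfg$k, n), call. = FALSE)
  }
  take <- min(n, floor(cfg$fit_sample))
  take <- max(take, cfg$k)
  rows <- with_seed(cfg$fit_seed, sort(sample.int(n, take)))
  model <- pq_kmeans(codes[rows, , drop = FALSE], k = cfg$k,
                     tables = tables, iters = cfg$fit_iters,
                     seed = cfg$fit_seed)
  dir <- file.path(cfg$output_dir, "04_clusters")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "model.json")
  jsonlite::write_json(list(k = model$k, centroids = model$centroids,
                            objective = model$objective,
                            iters_run = model$iters_run,
                            seed = model$seed),
                       path, auto_unbox = TRUE, digits = NA)
  update_manifest(cfg, "cluster_fit",
                  list(n_train = take, k = cfg$k,
                       iters_run = model$iters_run, seed = cfg$fit_seed,
                       objective_first = model$objective[1L],
                       objective_last =
                         model$objective[length(model$objective)],
                       checksums = file_checksums(path)))
  invisible(model)
}

read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cent <- matrix(as.integer(j$centroids), nrow = as.integer(j$k))
  structure(list(centroids = cent, k = as.integer(j$k),
                 labels = NULL, objective = as.numeric(j$objective),
                 populated = rep(TRUE, as.integer(j$k)),
                 iters_run = as.integer(j$iters_run),
                 seed = as.integer(j$seed)),
            class = "pq_kmeans")
}

#' Assign every molecule, compact clusters, persist assignment (stage)
#'
#' Streams all PQ codes through the trained model in batches, drops
#' unpopulated clusters, re-indexes labels densely and writes the
#' assignment (molecule id, cluster, SD), the old-to-new cluster mapping
#' and the compacted model.
#'
#' @param cfg a [pipeline_config()].
#' @return the compacted assignment data.frame, invisibly.
#' @export
stage_cluster_assign <- function(cfg) {
  codebook <- read_codebook_json(file.path(cfg$output_dir, "03_pq",
                                           "codebook.json"))
  tables <- pq_sd_tables(codebook)
  dir <- file.path(cfg$output_dir, "04_clusters")
  model <- read_model_json(file.path(dir, "model.json"))
  codes <- gather_codes(cfg)
  assignment <- stats::predict(model, codes, tables,
                               batch_size = cfg$batch_size)
  comp <- compact_clusters(model, assignment)
  out <- data.frame(id = seq_len(nrow(codes)),
                    cluster = comp$assignment$label,
                    sd = comp$assignment$sd)
  utils::write.csv(out, file.path(dir, "assignment.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(cluster = seq_along(comp$mapping),
                              original = comp$mapping),
                   file.path(dir, "mapping.csv"), row.names = FALSE)
  jsonlite::write_json(list(k = comp$model$k,
                            centroids = comp$model$centroids,
                            objective = model$objective,
                            iters_run = model$iters_run,
                            seed = model$seed),
                       file.path(dir, "model_compact.json"),
                       auto_unbox = TRUE, digits = NA)
  update_manifest(cfg, "cluster_assign",
                  list(n_assigned = nrow(out),
                       k_populated = comp$model$k,
                       k_requested = model$k,
                       checksums = file_checksums(
                         file.path(dir, c("assignment.csv", "mapping.csv",
                                          "model_compact.json")))))
  invisible(out)
}

read_assignment <- function(cfg) {
  utils::read.csv(file.path(cfg$output_dir, "04_clusters",
                            "assignment.csv"))
}

#' Select cluster representatives (stage)
#'
#' @param cfg a [pipeline_config()].
#' @return representatives data.frame (cluster, id, sd), invisibly.
#' @export
stage_representatives <- function(cfg) {
  codebook <- read_codebook_json(file.path(cfg$output_dir, "03_pq",
                                           "codebook.json"))
  tables <- pq_sd_tables(codebook)
  dir <- file.path(cfg$output_dir, "04_clusters")
  model <- read_model_json(file.path(dir, "model_compact.json"))
  codes <- gather_codes(cfg)
  assignment <- read_assignment(cfg)
  reps <- select_representatives(codes,
                                 data.frame(label = assignment$cluster,
                                            sd = assignment$sd),
                                 model, tables, ids = assignment$id)
  utils::write.csv(reps, file.path(dir, "representatives.csv"),
                   row.names = FALSE)
  update_manifest(cfg, "representatives",
                  list(n = nrow(reps),
                       checksums = file_checksums(
                         file.path(dir, "representatives.csv"))))
  invisible(reps)
}

#' Build the primary tree-map (stage)
#'
#' @param cfg a [pipeline_config()].
#' @return the primary \code{"treemap"}, invisibly.
#' @export
stage_tmap_primary <- function(cfg) {
  reps <- utils::read.csv(file.path(cfg$output_dir, "04_clusters",
                                    "representatives.csv"))
  data <- gather_descriptors(cfg, what = c("mqn", "panel"))
  idx <- reps$id
  primary <- build_primary(data$mqn[idx, , drop = FALSE],
                           meta = data.frame(id = reps$id,
                                             cluster = reps$cluster,
                                             smiles = data$smiles[idx],
                                             stringsAsFactors = FALSE),
                           panel = data$panel[idx, , drop = FALSE],
                           k = cfg$knn_k, seed = cfg$layout_seed)
  dir <- file.path(cfg$output_dir, "05_atlas")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(treemap_to_list(primary),
                       file.path(dir, "primary.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  update_manifest(cfg, "tmap_primary",
                  list(n_nodes = primary$n, n_edges = nrow(primary$edges),
                       knn_k = cfg$knn_k, layout_seed = cfg$layout_seed,
                       checksums = file_checksums(
                         file.path(dir, "primary.json"))))
  invisible(primary)
}

#' Build all secondary tree-maps (stage)
#'
#' One ECFP4/Tanimoto tree-map per populated cluster.
#'
#' @param cfg a [pipeline_config()].
#' @return vector of secondary JSON paths, invisibly.
#' @export
stage_tmap_secondary <- function(cfg) {
  assignment <- read_assignment(cfg)
  data <- gather_descriptors(cfg, what = c("ecfp", "panel"))
  dir <- file.path(cfg$output_dir, "05_atlas", "secondary")
  unlink(dir, recursive = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cids <- sort(unique(assignment$cluster))
  paths <- character(length(cids))
  for (ci in seq_along(cids)) {
    members <- assignment$id[assignment$cluster == cids[ci]]
    fps <- data$ecfp[members]
    attr(fps, "n_bits") <- cfg$n_bits
    sec <- build_secondary(fps,
                           meta = data.frame(id = members,
                                             smiles = data$smiles[members],
                                             stringsAsFactors = FALSE),
                           cluster_id = cids[ci],
                           panel = data$panel[members, , drop = FALSE],
                           k = cfg$knn_k, seed = cfg$layout_seed)
    paths[ci] <- file.path(dir, paste0(cids[ci], ".json"))
    jsonlite::write_json(treemap_to_list(sec), paths[ci],
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  }
  update_manifest(cfg, "tmap_secondary",
                  list(n_maps = length(paths)))
  invisible(paths)
}

#' Assemble and validate the nested atlas (stage)
#'
#' @param cfg a [pipeline_config()].
#' @return the validated \code{"nested_atlas"}, invisibly.
#' @export
stage_atlas <- function(cfg) {
  dir <- file.path(cfg$output_dir, "05_atlas")
  primary <- treemap_from_list(
    jsonlite::read_json(file.path(dir, "primary.json"),
                        simplifyVector = TRUE))
  files <- list.files(file.path(dir, "secondary"), pattern = "\\.json$",
                      full.names = TRUE)
  secondaries <- lapply(files, function(f) {
    treemap_from_list(jsonlite::read_json(f, simplifyVector = TRUE))
  })
  man <- read_manifest(cfg)
  n_total <- man$stages$descriptors$n_valid
  atlas <- assemble_atlas(primary, secondaries, n_total = n_total)
  jsonlite::write_json(atlas$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  update_manifest(cfg, "atlas",
                  list(n_total = atlas$manifest$n_total,
                       n_clusters = atlas$manifest$n_clusters))
  invisible(atlas)
}

#' Cluster quality diagnostics over the pipeline output (stage)
#'
#' Writes within/between distance summaries for the three metrics, the
#' cluster size distribution and the descriptor dispersion statistics as
#' CSV under \code{06_quality/}. The sampling design is scaled down
#' automatically when fewer clusters qualify.
#'
#' @param cfg a [pipeline_config()].
#' @return list of the computed summaries, invisibly.
#' @export
stage_quality <- function(cfg) {
  codebook <- read_codebook_json(file.path(cfg$output_dir, "03_pq",
                                           "codebook.json"))
  tables <- pq_sd_tables(codebook)
  codes <- gather_codes(cfg)
  assignment <- read_assignment(cfg)
  data <- gather_descriptors(cfg, what = c("mqn", "panel"))
  dir <- file.path(cfg$output_dir, "06_quality")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sizes <- table(assignment$cluster)
  npc <- min(cfg$quality_per_cluster, max(sizes))
  ncl <- min(cfg$quality_clusters, sum(sizes >= npc))
  summaries <- lapply(c("euclidean_mqn", "manhattan_mqn", "sd_pq"),
                      function(metric) {
    sample_cluster_distances(assignment$cluster, metric = metric,
                             x = data$mqn, codes = codes, tables = tables,
                             n_clusters = ncl, n_per_cluster = npc,
                             seed = cfg$seed)
  })
  dist_summary <- do.call(rbind, summaries)
  utils::write.csv(dist_summary, file.path(dir, "cluster_distances.csv"),
                   row.names = FALSE)
  csd <- cluster_size_distribution(assignment$cluster)
  utils::write.csv(data.frame(rank = seq_along(csd$sizes),
                              size = csd$sizes),
                   file.path(dir, "cluster_sizes.csv"), row.names = FALSE)
  disp <- dispersion_stats(data$panel, assignment$cluster)
  utils::write.csv(as.data.frame(disp),
                   file.path(dir, "dispersion_stats.csv"),
                   row.names = FALSE)
  update_manifest(cfg, "quality",
                  list(n_clusters_sampled = ncl, n_per_cluster = npc,
                       seed = cfg$seed))
  invisible(list(distances = dist_summary, sizes = csd, dispersion = disp))
}

#' Run the full pipeline
#'
#' Executes all stages in order. Fails fast on impossible configurations
#' (e.g. more clusters requested than input molecules) before any heavy
#' computation; on a stage failure the manifest records the completed
#' stages.
#'
#' @param cfg a [pipeline_config()].
#' @param quality also run the quality stage.
#' @return list with \code{atlas} (a \code{"nested_atlas"}) and
#'   \code{manifest}.
#' @export
run_pipeline <- function(cfg, quality = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  n_input <- sum(vapply(cfg$input, function(p) {
    length(read_lines_any(p))
  }, numeric(1)))
  if (cfg$k > n_input) {
    stop(sprintf("config requests k = %d clusters but the input has only %d lines",
                 cfg$k, n_input), call. = FALSE)
  }
  stage_shuffle(cfg)
  stage_descriptors(cfg)
  man <- read_manifest(cfg)
  if (cfg$k > man$stages$descriptors$n_valid) {
    stop(sprintf("config requests k = %d clusters but only %d valid molecules",
                 cfg$k, man$stages$descriptors$n_valid), call. = FALSE)
  }
  stage_pq_fit(cfg)
  stage_pq_encode(cfg)
  stage_cluster_fit(cfg)
  stage_cluster_assign(cfg)
  stage_representatives(cfg)
  stage_tmap_primary(cfg)
  stage_tmap_secondary(cfg)
  atlas <- stage_atlas(cfg)
  if (quality) stage_quality(cfg)
  man <- read_manifest(cfg)
  # conservation: valid molecules in = codes out = labels out
  stopifnot(man$stages$descriptors$n_valid == man$stages$pq_encode$n_codes,
            man$stages$pq_encode$n_codes ==
              man$stages$cluster_assign$n_assigned)
  list(atlas = atlas, manifest = man)
}
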