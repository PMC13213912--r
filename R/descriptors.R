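#' @title Molecular descriptors: MQN, ECFP4 and a physicochemical panel
#'
#' @description Molecules are represented throughout the package by three
#' complementary descriptors, all computed with RDKit through a bundled
#' batch interface (one subprocess call per batch of SMILES):
#' \itemize{
#'   \item \strong{MQN} (molecular quantum numbers): 42 non-negative integer
#'     counts of atom types, bond types, polar groups and topological
#'     features. This is the vector that is product-quantized and clustered.
#'   \item \strong{ECFP4}: circular substructure fingerprint of radius 2,
#'     folded to a fixed number of bits, compared by Tanimoto similarity;
#'     used for the secondary (within-cluster) tree-maps.
#'   \item \strong{Descriptor panel}: MW, heavy atom count, ring count,
#'     rotatable bonds, H-bond donors/acceptors, TPSA, fraction of sp3
#'     carbons, aromatic atom count; used for cluster-dispersion
#'     diagnostics and for colouring tree-maps.
#' }
#' @name descriptors
NULL

# locate the python interpreter used for the RDKit backend
python_binary <- function() {
  bin <- getOption("nestedtmap.python", "")
  if (!nzchar(bin)) bin <- Sys.getenv("NESTEDTMAP_PYTHON", "")
  if (!nzchar(bin)) bin <- Sys.which("python")
  if (!nzchar(bin)) bin <- Sys.which("python3")
  if (!nzchar(bin)) {
    stop("no 'python' interpreter found on PATH; the descriptor backend ",
         "requires Python with rdkit", call. = FALSE)
  }
  bin
}

descriptor_backend_script <- function() {
  path <- system.file("python", "descriptors.py", package = "nestedtmap")
  if (!nzchar(path)) stop("bundled descriptor backend not found")
  path
}

# run the RDKit backend on a SMILES file; returns the raw TSV as a data.frame
run_descriptor_backend <- function(input, what, n_bits = 2048L) {
  out <- tempfile(fileext = ".tsv")
  on.exit(unlink(out), add = TRUE)
  status <- system2(python_binary(),
                    c(shQuote(descriptor_backend_script()),
                      shQuote(input), shQuote(out),
                      "--what", paste(what, collapse = ","),
                      "--n-bits", as.integer(n_bits)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) {
    stop("descriptor backend failed (exit status ", status, ")",
         call. = FALSE)
  }
  utils::read.delim(out, sep = "\t", quote = "", comment.char = "",
                    colClasses = "character", check.names = FALSE)
}

# descriptor backend on an in-memory vector of SMILES lines
smiles_descriptors <- function(smiles, what = c("mqn", "ecfp", "panel"),
                               n_bits = 2048L) {
  stopifnot(is.character(smiles), length(smiles) > 0L)
  tmp <- tempfile(fileext = ".smi")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(smiles, tmp)
  run_descriptor_backend(tmp, what = what, n_bits = n_bits)
}

parse_backend_table <- function(tab, n_bits = 2048L) {
  n <- nrow(tab)
  records <- data.frame(
    id = as.integer(tab$index),
    smiles = tab$canonical_smiles,
    valid = tab$valid == "1",
    stringsAsFactors = FALSE
  )
  if ("ext_id" %in% names(tab)) records$ext_id <- tab$ext_id
  out <- list(records = records)
  mqn_cols <- grep("^mqn[0-9]+$", names(tab), value = TRUE)
  if (length(mqn_cols) > 0L) {
    mqn <- matrix(NA_integer_, nrow = n, ncol = length(mqn_cols),
                  dimnames = list(NULL, mqn_cols))
    ok <- records$valid
    if (any(ok)) {
      mqn[ok, ] <- vapply(tab[ok, mqn_cols, drop = FALSE], as.integer,
                          integer(sum(ok)))
    }
    out$mqn <- mqn
  }
  panel_cols <- intersect(
    c("MW", "HAC", "rings", "RBC", "HBD", "HBA", "TPSA", "FCsp3",
      "aromatic_atoms"), names(tab))
  if (length(panel_cols) > 0L) {
    panel <- as.data.frame(lapply(tab[panel_cols], function(v) {
      v[v == ""] <- NA
      as.numeric(v)
    }))
    out$panel <- panel
  }
  if ("ecfp_bits" %in% names(tab)) {
    out$ecfp <- lapply(tab$ecfp_bits, function(s) {
      if (is.na(s) || s == "") return(integer(0))
      as.integer(strsplit(s, " ", fixed = TRUE)[[1]])
    })
    out$ecfp[!records$valid] <- list(NULL)
    attr(out$ecfp, "n_bits") <- as.integer(n_bits)
  }
  out
}

#' Parse SMILES strings into molecule records
#'
#' Each input line is parsed with RDKit; parseable molecules are stored with
#' their canonical SMILES, unparseable lines are kept with \code{valid =
#' FALSE} and never abort the batch. A second tab-separated column, if
#' present, is preserved as an external identifier.
#'
#' @param smiles character vector, one molecule per element (optionally
#'   \code{"SMILES\tid"}).
#' @return a data.frame with columns \code{id} (1-based position in the
#'   input), \code{smiles} (canonical SMILES, \code{""} when invalid),
#'   \code{valid} (logical) and, when ids were supplied, \code{ext_id}.
#' @examples
#' \dontrun{
#' parse_smiles(c("c1ccccc1", "not_a_molecule"))
#' }
#' @export
parse_smiles <- function(smiles) {
  tab <- smiles_descriptors(smiles, what = "mqn")
  parse_backend_table(tab)$records
}

#' Compute MQN count vectors
#'
#' Computes the 42 MQN (molecular quantum numbers) integer counts for each
#' molecule using RDKit's published implementation, with no scaling or
#' centring applied afterwards.
#'
#' @param smiles character vector of SMILES. All must be valid; an
#'   unparseable entry raises an error (use [parse_smiles()] to screen).
#' @return integer matrix with one row per molecule and 42 columns.
#' @export
compute_mqn <- function(smiles) {
  parsed <- parse_backend_table(smiles_descriptors(smiles, what = "mqn"))
  if (!all(parsed$records$valid)) {
    bad <- which(!parsed$records$valid)
    stop("invalid SMILES at position(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  parsed$mqn
}

#' Compute ECFP4 fingerprints
#'
#' Radius-2 circular (Morgan) fingerprints folded to \code{n_bits} bits.
#' Fingerprints are returned sparsely, as sorted 0-based on-bit indices.
#'
#' @param smiles character vector of valid SMILES.
#' @param n_bits folded fingerprint length; must be a power of two.
#' @return list of integer vectors (on-bit indices) with attribute
#'   \code{n_bits}.
#' @export
compute_ecfp4 <- function(smiles, n_bits = 2048L) {
  n_bits <- as.integer(n_bits)
  if (n_bits < 2L || bitwAnd(n_bits, n_bits - 1L) != 0L) {
    stop("'n_bits' must be a power of two", call. = FALSE)
  }
  parsed <- parse_backend_table(
    smiles_descriptors(smiles, what = "ecfp", n_bits = n_bits),
    n_bits = n_bits)
  if (!all(parsed$records$valid)) {
    stop("invalid SMILES passed to compute_ecfp4()", call. = FALSE)
  }
  parsed$ecfp
}

#' Compute the physicochemical descriptor panel
#'
#' @param smiles character vector of valid SMILES.
#' @return data.frame with columns MW (g/mol), HAC, rings, RBC, HBD, HBA,
#'   TPSA (A^2), FCsp3 (fraction in [0,1]) and aromatic_atoms.
#' @export
compute_panel <- function(smiles) {
  parsed <- parse_backend_table(smiles_descriptors(smiles, what = "panel"))
  if (!all(parsed$records$valid)) {
    stop("invalid SMILES passed to compute_panel()", call. = FALSE)
  }
  parsed$panel
}

#' Compute all descriptors for a SMILES file in one pass
#'
#' Runs the RDKit backend once over a SMILES line file (optionally
#' gzip-compressed; an optional tab-separated id column is preserved) and
#' returns molecule records plus the requested descriptor blocks.
#' Unparseable lines are flagged, not fatal.
#'
#' @param path path to a SMILES line file (".gz" accepted).
#' @param what descriptor blocks to compute, subset of
#'   \code{c("mqn", "ecfp", "panel")}.
#' @param n_bits ECFP4 folded length.
#' @return list with components \code{records} (data.frame id/smiles/valid),
#'   and, as requested, \code{mqn} (integer matrix, NA rows for invalid
#'   molecules), \code{panel} (data.frame), \code{ecfp} (list of on-bit
#'   indices).
#' @export
describe_smiles_file <- function(path, what = c("mqn", "ecfp", "panel"),
                                 n_bits = 2048L) {
  what <- match.arg(what, several.ok = TRUE)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  parse_backend_table(
    run_descriptor_backend(path, what = what, n_bits = n_bits),
    n_bits = n_bits)
}

#' Tanimoto similarity between sparse fingerprints
#'
#' @param a,b integer vectors of on-bit indices.
#' @return Tanimoto similarity |A&B| / |A|B|; 1 when both are empty
#'   (identical molecules with no set bits).
#' @export
tanimoto <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' Pairwise Tanimoto similarity matrix
#'
#' @param fps list of sparse fingerprints (on-bit index vectors), as
#'   returned by [compute_ecfp4()].
#' @param n_bits folded length; defaults to the list's \code{n_bits}
#'   attribute.
#' @return symmetric numeric matrix of similarities with unit diagonal.
#' @export
tanimoto_matrix <- function(fps, n_bits = attr(fps, "n_bits")) {
  n <- length(fps)
  if (is.null(n_bits)) n_bits <- max(c(0L, unlist(fps))) + 1L
  m <- matrix(0, nrow = n, ncol = n_bits)
  for (i in seq_len(n)) m[i, fps[[i]] + 1L] <- 1
  inter <- tcrossprod(m)
  sizes <- rowSums(m)
  un <- outer(sizes, sizes, "+") - inter
  sim <- ifelse(un == 0, 1, inter / pmax(un, 1e-300))
  diag(sim) <- 1
  sim
}
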