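#' @title Synthetic fixtures: SMILES libraries and MQN-shaped blobs
#'
#' @description Two generators make every pipeline stage testable without
#' downloading any external library: a seeded enumerator of drug-like SMILES
#' built from a curated scaffold x linker x terminal fragment grammar
#' (emulating make-on-demand combinatorial libraries), and a generator of
#' labelled 42-dimensional non-negative integer count vectors ("blobs") with
#' controllable cluster separation, used as ground truth for clustering
#' recovery tests.
#' @name fixtures
NULL

# fragment grammar: every scaffold+linker+terminal concatenation is a valid
# SMILES (terminal scaffold atoms all retain free valence; ring-closure
# digits are reused only after closure). Exhaustively validated.
smiles_fragments <- function() {
  list(
    scaffolds = c(
      "CCCCCC", "CCOCCO", "CC(C)CC(C)C",                     # acyclic
      "C1CCCCC1", "c1ccccc1", "c1ccncc1", "C1CCNCC1", "C1CCOC1",  # 1 ring
      "c1ccc2ccccc2c1", "c1ccc(-c2ccccc2)cc1",
      "C1CCC2(CC1)CCCCC2", "C1CCc2ccccc2C1", "C1CC2CCC1CC2",  # 2 rings
      "c1ccc(-c2ccc(-c3ccccc3)cc2)cc1", "c1ccc2cc3ccccc3cc2c1",  # 3 rings
      "c1ccc(-c2ccc3cc4ccccc4cc3c2)cc1"                       # 4 rings
    ),
    linkers = c("C", "CC", "CCC", "CO", "CN", "COC", "CC(C)",
                "c1ccccc1", "C1CCCCC1", "CCOC", "CS(=O)(=O)", "C(=O)N"),
    terminals = c("C", "CC", "O", "N", "CCO", "CCN", "F", "Cl", "Br",
                  "C(F)(F)F", "OC", "N(C)C", "c1ccccc1", "c1ccncc1",
                  "N1CCOCC1", "C1CCNCC1", "C(=O)O", "C(=O)OC", "C#N",
                  "S(C)(=O)=O")
  )
}

#' Generate a synthetic drug-like SMILES library
#'
#' Enumerates molecules as scaffold + optional linker + optional terminal
#' fragment, drawn with a seeded RNG from a curated fragment grammar whose
#' every combination is a chemically valid SMILES with molecular weight
#' below 500 g/mol. Scaffolds span 0 to 4 rings so MQN vectors of the
#' library form non-degenerate clusters. Duplicates may occur and are
#' flagged, not removed.
#'
#' @param n number of molecules.
#' @param seed RNG seed; the output is fully determined by it.
#' @param path optional file to write (one SMILES per line; ".gz" accepted).
#' @return character vector of \code{n} SMILES with attribute
#'   \code{n_duplicates} (count of non-first occurrences). Written to
#'   \code{path} as a side effect when given.
#' @export
generate_smiles_library <- function(n, seed = 1L, path = NULL) {
  stopifnot_scalar_count(n, "n")
  frags <- smiles_fragments()
  lines <- with_seed(seed, {
    sc <- sample(frags$scaffolds, n, replace = TRUE)
    li <- sample(frags$linkers, n, replace = TRUE)
    te <- sample(frags$terminals, n, replace = TRUE)
    n_sub <- sample(0:2, n, replace = TRUE)
    out <- sc
    out[n_sub >= 1L] <- paste0(out[n_sub >= 1L], li[n_sub >= 1L])
    out[n_sub == 2L] <- paste0(out[n_sub == 2L], te[n_sub == 2L])
    out
  })
  attr(lines, "n_duplicates") <- sum(duplicated(lines))
  if (!is.null(path)) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    writeLines(lines, con)
    close(con)
    return(invisible(lines))
  }
  lines
}

#' Generate labelled MQN-shaped count-vector blobs
#'
#' Draws \code{k} integer cluster centres and perturbs each member by
#' per-coordinate rounded Gaussian noise truncated at zero, so every vector
#' remains a valid 42-dimensional non-negative integer count vector.
#' Centres are rescaled so their minimum pairwise Euclidean distance equals
#' \code{separation}, and shifted away from zero so the truncation is
#' essentially inactive; the expected within-blob distance to the centre is
#' about \code{spread * sqrt(d)}.
#'
#' @param n total number of vectors.
#' @param k number of ground-truth clusters.
#' @param spread per-coordinate noise standard deviation (0 gives exact
#'   copies of the centres).
#' @param separation minimum pairwise Euclidean distance between centres.
#' @param d dimensionality (42 for MQN-shaped vectors).
#' @param seed RNG seed.
#' @return list with \code{x} (n x d integer matrix), \code{labels}
#'   (integers 1..k), \code{centers} (k x d integer matrix).
#' @export
generate_mqn_blobs <- function(n, k, spread = 1, separation = 6 * spread *
                                 sqrt(d), d = 42L, seed = 1L) {
  stopifnot_scalar_count(n, "n")
  stopifnot_scalar_count(k, "k")
  stopifnot(spread >= 0, separation >= 0, n >= k)
  with_seed(seed, {
    repeat {
      centers <- matrix(runif(k * d, 0, 10), nrow = k)
      if (k == 1L) break
      dmin <- min(stats::dist(centers))
      if (dmin > 1e-8) {
        centers <- centers * (separation / dmin)
        break
      }
    }
    # keep coordinates comfortably above 0 so truncation rarely binds
    centers <- round(centers) + ceiling(3 * spread)
    labels <- sort(rep_len(seq_len(k), n))
    noise <- matrix(round(stats::rnorm(n * d, 0, spread)), nrow = n)
    x <- centers[labels, , drop = FALSE] + noise
    x[x < 0L] <- 0L
    storage.mode(x) <- "integer"
    storage.mode(centers) <- "integer"
    list(x = x, labels = labels, centers = centers)
  })
}
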