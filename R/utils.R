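# internal helpers shared across modules

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs \code{expr} under \code{set.seed(seed)} and restores the caller's RNG
#' state afterwards, so that library functions taking a \code{seed} argument
#' never perturb the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# squared Euclidean cross-distances between rows of x (n x d) and rows of
# centers (k x d); clamped at zero against round-off
dist2_cross <- function(x, centers) {
  x <- as.matrix(x)
  centers <- as.matrix(centers)
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") -
    2 * tcrossprod(x, centers)
  d2[d2 < 0] <- 0
  d2
}

# row-wise argmin with lowest-index tie-break
argmin_rows <- function(d) {
  max.col(-d, ties.method = "first")
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 ||
      x != floor(x)) {
    stop(sprintf("'%s' must be a single positive integer", name),
         call. = FALSE)
  }
  invisible(as.integer(x))
}
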