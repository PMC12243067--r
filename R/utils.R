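#' @importFrom methods new validObject is slot
#' @importFrom stats cor rnorm rbinom runif sd t.test setNames predict
#' @importFrom utils read.delim write.table read.csv write.csv head
NULL

## Run code under a temporary RNG state seeded with `seed`, restoring the
## caller's stream afterwards. All generator determinism flows through this.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

## Derive a reproducible vector of sub-seeds below 2^31 from one master seed.
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Spectral radius of a square matrix
#'
#' Largest absolute eigenvalue. For symmetric input the symmetric
#' eigensolver is used.
#'
#' @param A square numeric matrix.
#' @return Non-negative scalar.
#' @export
spectralRadius <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  sym <- max(abs(A - t(A))) < 1e-8 * max(1, max(abs(A)))
  max(abs(eigen(A, symmetric = sym, only.values = TRUE)$values))
}

## Enforce symmetry within tolerance, erroring otherwise.
checkSymmetric <- function(A, tol = 1e-8, what = "matrix") {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop(what, " must be a square matrix", call. = FALSE)
  dev <- max(abs(A - t(A)))
  if (dev > tol * max(1, max(abs(A))))
    stop(what, " is not symmetric (max asymmetry ", format(dev), ")",
         call. = FALSE)
  (A + t(A)) / 2
}

## Symmetrize and zero the diagonal (generator-internal helper).
symmetrizeZeroDiag <- function(A) {
  A <- (A + t(A)) / 2
  diag(A) <- 0
  A
}
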