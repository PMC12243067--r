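#' Stabilized linear system derived from functional connectivity
#'
#' Discrete-time symmetric dynamics matrix \eqn{A} with spectral radius < 1,
#' together with the normalization record \eqn{c = 1 + \sigma_{max}(C)}.
#'
#' @slot A the stabilized matrix.
#' @slot c normalization constant.
#' @export
setClass("SystemMatrix", slots = c(A = "matrix", c = "numeric"))

setValidity("SystemMatrix", function(object) {
  A <- object@A
  if (nrow(A) != ncol(A)) return("A must be square")
  if (max(abs(A - t(A))) > 1e-10 * max(1, max(abs(A))))
    return("A must be symmetric")
  if (spectralRadius(A) >= 1) return("A must have spectral radius < 1")
  TRUE
})

setMethod("show", "SystemMatrix", function(object) {
  cat("SystemMatrix:", nrow(object@A), "nodes, spectral radius",
      signif(spectralRadius(object@A), 4), ", normalization c =",
      signif(object@c, 6), "\n")
  invisible(object)
})

#' Stabilize a connectivity matrix into linear dynamics
#'
#' \eqn{A = C / (1 + \sigma_{max}(C))} where \eqn{\sigma_{max}} is the
#' largest singular value; the spectral radius of the result is strictly
#' below 1. The input must be symmetric with zero diagonal.
#'
#' @param C symmetric connectivity matrix with zero diagonal.
#' @return A \linkS4class{SystemMatrix}.
#' @export
stabilizeSystem <- function(C) {
  C <- checkSymmetric(C, tol = 1e-10, what = "connectivity matrix")
  diag(C) <- 0
  smax <- if (all(C == 0)) 0 else norm(C, type = "2")
  cc <- 1 + smax
  new("SystemMatrix", A = C / cc, c = cc)
}

## Extract the matrix from SystemMatrix or plain matrix input, asserting
## symmetry and (optionally) stability.
asSystem <- function(A, requireStable = TRUE) {
  if (is(A, "SystemMatrix")) A <- A@A
  A <- checkSymmetric(A, tol = 1e-10, what = "system matrix")
  if (requireStable && spectralRadius(A) >= 1)
    stop("unstable system: spectral radius ", format(spectralRadius(A)),
         " >= 1", call. = FALSE)
  A
}

#' Average controllability
#'
#' Per node \eqn{i}, the trace of the infinite-horizon discrete
#' controllability Gramian with input matrix \eqn{B = e_i}, i.e. the solution
#' trace of \eqn{A W A^T - W + e_i e_i^T = 0}. For symmetric \eqn{A} with
#' eigendecomposition \eqn{A = V \Lambda V^T} this equals
#' \eqn{\sum_j v_{ij}^2 / (1 - \lambda_j^2)}, which is the exact Lyapunov
#' solution. Every value is \eqn{\ge 1} (the \eqn{k = 0} term).
#'
#' @param A a \linkS4class{SystemMatrix} or stable symmetric matrix.
#' @return Numeric vector of length \code{nrow(A)}.
#' @export
averageControllability <- function(A) {
  A <- asSystem(A)
  e <- eigen(A, symmetric = TRUE)
  as.vector(e$vectors^2 %*% (1 / (1 - e$values^2)))
}

#' Modal controllability
#'
#' \eqn{\phi_i = \sum_j (1 - \lambda_j^2) v_{ij}^2} for the orthonormal
#' eigendecomposition \eqn{A = V \Lambda V^T}. High values indicate the
#' ability to excite fast-decaying (hard-to-reach) modes. Complex spectra are
#' not supported; the input must be symmetric.
#'
#' @param A a \linkS4class{SystemMatrix} or symmetric matrix.
#' @return Numeric vector of length \code{nrow(A)}.
#' @export
modalControllability <- function(A) {
  A <- asSystem(A, requireStable = FALSE)
  e <- eigen(A, symmetric = TRUE)
  as.vector(e$vectors^2 %*% (1 - e$values^2))
}

#' Finite-horizon continuous-time controllability Gramian
#'
#' \eqn{W(T) = \int_0^T e^{A_c t} B B^T e^{A_c^T t} dt}, computed by the
#' block-matrix-exponential method: the top-right block of
#' \eqn{\exp([[A_c, BB^T], [0, -A_c^T]] T)} equals \eqn{W(T) e^{-A_c^T T}}.
#' The result is symmetrized.
#'
#' @param Ac continuous-time system matrix.
#' @param B control input matrix (vector inputs are treated as one column).
#' @param horizon time horizon \eqn{T > 0}.
#' @return Symmetric positive semidefinite matrix.
#' @export
finiteHorizonGramian <- function(Ac, B, horizon = 1) {
  if (horizon <= 0) stop("horizon must be > 0", call. = FALSE)
  Ac <- as.matrix(Ac)
  B <- as.matrix(B)
  n <- nrow(Ac)
  stopifnot(ncol(Ac) == n, nrow(B) == n)
  M <- rbind(cbind(Ac, B %*% t(B)),
             cbind(matrix(0, n, n), -t(Ac))) * horizon
  E <- as.matrix(Matrix::expm(M))
  F11 <- E[seq_len(n), seq_len(n), drop = FALSE]
  F12 <- E[seq_len(n), n + seq_len(n), drop = FALSE]
  W <- F12 %*% t(F11)
  (W + t(W)) / 2
}

#' Minimum-energy state transition
#'
#' Energy of the minimum-norm control moving the continuous-time system
#' \eqn{\dot x = A_c x + B u} from \eqn{x_0} to \eqn{x_f} over horizon
#' \eqn{T}: with \eqn{v = x_f - e^{A_c T} x_0},
#' \eqn{E = v^T W(T)^{-1} v}. When the Gramian is rank deficient the
#' Moore-Penrose pseudoinverse is used and the reachability residual
#' \eqn{\|(I - W W^+) v\|} is reported; a condition number above
#' \code{condWarn} is recorded in the result.
#'
#' @param Ac,B system and input matrices.
#' @param x0,xf initial and target states.
#' @param horizon horizon \eqn{T > 0}.
#' @param condWarn condition-number threshold for the warning flag.
#' @return List with \code{energy}, \code{residual}, \code{condition},
#'   \code{warning} (logical).
#' @export
minTransitionEnergy <- function(Ac, B, x0, xf, horizon = 1,
                                condWarn = 1e12) {
  if (horizon <= 0) stop("horizon must be > 0", call. = FALSE)
  Ac <- as.matrix(Ac)
  x0 <- as.numeric(x0); xf <- as.numeric(xf)
  if (!all(is.finite(c(x0, xf)))) stop("states must be finite", call. = FALSE)
  W <- finiteHorizonGramian(Ac, B, horizon)
  v <- xf - as.vector(as.matrix(Matrix::expm(Ac * horizon)) %*% x0)
  e <- eigen(W, symmetric = TRUE)
  tol <- max(e$values) * length(v) * .Machine$double.eps
  keep <- e$values > tol
  cond <- max(e$values) / max(min(e$values[keep]), .Machine$double.xmin)
  y <- as.vector(t(e$vectors) %*% v)
  energy <- sum(y[keep]^2 / e$values[keep])
  residual <- sqrt(sum(y[!keep]^2))
  list(energy = energy, residual = residual, condition = cond,
       warning = cond > condWarn)
}

#' Regional activation energy
#'
#' Minimum control energy attributed to each region, on the shifted
#' continuous-time system \eqn{A_c = A - I} (all eigenvalues negative) over
#' horizon \code{horizon}.
#'
#' Two control-set conventions are implemented:
#' \describe{
#'   \item{\code{single_driver} (default)}{region \eqn{i} is the sole driver
#'   (\eqn{B = e_i}) steering the brain from rest to the uniform state
#'   \eqn{x_f = N^{-1/2} \mathbf{1}}. The per-region Gramian factorizes over
#'   the shared eigenbasis, \eqn{W_i = V D_u S D_u V^T} with
#'   \eqn{u = V^T e_i} and \eqn{S_{jk} = (e^{(\mu_j + \mu_k) T} - 1) /
#'   (\mu_j + \mu_k)}, so the energy is \eqn{y^T S^{-1} y} with
#'   \eqn{y = (V^T x_f) / u}. Because single-driver Gramians are severely
#'   ill-conditioned, eigenvector loadings are floored at
#'   \code{loadingFloor} in absolute value (a recorded regularization); the
#'   fraction of floored loadings is returned as an attribute.}
#'   \item{\code{whole_brain_control}}{all regions are driven (\eqn{B = I})
#'   and region \eqn{i} is the unit target \eqn{x_f = e_i}; the energy is the
#'   \eqn{i}-th diagonal entry of \eqn{W(T)^{-1}}, computed in closed form
#'   from the eigendecomposition.}
#' }
#'
#' @param A a \linkS4class{SystemMatrix} or stable symmetric matrix.
#' @param horizon horizon \eqn{T > 0} (default 1).
#' @param convention control-set convention.
#' @param loadingFloor regularization floor for single-driver loadings.
#' @return Positive numeric vector of length \code{nrow(A)}; attribute
#'   \code{convention} records the convention used.
#' @export
activationEnergy <- function(A, horizon = 1,
                             convention = c("single_driver",
                                            "whole_brain_control"),
                             loadingFloor = 0.01) {
  convention <- match.arg(convention)
  A <- asSystem(A)
  if (horizon <= 0) stop("horizon must be > 0", call. = FALSE)
  e <- eigen(A, symmetric = TRUE)
  V <- e$vectors
  mu <- e$values - 1                 # eigenvalues of A - I, all < 0
  n <- nrow(A)
  if (convention == "whole_brain_control") {
    w <- ifelse(abs(mu) > 1e-12,
                (exp(2 * mu * horizon) - 1) / (2 * mu),
                horizon)
    ae <- as.vector(V^2 %*% (1 / w))
  } else {
    MU <- outer(mu, mu, "+")
    S <- (exp(MU * horizon) - 1) / MU
    eS <- eigen(S, symmetric = TRUE)
    keepS <- eS$values > 1e-12 * max(eS$values)
    Sinv <- eS$vectors[, keepS, drop = FALSE] %*%
      (t(eS$vectors[, keepS, drop = FALSE]) / eS$values[keepS])
    xf <- rep(1 / sqrt(n), n)
    Vv <- as.vector(t(V) %*% xf)
    ae <- numeric(n)
    floored <- 0L
    for (i in seq_len(n)) {
      u <- V[i, ]
      small <- abs(u) < loadingFloor
      floored <- floored + sum(small)
      u[small] <- sign(u[small] + (u[small] == 0)) * loadingFloor
      y <- Vv / u
      ae[i] <- sum(y * (Sinv %*% y))
    }
    attr(ae, "flooredFraction") <- floored / (n * n)
  }
  attr(ae, "convention") <- convention
  attr(ae, "horizon") <- horizon
  ae
}

#' Controllability metrics for one subject
#'
#' Composes the per-subject chain: time series to Pearson connectivity,
#' stabilization, and the three regional metrics.
#'
#' @param ts regions-by-timepoints matrix.
#' @param horizon energy horizon.
#' @param convention energy convention (see \code{\link{activationEnergy}}).
#' @param negative negative-correlation handling for the connectivity step.
#' @return List with \code{fc}, \code{system} (the \code{SystemMatrix}) and a
#'   \code{metrics} data.frame (\code{average_ctrl}, \code{modal_ctrl},
#'   \code{activation_energy}).
#' @export
subjectProfile <- function(ts, horizon = 1,
                           convention = c("single_driver",
                                          "whole_brain_control"),
                           negative = "keep") {
  convention <- match.arg(convention)
  fc <- pearsonFC(ts, negative = negative)
  sys <- stabilizeSystem(fc)
  metrics <- data.frame(
    region = if (is.null(rownames(ts))) seq_len(nrow(ts)) - 1L else
      rownames(ts),
    average_ctrl = averageControllability(sys),
    modal_ctrl = modalControllability(sys),
    activation_energy = as.numeric(activationEnergy(sys, horizon,
                                                    convention)),
    stringsAsFactors = FALSE)
  list(fc = fc, system = sys, metrics = metrics)
}

#' Controllability profiles for a whole cohort
#'
#' Runs \code{\link{subjectProfile}} for every subject and assembles a
#' \code{SummarizedExperiment}: rows are regions (with the parcellation as
#' row data), columns are subjects (with the manifest as column data), and
#' the three assays are \code{average_ctrl}, \code{modal_ctrl} and
#' \code{activation_energy}. The energy convention and horizon are stored in
#' the metadata.
#'
#' @param cohort a \code{SyntheticCohort} with simulated time series, or a
#'   named list of regions-by-timepoints matrices (then \code{parcellation}
#'   and \code{manifest} must be supplied).
#' @param parcellation,manifest used when \code{cohort} is a plain list.
#' @param horizon,convention,negative passed to \code{\link{subjectProfile}}.
#' @return A \code{SummarizedExperiment} (class \code{ControllabilitySet}).
#' @export
computeProfiles <- function(cohort, parcellation = NULL, manifest = NULL,
                            horizon = 1,
                            convention = c("single_driver",
                                           "whole_brain_control"),
                            negative = "keep") {
  convention <- match.arg(convention)
  if (is(cohort, "SyntheticCohort")) {
    tsList <- cohort@timeSeries
    parcellation <- cohort@parcellation
    manifest <- cohort@manifest
  } else tsList <- cohort
  if (!length(tsList)) stop("no time series to profile", call. = FALSE)
  stopifnot(is(parcellation, "Parcellation"), is.data.frame(manifest))
  n <- nRegions(parcellation)
  ids <- names(tsList)
  assays <- lapply(c("average_ctrl", "modal_ctrl", "activation_energy"),
                   function(nm) matrix(NA_real_, n, length(ids),
                                       dimnames = list(NULL, ids)))
  names(assays) <- c("average_ctrl", "modal_ctrl", "activation_energy")
  for (j in seq_along(ids)) {
    ts <- tsList[[j]]
    if (nrow(ts) != n)
      stop("subject ", ids[j], ": ", nrow(ts), " regions, parcellation has ",
           n, call. = FALSE)
    p <- subjectProfile(ts, horizon, convention, negative)
    assays$average_ctrl[, j] <- p$metrics$average_ctrl
    assays$modal_ctrl[, j] <- p$metrics$modal_ctrl
    assays$activation_energy[, j] <- p$metrics$activation_energy
  }
  cd <- manifest[match(ids, manifest$subject_id), , drop = FALSE]
  rownames(cd) <- ids
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(regionTable(parcellation)),
    colData = S4Vectors::DataFrame(cd),
    metadata = list(horizon = horizon, convention = convention,
                    negative = negative))
  se
}

#' Write per-subject controllability profiles to TSV
#'
#' One file per subject with columns \code{region_id},
#' \code{average_ctrl}, \code{modal_ctrl}, \code{activation_energy}, plus a
#' JSON sidecar recording the horizon and energy convention.
#'
#' @param se profile set from \code{\link{computeProfiles}}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeProfiles <- function(se, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rid <- SummarizedExperiment::rowData(se)$region_id
  for (id in colnames(se)) {
    df <- data.frame(region_id = rid,
                     average_ctrl = signif(averageCtrl(se)[, id], 8),
                     modal_ctrl = signif(modalCtrl(se)[, id], 8),
                     activation_energy =
                       signif(activationEnergyAssay(se)[, id], 8))
    write.table(df, file.path(dir, paste0(id, "_profile.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(S4Vectors::metadata(se),
                       file.path(dir, "profiles_meta.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Assay accessors for controllability profile sets
#'
#' @param se a \code{SummarizedExperiment} produced by
#'   \code{\link{computeProfiles}}.
#' @return Regions-by-subjects matrix.
#' @export
averageCtrl <- function(se) SummarizedExperiment::assay(se, "average_ctrl")

#' @rdname averageCtrl
#' @export
modalCtrl <- function(se) SummarizedExperiment::assay(se, "modal_ctrl")

#' @rdname averageCtrl
#' @export
activationEnergyAssay <- function(se)
  SummarizedExperiment::assay(se, "activation_energy")
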