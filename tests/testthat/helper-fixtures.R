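## Shared fixtures: all built in code at test time.

## Toy parcellation with arbitrary per-system counts, e.g.
## toyParcellation(VN = 2, thalamus = 2).
toyParcellation <- function(...) {
  counts <- c(...)
  sys <- rep(names(counts), counts)
  cls <- ifelse(sys %in% corticalNetworks, "cortical", "subcortical")
  tab <- data.frame(
    region_id = seq_along(sys) - 1L,
    label = paste0(sys, "_", ave(seq_along(sys), sys, FUN = seq_along)),
    region_class = cls, system = sys,
    hemisphere = rep_len(c("L", "R"), length(sys)),
    stringsAsFactors = FALSE)
  new("Parcellation", table = tab)
}

## Random stable symmetric matrix with zero diagonal and spectral radius rho.
randStableSym <- function(n, rho = 0.8, seed = 1) {
  set.seed(seed)
  M <- matrix(rnorm(n * n), n, n)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  M * (rho / max(abs(eigen(M, symmetric = TRUE, only.values = TRUE)$values)))
}

## Truncated-series oracle for average controllability: sum_k ||A^k e_i||^2,
## truncated so the neglected tail is below 1e-12 relative.
seriesAvgCtrl <- function(A) {
  rho <- max(abs(eigen(A, symmetric = TRUE, only.values = TRUE)$values))
  K <- ceiling(log(1e-14) / (2 * log(rho)))
  P <- diag(nrow(A))
  acc <- rowSums(P^2)
  for (k in seq_len(K)) {
    P <- A %*% P
    acc <- acc + rowSums(P^2)
  }
  acc
}

## Composite-Simpson oracle for the finite-horizon Gramian; uses a single
## matrix exponential per step via repeated multiplication.
simpsonGramian <- function(Ac, B, horizon, panels = 2000) {
  n <- nrow(Ac)
  h <- horizon / (2 * panels)
  Eh <- as.matrix(Matrix::expm(Ac * h))
  BBt <- B %*% t(B)
  Ek <- diag(n)
  f <- function(Ek) Ek %*% BBt %*% t(Ek)
  W <- f(Ek)                    # t = 0
  for (k in seq_len(2 * panels - 1)) {
    Ek <- Eh %*% Ek
    W <- W + (if (k %% 2 == 1) 4 else 2) * f(Ek)
  }
  Ek <- Eh %*% Ek
  W <- W + f(Ek)                # t = T
  W * h / 3
}

## Small cohort spec used by several files (fast, still recovers effects).
smallSpec <- function(...) {
  args <- list(nHC = 10L, nCPMS = 10L, nCIMS = 10L, nRegions = 60L,
               nThalamic = 8L, nTimepoints = 60L)
  override <- list(...)
  args[names(override)] <- override
  do.call(cohortSpec, args)
}

## Mean thalamic value of a metric matrix given a parcellation.
thalMean <- function(mat, parc) {
  colMeans(mat[systemMembers(parc, "thalamus"), , drop = FALSE])
}
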