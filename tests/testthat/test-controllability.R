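test_that("stabilization normalizes by one plus the top singular value", {
  expect_equal(stabilizeSystem(matrix(0, 3, 3))@A, matrix(0, 3, 3))
  expect_equal(stabilizeSystem(matrix(0, 3, 3))@c, 1)

  C <- matrix(c(0, 1, 1, 0), 2, 2)
  s <- stabilizeSystem(C)
  expect_equal(s@A[1, 2], 0.5)
  expect_equal(s@c, 2)

  C <- randStableSym(8, 0.9, 31) * 4      # arbitrary symmetric matrix
  diag(C) <- 0
  s <- stabilizeSystem(C)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(spectralRadius(s@A), 1)
  expect_equal(spectralRadius(s@A),
               max(abs(ev)) / (1 + max(abs(ev))), tolerance = 1e-10)

  asym <- matrix(rnorm(9), 3, 3)
  expect_error(stabilizeSystem(asym), "symmetric")
})

test_that("average controllability matches closed forms and the series oracle", {
  expect_equal(averageControllability(matrix(0, 4, 4)), rep(1, 4))
  expect_equal(averageControllability(matrix(0.5, 1, 1)), 4 / 3,
               tolerance = 1e-12)

  for (s in 1:50) {
    A <- randStableSym(10, runif(1, 0.3, 0.95), s)
    ac <- averageControllability(A)
    expect_true(all(ac >= 1))
    expect_equal(ac, seriesAvgCtrl(A), tolerance = 1e-8)
  }
})

test_that("modal controllability matches closed forms and the trace identity", {
  expect_equal(modalControllability(matrix(0, 4, 4)), rep(1, 4))
  expect_equal(modalControllability(diag(c(0.9, 0.1))), c(0.19, 0.99))

  A <- randStableSym(12, 0.85, 77)
  phi <- modalControllability(A)
  ## row-norm identity: phi_i = 1 - (A^2)_ii, an eigen-free oracle
  expect_equal(phi, 1 - rowSums(A^2), tolerance = 1e-10)
  lam <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(phi), 12 - sum(lam^2), tolerance = 1e-10)
})

test_that("finite-horizon Gramian matches integrals and quadrature", {
  expect_equal(finiteHorizonGramian(matrix(0, 1, 1), 1, 1)[1, 1], 1,
               tolerance = 1e-12)
  expect_equal(finiteHorizonGramian(matrix(-1, 1, 1), 1, 1)[1, 1],
               (1 - exp(-2)) / 2, tolerance = 1e-12)

  set.seed(12)
  Ac <- matrix(rnorm(16, sd = 0.5), 4, 4)
  Ac <- Ac - diag(4) * (max(Re(eigen(Ac)$values)) + 0.5)
  W <- finiteHorizonGramian(Ac, diag(4), 1)
  Wq <- simpsonGramian(Ac, diag(4), 1, panels = 2000)
  expect_lt(max(abs(W - Wq)) / max(abs(W)), 1e-8)
  expect_true(all(eigen(W, symmetric = TRUE, only.values = TRUE)$values >
                  -1e-10))
  expect_error(finiteHorizonGramian(Ac, diag(4), 0), "horizon")
})

test_that("minimum transition energy matches closed forms and optimal control", {
  ## free evolution costs nothing
  set.seed(4)
  Ac <- matrix(rnorm(9, sd = 0.4), 3, 3); Ac <- Ac - diag(3) * 2
  x0 <- rnorm(3)
  xf <- as.vector(as.matrix(Matrix::expm(Ac)) %*% x0)
  res <- minTransitionEnergy(Ac, diag(3), x0, xf, 1)
  expect_lt(res$energy, 1e-16)

  ## scalar closed form
  res <- minTransitionEnergy(matrix(-1, 1, 1), 1, 0, 1, 1)
  expect_equal(res$energy, 2 / (1 - exp(-2)), tolerance = 1e-6)
  expect_equal(res$energy, 2.31303, tolerance = 1e-5)

  ## discretized optimal control oracle (piecewise-constant control,
  ## minimum-norm least squares)
  K <- 500; h <- 1 / K
  G <- as.matrix(Matrix::expm(rbind(cbind(Ac, diag(3)),
                                    matrix(0, 3, 6)) * h))[1:3, 4:6]
  Eh <- as.matrix(Matrix::expm(Ac * h))
  xf <- c(1, -0.5, 0.25)
  v <- xf                          # x0 = 0
  MMt <- matrix(0, 3, 3)
  Mk <- G                          # e^{A(T - t_k - h)} G for the last segment
  for (k in K:1) {
    MMt <- MMt + Mk %*% t(Mk)
    Mk <- Eh %*% Mk
  }
  ## minimum-norm solution u = M'(MM')^-1 v gives E = h v'(MM')^-1 v
  Eoracle <- h * drop(t(v) %*% solve(MMt) %*% v)
  res <- minTransitionEnergy(Ac, diag(3), c(0, 0, 0), xf, 1)
  expect_equal(res$energy, Eoracle, tolerance = 1e-3)
  expect_error(minTransitionEnergy(Ac, diag(3), 0:2, c(1, 1, Inf), 1),
               "finite")
})

test_that("activation energy conventions match their definitions", {
  ## whole-brain convention, decoupled closed form at A = 0
  ae <- activationEnergy(matrix(0, 5, 5), convention = "whole_brain_control")
  expect_equal(as.numeric(ae), rep(2 / (1 - exp(-2)), 5), tolerance = 1e-10)

  ## whole-brain convention equals the diagonal of the Gramian inverse
  A <- randStableSym(10, 0.8, 21)
  ae <- activationEnergy(A, convention = "whole_brain_control")
  W <- finiteHorizonGramian(A - diag(10), diag(10), 1)
  expect_equal(as.numeric(ae), diag(solve(W)), tolerance = 1e-9)

  ## single-driver energy equals the generic Gramian-inverse energy when no
  ## loading is floored (well-conditioned small system; single-driver
  ## Gramians become numerically singular quickly as n or 1/T grow)
  A <- randStableSym(4, 0.5, 22)
  n <- 4
  ae <- activationEnergy(A, horizon = 2, convention = "single_driver",
                         loadingFloor = 0)
  for (i in seq_len(n)) {
    B <- matrix(0, n, 1); B[i] <- 1
    ref <- minTransitionEnergy(A - diag(n), B, rep(0, n),
                               rep(1 / sqrt(n), n), 2)
    expect_equal(ae[i], ref$energy, tolerance = 1e-8)
  }

  ## permutation equivariance
  A <- randStableSym(6, 0.5, 23)
  perm <- c(3, 1, 6, 2, 5, 4)
  ae <- as.numeric(activationEnergy(A, horizon = 2))
  aeP <- as.numeric(activationEnergy(A[perm, perm], horizon = 2))
  ## exact in exact arithmetic; tolerance reflects the ~1e12 dynamic range
  ## of single-driver energies
  expect_equal(aeP, ae[perm], tolerance = 1e-4)

  expect_error(activationEnergy(A, convention = "driver"), "arg")
})

test_that("average controllability grows with a node's weighted degree", {
  set.seed(8)
  G <- abs(randStableSym(20, 0.8, 9))
  acs <- vapply(c(0.5, 1, 1.5, 2, 2.5), function(s) {
    M <- G
    M[1, ] <- M[1, ] * s
    M[, 1] <- t(M[1, , drop = FALSE])
    M <- (M + t(M)) / 2; diag(M) <- 0
    averageControllability(stabilizeSystem(M))[1]
  }, numeric(1))
  expect_true(all(diff(acs) > 0))
})

test_that("subject profiles are deterministic and near-null for empty coupling", {
  ## noise-only series: AC stays near 1
  ts <- simulateVAR1(matrix(0, 20, 20), 5000, 1, seed = 13)
  p <- subjectProfile(ts)
  expect_true(all(abs(p$metrics$average_ctrl - 1) < 0.1))

  ts2 <- simulateVAR1(randStableSym(15, 0.8, 3), 80, 1, seed = 5)
  p1 <- subjectProfile(ts2)
  p2 <- subjectProfile(ts2)
  expect_identical(p1$metrics, p2$metrics)
})

test_that("strengthened thalamic coupling raises thalamic average controllability", {
  spec <- smallSpec(nHC = 1L, nCPMS = 1L, nCIMS = 1L, nTimepoints = 100L)
  parc <- makeParcellation(46, 14, 8)
  gt <- buildBaseCoupling(parc, spec, seed = 1)
  thal <- systemMembers(parc, "thalamus")
  wins <- vapply(1:6, function(s) {
    Ahc <- makeSubjectCoupling(gt, "HC", spec, seed = s)
    Aci <- makeSubjectCoupling(gt, "CIMS", spec, seed = 1000 + s)
    acHC <- averageControllability(stabilizeSystem(
      pearsonFC(simulateVAR1(Ahc, 100, 1, seed = 2000 + s))))
    acCI <- averageControllability(stabilizeSystem(
      pearsonFC(simulateVAR1(Aci, 100, 1, seed = 3000 + s))))
    mean(acCI[thal]) > mean(acHC[thal])
  }, logical(1))
  expect_gte(sum(wins), 5)
})
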