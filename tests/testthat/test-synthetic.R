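test_that("base coupling satisfies its construction contract", {
  parc <- toyParcellation(DMN = 4, thalamus = 2)
  spec <- cohortSpec(nRegions = 6L, nThalamic = 2L, spectralRadius = 0.5)
  gt <- buildBaseCoupling(parc, spec, seed = 1)
  W <- gt@matrix
  expect_equal(W, t(W))
  expect_true(all(diag(W) == 0))
  expect_lt(abs(spectralRadius(W) - 0.5), 1e-9)
  expect_equal(gt@effectMask,
               outer(regionSystems(parc) == "thalamus",
                     regionSystems(parc) != "thalamus") |
               outer(regionSystems(parc) != "thalamus",
                     regionSystems(parc) == "thalamus"))

  gt2 <- buildBaseCoupling(parc, spec, seed = 1)
  expect_identical(gt@matrix, gt2@matrix)

  noThal <- toyParcellation(DMN = 4, hippocampus = 2)
  expect_error(buildBaseCoupling(noThal, spec, 1), "thalamus")
})

test_that("within-system weights exceed between-system weights", {
  spec <- cohortSpec()
  parc <- defaultParcellation()
  gt <- buildBaseCoupling(parc, spec, seed = 7)
  sys <- regionSystems(parc)
  same <- outer(sys, sys, "==") & !diag(nRegions(parc))
  W <- gt@matrix
  expect_gt(mean(W[same]), mean(W[!same & !diag(nRegions(parc))]))
})

test_that("subject coupling applies the effect where and only where masked", {
  parc <- toyParcellation(DMN = 6, FPN = 6, thalamus = 4)
  spec <- cohortSpec(nRegions = 16L, nThalamic = 4L, couplingNoiseSD = 0,
                     couplingEffectCIMS = 0.3, couplingEffectCPMS = 0)
  gt <- buildBaseCoupling(parc, spec, seed = 2)

  hc <- makeSubjectCoupling(gt, "HC", spec, seed = 3)
  expect_equal(hc, gt@matrix, tolerance = 1e-12)

  ci <- makeSubjectCoupling(gt, "CIMS", spec, seed = 3)
  off <- !diag(16) & gt@matrix != 0
  ratio <- ci[off] / gt@matrix[off]
  inMask <- gt@effectMask[off]
  ## non-thalamic edges change only through the global rescale factor
  expect_lt(diff(range(ratio[!inMask])), 1e-10)
  scale <- mean(ratio[!inMask])
  expect_equal(ratio[inMask], rep(1.3 * scale, sum(inMask)),
               tolerance = 1e-10)
  ## thalamic weighted degree increases pre-rescale
  thal <- regionSystems(parc) == "thalamus"
  expect_gt(sum(abs(ci[thal, ] / scale)), sum(abs(gt@matrix[thal, ])))
  expect_lt(abs(spectralRadius(ci) - spec@spectralRadius), 1e-9)

  expect_error(makeSubjectCoupling(gt, "patient", spec, 1), "unknown group")
})

test_that("patient ensembles have elevated thalamic degree", {
  parc <- toyParcellation(DMN = 10, FPN = 10, VN = 10, thalamus = 6,
                          caudate = 4)
  spec <- cohortSpec(nRegions = 40L, nThalamic = 6L,
                     couplingEffectCIMS = 0.3, couplingEffectCPMS = 0.15,
                     couplingNoiseSD = 0.02)
  gt <- buildBaseCoupling(parc, spec, seed = 4)
  thal <- regionSystems(parc) == "thalamus"
  deg <- function(M) sum(abs(M[thal, ]))
  ci <- vapply(1:8, function(s)
    deg(makeSubjectCoupling(gt, "CIMS", spec, s)), numeric(1))
  hc <- vapply(1:8, function(s)
    deg(makeSubjectCoupling(gt, "HC", spec, s)), numeric(1))
  expect_gt(mean(ci), mean(hc))
})

test_that("VAR(1) simulation matches closed-form stationary behaviour", {
  ## white noise: unit variance
  x <- simulateVAR1(matrix(0, 10, 10), 5000, noiseSD = 1, seed = 1)
  v <- apply(x, 1, var)
  expect_true(all(v > 0.94 & v < 1.06))

  ## no innovation: identically zero after burn-in
  A <- randStableSym(5, 0.7, 2)
  expect_true(all(simulateVAR1(A, 50, noiseSD = 0, seed = 1) == 0))

  ## scalar AR(1): lag-1 autocorrelation = a
  x <- simulateVAR1(matrix(0.5, 1, 1), 20000, noiseSD = 1, seed = 3)
  r1 <- cor(x[1, -1], x[1, -20000])
  expect_lt(abs(r1 - 0.5), 0.03)

  expect_error(simulateVAR1(diag(2) * 1.2, 10), "spectral radius")
})

test_that("cohort generation is deterministic and correctly shaped", {
  spec <- smallSpec()
  c1 <- generateCohort(spec, seed = 11)
  c2 <- generateCohort(spec, seed = 11)
  expect_identical(c1@manifest, c2@manifest)
  expect_identical(c1@timeSeries[[5]], c2@timeSeries[[5]])

  expect_equal(nrow(c1@manifest), 30L)
  expect_true(all(vapply(c1@timeSeries, function(m)
    all(dim(m) == c(60, 60)), logical(1))))
  expect_true(all(is.na(c1@manifest$edss[c1@manifest$group == "HC"])))
  expect_true(all(!is.na(c1@manifest$edss[c1@manifest$group != "HC"])))
  ## both disability strata populated
  strat <- edssStratify(c1@manifest$edss)
  expect_true(all(c("lt4", "ge4") %in% strat))
})

test_that("profiles round-trip to per-subject TSVs", {
  ch <- generateCohort(cohortSpec(nHC = 2L, nCPMS = 2L, nCIMS = 2L,
                                  nRegions = 30L, nThalamic = 4L,
                                  nTimepoints = 30L), seed = 3)
  se <- computeProfiles(ch)
  dir <- tempfile()
  writeProfiles(se, dir)
  expect_length(list.files(dir), 7L)   # 6 subjects + metadata sidecar
  p1 <- read.delim(file.path(dir, "S001_profile.tsv"))
  expect_equal(p1$average_ctrl, signif(averageCtrl(se)[, "S001"], 8))
})

test_that("a cohort too small to populate both disability strata errors", {
  expect_error(
    generateCohort(cohortSpec(nHC = 2L, nCPMS = 2L, nCIMS = 2L,
                              nRegions = 30L, nThalamic = 4L,
                              nTimepoints = 30L), seed = 2,
                   simulate = FALSE),
    "stratum is empty")
})

test_that("reference cohort dimensions match the study layout", {
  spec <- cohortSpec()
  ch <- generateCohort(spec, seed = 42, simulate = FALSE)
  expect_equal(nrow(ch@manifest), 129L)
  expect_equal(as.vector(table(factor(ch@manifest$group,
                                      c("HC", "CPMS", "CIMS")))),
               c(27L, 47L, 55L))
  expect_equal(nRegions(ch@parcellation), 454L)
  expect_equal(spec@nTimepoints, 100L)
})

test_that("the impairment rule recovers generative labels", {
  agree <- vapply(1:10, function(s) {
    ch <- generateCohort(cohortSpec(), seed = s, simulate = FALSE)
    ph <- cohortPhenotypes(ch@manifest)
    pat <- ch@manifest$group != "HC"
    mean(ph$status[pat] == ch@manifest$group[pat])
  }, numeric(1))
  expect_true(all(agree >= 0.95))
})

test_that("with no cognitive effect the rule recovers labels at chance", {
  agree <- vapply(1:10, function(s) {
    ch <- generateCohort(cohortSpec(subtestEffectCIMS = 0,
                                    couplingEffectCPMS = 0,
                                    couplingEffectCIMS = 0),
                         seed = 100 + s, simulate = FALSE)
    ph <- cohortPhenotypes(ch@manifest)
    pat <- ch@manifest$group != "HC"
    mean(ph$status[pat] == ch@manifest$group[pat])
  }, numeric(1))
  expect_true(all(agree > 0.35 & agree < 0.65))
})

test_that("thalamic volume separates MS from HC but not CIMS from CPMS", {
  pHCMS <- numeric(50)
  pCC <- numeric(50)
  for (s in 1:50) {
    ch <- generateCohort(cohortSpec(), seed = 200 + s, simulate = FALSE)
    m <- ch@manifest
    pCC[s] <- t.test(m$thalamic_volume[m$group == "CIMS"],
                     m$thalamic_volume[m$group == "CPMS"])$p.value
    pHCMS[s] <- t.test(m$thalamic_volume[m$group == "HC"],
                       m$thalamic_volume[m$group != "HC"])$p.value
  }
  rejCC <- mean(pCC < 0.05)
  expect_gte(rejCC, 0.0)
  expect_lte(rejCC, 0.12)
  expect_gt(mean(pHCMS < 0.05), 0.9)
})

test_that("cohort files round-trip through disk", {
  ch <- generateCohort(smallSpec(nHC = 2L, nCPMS = 2L, nCIMS = 2L,
                                 nTimepoints = 20L), seed = 3)
  dir <- tempfile()
  writeCohort(ch, dir)
  ts <- readTimeSeriesTSV(file.path(dir, "timeseries", "S001.tsv"))
  expect_equal(dim(ts), dim(ch@timeSeries[[1]]))
  expect_equal(unname(ts), unname(signif(ch@timeSeries[[1]], 8)),
               tolerance = 1e-7)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 6L)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(gt$seed, 3)
})
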