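#' Ground-truth coupling template
#'
#' Symmetric zero-diagonal coupling matrix with a boolean mask marking the
#' thalamo-cortical edges perturbed in patient groups. The spectral radius
#' equals the specification's target exactly (up to floating point).
#'
#' @slot matrix the coupling matrix.
#' @slot effectMask logical matrix, \code{TRUE} on thalamus-to-nonthalamus
#'   edges.
#' @slot spectralRadius the target radius the matrix was scaled to.
#' @export
setClass("GroundTruthCoupling", slots = c(
  matrix = "matrix", effectMask = "matrix", spectralRadius = "numeric"))

setValidity("GroundTruthCoupling", function(object) {
  M <- object@matrix
  if (nrow(M) != ncol(M)) return("coupling must be square")
  if (max(abs(M - t(M))) > 0) return("coupling must be exactly symmetric")
  if (any(diag(M) != 0)) return("diagonal must be exactly zero")
  if (abs(spectralRadius(M) - object@spectralRadius) > 1e-9)
    return("spectral radius does not match the recorded target")
  if (!identical(dim(object@effectMask), dim(M)))
    return("effectMask dimension mismatch")
  TRUE
})

setMethod("show", "GroundTruthCoupling", function(object) {
  cat("GroundTruthCoupling:", nrow(object@matrix), "regions, spectral radius",
      object@spectralRadius, ",", sum(object@effectMask), "maskable edges\n")
  invisible(object)
})

## Sub-block assignment: split every system into contiguous groups of ~8
## regions. Returns an integer vector of sub-block ids.
subBlockAssignment <- function(systems, size = 8L) {
  sub <- integer(length(systems))
  counter <- 0L
  for (s in unique(systems)) {
    idx <- which(systems == s)
    k <- length(idx)
    nsb <- max(1L, as.integer(round(k / size)))
    sub[idx] <- counter + rep(seq_len(nsb), length.out = k)
    counter <- counter + nsb
  }
  sub
}

#' Build the base coupling template for a cohort
#'
#' Constructs a structured symmetric coupling matrix: a weak global positive
#' background, system-level blocks, strong ~8-region sub-blocks (within-system
#' weights exceed between-system weights), and focal positive thalamo-cortical
#' projections that make the thalamus a connector hub (each thalamic region
#' projects onto one cortical sub-block, assigned round-robin). A small
#' multiplicative jitter individualises the template per seed; the result is
#' scaled so its spectral radius equals \code{spec@spectralRadius} exactly.
#'
#' @param parcellation a \code{Parcellation} containing a thalamus system.
#' @param spec a \code{CohortSpec}.
#' @param seed integer seed (jitter only; the skeleton is deterministic).
#' @return A \linkS4class{GroundTruthCoupling}.
#' @export
buildBaseCoupling <- function(parcellation, spec, seed = 1L) {
  stopifnot(is(parcellation, "Parcellation"), is(spec, "CohortSpec"))
  sys <- regionSystems(parcellation)
  if (length(unique(sys)) < 2L)
    stop("parcellation must define at least two systems", call. = FALSE)
  if (!"thalamus" %in% sys)
    stop("parcellation does not contain a thalamus system", call. = FALSE)
  n <- length(sys)
  if (n != spec@nRegions)
    stop("parcellation size (", n, ") does not match spec@nRegions (",
         spec@nRegions, ")", call. = FALSE)
  thal <- sys == "thalamus"
  cortical <- regionTable(parcellation)$region_class == "cortical"

  W <- matrix(spec@backgroundWeight / n, n, n)
  for (s in unique(sys)) {
    idx <- sys == s
    k <- sum(idx)
    if (k > 1) W[idx, idx] <- W[idx, idx] + spec@blockWeight / (k - 1)
  }
  sub <- subBlockAssignment(sys)
  for (b in unique(sub)) {
    idx <- sub == b
    k <- sum(idx)
    if (k > 1) {
      be <- if (sys[which(idx)[1]] == "thalamus")
        spec@thalamicBlockWeight else spec@subBlockWeight
      W[idx, idx] <- W[idx, idx] + be / (k - 1)
    }
  }
  ## focal thalamo-cortical projections, round-robin over cortical sub-blocks
  cortSubs <- unique(sub[cortical])
  ti <- which(thal)
  for (j in seq_along(ti)) {
    b <- cortSubs[((j - 1L) %% length(cortSubs)) + 1L]
    mem <- which(sub == b)
    tgt <- mem[seq_len(min(spec@nProjections, length(mem)))]
    w <- spec@hubWeight / sqrt(length(tgt))
    W[ti[j], tgt] <- W[ti[j], tgt] + w
    W[tgt, ti[j]] <- W[ti[j], tgt]
  }
  withSeed(seed, {
    J <- matrix(rnorm(n * n, 0, spec@jitterSD), n, n)
    J <- (J + t(J)) / 2
    W <- W * (1 + J)
  })
  W <- symmetrizeZeroDiag(W)
  W <- W * (spec@spectralRadius / spectralRadius(W))
  mask <- outer(thal, !thal) | outer(!thal, thal)
  new("GroundTruthCoupling", matrix = W, effectMask = mask,
      spectralRadius = spec@spectralRadius)
}

#' Subject-level coupling matrix
#'
#' Applies the group-specific thalamo-cortical effect (masked edges multiplied
#' by \code{1 + effect}), adds symmetric i.i.d. individual coupling noise, and
#' rescales to the specification's spectral radius. With zero effect and zero
#' coupling noise the base matrix is returned unchanged.
#'
#' @param base a \linkS4class{GroundTruthCoupling}.
#' @param group one of \code{"HC"}, \code{"CPMS"}, \code{"CIMS"}.
#' @param spec a \code{CohortSpec}.
#' @param seed integer seed for the individual noise.
#' @param effectScale optional multiplier of the group effect (used to encode
#'   disability severity; default 1).
#' @return Symmetric zero-diagonal matrix with spectral radius
#'   \code{spec@spectralRadius}.
#' @export
makeSubjectCoupling <- function(base, group, spec, seed = 1L,
                                effectScale = 1) {
  stopifnot(is(base, "GroundTruthCoupling"), is(spec, "CohortSpec"))
  eff <- switch(group,
                HC = 0,
                CPMS = spec@couplingEffectCPMS,
                CIMS = spec@couplingEffectCIMS,
                stop("unknown group '", group, "'", call. = FALSE))
  eff <- eff * effectScale
  M <- base@matrix
  M[base@effectMask] <- M[base@effectMask] * (1 + eff)
  if (spec@couplingNoiseSD > 0) {
    n <- nrow(M)
    withSeed(seed, {
      E <- matrix(rnorm(n * n, 0, spec@couplingNoiseSD), n, n)
      M <- M + (E + t(E)) / 2
    })
  }
  M <- symmetrizeZeroDiag(M)
  sr <- spectralRadius(M)
  if (sr > 0) M <- M * (spec@spectralRadius / sr)
  M
}

#' Simulate a stationary VAR(1) time series
#'
#' Iterates \eqn{x_{t+1} = A x_t + \epsilon_t} with isotropic Gaussian
#' innovations, discards the burn-in, and returns a regions-by-timepoints
#' matrix.
#'
#' @param A stable coupling matrix (spectral radius < 1).
#' @param nTimepoints number of retained timepoints (\eqn{\ge 2}).
#' @param noiseSD innovation standard deviation.
#' @param seed integer seed.
#' @param burnin discarded initial steps (default 300).
#' @return Matrix of dimension \code{nrow(A)} x \code{nTimepoints}.
#' @export
simulateVAR1 <- function(A, nTimepoints, noiseSD = 1, seed = NULL,
                         burnin = 300L) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (nTimepoints < 2) stop("nTimepoints must be >= 2", call. = FALSE)
  sr <- spectralRadius(A)
  if (sr >= 1)
    stop("unstable dynamics: spectral radius ", format(sr), " >= 1",
         call. = FALSE)
  n <- nrow(A)
  total <- burnin + nTimepoints
  withSeed(seed, {
    eps <- if (noiseSD > 0)
      matrix(rnorm(n * total, 0, noiseSD), n, total) else
      matrix(0, n, total)
    x <- numeric(n)
    out <- matrix(0, n, nTimepoints)
    for (t in seq_len(total)) {
      x <- as.vector(A %*% x) + eps[, t]
      if (t > burnin) out[, t - burnin] <- x
    }
    out
  })
}

#' Synthetic multi-subject cohort
#'
#' Container for a generated cohort: the specification, the parcellation, the
#' subject manifest (demographics, group, thalamic volume, EDSS, subtest
#' scores), per-subject regional time series, and the ground truth (base
#' coupling, perturbed edges, per-subject seeds).
#'
#' @slot spec the \code{CohortSpec}.
#' @slot parcellation the \code{Parcellation}.
#' @slot manifest subject-level \code{data.frame}.
#' @slot timeSeries named list of regions-by-timepoints matrices (possibly
#'   empty when only the manifest was generated).
#' @slot groundTruth list with the base coupling and generation seeds.
#' @export
setClass("SyntheticCohort", slots = c(
  spec = "CohortSpec", parcellation = "Parcellation",
  manifest = "data.frame", timeSeries = "list", groundTruth = "list"))

setMethod("show", "SyntheticCohort", function(object) {
  m <- object@manifest
  cat("SyntheticCohort:", nrow(m), "subjects (",
      sum(m$group == "HC"), "HC,", sum(m$group == "CPMS"), "CPMS,",
      sum(m$group == "CIMS"), "CIMS );",
      length(object@timeSeries), "time-series matrices\n")
  invisible(object)
})

## Truncated-normal draw by rejection (bounds in natural units).
rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    cand <- rnorm(length(need), mean, sd)
    ok <- cand >= lower & cand <= upper
    out[need[ok]] <- cand[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a synthetic cohort
#'
#' Draws subjects per group with demographics, thalamic volumes, EDSS scores,
#' cognitive subtest scores, and (optionally) VAR(1) regional time series from
#' subject-specific coupling matrices. CIMS subjects have three randomly
#' chosen subtests suppressed by \code{subtestEffectCIMS} HC-SDs so the
#' impairment rule recovers the generative label; thalamic volume is reduced
#' by \code{volumeEffectMS} SDs in both patient groups (uninformative between
#' CIMS and CPMS); EDSS is sampled so both disability strata are populated and
#' modulates the individual coupling effect.
#'
#' @param spec a \code{CohortSpec}.
#' @param parcellation a \code{Parcellation}; default built from the spec's
#'   dimensions.
#' @param seed master seed; every draw is derived from it.
#' @param simulate if \code{FALSE}, skip time-series simulation (manifest
#'   only).
#' @return A \linkS4class{SyntheticCohort}.
#' @export
generateCohort <- function(spec = cohortSpec(), parcellation = NULL,
                           seed = 1L, simulate = TRUE) {
  stopifnot(is(spec, "CohortSpec"))
  if (is.null(parcellation)) {
    ## keep the cortical/subcortical split proportional to the default table
    nSub <- max(spec@nThalamic + 6L, as.integer(round(spec@nRegions * 54 / 454)))
    parcellation <- makeParcellation(spec@nRegions - nSub, nSub,
                                     spec@nThalamic)
  }
  stopifnot(is(parcellation, "Parcellation"))
  groups <- c(rep("HC", spec@nHC), rep("CPMS", spec@nCPMS),
              rep("CIMS", spec@nCIMS))
  nSubj <- length(groups)
  seeds <- deriveSeeds(seed, nSubj + 2L)
  baseSeed <- seeds[nSubj + 1L]
  phenoSeed <- seeds[nSubj + 2L]
  base <- buildBaseCoupling(parcellation, spec, baseSeed)

  subtests <- names(defaultDomainMap())
  manifest <- withSeed(phenoSeed, {
    isMS <- groups != "HC"
    age <- numeric(nSubj)
    age[!isMS] <- rtruncnorm1(sum(!isMS), spec@ageMeanHC, spec@ageSD, 18, 60)
    age[isMS] <- rtruncnorm1(sum(isMS), spec@ageMeanMS, spec@ageSD, 18, 60)
    sex <- ifelse(rbinom(nSubj, 1, spec@femaleProb) == 1, "F", "M")
    volume <- rnorm(nSubj, 10 - spec@volumeEffectMS * isMS, 1)
    edss <- rep(NA_real_, nSubj)
    edss[isMS] <- pmin(6.5, pmax(0, round(
      rtruncnorm1(sum(isMS), 4, 1.3, 0, 6.5) * 2) / 2))
    if (any(isMS)) {
      strata <- edss[isMS] >= 4
      if (all(strata) || !any(strata))
        stop("cohort too small: an EDSS stratum is empty", call. = FALSE)
    }
    scores <- matrix(rnorm(nSubj * length(subtests),
                           subtestBaseMean,
                           ifelse(isMS, subtestPatientSD, subtestBaseSD)),
                     nSubj, length(subtests))
    colnames(scores) <- subtests
    for (i in which(groups == "CIMS")) {
      imp <- sample(length(subtests), 3L)
      scores[i, imp] <- scores[i, imp] -
        spec@subtestEffectCIMS * subtestBaseSD
    }
    df <- data.frame(
      subject_id = sprintf("S%03d", seq_len(nSubj)),
      group = groups, age = round(age, 1), sex = sex,
      thalamic_volume = round(volume, 3), edss = edss,
      stringsAsFactors = FALSE)
    cbind(df, round(as.data.frame(scores), 2))
  })

  ts <- list()
  if (simulate) {
    ts <- vector("list", nSubj)
    names(ts) <- manifest$subject_id
    for (i in seq_len(nSubj)) {
      effScale <- 1
      if (groups[i] != "HC" && spec@edssEffect > 0)
        effScale <- 1 + spec@edssEffect *
          (if (manifest$edss[i] >= 4) 0.5 else -0.5)
      subSeeds <- deriveSeeds(seeds[i], 2L)
      A <- makeSubjectCoupling(base, groups[i], spec, subSeeds[1],
                               effectScale = effScale)
      ts[[i]] <- simulateVAR1(A, spec@nTimepoints, spec@noiseSD,
                              subSeeds[2], spec@burnin)
      rownames(ts[[i]]) <- regionTable(parcellation)$label
    }
  }
  new("SyntheticCohort", spec = spec, parcellation = parcellation,
      manifest = manifest, timeSeries = ts,
      groundTruth = list(base = base, seed = seed, subjectSeeds = seeds,
                         groups = groups))
}

#' Write a cohort to disk
#'
#' Writes one TSV per subject (first column the region label, remaining
#' columns the timepoints, no header), the manifest CSV, the parcellation
#' TSV, and a ground-truth JSON (seed, effect sizes, perturbed-edge count).
#'
#' @param cohort a \code{SyntheticCohort}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "SyntheticCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsdir <- file.path(dir, "timeseries")
  dir.create(tsdir, showWarnings = FALSE)
  for (id in names(cohort@timeSeries)) {
    m <- cohort@timeSeries[[id]]
    df <- data.frame(region = rownames(m), signif(m, 8),
                     stringsAsFactors = FALSE)
    write.table(df, file.path(tsdir, paste0(id, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  write.csv(cohort@manifest, file.path(dir, "manifest.csv"),
            row.names = FALSE)
  writeParcellation(cohort@parcellation, file.path(dir, "parcellation.tsv"))
  gt <- cohort@groundTruth
  spec <- cohort@spec
  jsonlite::write_json(list(
    seed = gt$seed,
    coupling_effect_cpms = spec@couplingEffectCPMS,
    coupling_effect_cims = spec@couplingEffectCIMS,
    spectral_radius = spec@spectralRadius,
    n_perturbed_edges = sum(gt$base@effectMask)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a subject time-series TSV
#'
#' Format as written by \code{\link{writeCohort}}: no header, region label in
#' the first column.
#'
#' @param path file path.
#' @return Numeric matrix with region labels as row names.
#' @export
readTimeSeriesTSV <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  colnames(m) <- NULL
  storage.mode(m) <- "double"
  m
}
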