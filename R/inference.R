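#' Covariate-adjusted permutation test (Freedman-Lane)
#'
#' Tests the group effect on \code{y} while holding nuisance covariates
#' fixed. The reduced model \code{y ~ X} is fitted; its residuals are
#' permuted, re-added to the reduced fit, and the regression t statistic of
#' the group indicator in the full model is recomputed for every
#' permutation. The two-sided p-value is
#' \eqn{(1 + \#\{|t^*| \ge |t|\}) / (1 + n_{perm})}.
#'
#' @param y numeric outcome vector.
#' @param group binary group labels (logical, 0/1, or two-level factor).
#' @param X nuisance covariate matrix (without intercept; one is added), or
#'   \code{NULL} for an unadjusted test.
#' @param nPerm number of permutations (default 10000).
#' @param seed integer seed for the permutation stream.
#' @return List with \code{statistic} (observed t), \code{p} (permutation
#'   p-value), \code{df}, \code{nPerm}.
#' @export
adjustedPermutationTest <- function(y, group, X = NULL, nPerm = 10000L,
                                    seed = 1L) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.factor(group)) group <- as.integer(group) - 1L
  g <- as.numeric(group)
  if (length(g) != n) stop("y and group lengths differ", call. = FALSE)
  if (length(unique(g)) != 2L)
    stop("group must have exactly two levels, both non-empty",
         call. = FALSE)
  g <- as.numeric(g == max(g))
  X <- if (is.null(X)) matrix(1, n, 1) else cbind(1, as.matrix(X))
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("covariate matrix is rank deficient", call. = FALSE)
  df <- n - ncol(X) - 1L
  if (df < 1) stop("not enough observations for the model", call. = FALSE)
  if (sd(y) == 0) {
    warning("constant outcome; p set to 1")
    return(list(statistic = 0, p = 1, df = df, nPerm = nPerm))
  }
  r <- qr.resid(qx, y)            # reduced-model residuals
  gt <- qr.resid(qx, g)           # group partialled against X
  gn2 <- sum(gt^2)
  if (gn2 < 1e-12 * n)
    stop("group indicator is collinear with the covariates", call. = FALSE)
  ssr <- sum(r^2)
  tstat <- function(num) {
    rss <- pmax(ssr - num^2 / gn2, 0)
    num / sqrt(gn2) / sqrt(rss / df)
  }
  tObs <- tstat(sum(gt * r))
  perm <- withSeed(seed, {
    idx <- vapply(seq_len(nPerm), function(i) sample.int(n),
                  integer(n))
    matrix(r[idx], n, nPerm)
  })
  nums <- as.vector(crossprod(perm, gt))
  tPerm <- tstat(nums)
  p <- (1 + sum(abs(tPerm) >= abs(tObs))) / (1 + nPerm)
  list(statistic = tObs, p = p, df = df, nPerm = nPerm)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity,
#' capped at 1 (delegates to \code{\link[stats]{p.adjust}}).
#'
#' @param p numeric vector of p-values in \eqn{[0, 1]}.
#' @return Adjusted p-values, same length and order as the input.
#' @export
bhFDR <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Pearson chi-squared test on a contingency table
#'
#' Without continuity correction; degrees of freedom
#' \eqn{(r - 1)(c - 1)}.
#'
#' @param table matrix of non-negative integer counts, at least 2x2.
#' @return List with \code{statistic}, \code{df}, \code{p}.
#' @export
chiSquaredContingency <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2)
    stop("need at least a 2x2 table", call. = FALSE)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal in the contingency table", call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

## Contrast ladder used by the group comparisons.
contrastDefs <- function() list(
  HC_vs_MS = function(st) ifelse(st == "HC", 0, 1),
  HC_vs_CPMS = function(st) ifelse(st == "HC", 0,
                                   ifelse(st == "CPMS", 1, NA)),
  HC_vs_CIMS = function(st) ifelse(st == "HC", 0,
                                   ifelse(st == "CIMS", 1, NA)),
  CPMS_vs_CIMS = function(st) ifelse(st == "CPMS", 0,
                                     ifelse(st == "CIMS", 1, NA)))

#' Covariate-adjusted group comparisons over the aggregation ladder
#'
#' Runs the Freedman-Lane permutation test for every combination of
#' contrast (HC vs MS, HC vs CPMS, HC vs CIMS, CPMS vs CIMS), metric
#' (average, modal, energy) and aggregation unit (global; the 8 networks;
#' the 7 nuclei), adjusting for age (standardized) and sex. FDR correction
#' is applied within each (contrast, metric, level) family, mirroring the
#' 8-network and 7-nucleus scans.
#'
#' @param aggregated long-format table from \code{\link{aggregateMetrics}}.
#' @param manifest cohort manifest (needs \code{subject_id}, \code{age},
#'   \code{sex}).
#' @param status per-subject group labels aligned with the manifest
#'   (\code{HC}/\code{CPMS}/\code{CIMS}); defaults to \code{manifest$group}.
#' @param nPerm permutations per test (default 10000).
#' @param seed master seed; each test derives its own stream.
#' @param levels which aggregation levels to test.
#' @param contrasts which contrasts to run (default all four).
#' @param alpha significance level for the \code{significant} flag.
#' @return \code{data.frame} with one row per test: contrast, level, unit,
#'   metric, observed statistic, direction, \code{p_perm}, \code{p_fdr},
#'   \code{significant}, provenance columns (\code{n_perm}, \code{seed},
#'   \code{family}).
#' @export
runGroupComparisons <- function(aggregated, manifest, status = NULL,
                                nPerm = 10000L, seed = 1L,
                                levels = c("global", "network", "nucleus"),
                                contrasts = c("HC_vs_MS", "HC_vs_CPMS",
                                              "HC_vs_CIMS", "CPMS_vs_CIMS"),
                                alpha = 0.05) {
  if (is.null(status)) status <- manifest$group
  stopifnot(length(status) == nrow(manifest))
  names(status) <- manifest$subject_id
  covAge <- as.numeric(scale(manifest$age))
  covSex <- as.numeric(manifest$sex == "F")
  names(covAge) <- names(covSex) <- manifest$subject_id
  contrasts <- contrastDefs()[match.arg(contrasts, several.ok = TRUE)]
  rows <- list()
  testSeedPool <- deriveSeeds(seed, 4L * 3L * 16L)
  k <- 0L
  for (cn in names(contrasts)) {
    lab <- contrasts[[cn]](status)
    for (metric in unique(aggregated$metric)) {
      for (lev in levels) {
        sub <- aggregated[aggregated$metric == metric &
                          aggregated$level == lev, , drop = FALSE]
        fam <- paste(cn, metric, lev, sep = ".")
        famRows <- list()
        for (u in unique(sub$unit)) {
          k <- k + 1L
          us <- sub[sub$unit == u, , drop = FALSE]
          li <- lab[us$subject_id]
          keep <- !is.na(li)
          if (!length(unique(li[keep])) == 2L)
            stop("contrast ", cn, " has an empty group", call. = FALSE)
          res <- adjustedPermutationTest(
            us$value[keep], li[keep],
            X = cbind(age = covAge[us$subject_id][keep],
                      sex = covSex[us$subject_id][keep]),
            nPerm = nPerm, seed = testSeedPool[((k - 1L) %%
                                                length(testSeedPool)) + 1L])
          famRows[[length(famRows) + 1L]] <- data.frame(
            contrast = cn, level = lev, unit = u, metric = metric,
            statistic = res$statistic,
            direction = sign(res$statistic),
            p_perm = res$p, stringsAsFactors = FALSE)
        }
        fr <- do.call(rbind, famRows)
        fr$p_fdr <- bhFDR(fr$p_perm)
        fr$significant <- fr$p_fdr < alpha
        fr$family <- fam
        rows[[length(rows) + 1L]] <- fr
      }
    }
  }
  out <- do.call(rbind, rows)
  out$n_perm <- nPerm
  out$seed <- seed
  rownames(out) <- NULL
  out
}
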