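#' Aggregate regional metrics to analysis units
#'
#' Unweighted means of region-level controllability metrics at three levels:
#' \code{global} (all regions, unit \code{whole_brain}), \code{network}
#' (the seven cortical networks plus the whole subcortex as an eighth unit)
#' and \code{nucleus} (the seven subcortical nuclei).
#'
#' @param profiles a \code{SummarizedExperiment} from
#'   \code{\link{computeProfiles}}, or a named list of regions-by-subjects
#'   matrices.
#' @param parcellation the matching \code{Parcellation} (taken from the
#'   profile row data when omitted).
#' @return Long-format \code{data.frame} with columns \code{subject_id},
#'   \code{level}, \code{unit}, \code{metric} (\code{average}, \code{modal},
#'   \code{energy}) and \code{value}.
#' @export
aggregateMetrics <- function(profiles, parcellation = NULL) {
  if (is(profiles, "SummarizedExperiment")) {
    mats <- list(average = averageCtrl(profiles),
                 modal = modalCtrl(profiles),
                 energy = activationEnergyAssay(profiles))
    if (is.null(parcellation))
      parcellation <- new("Parcellation", table = as.data.frame(
        SummarizedExperiment::rowData(profiles)))
  } else {
    mats <- profiles
    names(mats) <- sub("^average_ctrl$", "average",
                       sub("^modal_ctrl$", "modal",
                           sub("^activation_energy$", "energy", names(mats))))
  }
  stopifnot(is(parcellation, "Parcellation"))
  n <- nRegions(parcellation)
  tab <- regionTable(parcellation)
  units <- c(list(whole_brain = seq_len(n)),
             lapply(setNames(corticalNetworks, corticalNetworks),
                    function(s) which(tab$system == s)),
             list(subcortical = which(tab$region_class == "subcortical")),
             lapply(setNames(subcorticalNuclei, subcorticalNuclei),
                    function(s) which(tab$system == s)))
  levels <- c("global", rep("network", 8L), rep("nucleus", 7L))
  out <- list()
  for (metric in names(mats)) {
    m <- mats[[metric]]
    if (nrow(m) != n)
      stop("metric '", metric, "' has ", nrow(m),
           " regions but parcellation has ", n, call. = FALSE)
    for (u in seq_along(units)) {
      idx <- units[[u]]
      if (!length(idx)) next
      vals <- colMeans(m[idx, , drop = FALSE])
      out[[length(out) + 1L]] <- data.frame(
        subject_id = colnames(m), level = levels[u],
        unit = names(units)[u], metric = metric, value = as.numeric(vals),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Cognitive domain scores and global score
#'
#' \code{domainScores} averages the subtests assigned to each domain;
#' \code{globalCognitiveScore} averages the four domain means (a mean of
#' means, not a pooled subtest mean).
#'
#' @param subtests named numeric vector of subtest scores.
#' @param domainMap named character vector mapping subtest to domain
#'   (default \code{\link{defaultDomainMap}}).
#' @return \code{domainScores}: named numeric vector, one entry per domain;
#'   \code{globalCognitiveScore}: scalar.
#' @export
domainScores <- function(subtests, domainMap = defaultDomainMap()) {
  miss <- setdiff(names(subtests), names(domainMap))
  if (length(miss))
    stop("subtest(s) not mapped to a domain: ",
         paste(miss, collapse = ", "), call. = FALSE)
  need <- setdiff(names(domainMap), names(subtests))
  if (length(need))
    stop("missing subtest(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  doms <- unique(unname(domainMap))
  vapply(doms, function(d)
    mean(subtests[names(domainMap)[domainMap == d]]), numeric(1))
}

#' @rdname domainScores
#' @export
globalCognitiveScore <- function(subtests,
                                 domainMap = defaultDomainMap()) {
  mean(domainScores(subtests, domainMap))
}

#' Classify cognitive impairment status
#'
#' A patient is impaired (CIMS) when at least two subtests score at least
#' 1.5 control standard deviations below the control mean (the boundary
#' counts as impaired); otherwise preserved (CPMS).
#'
#' @param patientSubtests named numeric vector of a patient's subtest scores.
#' @param hcMeans,hcSDs named control means and standard deviations for the
#'   same subtests; all SDs must be positive.
#' @param threshold SD multiplier (default 1.5).
#' @param minImpaired minimum impaired subtests for CIMS (default 2).
#' @return \code{"CIMS"} or \code{"CPMS"}.
#' @export
classifyCIMS <- function(patientSubtests, hcMeans, hcSDs,
                         threshold = 1.5, minImpaired = 2L) {
  nm <- names(patientSubtests)
  if (is.null(nm) || !all(nm %in% names(hcMeans)) ||
      !all(nm %in% names(hcSDs)))
    stop("subtest names must match between patient and control statistics",
         call. = FALSE)
  if (any(hcSDs[nm] <= 0)) stop("control SDs must be positive",
                                call. = FALSE)
  impaired <- patientSubtests <= hcMeans[nm] - threshold * hcSDs[nm]
  if (sum(impaired) >= minImpaired) "CIMS" else "CPMS"
}

#' Disability stratum from an EDSS score
#'
#' Scores below 4.0 map to \code{"lt4"}, scores of 4.0 or higher to
#' \code{"ge4"} (the boundary is inclusive), and missing values (healthy
#' controls) to \code{"none"}.
#'
#' @param edss numeric vector of EDSS scores in \eqn{[0, 10]} or \code{NA}.
#' @return Character vector of strata.
#' @export
edssStratify <- function(edss) {
  bad <- !is.na(edss) & (edss < 0 | edss > 10)
  if (any(bad)) stop("EDSS out of range [0, 10]: ",
                     paste(edss[bad], collapse = ", "), call. = FALSE)
  ifelse(is.na(edss), "none", ifelse(edss >= 4, "ge4", "lt4"))
}

#' Cognitive phenotypes for a cohort manifest
#'
#' Computes per-subject domain scores, the global cognitive score, the
#' CIMS/CPMS status of patients (from the cohort's own control statistics)
#' and the EDSS stratum.
#'
#' @param manifest cohort manifest with \code{group}, \code{edss} and one
#'   column per subtest.
#' @param domainMap subtest-to-domain map.
#' @return \code{data.frame} with \code{subject_id}, one column per domain,
#'   \code{global_score}, \code{status} and \code{edss_stratum}.
#' @export
cohortPhenotypes <- function(manifest, domainMap = defaultDomainMap()) {
  subtests <- names(domainMap)
  miss <- setdiff(subtests, names(manifest))
  if (length(miss))
    stop("manifest lacks subtest column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  hc <- manifest$group == "HC"
  if (!any(hc)) stop("manifest contains no HC subjects", call. = FALSE)
  hcMeans <- vapply(subtests, function(s) mean(manifest[[s]][hc]),
                    numeric(1))
  hcSDs <- vapply(subtests, function(s) sd(manifest[[s]][hc]), numeric(1))
  doms <- unique(unname(domainMap))
  out <- data.frame(subject_id = manifest$subject_id,
                    stringsAsFactors = FALSE)
  scoreMat <- t(apply(manifest[, subtests, drop = FALSE], 1, function(x)
    domainScores(setNames(as.numeric(x), subtests), domainMap)))
  colnames(scoreMat) <- doms
  out <- cbind(out, as.data.frame(scoreMat))
  out$global_score <- rowMeans(scoreMat)
  out$status <- vapply(seq_len(nrow(manifest)), function(i)
    if (hc[i]) "HC" else
      classifyCIMS(setNames(as.numeric(manifest[i, subtests]), subtests),
                   hcMeans, hcSDs), character(1))
  out$edss_stratum <- edssStratify(manifest$edss)
  out
}
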