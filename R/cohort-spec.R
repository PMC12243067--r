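#' Specification of a synthetic cohort
#'
#' Parameter object defining the study conditions emulated by the synthetic
#' generator: group sizes, parcellation dimensions, acquisition length, the
#' coupling template, group-specific thalamo-cortical coupling effects, and
#' phenotype parameters. Defaults reproduce the reference cohort: 27 healthy
#' controls (HC), 47 cognitively preserved (CPMS) and 55 cognitively impaired
#' (CIMS) patients, 454 regions with a 16-region thalamus, 100 timepoints.
#'
#' @slot nHC,nCPMS,nCIMS group sizes.
#' @slot nRegions,nThalamic,nTimepoints parcellation dimensions and series
#'   length.
#' @slot couplingEffectCPMS,couplingEffectCIMS dimensionless multipliers
#'   (\eqn{\ge 0}) applied to thalamo-cortical edges in patients; the CIMS
#'   effect must be at least the CPMS effect.
#' @slot spectralRadius target spectral radius \eqn{\rho \in (0,1)} of every
#'   subject coupling matrix.
#' @slot noiseSD innovation standard deviation of the VAR(1) dynamics.
#' @slot couplingNoiseSD standard deviation of the symmetric between-subject
#'   coupling noise.
#' @slot volumeEffectMS standardized thalamic-volume decrement in patients.
#' @slot subtestEffectCIMS cognitive suppression, in HC-SD units, applied to
#'   the impaired subtests of CIMS subjects.
#' @slot edssEffect fractional modulation of the individual coupling effect by
#'   disability stratum (EDSS \eqn{\ge} 4 patients get \code{1 + edssEffect/2}
#'   times the group effect, EDSS < 4 get \code{1 - edssEffect/2}).
#' @slot ageMeanHC,ageMeanMS,ageSD age distribution (years), truncated to
#'   18--60.
#' @slot femaleProb probability of female sex, all groups.
#' @slot burnin discarded VAR(1) burn-in steps.
#' @slot backgroundWeight,blockWeight,subBlockWeight,thalamicBlockWeight,hubWeight
#'   relative eigen-weights of the coupling template components (global
#'   positive background, system blocks, ~8-region sub-blocks, thalamic block,
#'   focal thalamo-cortical projections).
#' @slot nProjections number of cortical targets per thalamic region.
#' @slot jitterSD multiplicative edge jitter of the template.
#' @export
setClass("CohortSpec", slots = c(
  nHC = "integer", nCPMS = "integer", nCIMS = "integer",
  nRegions = "integer", nThalamic = "integer", nTimepoints = "integer",
  couplingEffectCPMS = "numeric", couplingEffectCIMS = "numeric",
  spectralRadius = "numeric", noiseSD = "numeric",
  couplingNoiseSD = "numeric", volumeEffectMS = "numeric",
  subtestEffectCIMS = "numeric", edssEffect = "numeric",
  ageMeanHC = "numeric", ageMeanMS = "numeric", ageSD = "numeric",
  femaleProb = "numeric", burnin = "integer",
  backgroundWeight = "numeric", blockWeight = "numeric",
  subBlockWeight = "numeric", thalamicBlockWeight = "numeric",
  hubWeight = "numeric", nProjections = "integer", jitterSD = "numeric"))

setValidity("CohortSpec", function(object) {
  counts <- c(object@nHC, object@nCPMS, object@nCIMS, object@nRegions,
              object@nThalamic, object@nTimepoints)
  if (any(counts <= 0L)) return("all counts must be > 0")
  if (object@nThalamic >= object@nRegions)
    return("nThalamic must be smaller than nRegions")
  if (object@spectralRadius <= 0 || object@spectralRadius >= 1)
    return("spectralRadius must lie in (0, 1)")
  if (object@couplingEffectCPMS < 0)
    return("couplingEffectCPMS must be >= 0")
  if (object@couplingEffectCIMS < object@couplingEffectCPMS)
    return("couplingEffectCIMS must be >= couplingEffectCPMS")
  if (object@noiseSD < 0 || object@couplingNoiseSD < 0)
    return("noise standard deviations must be >= 0")
  if (object@edssEffect < 0 || object@edssEffect >= 2)
    return("edssEffect must lie in [0, 2)")
  TRUE
})

#' Create a synthetic cohort specification
#'
#' @param nHC,nCPMS,nCIMS group sizes.
#' @param nRegions,nThalamic,nTimepoints dimensions.
#' @param couplingEffectCPMS,couplingEffectCIMS thalamo-cortical coupling
#'   multipliers for the two patient groups.
#' @param spectralRadius target spectral radius of subject couplings.
#' @param noiseSD,couplingNoiseSD VAR innovation and coupling-noise SDs.
#' @param volumeEffectMS,subtestEffectCIMS,edssEffect phenotype effects.
#' @param ageMeanHC,ageMeanMS,ageSD,femaleProb demographics.
#' @param burnin VAR burn-in.
#' @param backgroundWeight,blockWeight,subBlockWeight,thalamicBlockWeight,hubWeight,nProjections,jitterSD
#'   coupling template parameters; see \linkS4class{CohortSpec}.
#' @return A validated \code{CohortSpec}.
#' @export
cohortSpec <- function(nHC = 27L, nCPMS = 47L, nCIMS = 55L,
                       nRegions = 454L, nThalamic = 16L, nTimepoints = 100L,
                       couplingEffectCPMS = 1.5, couplingEffectCIMS = 3.0,
                       spectralRadius = 0.9, noiseSD = 1,
                       couplingNoiseSD = 0.002, volumeEffectMS = 1.0,
                       subtestEffectCIMS = 2.5, edssEffect = 0.5,
                       ageMeanHC = 40, ageMeanMS = 45, ageSD = 10,
                       femaleProb = 0.65, burnin = 300L,
                       backgroundWeight = 0.5, blockWeight = 0.4,
                       subBlockWeight = 1.0, thalamicBlockWeight = 0.3,
                       hubWeight = 0.2, nProjections = 8L, jitterSD = 0.02) {
  obj <- new("CohortSpec",
             nHC = as.integer(nHC), nCPMS = as.integer(nCPMS),
             nCIMS = as.integer(nCIMS), nRegions = as.integer(nRegions),
             nThalamic = as.integer(nThalamic),
             nTimepoints = as.integer(nTimepoints),
             couplingEffectCPMS = couplingEffectCPMS,
             couplingEffectCIMS = couplingEffectCIMS,
             spectralRadius = spectralRadius, noiseSD = noiseSD,
             couplingNoiseSD = couplingNoiseSD,
             volumeEffectMS = volumeEffectMS,
             subtestEffectCIMS = subtestEffectCIMS, edssEffect = edssEffect,
             ageMeanHC = ageMeanHC, ageMeanMS = ageMeanMS, ageSD = ageSD,
             femaleProb = femaleProb, burnin = as.integer(burnin),
             backgroundWeight = backgroundWeight, blockWeight = blockWeight,
             subBlockWeight = subBlockWeight,
             thalamicBlockWeight = thalamicBlockWeight,
             hubWeight = hubWeight, nProjections = as.integer(nProjections),
             jitterSD = jitterSD)
  validObject(obj)
  obj
}

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", object@nHC, "HC /", object@nCPMS, "CPMS /",
      object@nCIMS, "CIMS;", object@nRegions, "regions x",
      object@nTimepoints, "timepoints\n")
  cat("  coupling effects:", object@couplingEffectCPMS, "(CPMS)",
      object@couplingEffectCIMS, "(CIMS); spectral radius",
      object@spectralRadius, "\n")
  invisible(object)
})

#' Cognitive subtest battery and domain map
#'
#' Nine synthetic subtests grouped into four cognitive domains, mirroring the
#' structure of a brief repeatable neuropsychological battery (verbal memory,
#' visual memory, attention/information processing, verbal fluency) without
#' cloning any published instrument. All subtests are higher-is-better.
#'
#' @return Named character vector mapping subtest name to domain.
#' @export
defaultDomainMap <- function() {
  c(srt_lts = "verbal_memory", srt_cltr = "verbal_memory",
    srt_delayed = "verbal_memory",
    spart = "visual_memory", spart_delayed = "visual_memory",
    sdmt = "attention_ips", pasat3 = "attention_ips",
    pasat2 = "attention_ips",
    wlg = "verbal_fluency")
}

## HC subtest distribution used by the generator (mean, SD per subtest).
subtestBaseMean <- 50
subtestBaseSD <- 10
## Patients are drawn with lower within-group dispersion so the impairment
## rule separates cleanly (see the methods vignette).
subtestPatientSD <- 5
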