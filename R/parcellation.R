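#' Cortical network and subcortical nucleus labels
#'
#' The seven canonical cortical resting-state networks and the seven
#' subcortical nuclei used throughout the package.
#'
#' @name systems
#' @export corticalNetworks
corticalNetworks <- c("VN", "SMN", "DAN", "VAN", "LN", "FPN", "DMN")

#' @rdname systems
#' @export
subcorticalNuclei <- c("hippocampus", "thalamus", "amygdala", "caudate",
                       "nucleus_accumbens", "putamen", "globus_pallidus")

#' Parcellation of brain regions into networks and nuclei
#'
#' An S4 container for a region table with columns \code{region_id}
#' (0-based, contiguous), \code{label}, \code{region_class}
#' (\code{cortical}/\code{subcortical}), \code{system} (one of the seven
#' cortical networks for cortical regions, one of the seven nuclei for
#' subcortical regions) and \code{hemisphere} (\code{L}/\code{R}).
#'
#' @slot table the validated region \code{data.frame}.
#' @export
setClass("Parcellation", slots = c(table = "data.frame"))

setValidity("Parcellation", function(object) {
  tab <- object@table
  req <- c("region_id", "label", "region_class", "system", "hemisphere")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  n <- nrow(tab)
  if (n < 1) return("empty region table")
  if (anyDuplicated(tab$region_id))
    return(paste0("duplicate region_id at row ",
                  which(duplicated(tab$region_id))[1]))
  if (!identical(sort(as.integer(tab$region_id)), 0:(n - 1)))
    return("region_id values must be contiguous 0..N-1")
  if (!all(tab$region_class %in% c("cortical", "subcortical"))) {
    bad <- which(!tab$region_class %in% c("cortical", "subcortical"))[1]
    return(paste0("unknown region_class at row ", bad))
  }
  if (!all(tab$hemisphere %in% c("L", "R")))
    return("hemisphere must be L or R")
  badSys <- which(!tab$system %in% c(corticalNetworks, subcorticalNuclei))
  if (length(badSys))
    return(paste0("unknown system '", tab$system[badSys[1]], "' at row ",
                  badSys[1]))
  cortBad <- which(tab$region_class == "cortical" &
                   !tab$system %in% corticalNetworks)
  if (length(cortBad))
    return(paste0("cortical region assigned to subcortical system at row ",
                  cortBad[1]))
  subBad <- which(tab$region_class == "subcortical" &
                  !tab$system %in% subcorticalNuclei)
  if (length(subBad))
    return(paste0("subcortical region assigned to cortical network at row ",
                  subBad[1]))
  TRUE
})

#' @describeIn Parcellation number of regions
#' @param object,x a \code{Parcellation}.
#' @export
setMethod("length", "Parcellation", function(x) nrow(x@table))

setMethod("show", "Parcellation", function(object) {
  tab <- object@table
  cat("Parcellation with", nrow(tab), "regions (",
      sum(tab$region_class == "cortical"), "cortical,",
      sum(tab$region_class == "subcortical"), "subcortical;",
      sum(tab$system == "thalamus"), "thalamic )\n")
  invisible(object)
})

#' Accessors for Parcellation
#'
#' \code{regionTable} returns the region table; \code{regionSystems} the
#' per-region system vector; \code{systemMembers} the 1-based row indices of
#' one system; \code{nRegions} the region count.
#'
#' @param parc a \code{Parcellation}.
#' @param system system name.
#' @return See individual descriptions.
#' @export
regionTable <- function(parc) {
  stopifnot(is(parc, "Parcellation"))
  parc@table
}

#' @rdname regionTable
#' @export
regionSystems <- function(parc) regionTable(parc)$system

#' @rdname regionTable
#' @export
systemMembers <- function(parc, system) {
  sys <- regionSystems(parc)
  if (!system %in% sys) stop("system '", system, "' not in parcellation",
                             call. = FALSE)
  which(sys == system)
}

#' @rdname regionTable
#' @export
nRegions <- function(parc) nrow(regionTable(parc))

#' Construct a synthetic parcellation
#'
#' Builds a parcellation with \code{nCortical} regions distributed over the
#' seven cortical networks and \code{nSubcortical} regions over the seven
#' nuclei, of which exactly \code{nThalamic} form the thalamus. The default
#' reproduces the 454-region layout used throughout (400 cortical + 54
#' subcortical with a 16-region thalamus). Hemispheres alternate within each
#' system. This is a synthetic stand-in table, not a published atlas.
#'
#' @param nCortical number of cortical regions.
#' @param nSubcortical number of subcortical regions.
#' @param nThalamic number of thalamic regions (part of \code{nSubcortical}).
#' @return A \code{Parcellation}.
#' @export
makeParcellation <- function(nCortical = 400L, nSubcortical = 54L,
                             nThalamic = 16L) {
  nCortical <- as.integer(nCortical)
  nSubcortical <- as.integer(nSubcortical)
  nThalamic <- as.integer(nThalamic)
  if (nCortical < 7L) stop("need at least one region per cortical network")
  if (nThalamic < 1L || nSubcortical - nThalamic < 6L)
    stop("need nThalamic >= 1 and at least one region per remaining nucleus")
  cortCounts <- diff(round(seq(0, nCortical, length.out = 8)))
  otherNuclei <- setdiff(subcorticalNuclei, "thalamus")
  otherCounts <- diff(round(seq(0, nSubcortical - nThalamic, length.out = 7)))
  sys <- c(rep(corticalNetworks, cortCounts),
           rep("thalamus", nThalamic),
           rep(otherNuclei, otherCounts))
  cls <- c(rep("cortical", nCortical), rep("subcortical", nSubcortical))
  hemi <- character(length(sys))
  for (s in unique(sys)) {
    ix <- which(sys == s)
    hemi[ix] <- rep_len(c("L", "R"), length(ix))
  }
  tab <- data.frame(
    region_id = 0:(nCortical + nSubcortical - 1L),
    label = paste0(sys, "_", ave(seq_along(sys), sys, FUN = seq_along)),
    region_class = cls,
    system = sys,
    hemisphere = hemi,
    stringsAsFactors = FALSE)
  new("Parcellation", table = tab)
}

#' Default 454-region parcellation
#'
#' @return The packaged default: 400 cortical regions over seven networks and
#'   54 subcortical regions over seven nuclei with a 16-region thalamus.
#' @export
defaultParcellation <- function() makeParcellation(400L, 54L, 16L)

#' Read a parcellation from a TSV file
#'
#' The file must be tab-separated with a header row containing the columns
#' described in \linkS4class{Parcellation}. Schema violations raise an error
#' naming the offending row.
#'
#' @param path file path.
#' @return A \code{Parcellation}.
#' @export
loadParcellation <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  obj <- new("Parcellation", table = tab)
  validObject(obj)
  obj
}

#' Write a parcellation to TSV
#'
#' @param parc a \code{Parcellation}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeParcellation <- function(parc, path) {
  write.table(regionTable(parc), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
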