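#' Default pipeline configuration
#'
#' Nested list mirroring the analysis stages. \code{demoConfig} is a small
#' fast variant (12 subjects, 30 regions, 200 permutations) used for smoke
#' tests and examples.
#'
#' @param seed master seed recorded in the configuration.
#' @return Named list.
#' @export
defaultConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    cohort = list(n_hc = 27L, n_cpms = 47L, n_cims = 55L,
                  n_regions = 454L, n_thalamic = 16L, n_timepoints = 100L,
                  coupling_effect_cpms = 1.5, coupling_effect_cims = 3.0,
                  spectral_radius = 0.9, noise_sd = 1,
                  volume_effect_ms = 1.0, subtest_effect_cims = 2.5),
    fc = list(negative = "keep"),
    controllability = list(horizon = 1, convention = "single_driver"),
    stats = list(n_perm = 10000L, alpha = 0.05),
    classification = list(k = 5L, repeats = 100L, cost = 1))
}

#' @rdname defaultConfig
#' @export
demoConfig <- function(seed = 1L) {
  cfg <- defaultConfig(seed)
  cfg$cohort$n_hc <- 4L; cfg$cohort$n_cpms <- 4L; cfg$cohort$n_cims <- 4L
  cfg$cohort$n_regions <- 30L; cfg$cohort$n_thalamic <- 4L
  cfg$stats$n_perm <- 200L
  cfg$classification$repeats <- 5L
  cfg$classification$k <- 3L
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks the configuration schema without running anything.
#'
#' @param config configuration list (see \code{\link{defaultConfig}}).
#' @return Character vector of problems; empty when the configuration is
#'   valid.
#' @export
validateConfig <- function(config) {
  problems <- character()
  bad <- function(msg) problems <<- c(problems, msg)
  if (!is.list(config)) return("config must be a list")
  co <- config$cohort
  if (is.null(co)) bad("missing section: cohort") else {
    for (f in c("n_hc", "n_cpms", "n_cims", "n_regions", "n_thalamic",
                "n_timepoints"))
      if (is.null(co[[f]]) || co[[f]] < 1)
        bad(paste0("cohort$", f, " must be a positive count"))
    if (!is.null(co$spectral_radius) &&
        (co$spectral_radius <= 0 || co$spectral_radius >= 1))
      bad("cohort$spectral_radius must lie in (0, 1)")
    if (!is.null(co$coupling_effect_cpms) &&
        !is.null(co$coupling_effect_cims) &&
        (co$coupling_effect_cpms < 0 ||
         co$coupling_effect_cims < co$coupling_effect_cpms))
      bad("coupling effects must satisfy 0 <= cpms <= cims")
  }
  if (!is.null(config$fc$negative) &&
      !config$fc$negative %in% c("keep", "absolute", "zero"))
    bad("fc$negative must be one of keep, absolute, zero")
  conv <- config$controllability$convention
  if (!is.null(conv) &&
      !conv %in% c("single_driver", "whole_brain_control"))
    bad(paste0("controllability$convention '", conv,
               "' invalid; valid values: single_driver,",
               " whole_brain_control"))
  if (!is.null(config$controllability$horizon) &&
      config$controllability$horizon <= 0)
    bad("controllability$horizon must be > 0")
  if (!is.null(config$stats$n_perm) && config$stats$n_perm < 1)
    bad("stats$n_perm must be >= 1")
  if (!is.null(config$classification$k) && config$classification$k < 2)
    bad("classification$k must be >= 2")
  problems
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path file path (extension decides the parser).
#' @return Configuration list merged over the defaults.
#' @export
readConfig <- function(path) {
  cfg <- if (grepl("[.]json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  base <- defaultConfig(seed = if (is.null(cfg$seed)) 1L else cfg$seed)
  for (sec in names(base)) {
    if (is.list(base[[sec]]) && !is.null(cfg[[sec]]))
      for (f in names(cfg[[sec]])) base[[sec]][[f]] <- cfg[[sec]][[f]]
    else if (!is.null(cfg[[sec]])) base[[sec]] <- cfg[[sec]]
  }
  base
}

stageChecksums <- function(files) {
  files <- files[file.exists(files)]
  as.list(tools::md5sum(files))
}

#' Run the full analysis pipeline
#'
#' Executes simulate, profile, aggregate, phenotype, compare and classify in
#' order, writing every stage's outputs and a run manifest (stage records,
#' output checksums, seeds) to \code{outDir}. A stage is skipped when its
#' recorded output checksums still match on disk; any stage failure aborts
#' with the stage name.
#'
#' @param config configuration list (validated first).
#' @param outDir output directory.
#' @param force rerun all stages even when checksums match.
#' @return List with the run manifest and the consolidated result tables
#'   (\code{comparisons}, \code{classification}), invisibly.
#' @export
runPipeline <- function(config = defaultConfig(), outDir, force = FALSE) {
  problems <- validateConfig(config)
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifestPath <- file.path(outDir, "run_manifest.json")
  runManifest <- if (file.exists(manifestPath) && !force)
    jsonlite::read_json(manifestPath, simplifyVector = TRUE) else
    list(stages = list())
  runManifest$config <- config
  runManifest$version <- as.character(utils::packageVersion("brainctrl"))

  stageDone <- function(name, files) {
    rec <- runManifest$stages[[name]]
    if (force || is.null(rec)) return(FALSE)
    cur <- stageChecksums(files)
    identical(as.list(rec$checksums), cur) && length(cur) == length(files)
  }
  record <- function(name, files) {
    runManifest$stages[[name]] <<- list(
      completed = TRUE, time = format(Sys.time()),
      checksums = stageChecksums(files))
    jsonlite::write_json(runManifest, manifestPath, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  runStage <- function(name, files, fun) {
    if (stageDone(name, files)) {
      message("stage ", name, ": up to date, skipped")
      return(FALSE)
    }
    message("stage ", name, ": running")
    tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    record(name, files)
    TRUE
  }

  co <- config$cohort
  spec <- cohortSpec(
    nHC = co$n_hc, nCPMS = co$n_cpms, nCIMS = co$n_cims,
    nRegions = co$n_regions, nThalamic = co$n_thalamic,
    nTimepoints = co$n_timepoints,
    couplingEffectCPMS = co$coupling_effect_cpms,
    couplingEffectCIMS = co$coupling_effect_cims,
    spectralRadius = co$spectral_radius, noiseSD = co$noise_sd,
    volumeEffectMS = co$volume_effect_ms,
    subtestEffectCIMS = co$subtest_effect_cims)

  cohortDir <- file.path(outDir, "cohort")
  manifestCsv <- file.path(cohortDir, "manifest.csv")
  env <- new.env(parent = emptyenv())

  runStage("simulate", c(manifestCsv,
                         file.path(cohortDir, "ground_truth.json")),
           function() {
    env$cohort <- generateCohort(spec, seed = config$seed)
    writeCohort(env$cohort, cohortDir)
  })

  profilesPath <- file.path(outDir, "profiles.tsv")
  aggPath <- file.path(outDir, "aggregated.tsv")
  phenoPath <- file.path(outDir, "phenotypes.csv")
  compPath <- file.path(outDir, "comparisons.tsv")
  clsPath <- file.path(outDir, "classification.tsv")

  needCohort <- function() {
    if (is.null(env$cohort))
      env$cohort <- generateCohort(spec, seed = config$seed)
    env$cohort
  }

  runStage("profile", profilesPath, function() {
    cohort <- needCohort()
    env$profiles <- computeProfiles(
      cohort, horizon = config$controllability$horizon,
      convention = config$controllability$convention,
      negative = config$fc$negative)
    prof <- data.frame(
      region_id = regionTable(cohort@parcellation)$region_id,
      do.call(cbind, lapply(
        list(average_ctrl = averageCtrl(env$profiles),
             modal_ctrl = modalCtrl(env$profiles),
             activation_energy = activationEnergyAssay(env$profiles)),
        function(m) signif(rowMeans(m), 8))))
    write.table(prof, profilesPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeProfiles(env$profiles, file.path(outDir, "profiles"))
  })

  needProfiles <- function() {
    if (is.null(env$profiles))
      env$profiles <- computeProfiles(
        needCohort(), horizon = config$controllability$horizon,
        convention = config$controllability$convention,
        negative = config$fc$negative)
    env$profiles
  }

  runStage("aggregate", aggPath, function() {
    env$agg <- aggregateMetrics(needProfiles())
    write.table(env$agg, aggPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  })

  runStage("phenotype", phenoPath, function() {
    env$pheno <- cohortPhenotypes(needCohort()@manifest)
    write.csv(env$pheno, phenoPath, row.names = FALSE)
  })

  needTables <- function() {
    if (is.null(env$agg)) {
      if (file.exists(aggPath))
        env$agg <- read.delim(aggPath, stringsAsFactors = FALSE)
      else { env$agg <- aggregateMetrics(needProfiles()) }
    }
    if (is.null(env$pheno)) {
      if (file.exists(phenoPath))
        env$pheno <- read.csv(phenoPath, stringsAsFactors = FALSE)
      else env$pheno <- cohortPhenotypes(needCohort()@manifest)
    }
    invisible(NULL)
  }

  runStage("compare", compPath, function() {
    needTables()
    cohort <- needCohort()
    comp <- runGroupComparisons(env$agg, cohort@manifest,
                                status = env$pheno$status,
                                nPerm = config$stats$n_perm,
                                seed = config$seed,
                                alpha = config$stats$alpha)
    env$comparisons <- comp
    write.table(comp, compPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  })

  runStage("classify", clsPath, function() {
    needTables()
    cohort <- needCohort()
    cls <- runClassification(env$agg, cohort@manifest,
                             status = env$pheno$status,
                             k = config$classification$k,
                             repeats = config$classification$repeats,
                             cost = config$classification$cost,
                             seed = config$seed)
    env$classification <- cls
    write.table(cls, clsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  })

  if (is.null(env$comparisons) && file.exists(compPath))
    env$comparisons <- read.delim(compPath, stringsAsFactors = FALSE)
  if (is.null(env$classification) && file.exists(clsPath))
    env$classification <- read.delim(clsPath, stringsAsFactors = FALSE)
  invisible(list(manifest = runManifest,
                 comparisons = env$comparisons,
                 classification = env$classification))
}
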