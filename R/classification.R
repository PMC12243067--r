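#' Area under the ROC curve
#'
#' Mann-Whitney form: the probability that a random positive outscores a
#' random negative, with ties counted one half.
#'
#' @param scores numeric decision scores.
#' @param labels binary labels (1/TRUE = positive class).
#' @return Scalar in \eqn{[0, 1]}.
#' @export
rocAUC <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix performance metrics
#'
#' Precision, accuracy, sensitivity and specificity from binary predictions.
#' Precision with no positive predictions and sensitivity/specificity with
#' an absent class are returned as \code{NA}.
#'
#' @param predicted,labels binary vectors of equal length (1/TRUE =
#'   positive).
#' @return Named numeric vector.
#' @export
confusionMetrics <- function(predicted, labels) {
  predicted <- as.logical(predicted); labels <- as.logical(labels)
  if (length(predicted) != length(labels))
    stop("length mismatch", call. = FALSE)
  tp <- sum(predicted & labels); fp <- sum(predicted & !labels)
  tn <- sum(!predicted & !labels); fn <- sum(!predicted & labels)
  c(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    accuracy = (tp + tn) / length(labels),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

## Stratified fold assignment: shuffles within class, deals folds round-robin.
stratifiedFolds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Repeated stratified cross-validated linear SVM
#'
#' Stratified k-fold cross-validation repeated \code{repeats} times. Within
#' each training fold, features are standardized using training-fold
#' statistics only; a linear support vector machine (cost \code{C}) is
#' fitted and held-out subjects are scored with decision values (for AUC)
#' and signed predictions (for the confusion metrics). Metrics are reported
#' as mean and SD over all fold-repeats.
#'
#' @param X subjects-by-features numeric matrix (no missing values).
#' @param labels binary labels (logical or coercible; \code{TRUE} =
#'   positive class).
#' @param k folds (default 5).
#' @param repeats repetitions (default 100).
#' @param cost SVM regularization parameter (default 1).
#' @param classWeights \code{"balanced"} (default) weights classes inversely
#'   to their training-fold frequencies; \code{"none"} fits unweighted. With
#'   markedly imbalanced groups the unweighted linear SVM collapses onto the
#'   majority class with a sign-unstable separating direction, so balancing
#'   is the default.
#' @param seed integer seed for the fold shuffling.
#' @return List with \code{mean} and \code{sd} (named vectors over
#'   \code{auc}, \code{precision}, \code{accuracy}, \code{sensitivity},
#'   \code{specificity}), \code{folds} (per-fold metric matrix) and the
#'   \code{cv} configuration.
#' @export
repeatedCvSvm <- function(X, labels, k = 5L, repeats = 100L, cost = 1,
                          classWeights = c("balanced", "none"),
                          seed = 1L) {
  classWeights <- match.arg(classWeights)
  X <- as.matrix(X)
  labels <- as.logical(labels)
  if (anyNA(X) || anyNA(labels)) stop("missing values", call. = FALSE)
  if (min(table(labels)) < k)
    stop("smallest class has fewer members than folds; use smaller k",
         call. = FALSE)
  y <- factor(ifelse(labels, "pos", "neg"), levels = c("neg", "pos"))
  metricNames <- c("auc", "precision", "accuracy", "sensitivity",
                   "specificity")
  res <- withSeed(seed, {
    out <- matrix(NA_real_, repeats * k, length(metricNames),
                  dimnames = list(NULL, metricNames))
    row <- 0L
    for (r in seq_len(repeats)) {
      fold <- stratifiedFolds(labels, k)
      for (f in seq_len(k)) {
        row <- row + 1L
        tr <- fold != f; te <- !tr
        mu <- colMeans(X[tr, , drop = FALSE])
        sdv <- apply(X[tr, , drop = FALSE], 2, sd)
        sdv[sdv == 0] <- 1
        Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
        Xte <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sdv, "/")
        cw <- if (classWeights == "balanced") {
          tb <- table(y[tr])
          setNames(as.numeric(sum(tb) / (2 * tb)), names(tb))
        } else NULL
        fit <- e1071::svm(Xtr, y[tr], kernel = "linear", cost = cost,
                          class.weights = cw, scale = FALSE)
        pr <- predict(fit, Xte, decision.values = TRUE)
        dv <- attr(pr, "decision.values")
        ## decision values are oriented toward the first class in the
        ## column name "A/B": positive value votes for class A
        firstClass <- strsplit(colnames(dv)[1], "/")[[1]][1]
        score <- if (firstClass == "pos") dv[, 1] else -dv[, 1]
        out[row, "auc"] <- rocAUC(score, labels[te])
        out[row, -1] <- confusionMetrics(pr == "pos", labels[te])
      }
    }
    out
  })
  list(mean = colMeans(res, na.rm = TRUE),
       sd = apply(res, 2, sd, na.rm = TRUE),
       folds = res,
       cv = list(k = k, repeats = repeats, cost = cost, seed = seed))
}

#' Predictive feature sets for the classification tasks
#'
#' Builds the three feature sets of a task: \code{controllability}
#' (thalamic average, modal and energy aggregates), \code{volume}
#' (thalamic volume) and \code{combination} (their column concatenation).
#'
#' @param aggregated long-format table from \code{\link{aggregateMetrics}}.
#' @param manifest cohort manifest with \code{thalamic_volume}.
#' @return Named list of subjects-by-features matrices with subject ids as
#'   row names.
#' @export
buildFeatureSets <- function(aggregated, manifest) {
  thal <- aggregated[aggregated$level == "nucleus" &
                     aggregated$unit == "thalamus", , drop = FALSE]
  if (!nrow(thal)) stop("no thalamus aggregates found", call. = FALSE)
  ids <- manifest$subject_id
  ctrl <- sapply(c("average", "modal", "energy"), function(m) {
    v <- thal$value[thal$metric == m][match(ids,
           thal$subject_id[thal$metric == m])]
    if (anyNA(v)) stop("missing thalamic ", m, " aggregate", call. = FALSE)
    v
  })
  rownames(ctrl) <- ids
  colnames(ctrl) <- c("thalamic_average", "thalamic_modal",
                      "thalamic_energy")
  if (!"thalamic_volume" %in% names(manifest))
    stop("manifest lacks thalamic_volume", call. = FALSE)
  vol <- matrix(manifest$thalamic_volume, ncol = 1,
                dimnames = list(ids, "thalamic_volume"))
  list(controllability = ctrl, volume = vol,
       combination = cbind(ctrl, vol))
}

#' Linear SVM classification over the task panel
#'
#' Runs the repeated cross-validated linear SVM for the three tasks
#' (MS vs HC; CIMS vs CPMS; EDSS < 4 vs >= 4) and the three feature sets,
#' reporting the mean (SD) metric panel.
#'
#' @param aggregated aggregated metrics table.
#' @param manifest cohort manifest.
#' @param status per-subject status labels (defaults to
#'   \code{manifest$group}).
#' @param tasks subset of tasks to run.
#' @param k,repeats,cost,seed cross-validation settings.
#' @return \code{data.frame} with one row per task x feature set x metric,
#'   columns \code{mean} and \code{sd}.
#' @export
runClassification <- function(aggregated, manifest, status = NULL,
                              tasks = c("MS_vs_HC", "CIMS_vs_CPMS",
                                        "EDSS_lt4_vs_ge4"),
                              k = 5L, repeats = 100L, cost = 1, seed = 1L) {
  tasks <- match.arg(tasks, several.ok = TRUE)
  if (is.null(status)) status <- manifest$group
  fs <- buildFeatureSets(aggregated, manifest)
  stratum <- edssStratify(manifest$edss)
  taskLabels <- list(
    MS_vs_HC = list(keep = rep(TRUE, nrow(manifest)),
                    pos = status != "HC"),
    CIMS_vs_CPMS = list(keep = status %in% c("CPMS", "CIMS"),
                        pos = status == "CIMS"),
    EDSS_lt4_vs_ge4 = list(keep = stratum %in% c("lt4", "ge4"),
                           pos = stratum == "ge4"))
  seeds <- deriveSeeds(seed, length(tasks) * length(fs))
  out <- list(); i <- 0L
  for (task in tasks) {
    tl <- taskLabels[[task]]
    for (set in names(fs)) {
      i <- i + 1L
      rep_ <- repeatedCvSvm(fs[[set]][tl$keep, , drop = FALSE],
                            tl$pos[tl$keep], k = k, repeats = repeats,
                            cost = cost, seed = seeds[i])
      out[[i]] <- data.frame(
        task = task, feature_set = set,
        metric = names(rep_$mean), mean = as.numeric(rep_$mean),
        sd = as.numeric(rep_$sd), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
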