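#' Pearson functional connectivity matrix
#'
#' Pairwise Pearson correlation between regional time series. The diagonal is
#' stored as zero (self-connections are excluded before stabilization) and
#' symmetry is enforced by construction. Negative correlations are retained
#' by default; \code{negative = "absolute"} takes absolute values and
#' \code{negative = "zero"} clips them at zero, making the choice auditable.
#'
#' @param ts regions-by-timepoints matrix with at least two timepoints.
#' @param negative handling of negative correlations.
#' @return Symmetric correlation matrix with zero diagonal, entries in
#'   \eqn{[-1, 1]}.
#' @export
pearsonFC <- function(ts, negative = c("keep", "absolute", "zero")) {
  negative <- match.arg(negative)
  stopifnot(is.matrix(ts))
  if (ncol(ts) < 2) stop("need at least 2 timepoints", call. = FALSE)
  v <- apply(ts, 1, stats::var)
  if (any(v <= 0)) {
    bad <- which(v <= 0)
    stop("zero temporal variance in region(s): ",
         paste(head(bad, 10), collapse = ", "), call. = FALSE)
  }
  C <- cor(t(ts))
  C <- (C + t(C)) / 2
  diag(C) <- 0
  C <- switch(negative,
              keep = C,
              absolute = abs(C),
              zero = pmax(C, 0))
  dimnames(C) <- list(rownames(ts), rownames(ts))
  C
}

#' Write / read a functional connectivity matrix as TSV
#'
#' The file carries region identifiers as a header row and first column.
#'
#' @param fc square matrix with row names.
#' @param path file path.
#' @return \code{path} (write) or the matrix (read).
#' @export
writeFC <- function(fc, path) {
  df <- data.frame(region = rownames(fc), signif(fc, 8), check.names = FALSE)
  colnames(df) <- c("region", rownames(fc))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFC
#' @export
readFC <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
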