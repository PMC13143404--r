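# Readers and writers: Matrix Market and delimited text for responses and
# covariates, full-precision delimited output for parameter blocks, JSON
# manifests, and model-based imputation of missing entries.

#' Read a response matrix and covariates into a GMFData object
#'
#' The response may be a Matrix Market coordinate file (integer or real) or
#' a delimited text matrix (comma-separated, header row, '.' decimal).
#' Missing (\code{NA}/empty) cells become unobserved entries of the mask.
#' Covariate files are delimited with a header; an optional \code{id}
#' column is cross-checked against the corresponding dimension names of
#' the response when both are present.
#'
#' @param file path to the response matrix.
#' @param format \code{"auto"} (by extension), \code{"mm"} (Matrix Market)
#'   or \code{"csv"}.
#' @param orientation \code{"cellsByGenes"} (rows are cells, the internal
#'   layout) or \code{"genesByCells"} (transposed on read, the common
#'   layout of expression matrices).
#' @param rowCovariates,colCovariates optional paths to delimited covariate
#'   tables (cells and genes respectively).
#' @param ... passed to \code{\link{gmfData}} (weights, offset, mask).
#' @return a \code{\link{GMFData}}.
#' @export
readGMFData <- function(file, format = c("auto", "mm", "csv"),
                        orientation = c("cellsByGenes", "genesByCells"),
                        rowCovariates = NULL, colCovariates = NULL, ...) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(file)) stopf("file '%s' does not exist", file)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", file, ignore.case = TRUE)) "mm" else "csv"
  Y <- if (format == "mm") {
    as.matrix(Matrix::readMM(file))
  } else {
    as.matrix(utils::read.csv(file, header = TRUE, check.names = FALSE))
  }
  storage.mode(Y) <- "double"
  if (orientation == "genesByCells") Y <- t(Y)
  X <- if (!is.null(rowCovariates))
    .readCovariates(rowCovariates, nrow(Y), "row") else NULL
  Z <- if (!is.null(colCovariates))
    .readCovariates(colCovariates, ncol(Y), "column") else NULL
  gmfData(Y, X = X, Z = Z, ...)
}

.readCovariates <- function(file, expected, what) {
  if (!file.exists(file)) stopf("file '%s' does not exist", file)
  tab <- utils::read.csv(file, header = TRUE, check.names = FALSE)
  if ("id" %in% names(tab)) {
    ids <- tab[["id"]]
    if (anyDuplicated(ids)) stopf("duplicate ids in '%s'", file)
    tab <- tab[names(tab) != "id"]
  }
  if (nrow(tab) != expected)
    stopf("%s covariates have %d rows but the response implies %d",
          what, nrow(tab), expected)
  M <- as.matrix(tab)
  storage.mode(M) <- "double"
  if (any(!is.finite(M))) stopf("non-finite cells in covariate file '%s'", file)
  M
}

#' Write fitted parameter blocks and the run manifest
#'
#' Writes \code{U.csv}, \code{V.csv}, \code{B.csv} and \code{Gamma.csv}
#' (full \code{\%.17g} precision, so a write/read round trip reproduces
#' the doubles bitwise) plus \code{manifest.json} with the complete
#' configuration echo.
#'
#' @param fit a \code{\link{GMFFit}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeGMFFit <- function(fit, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    writeMatrixCSV(fit@params@U, file.path(dir, "U.csv")),
    writeMatrixCSV(fit@params@V, file.path(dir, "V.csv")),
    writeMatrixCSV(fit@params@B, file.path(dir, "B.csv")),
    writeMatrixCSV(fit@params@Gamma, file.path(dir, "Gamma.csv")))
  man <- file.path(dir, "manifest.json")
  jsonlite::write_json(fit@manifest, man, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(paths, man))
}

#' Full-precision delimited matrix output
#'
#' @param x numeric matrix.
#' @param file destination path.
#' @return invisibly, \code{file}.
#' @export
writeMatrixCSV <- function(x, file) {
  x <- as.matrix(x)
  chr <- matrix(sprintf("%.17g", x), nrow(x), ncol(x))
  cols <- colnames(x)
  if (is.null(cols)) cols <- paste0("c", seq_len(ncol(x)))
  utils::write.table(chr, file, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = cols)
  invisible(file)
}

#' Read a matrix written by \code{writeMatrixCSV}
#'
#' @param file path.
#' @return numeric matrix.
#' @export
readMatrixCSV <- function(file) {
  M <- as.matrix(utils::read.csv(file, header = TRUE, check.names = FALSE))
  storage.mode(M) <- "double"
  M
}

#' Model-based completion of a partially observed matrix
#'
#' Returns the response matrix with every unobserved entry replaced by the
#' fitted mean \eqn{g^{-1}(\hat\eta_{ij})}; observed values are untouched.
#'
#' @param data a \code{\link{GMFData}}.
#' @param params fitted \code{\link{GMFParams}} (or a \code{\link{GMFFit}}).
#' @param family a \code{\link{GMFFamily}}; taken from the fit when a
#'   \code{\link{GMFFit}} is supplied.
#' @return completed numeric matrix.
#' @export
imputeValues <- function(data, params, family = NULL) {
  if (methods::is(params, "GMFFit")) {
    if (is.null(family)) family <- params@family
    params <- params@params
  }
  if (is.null(family)) stopf("a family is required")
  mu <- predictMean(data, params, family)
  out <- data@Y
  out[!data@mask] <- mu[!data@mask]
  out
}
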