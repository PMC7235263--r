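detect_sep <- function(path) {
  l1 <- readLines(path, n = 1L)
  if (grepl("\t", l1)) "\t" else ","
}

#' Read / write long-format phenotype tables
#'
#' Delimited text (comma or tab, auto-detected on read) with header columns
#' `genotype, trial, rep, subblock, timepoint, env, trait, value`; missing
#' values are empty fields.
#'
#' @param path file path.
#' @param data phenotype data frame; absent design columns are written empty.
#' @param sep field separator for writing (default comma).
#' @return `read_phenotypes`: a validated data frame. `write_phenotypes`:
#'   `path`, invisibly.
#' @export
read_phenotypes <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", na.strings = "",
                          stringsAsFactors = FALSE)
  if ("value" %in% names(df)) df$value <- as.numeric(df$value)
  validate_phenotypes(df)
  df
}

#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(data, path, sep = ",") {
  cols <- c("genotype", "trial", "rep", "subblock", "timepoint", "env",
            "trait", "value")
  out <- data.frame(row.names = seq_len(nrow(data)))
  for (cl in cols) out[[cl]] <- if (cl %in% names(data)) data[[cl]] else NA
  utils::write.table(out, path, sep = sep, quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Read / write labeled square covariance matrices
#'
#' Tab-delimited with a band-label header row and a label first column.
#'
#' @param M square numeric matrix with dimnames.
#' @param path file path.
#' @return `read_cov_matrix`: labeled matrix; `write_cov_matrix`: `path`,
#'   invisibly.
#' @export
write_cov_matrix <- function(M, path) {
  M <- as.matrix(M)
  if (is.null(rownames(M))) rownames(M) <- colnames(M) %||%
      paste0("b", seq_len(nrow(M)))
  if (is.null(colnames(M))) colnames(M) <- rownames(M)
  df <- data.frame(label = rownames(M), M, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cov_matrix
#' @export
read_cov_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df[[1]]
  storage.mode(M) <- "double"
  M
}

#' Read / write wide band (reflectance) matrices
#'
#' Tab-delimited, one row per plot, one column per band; band labels of the
#' form `wl<wavelength>` carry the wavelength metadata.
#'
#' @param X n x p matrix.
#' @param wavelength length-p wavelengths in nm (stored in the header).
#' @param path file path.
#' @return `read_band_matrix`: list with `X` and `wavelength`;
#'   `write_band_matrix`: `path`, invisibly.
#' @export
write_band_matrix <- function(X, wavelength, path) {
  X <- as.matrix(X)
  stopifnot(length(wavelength) == ncol(X))
  colnames(X) <- paste0("wl", format(wavelength, trim = TRUE, digits = 10))
  utils::write.table(X, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_band_matrix
#' @export
read_band_matrix <- function(path) {
  X <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  wl <- as.numeric(sub("^wl", "", colnames(X)))
  if (anyNA(wl)) stop("band labels must be of the form wl<wavelength>")
  list(X = X, wavelength = wl)
}

#' Serialize index coefficients as sparse JSON
#'
#' Coefficients are stored sparsely (label -> value for nonzero entries only)
#' together with the regularization metadata, one record per solution
#' (a path writes one record per penalty).
#'
#' @param coef a `"psi"` or `"psi_path"` object.
#' @param path file path.
#' @return `read_index_json`: list of solution records; `write_index_json`:
#'   `path`, invisibly.
#' @export
write_index_json <- function(coef, path) {
  one <- function(beta, method, lambda, alpha, q, labels) {
    nz <- which(beta != 0)
    if (is.null(labels)) labels <- paste0("b", seq_along(beta))
    list(method = method, lambda = lambda, alpha = alpha, q = q,
         p = length(beta),
         coefficients = as.list(stats::setNames(beta[nz], labels[nz])))
  }
  recs <- if (inherits(coef, "psi_path")) {
    lapply(seq_along(coef$lambda), function(i)
      one(coef$beta[, i], coef$method, coef$lambda[i], coef$alpha,
          NA_integer_, coef$labels))
  } else {
    list(one(coef$beta, coef$method, coef$lambda, coef$alpha, coef$q,
             coef$labels))
  }
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_index_json
#' @export
read_index_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Write evaluation results as JSON records
#'
#' @param results a list (e.g. per-partition evaluation lists or aggregate
#'   summaries).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to re-execute a run: the configuration, the
#' seed, package and R versions, and md5 digests of the input files.
#'
#' @param path manifest file path.
#' @param config named list echoing the run configuration.
#' @param seed integer seed used for the run.
#' @param inputs character vector of input file paths to digest.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, config = list(), seed = NA_integer_,
                           inputs = character(0)) {
  digests <- if (length(inputs)) {
    missing_in <- inputs[!file.exists(inputs)]
    if (length(missing_in))
      stop("manifest input does not exist: ", missing_in[1])
    stats::setNames(as.list(tools::md5sum(inputs)), basename(inputs))
  } else list()
  man <- list(config = config, seed = seed,
              package = as.character(utils::packageVersion("psindex")),
              r_version = paste(R.version$major, R.version$minor, sep = "."),
              inputs = digests)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(man)
}
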