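#' Assemble a factor panel
#'
#' Bundles a response panel `Y` (one row per time point, one column per
#' variable) with an observed-factor panel `F` (same rows, one column per
#' factor) into a validated container used by all fitting and testing
#' functions. The model is `y_t = B f_t + u_t`: each variable loads linearly
#' on the common factors, and the idiosyncratic errors may be correlated
#' across variables.
#'
#' @param Y Numeric matrix or data frame, `T` rows (time) by `p` columns
#'   (variables).
#' @param F Numeric matrix or data frame, `T` rows by `K` columns (observed
#'   factors). `K` must be smaller than `T`.
#' @return An object of class `factor_panel` with elements `Y`, `F`,
#'   `n_time`, `p` and `K`.
#' @examples
#' sim <- simulate_panel(n_time = 50, p = 5, model = 2, seed = 1)
#' panel <- sim$panel
#' panel
#' @export
factor_panel <- function(Y, F) {
  Y <- as.matrix(Y)
  Fm <- as.matrix(F)
  storage.mode(Y) <- "double"
  storage.mode(Fm) <- "double"
  if (!all(is.finite(Y)) || !all(is.finite(Fm))) {
    stop("Y and F must be numeric with no missing or infinite values")
  }
  if (nrow(Y) != nrow(Fm)) {
    stop("Y and F must have the same number of rows (time points); got ",
         nrow(Y), " and ", nrow(Fm))
  }
  if (ncol(Fm) >= nrow(Fm)) {
    stop("number of factors K must be smaller than the sample size T")
  }
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  if (is.null(colnames(Fm))) colnames(Fm) <- paste0("f", seq_len(ncol(Fm)))
  structure(
    list(Y = Y, F = Fm,
         n_time = nrow(Y), p = ncol(Y), K = ncol(Fm)),
    class = "factor_panel"
  )
}

#' @export
print.factor_panel <- function(x, ...) {
  cat("<factor_panel> T =", x$n_time, "time points, p =", x$p,
      "variables, K =", x$K, "factors\n")
  invisible(x)
}

#' Read / write a factor panel as delimited text
#'
#' The on-disk format is two delimited files with a header row of column
#' names and one row per time point, aligned by row order.
#'
#' @param y_file,f_file Paths of the response and factor files.
#' @param delim Field delimiter (default comma).
#' @return `read_factor_panel()` returns a [factor_panel];
#'   `write_factor_panel()` invisibly returns the panel.
#' @export
read_factor_panel <- function(y_file, f_file, delim = ",") {
  Y <- readr::read_delim(y_file, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  Fm <- readr::read_delim(f_file, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  factor_panel(Y, Fm)
}

#' @rdname read_factor_panel
#' @param panel A [factor_panel].
#' @export
write_factor_panel <- function(panel, y_file, f_file, delim = ",") {
  stopifnot(inherits(panel, "factor_panel"))
  readr::write_delim(tibble::as_tibble(panel$Y), y_file, delim = delim)
  readr::write_delim(tibble::as_tibble(panel$F), f_file, delim = delim)
  invisible(panel)
}

#' Center the responses and standardize the factors
#'
#' Subtracts the column mean from every response series and affinely
#' transforms every factor series to mean zero and unit sample standard
#' deviation. This is the conventional pre-processing before testing
#' loadings on return panels; the model itself carries no intercept, so
#' centering absorbs any level shift.
#'
#' @param panel A [factor_panel].
#' @return A new `factor_panel`; the input is not modified.
#' @export
standardize_panel <- function(panel) {
  stopifnot(inherits(panel, "factor_panel"))
  if (panel$n_time < 2) stop("standardization needs at least two time points")
  Y <- scale(panel$Y, center = TRUE, scale = FALSE)
  sds <- apply(panel$F, 2L, sd)
  if (any(sds < sqrt(.Machine$double.eps))) {
    stop("constant factor column (zero variance): ",
         paste(colnames(panel$F)[sds < sqrt(.Machine$double.eps)],
               collapse = ", "))
  }
  Fm <- scale(panel$F, center = TRUE, scale = sds)
  attr(Y, "scaled:center") <- NULL
  attr(Fm, "scaled:center") <- NULL
  attr(Fm, "scaled:scale") <- NULL
  factor_panel(Y, Fm)
}
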