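#' Ordinary least squares via minimum-norm SVD solve
#'
#' Fits y ~ X by ordinary least squares using an economy singular value
#' decomposition.  Rank deficiency (e.g. a predictor collinear with earlier
#' ones) is handled by the minimum-norm solution: singular values below
#' `max(dim(X)) * eps * d[1]` are treated as zero, so collinear columns get
#' zero extra coefficient mass and the fitted values are unaffected.
#'
#' The mean squared error is defined as RSS / (n - 1) — the same n - 1
#' denominator as the sample variance of y — so that stagewise MSE drops
#' convert directly into percentages of variance explained.
#'
#' @param y numeric response vector (windowed read counts).
#' @param X numeric matrix or data frame of predictor columns (no intercept
#'   column; one is added unless `intercept = FALSE`).
#' @param intercept logical; include an intercept (default TRUE).
#' @return list with components `coefficients` (intercept first), `fitted`,
#'   `residuals`, `rss`, `mse` (= RSS/(n-1)), `rank`, `se` (classical
#'   standard errors, NA for null directions), `se_hc1`
#'   (heteroskedasticity-robust HC1 standard errors), `n`.
#' @export
fit_ols <- function(y, X, intercept = TRUE) {
  y <- as.numeric(y)
  n <- length(y)
  X <- if (is.null(X)) matrix(numeric(0), nrow = n, ncol = 0) else as.matrix(X)
  if (nrow(X) != n) stop("y and X have different numbers of rows")
  Xf <- if (intercept) cbind(`(Intercept)` = 1, X) else X
  p <- ncol(Xf)
  if (n <= p) stop("need more observations than coefficients (n = ", n,
                   ", p = ", p, ")")
  if (stats::var(y) == 0) stop("degenerate regressand: var(y) = 0")

  sv <- svd(Xf)
  tol <- max(dim(Xf)) * .Machine$double.eps * sv$d[1]
  keep <- sv$d > tol
  rank <- sum(keep)
  uty <- crossprod(sv$u[, keep, drop = FALSE], y)
  beta <- sv$v[, keep, drop = FALSE] %*% (uty / sv$d[keep])
  beta <- drop(beta)
  names(beta) <- colnames(Xf)
  fitted <- drop(Xf %*% beta)
  res <- y - fitted
  rss <- sum(res^2)

  # (X'X)^+ for standard errors, via the same SVD
  xtx_pinv <- sv$v[, keep, drop = FALSE] %*%
    (t(sv$v[, keep, drop = FALSE]) / sv$d[keep]^2)
  sigma2 <- rss / max(n - rank, 1)
  se <- sqrt(pmax(diag(xtx_pinv) * sigma2, 0))
  # HC1: meat = X' diag(e^2) X, scaled n/(n - rank)
  Xe <- Xf * res
  meat <- crossprod(Xe)
  vc_hc1 <- xtx_pinv %*% meat %*% xtx_pinv * n / max(n - rank, 1)
  se_hc1 <- sqrt(pmax(diag(vc_hc1), 0))
  names(se) <- names(se_hc1) <- colnames(Xf)

  list(coefficients = beta, fitted = fitted, residuals = res,
       rss = rss, mse = rss / (n - 1), rank = rank,
       se = se, se_hc1 = se_hc1, n = n, intercept = intercept)
}

#' Staged regression decomposition of a windowed signal
#'
#' Grows an ordinary-least-squares model one predictor at a time in a fixed
#' priority order and attributes to each predictor its marginal explanatory
#' gain.  Stage 0 is the intercept-only model, whose MSE equals the sample
#' variance of y; stage i adds predictor i and refits all coefficients.  The
#' percentage of variance (POV) explained by the predictor added at stage i
#' is
#'
#'   POV_i = 100 * (MSE_{i-1} - MSE_i) / var(y)
#'
#' with MSE_i = RSS_i / (n - 1) and var(y) the (n - 1)-denominator sample
#' variance.  The POVs telescope: their sum equals 100 * R^2 of the full
#' model.  The default predictor order is mappability, GC content, DNaseI
#' hypersensitivity (chromatin accessibility), input-DNA control, IgG
#' control — fixed a priori from least to most experiment-specific.
#'
#' @param y numeric vector of windowed read counts (the regressand).
#' @param predictors named list of numeric vectors (or a data frame), one
#'   per predictor, all aligned to the same window grid, in the stage order.
#' @param width optional window width in bp, recorded in the result.
#' @return a `decomposition` object: list with `predictors` (names in stage
#'   order), `stage_fits` (list of [fit_ols()] results, index 1 =
#'   intercept-only stage 0), `mse` (length K+1, stage 0..K), `pov` (named,
#'   per predictor, percent), `total_pov` (percent, = 100 R^2), `var_y`,
#'   `n`, `width`, `fit` (the final-stage fit).
#' @export
staged_decompose <- function(y, predictors, width = NULL) {
  if (is.data.frame(predictors)) predictors <- as.list(predictors)
  stopifnot(is.list(predictors), length(predictors) >= 1)
  if (is.null(names(predictors)) || any(names(predictors) == ""))
    names(predictors) <- paste0("x", seq_along(predictors))
  y <- as.numeric(y)
  n <- length(y)
  lens <- vapply(predictors, length, integer(1))
  if (any(lens != n)) stop("all predictors must have the same length as y")
  K <- length(predictors)
  var_y <- stats::var(y)
  if (!is.finite(var_y) || var_y == 0) stop("degenerate regressand: var(y) = 0")

  X <- do.call(cbind, lapply(predictors, as.numeric))
  colnames(X) <- names(predictors)

  stage_fits <- vector("list", K + 1L)
  stage_fits[[1]] <- fit_ols(y, NULL, intercept = TRUE)  # stage 0
  mse <- numeric(K + 1L)
  mse[1] <- stage_fits[[1]]$mse
  for (i in seq_len(K)) {
    stage_fits[[i + 1L]] <- fit_ols(y, X[, seq_len(i), drop = FALSE])
    mse[i + 1L] <- stage_fits[[i + 1L]]$mse
  }

  pov <- 100 * (mse[seq_len(K)] - mse[seq_len(K) + 1L]) / var_y
  names(pov) <- names(predictors)
  neg <- pov < 0
  if (any(pov < -1e-8))
    stop("internal consistency failure: POV < -1e-8 for ",
         paste(names(pov)[pov < -1e-8], collapse = ", "))
  pov[neg] <- 0

  structure(list(predictors = names(predictors),
                 stage_fits = stage_fits,
                 mse = mse,
                 pov = pov,
                 total_pov = 100 * (mse[1] - mse[K + 1L]) / var_y,
                 var_y = var_y,
                 n = n,
                 width = width,
                 fit = stage_fits[[K + 1L]]),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("Staged decomposition: n = %d windows%s\n", x$n,
              if (!is.null(x$width)) sprintf(" of %d bp", x$width) else ""))
  tab <- data.frame(predictor = x$predictors,
                    POV = sprintf("%.2f", x$pov))
  print(tab, row.names = FALSE)
  cat(sprintf("total POV = %.2f%% (var(y) = %.4g)\n", x$total_pov, x$var_y))
  invisible(x)
}

#' Predict background signal from a fitted decomposition
#'
#' Applies the final-stage coefficients to new feature rows, giving the
#' expected read count attributable to the non-binding background.
#' Predictions are not clamped and may be negative; `round = TRUE` rounds to
#' the nearest integer for display alongside true (integer) counts.
#'
#' @param fit a [staged_decompose()] result.
#' @param features matrix or data frame whose columns are the predictors in
#'   the training order (no intercept column).
#' @param round logical; round predictions to the nearest integer.
#' @return numeric vector of predicted counts.
#' @export
predict_background <- function(fit, features, round = FALSE) {
  stopifnot(inherits(fit, "decomposition"))
  X <- as.matrix(features)
  K <- length(fit$predictors)
  if (ncol(X) != K)
    stop(sprintf("feature column count %d does not match %d trained predictors",
                 ncol(X), K))
  beta <- fit$fit$coefficients
  yhat <- drop(cbind(1, X) %*% beta)
  if (round) round(yhat) else yhat
}

#' Multiscale staged decomposition
#'
#' Re-runs the staged decomposition over a range of window widths 2^k + 1,
#' re-tiling the genome and re-counting every read set and track from the
#' base-pair level at each scale (grids at different scales do not nest, so
#' no aggregation shortcut is taken).
#'
#' @param chip a deduplicated [read_set()] (the regressand).
#' @param tracks named list with elements `mappability` and `gc`, each a
#'   [binary_track()].
#' @param controls named list of deduplicated [read_set()]s in stage order
#'   after the tracks (default semantics: `dnase`, `idna`, `igg`).
#' @param sizes a [chrom_sizes()] object.
#' @param k_range integer vector of exponents; widths are 2^k + 1
#'   (default 7:20).
#' @param exclude chromosomes to exclude (default `"chrY"`).
#' @return a `multiscale` object: list of [staged_decompose()] results named
#'   by width, widths strictly increasing.
#' @export
multiscale_decompose <- function(chip, tracks, controls, sizes,
                                 k_range = 7:20, exclude = "chrY") {
  stopifnot(length(k_range) >= 1)
  k_range <- sort(unique(as.integer(k_range)))
  out <- list()
  for (k in k_range) {
    width <- 2L^k + 1L
    grid <- make_window_grid(sizes, width, exclude = exclude)
    if (n_windows(grid) == 0L)
      stop(sprintf("width %d exceeds every chromosome length", width))
    preds <- c(lapply(tracks, track_fraction, grid = grid),
               lapply(controls, count_reads, grid = grid))
    y <- count_reads(chip, grid)
    out[[as.character(width)]] <- staged_decompose(y, preds, width = width)
  }
  structure(out, class = "multiscale")
}

#' @export
print.multiscale <- function(x, ...) {
  cat("Multiscale decomposition over", length(x), "window width(s)\n")
  print(pov_table(x), row.names = FALSE)
  invisible(x)
}

#' Long-format POV table
#'
#' @param x a `decomposition` or `multiscale` object.
#' @param dataset optional dataset label column.
#' @return data frame with columns `dataset`, `width`, `predictor`, `pov`,
#'   `total_pov`.
#' @export
pov_table <- function(x, dataset = NA_character_) {
  if (inherits(x, "decomposition")) x <- list(x)
  do.call(rbind, lapply(x, function(d) {
    data.frame(dataset = dataset,
               width = if (is.null(d$width)) NA_integer_ else d$width,
               predictor = d$predictors,
               pov = unname(d$pov),
               total_pov = d$total_pov,
               stringsAsFactors = FALSE)
  }))
}

#' Serialize a fitted decomposition to JSON
#'
#' Writes predictor order, per-stage coefficients and MSEs, var(y), window
#' width and n, plus optional input-file hashes, as a JSON document.
#'
#' @param fit a [staged_decompose()] result.
#' @param path output path.
#' @param input_files optional character vector of paths whose md5 hashes
#'   are recorded.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(fit, path, input_files = NULL) {
  stopifnot(inherits(fit, "decomposition"))
  doc <- list(predictors = fit$predictors,
              stages = lapply(fit$stage_fits, function(s)
                list(coefficients = as.list(s$coefficients), mse = s$mse)),
              pov = as.list(fit$pov),
              total_pov = fit$total_pov,
              var_y = fit$var_y,
              n = fit$n,
              width = fit$width)
  if (!is.null(input_files))
    doc$input_md5 <- as.list(tools::md5sum(input_files))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read back a serialized decomposition model
#'
#' Restores enough of a [write_model_json()] document to call
#' [predict_background()]: predictor order, final coefficients, width.
#'
#' @param path path to the JSON document.
#' @return a `decomposition` object (without per-stage fitted values).
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  K <- length(doc$predictors)
  stage_fits <- lapply(doc$stages, function(s)
    list(coefficients = unlist(s$coefficients), mse = s$mse))
  structure(list(predictors = unlist(doc$predictors),
                 stage_fits = stage_fits,
                 mse = vapply(stage_fits, `[[`, numeric(1), "mse"),
                 pov = unlist(doc$pov),
                 total_pov = doc$total_pov,
                 input_md5 = doc$input_md5,
                 var_y = doc$var_y,
                 n = doc$n,
                 width = doc$width,
                 fit = stage_fits[[K + 1L]]),
            class = "decomposition")
}
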