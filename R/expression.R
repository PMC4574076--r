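#' TSS-centred windows
#'
#' Builds symmetric windows of `2h + 1` bp around transcription start sites.
#' The TSS of a BED row is its start for "+" rows and end - 1 for "-" rows
#' (so 1-bp rows and full gene intervals are both accepted).  Near-edge TSSs
#' are excluded and counted; TSSs of distinct genes landing on the same
#' (chrom, position) are collapsed into one window with the gene ids
#' concatenated.
#'
#' Expression at a TSS is measured as the number of CAGE 5'-tag reads in the
#' same window, countable with [count_in_intervals()].
#'
#' @param path path to a BED file of TSSs (>= 4 columns; strand in column 6
#'   if present, "+" assumed otherwise).
#' @param sizes a [chrom_sizes()] object.
#' @param h half-width in bp (default 64, 129-bp windows).
#' @return data frame with columns `chrom`, `tss`, `start`, `end`, `id`.
#' @export
tss_windows <- function(path, sizes, h = 64L) {
  stopifnot(inherits(sizes, "chrom_sizes"))
  h <- as.integer(h)
  tab <- read_bed_table(path, min_cols = 4L)
  strand <- if (length(tab) >= 6L) tab[[6]] else rep("+", length(tab[[1]]))
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "+"
  tss <- ifelse(strand == "+", tab[[2]], tab[[3]] - 1L)
  chrom <- tab[[1]]
  id <- tab[[4]]
  known <- chrom %in% names(sizes)
  chrom <- chrom[known]; tss <- tss[known]; id <- id[known]
  if (!length(chrom)) stop(path, ": no TSSs on known chromosomes")
  inb <- tss - h >= 0L & tss + h + 1L <= unname(sizes[chrom])
  if (any(!inb))
    message(sprintf("tss_windows: excluded %d near-edge TSS(s)", sum(!inb)))
  chrom <- chrom[inb]; tss <- tss[inb]; id <- id[inb]
  key <- paste(chrom, tss)
  if (anyDuplicated(key)) {
    id <- vapply(split(id, key)[unique(key)], paste, character(1),
                 collapse = ",")
    first <- !duplicated(key)
    chrom <- chrom[first]; tss <- tss[first]
  }
  o <- order(chrom, tss, method = "radix")
  data.frame(chrom = chrom[o], tss = tss[o],
             start = tss[o] - h, end = tss[o] + h + 1L,
             id = unname(id[o]), stringsAsFactors = FALSE)
}

fold_assignment <- function(n, folds, seed) {
  set.seed(seed)
  sample(rep(seq_len(folds), length.out = n))
}

#' Cross-validated linear prediction of expression
#'
#' Randomly partitions the TSSs into `folds` roughly equal groups, trains an
#' ordinary-least-squares model (with intercept) on all but one group, and
#' predicts the left-out group; repeats over all folds.  Reports both the
#' pooled out-of-fold Pearson correlation between truth and prediction (the
#' headline number) and the per-fold correlations, whose spread gives a 95%
#' t confidence interval.
#'
#' @param y numeric vector of expression counts (e.g. CAGE reads per TSS
#'   window).
#' @param X matrix or data frame of feature columns aligned to `y`.
#' @param folds number of CV folds (default 10).
#' @param seed integer seed for the fold assignment (mandatory; the same
#'   seed reproduces the same folds bit-for-bit).
#' @param label optional label for the feature set (defaults to the joined
#'   column names).
#' @return a `cv_result` list: `pooled_pcc`, `fold_pcc` (length `folds`),
#'   `ci` (95% CI of the mean fold PCC), `mean_fold_pcc`, `folds`, `seed`,
#'   `fold_id`, `prediction` (pooled out-of-fold predictions), `label`.
#' @export
cv_predict <- function(y, X, folds = 10L, seed, label = NULL) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (n < folds * (ncol(X) + 2L))
    stop("too few observations for ", folds, "-fold CV with ",
         ncol(X), " features")
  fold_id <- fold_assignment(n, folds, seed)
  pred <- numeric(n)
  fold_pcc <- numeric(folds)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    ytr <- y[!test]
    if (stats::var(ytr) == 0)
      stop("zero-variance expression in training fold ", f)
    fit <- fit_ols(ytr, X[!test, , drop = FALSE])
    ph <- drop(cbind(1, X[test, , drop = FALSE]) %*% fit$coefficients)
    pred[test] <- ph
    fold_pcc[f] <- if (stats::var(ph) > 0 && stats::var(y[test]) > 0)
      stats::cor(y[test], ph) else NA_real_
  }
  m <- mean(fold_pcc, na.rm = TRUE)
  s <- stats::sd(fold_pcc, na.rm = TRUE)
  ci <- m + c(-1, 1) * stats::qt(0.975, folds - 1L) * s / sqrt(folds)
  structure(list(pooled_pcc = stats::cor(y, pred),
                 fold_pcc = fold_pcc,
                 mean_fold_pcc = m,
                 ci = ci,
                 folds = folds, seed = seed, fold_id = fold_id,
                 prediction = pred,
                 label = label %||% paste(colnames(X), collapse = "+")),
            class = "cv_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result [%s]: pooled PCC = %.4f (fold mean %.4f, 95%% CI %.4f..%.4f)\n",
              x$label, x$pooled_pcc, x$mean_fold_pcc, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Gain in cross-validated correlation from one extra signal
#'
#' Fits the core background predictors alone and augmented with one
#' additional signal (a TF or histone-mark read count), on identical fold
#' assignments, and reports the increase in pooled out-of-fold Pearson
#' correlation.  A signal genuinely informative about expression beyond the
#' core predictors yields a positive increase; a signal whose association
#' with expression is entirely mediated by chromatin accessibility (already
#' in the core) yields an increase near zero however high its standalone
#' correlation.  The increase may be negative (CV noise).
#'
#' @param y expression counts.
#' @param core_features matrix/data frame of core predictor columns.
#' @param extra_feature numeric vector, the candidate signal.
#' @param folds,seed as in [cv_predict()] (folds shared by construction).
#' @param extra_label label for the candidate signal.
#' @return a `delta_pcc` list: `baseline` and `augmented` ([cv_predict()]
#'   results), `increase` = augmented - baseline pooled PCC.
#' @export
delta_pcc <- function(y, core_features, extra_feature, folds = 10L, seed,
                      extra_label = "extra") {
  core <- as.matrix(core_features)
  base <- cv_predict(y, core, folds = folds, seed = seed, label = "core")
  aug <- cv_predict(y, cbind(core, stats::setNames(data.frame(extra_feature),
                                                   extra_label)),
                    folds = folds, seed = seed,
                    label = paste0("core+", extra_label))
  stopifnot(identical(base$fold_id, aug$fold_id))
  structure(list(baseline = base, augmented = aug,
                 increase = aug$pooled_pcc - base$pooled_pcc,
                 extra_label = extra_label),
            class = "delta_pcc")
}

#' @export
print.delta_pcc <- function(x, ...) {
  cat(sprintf("delta_pcc [%s]: core %.4f -> %.4f (increase %+.4f)\n",
              x$extra_label, x$baseline$pooled_pcc, x$augmented$pooled_pcc,
              x$increase))
  invisible(x)
}

#' Write an expression-association report
#'
#' Tab-separated table with one row per evaluated feature set: label,
#' pooled PCC, fold-mean PCC, CI bounds, and (where supplied) the increase
#' over the core predictors.
#'
#' @param results list of `cv_result` and/or `delta_pcc` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_report <- function(results, path) {
  rows <- lapply(results, function(r) {
    if (inherits(r, "delta_pcc")) {
      data.frame(feature_set = r$augmented$label,
                 pooled_pcc = r$augmented$pooled_pcc,
                 fold_mean_pcc = r$augmented$mean_fold_pcc,
                 ci_low = r$augmented$ci[1], ci_high = r$augmented$ci[2],
                 delta_vs_core = r$increase)
    } else {
      data.frame(feature_set = r$label, pooled_pcc = r$pooled_pcc,
                 fold_mean_pcc = r$mean_fold_pcc,
                 ci_low = r$ci[1], ci_high = r$ci[2],
                 delta_vs_core = NA_real_)
    }
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
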