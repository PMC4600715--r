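#' Log-transform raw intensities
#'
#' Adds a `y_log = log2(intensity)` column and drops empty wells (their
#' count is recorded in the `n_empty_dropped` attribute and reported via a
#' message). Raw CellTiter-Blue style fluorescence is strictly positive, so
#' a non-positive intensity here indicates corrupt input and is an error.
#'
#' @param dataset A [screen_dataset()].
#' @return The dataset with empty wells removed and a `y_log` column on
#'   `$wells`; attribute `n_empty_dropped` carries the dropped count.
#' @export
log_transform <- function(dataset) {
  if (!inherits(dataset, "screen_dataset")) stop("not a screen_dataset")
  w <- dataset$wells
  empty <- w$well_type == "empty"
  n_empty <- sum(empty)
  if (n_empty) {
    w <- w[!empty, , drop = FALSE]
    rownames(w) <- NULL
    message(sprintf("log_transform: dropped %d empty well(s)", n_empty))
  }
  bad <- which(is.na(w$intensity) | w$intensity <= 0)
  if (length(bad))
    stop(sprintf("non-positive intensity at screen %s, plate %s, well %s",
                 w$screen[bad[1L]], w$plate[bad[1L]], w$well[bad[1L]]))
  w$y_log <- log2(w$intensity)
  dataset$wells <- w
  attr(dataset, "n_empty_dropped") <- n_empty
  dataset
}

#' Fit the additive plate/screen normalization model
#'
#' Fits, by ordinary least squares under sum-to-zero constraints, the model
#' \deqn{y_{log} = \mu + \alpha_{plate} + \beta_{screen} + \varepsilon}
#' where `plate` indexes the library plate (shared content across screens)
#' and `screen` the replicate screen. Because the correction applied to a
#' physical plate is the single constant \eqn{\alpha_p + \beta_s}, all wells
#' of one physical plate are shifted identically and every within-plate
#' contrast -- in particular the between-cell-line signal of a given siRNA --
#' is preserved exactly.
#'
#' By default only `sample` wells enter the fit: positive-control wells are
#' near-zero-viability outliers that would bias the offsets, and empty wells
#' carry no signal. Controls are still shifted by the fitted offsets when
#' the model is applied.
#'
#' @param logdata Output of [log_transform()].
#' @param fit_wells `"sample"` (default) to estimate offsets from sample
#'   wells only, or `"all"` to include control wells.
#' @return An object of class `plate_screen_model` with elements `mu`,
#'   `alpha` (named, sum-to-zero), `beta` (named, sum-to-zero),
#'   `residual_scale`, `fit_wells`, `n_fit_wells`.
#' @export
fit_plate_screen_model <- function(logdata, fit_wells = c("sample", "all")) {
  fit_wells <- match.arg(fit_wells)
  w <- logdata$wells
  if (is.null(w$y_log)) stop("no y_log column; call log_transform() first")
  if (fit_wells == "sample") w <- w[w$well_type == "sample", , drop = FALSE]
  if (!nrow(w)) stop("no wells available for model fitting")

  plates <- sort(unique(logdata$wells$plate))
  screens <- sort(unique(logdata$wells$screen))
  pi <- match(w$plate, plates)
  si <- match(w$screen, screens)
  p <- length(plates); s <- length(screens)
  empty_plate <- setdiff(seq_len(p), unique(pi))
  if (length(empty_plate))
    stop("plate '", plates[empty_plate[1L]], "' has no usable wells for the fit")
  empty_screen <- setdiff(seq_len(s), unique(si))
  if (length(empty_screen))
    stop("screen '", screens[empty_screen[1L]],
         "' has no usable wells for the fit")

  y <- w$y_log
  n <- length(y)
  # Exact OLS via the small normal equations in the sum-to-zero
  # parameterization: unknowns are mu, alpha[1..p-1], beta[1..s-1]. The
  # cross-products only depend on the (plate, screen) cell counts, so the
  # system is (p+s-1)-dimensional regardless of the number of wells.
  if (p == 1L && s == 1L) {
    mu <- mean(y)
    alpha <- stats::setNames(0, plates)
    beta <- stats::setNames(0, screens)
    res <- y - mu
    df <- n - 1L
  } else {
    cell <- (si - 1L) * p + pi
    n_ps <- tabulate(cell, p * s)
    y_ps <- numeric(p * s)
    sums <- rowsum(y, cell)
    y_ps[as.integer(rownames(sums))] <- sums[, 1L]
    A <- if (p > 1L) stats::contr.sum(p) else matrix(0, 1L, 0L)  # p x (p-1)
    B <- if (s > 1L) stats::contr.sum(s) else matrix(0, 1L, 0L)  # s x (s-1)
    pg <- rep(seq_len(p), times = s)
    sg <- rep(seq_len(s), each = p)
    V <- cbind(1, A[pg, , drop = FALSE], B[sg, , drop = FALSE])
    XtX <- crossprod(V, n_ps * V)
    Xty <- crossprod(V, y_ps)
    theta <- tryCatch(solve(XtX, Xty), error = function(e)
      stop("normalization design is rank deficient: ", conditionMessage(e)))
    theta <- drop(theta)
    mu <- theta[1L]
    a <- if (p > 1L) drop(A %*% theta[2:p]) else 0
    b <- if (s > 1L) drop(B %*% theta[(p + 1L):(p + s - 1L)]) else 0
    alpha <- stats::setNames(a, plates)
    beta <- stats::setNames(b, screens)
    res <- y - (mu + alpha[pi] + beta[si])
    df <- n - (p + s - 1L)
  }
  residual_scale <- if (df > 0) sqrt(sum(res^2) / df) else NA_real_
  structure(list(mu = unname(mu), alpha = alpha, beta = beta,
                 residual_scale = residual_scale, fit_wells = fit_wells,
                 n_fit_wells = n),
            class = "plate_screen_model")
}

#' @export
print.plate_screen_model <- function(x, ...) {
  cat("<plate_screen_model> additive plate + screen offsets (log2 scale)\n")
  cat(sprintf("  grand mean: %.4f; %d plate offsets, %d screen offsets\n",
              x$mu, length(x$alpha), length(x$beta)))
  cat(sprintf("  residual scale: %.4f (fit on %d %s wells)\n",
              x$residual_scale, x$n_fit_wells, x$fit_wells))
  invisible(x)
}

#' @export
coef.plate_screen_model <- function(object, ...) {
  c(mu = object$mu,
    stats::setNames(object$alpha, paste0("plate:", names(object$alpha))),
    stats::setNames(object$beta, paste0("screen:", names(object$beta))))
}

#' Predicted plate/screen baseline
#'
#' Returns the fitted value \eqn{\mu + \alpha_p + \beta_s} for each row of
#' `newdata` (any data frame with `plate` and `screen` columns).
#'
#' @param object A `plate_screen_model`.
#' @param newdata Data frame with `plate` and `screen` columns; defaults to
#'   nothing (errors) since the model stores no data.
#' @param ... Unused.
#' @export
predict.plate_screen_model <- function(object, newdata, ...) {
  a <- object$alpha[as.character(newdata$plate)]
  b <- object$beta[as.character(newdata$screen)]
  if (anyNA(a)) stop("unseen plate level: ",
                     newdata$plate[which(is.na(a))[1L]])
  if (anyNA(b)) stop("unseen screen level: ",
                     newdata$screen[which(is.na(b))[1L]])
  unname(object$mu + a + b)
}

#' Apply a fitted normalization model
#'
#' Subtracts the fitted plate and screen offsets from each well's log2
#' intensity, retaining the grand mean:
#' \eqn{\hat y = y_{log} - \alpha_p - \beta_s}. Differences between wells on
#' the same physical plate are unchanged bit-for-bit.
#'
#' The correction applied to each physical plate,
#' \eqn{\alpha_p + \beta_s}, is quantized to a multiple of \eqn{2^{-40}}
#' (about 9e-13 log2 units, far below any measurement precision) before
#' subtraction. On that grid the IEEE subtraction is exact for all
#' realistic log2 intensities, so within-plate differences are preserved
#' bit-for-bit rather than merely to rounding error.
#'
#' @param logdata Output of [log_transform()].
#' @param model A [fit_plate_screen_model()] fit whose levels cover all
#'   plates and screens present.
#' @return `logdata` with a `y_norm` column added; the model is attached as
#'   attribute `normalization_model`.
#' @export
apply_normalization <- function(logdata, model) {
  if (!inherits(model, "plate_screen_model")) stop("not a plate_screen_model")
  w <- logdata$wells
  a <- model$alpha[w$plate]
  if (anyNA(a)) stop("plate '", w$plate[which(is.na(a))[1L]],
                     "' not covered by the normalization model")
  b <- model$beta[w$screen]
  if (anyNA(b)) stop("screen '", w$screen[which(is.na(b))[1L]],
                     "' not covered by the normalization model")
  corr <- round((unname(a) + unname(b)) * 2^40) / 2^40
  w$y_norm <- w$y_log - corr
  logdata$wells <- w
  attr(logdata, "normalization_model") <- model
  logdata
}

#' Percent viability relative to on-plate negative controls
#'
#' Expresses every well as a percentage of the mean of the non-targeting
#' (negative-control) wells on the same physical plate, on the linear
#' (unlogged) scale. With `scale = "raw"` the raw intensities are used; with
#' `scale = "log"` the normalized log2 values are exponentiated back to the
#' linear scale first (requires [apply_normalization()] output). Per-siRNA
#' means and standard deviations across replicate screens are computed per
#' cell line alongside.
#'
#' @param dataset A [screen_dataset()] (for `scale = "raw"`) or the output
#'   of [apply_normalization()] (for `scale = "log"`).
#' @param scale `"raw"` (default) or `"log"`.
#' @return A list of class `control_viability`: `wells` (the well table with
#'   a `viability` column, in percent) and `per_sirna` (mean and sd of
#'   viability per siRNA and cell line across screens).
#' @export
normalize_to_controls <- function(dataset, scale = c("raw", "log")) {
  scale <- match.arg(scale)
  w <- dataset$wells
  w <- w[w$well_type != "empty", , drop = FALSE]
  value <- if (scale == "raw") {
    w$intensity
  } else {
    if (is.null(w$y_norm))
      stop("scale = 'log' requires normalized data (apply_normalization)")
    2^w$y_norm
  }
  sp <- paste(w$screen, w$plate, sep = "\r")
  usp <- unique(sp)
  neg <- w$well_type == "negative_control"
  if (!any(neg)) stop("no negative-control wells present")
  idx <- match(sp, usp)
  csum <- numeric(length(usp)); cn <- numeric(length(usp))
  t1 <- rowsum(value[neg], idx[neg])
  csum[as.integer(rownames(t1))] <- t1[, 1L]
  cn_t <- table(idx[neg])
  cn[as.integer(names(cn_t))] <- as.integer(cn_t)
  if (any(cn == 0)) {
    parts <- strsplit(usp[which(cn == 0)[1L]], "\r", fixed = TRUE)[[1L]]
    stop(sprintf("plate %s in screen %s has no negative-control well",
                 parts[2L], parts[1L]))
  }
  cmean <- csum / cn
  if (any(cmean <= 0)) {
    parts <- strsplit(usp[which(cmean <= 0)[1L]], "\r", fixed = TRUE)[[1L]]
    stop(sprintf("control mean is non-positive on plate %s, screen %s",
                 parts[2L], parts[1L]))
  }
  w$viability <- 100 * value / cmean[idx]

  smp <- w[w$well_type == "sample", , drop = FALSE]
  key <- paste(smp$sirna, smp$cell_line, sep = "\r")
  uk <- unique(key)
  i <- match(key, uk)
  n_k <- tabulate(i, length(uk))
  mean_k <- numeric(length(uk))
  t2 <- rowsum(smp$viability, i)
  mean_k[as.integer(rownames(t2))] <- t2[, 1L] / n_k[as.integer(rownames(t2))]
  ss <- rowsum((smp$viability - mean_k[i])^2, i)
  sd_k <- rep(NA_real_, length(uk))
  ii <- as.integer(rownames(ss))
  sd_k[ii] <- ifelse(n_k[ii] > 1L, sqrt(ss[, 1L] / (n_k[ii] - 1L)), NA_real_)
  parts <- do.call(rbind, strsplit(uk, "\r", fixed = TRUE))
  per_sirna <- data.frame(sirna = parts[, 1L], cell_line = parts[, 2L],
                          n = n_k, mean_viability = mean_k,
                          sd_viability = sd_k, stringsAsFactors = FALSE)
  per_sirna <- per_sirna[order(per_sirna$sirna, per_sirna$cell_line), ]
  rownames(per_sirna) <- NULL
  structure(list(wells = w, per_sirna = per_sirna, scale = scale),
            class = "control_viability")
}

#' @export
print.control_viability <- function(x, ...) {
  cat(sprintf(
    "<control_viability> %d wells, %d siRNA x cell-line summaries (%s scale)\n",
    nrow(x$wells), nrow(x$per_sirna), x$scale))
  invisible(x)
}
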