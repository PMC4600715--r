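#' Fit the full paired-screen analysis
#'
#' One-call interface running the screen-analysis core on a validated
#' dataset: log2 transformation, additive plate/screen-effect normalization
#' by least squares, empirical-Bayes moderated differential-viability
#' testing between the two cell lines, Benjamini-Hochberg FDR adjustment,
#' and hit selection with direction filtering.
#'
#' @param dataset A [screen_dataset()].
#' @param mutant,corrected Cell-line labels of the mutant and corrected
#'   lines.
#' @param fdr_max FDR gate for hit selection (default 0.10, inclusive).
#' @param direction Hit direction filter, `"mutant_lethal"` (default) or
#'   `"either"`.
#' @param fit_wells Wells used to estimate the normalization offsets
#'   (`"sample"` or `"all"`).
#' @param prior Optional [estimate_prior()] object; estimated from the data
#'   when `NULL`.
#' @return An object of class `paired_screen_fit` with elements
#'   `normalization` (the [fit_plate_screen_model()]), `results` (the full
#'   [moderated_test()] table), `hits` (the [select_hits()] selection),
#'   `prior`, `normalized` (the normalized dataset), `mutant`, `corrected`,
#'   `fdr_max`, `direction`, `call`.
#' @examples
#' sim <- simulate_screen(screen_sim_config(n_genes = 200, truth_seed = 7),
#'                        seed = 42)
#' fit <- paired_screen(sim$dataset, mutant = "mutant",
#'                      corrected = "corrected")
#' summary(fit)
#' @export
paired_screen <- function(dataset, mutant, corrected, fdr_max = 0.10,
                          direction = c("mutant_lethal", "either"),
                          fit_wells = c("sample", "all"), prior = NULL) {
  direction <- match.arg(direction)
  fit_wells <- match.arg(fit_wells)
  logdata <- log_transform(dataset)
  model <- fit_plate_screen_model(logdata, fit_wells = fit_wells)
  normalized <- apply_normalization(logdata, model)
  results <- moderated_test(normalized, mutant = mutant,
                            corrected = corrected, prior = prior)
  hits <- select_hits(results, fdr_max = fdr_max, direction = direction)
  structure(list(normalization = model,
                 results = results,
                 hits = hits,
                 prior = attr(results, "prior"),
                 normalized = normalized,
                 mutant = mutant, corrected = corrected,
                 fdr_max = fdr_max, direction = direction,
                 call = match.call()),
            class = "paired_screen_fit")
}

#' @export
print.paired_screen_fit <- function(x, ...) {
  cat("<paired_screen_fit>\n")
  cat(sprintf("  %d siRNAs tested (%s vs %s); %d hits at q <= %.3g (%s)\n",
              nrow(x$results), x$mutant, x$corrected, nrow(x$hits),
              x$fdr_max, x$direction))
  invisible(x)
}

#' @export
summary.paired_screen_fit <- function(object, ...) {
  excl <- attr(object$hits, "exclusions")
  out <- list(
    n_tested = nrow(object$results),
    n_hits = nrow(object$hits),
    fdr_max = object$fdr_max,
    direction = object$direction,
    exclusions = excl,
    prior_d0 = object$prior$d0,
    prior_s0sq = object$prior$s0sq,
    residual_scale = object$normalization$residual_scale,
    n_plates = length(object$normalization$alpha),
    n_screens = length(object$normalization$beta))
  class(out) <- "summary.paired_screen_fit"
  out
}

#' @export
print.summary.paired_screen_fit <- function(x, ...) {
  cat("Paired isogenic screen analysis\n")
  cat(sprintf("  normalization: %d plate + %d screen offsets, residual scale %.4f\n",
              x$n_plates, x$n_screens, x$residual_scale))
  cat(sprintf("  variance prior: d0 = %s, s0^2 = %.4g\n",
              if (is.finite(x$prior_d0)) sprintf("%.2f", x$prior_d0)
              else "Inf", x$prior_s0sq))
  cat(sprintf("  %d siRNAs tested, %d hits at q <= %.3g (%s)\n",
              x$n_tested, x$n_hits, x$fdr_max, x$direction))
  if (!is.null(x$exclusions))
    for (i in seq_along(x$exclusions))
      cat(sprintf("    excluded, %s: %d\n", names(x$exclusions)[i],
                  x$exclusions[i]))
  invisible(x)
}

#' @export
coef.paired_screen_fit <- function(object, ...) {
  stats::setNames(object$results$effect, object$results$sirna)
}

#' Normalization residuals of a paired-screen fit
#'
#' Residuals of the plate/screen normalization model on the wells used for
#' the fit (log2 scale): \eqn{y_{log} - \mu - \alpha_p - \beta_s}.
#'
#' @param object A [paired_screen()] fit.
#' @param ... Unused.
#' @export
residuals.paired_screen_fit <- function(object, ...) {
  w <- object$normalized$wells
  if (object$normalization$fit_wells == "sample")
    w <- w[w$well_type == "sample", , drop = FALSE]
  w$y_norm - object$normalization$mu
}

#' Volcano plot of a paired-screen fit
#'
#' Per-siRNA effect (log2, positive = more lethal in the mutant line)
#' against \eqn{-\log_{10} p}; selected hits are highlighted.
#'
#' @param x A [paired_screen()] fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.paired_screen_fit <- function(x, ...) {
  r <- x$results
  is_hit <- r$sirna %in% x$hits$sirna
  graphics::plot(r$effect, -log10(r$p),
                 xlab = expression(log[2] ~ "effect (corrected - mutant)"),
                 ylab = expression(-log[10] ~ p),
                 pch = 16, cex = 0.4,
                 col = ifelse(is_hit, "firebrick", "grey50"), ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Simulate screens from a fitted analysis
#'
#' Parametric simulation from the fitted normalization model and per-siRNA
#' effect estimates: regenerates well-level log2 intensities as
#' \eqn{\mu + \alpha_p + \beta_s + effects + N(0, residual\_scale^2)} on the
#' original layout. Useful for posterior-predictive style checks of the
#' normalization fit.
#'
#' @param object A [paired_screen()] fit.
#' @param nsim Number of simulated datasets.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of `nsim` data frames shaped like the well table with
#'   simulated `intensity`.
#' @export
simulate.paired_screen_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  w <- object$normalized$wells
  m <- object$normalization
  # per-siRNA centre: observed mean normalized value per cell line
  key <- paste(w$sirna, w$cell_line, sep = "\r")
  centre <- tapply(w$y_norm, key, mean)
  base <- unname(centre[key])
  out <- vector("list", nsim)
  for (k in seq_len(nsim)) {
    y <- unname(m$alpha[w$plate]) + unname(m$beta[w$screen]) + base +
      stats::rnorm(nrow(w), 0, m$residual_scale)
    sim <- w[c("screen", "cell_line", "plate", "well", "sirna", "gene",
               "well_type")]
    sim$intensity <- 2^y
    out[[k]] <- sim
  }
  out
}
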