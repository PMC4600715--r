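#' Estimate the empirical-Bayes variance prior
#'
#' Given per-siRNA sample variances \eqn{s^2_g} on \eqn{d_g} residual
#' degrees of freedom, estimates the scaled inverse-chi-square prior
#' (prior degrees of freedom \eqn{d_0}, prior variance \eqn{s_0^2}) by
#' moment matching on \eqn{z_g = \log s^2_g}:
#' \deqn{trigamma(d_0/2) = var(z) - mean(trigamma(d_g/2))}
#' solved by monotone root finding, then
#' \deqn{\log s_0^2 = mean(z) - mean(digamma(d_g/2)) + digamma(d_0/2)
#'       - \log d_0 + mean(\log d_g).}
#' When the observed scatter of \eqn{z} does not exceed the expected
#' chi-square scatter, the prior is degenerate: \eqn{d_0 = \infty} and
#' \eqn{s_0^2} is the bias-corrected geometric-mean estimate. Zero variances
#' (possible with duplicated values) are excluded from estimation.
#'
#' @param s2 Numeric vector of sample variances.
#' @param df Residual degrees of freedom, a scalar or vector matching `s2`.
#' @return An object of class `shrinkage_prior`: list with `d0`, `s0sq`,
#'   `n_used`.
#' @seealso [moderated_test()]
#' @export
estimate_prior <- function(s2, df) {
  if (length(df) == 1L) df <- rep(df, length(s2))
  if (length(df) != length(s2)) stop("'df' must be scalar or match 's2'")
  keep <- is.finite(s2) & s2 > 0 & is.finite(df) & df >= 1
  if (all(!is.finite(s2) | s2 == 0))
    stop("all variances are zero or missing; cannot estimate a prior")
  s2u <- s2[keep]; dfu <- df[keep]
  if (length(s2u) < 2L)
    stop("need at least 2 positive variances to estimate the prior")
  z <- log(s2u)
  evar <- stats::var(z) - mean(trigamma(dfu / 2))
  if (!is.finite(evar) || evar <= 0) {
    d0 <- Inf
    log_s0 <- mean(z - digamma(dfu / 2) + log(dfu / 2))
  } else {
    # trigamma is strictly decreasing on (0, Inf); solve on the log scale
    f <- function(lx) trigamma(exp(lx)) - evar
    root <- stats::uniroot(f, lower = log(1e-8), upper = log(1e10),
                           tol = .Machine$double.eps^0.5)
    d0 <- 2 * exp(root$root)
    log_s0 <- mean(z) - mean(digamma(dfu / 2)) + digamma(d0 / 2) -
      log(d0) + mean(log(dfu))
  }
  structure(list(d0 = d0, s0sq = exp(log_s0), n_used = length(s2u)),
            class = "shrinkage_prior")
}

#' @export
print.shrinkage_prior <- function(x, ...) {
  cat(sprintf("<shrinkage_prior> d0 = %s, s0^2 = %.6g (from %d variances)\n",
              if (is.finite(x$d0)) sprintf("%.3f", x$d0) else "Inf",
              x$s0sq, x$n_used))
  invisible(x)
}

#' Shrink variances toward the prior
#'
#' Posterior (moderated) variances
#' \eqn{\tilde s^2_g = (d_0 s_0^2 + d_g s^2_g) / (d_0 + d_g)}; with
#' \eqn{d_0 = \infty} this is \eqn{s_0^2} for every siRNA.
#'
#' @param s2 Sample variances.
#' @param df Residual degrees of freedom (scalar or vector).
#' @param prior A [estimate_prior()] object.
#' @return Numeric vector of moderated variances.
#' @export
shrink_variances <- function(s2, df, prior) {
  if (is.infinite(prior$d0)) return(rep(prior$s0sq, length(s2)))
  (prior$d0 * prior$s0sq + df * s2) / (prior$d0 + df)
}

#' Moderated differential-viability test
#'
#' Per-siRNA empirical-Bayes moderated t-test for differential viability
#' between the two cell lines of a paired isogenic screen. For each siRNA
#' the replicate value in a screen is the mean normalized log2 intensity of
#' its well(s) in that screen. The effect is
#' \deqn{\Delta_g = mean(\hat y, corrected) - mean(\hat y, mutant)}
#' (positive = more lethal in the mutant line), tested with the pooled
#' variance shrunk toward the prior:
#' \deqn{\tilde t_g = \Delta_g / \sqrt{\tilde s^2_g (1/n_- + 1/n_+)}}
#' referred to a t distribution on \eqn{d_0 + d_g} degrees of freedom
#' (standard normal when \eqn{d_0 = \infty}). Unbalanced replicate structure
#' (e.g. 2 screens in one line, 3 in the other) is handled by the pooled
#' form; group sizes are reported per siRNA. siRNAs absent from one group
#' are excluded with a message (count in attribute `n_excluded_one_group`).
#'
#' @param normalized Output of [apply_normalization()] (or any
#'   `screen_dataset` whose wells carry a `y_norm` column).
#' @param mutant,corrected Cell-line labels identifying the two groups.
#' @param prior A [estimate_prior()] object, or `NULL` (default) to estimate
#'   it from the data.
#' @return A data frame of class `differential_result` with columns `sirna`,
#'   `gene`, `n_minus`, `n_plus`, `effect`, `s2`, `df`, `s2_mod`, `t_mod`,
#'   `p`, `q`, sorted ascending by `q` then `p`. The prior is attached as
#'   attribute `prior`.
#' @export
moderated_test <- function(normalized, mutant, corrected, prior = NULL) {
  w <- if (inherits(normalized, "screen_dataset")) normalized$wells
       else normalized
  if (is.null(w$y_norm))
    stop("no y_norm column; run apply_normalization() first")
  w <- w[w$well_type == "sample", , drop = FALSE]
  lines_present <- unique(w$cell_line)
  if (!(mutant %in% lines_present)) stop("no screens for cell line '",
                                         mutant, "'")
  if (!(corrected %in% lines_present)) stop("no screens for cell line '",
                                            corrected, "'")
  w <- w[w$cell_line %in% c(mutant, corrected), , drop = FALSE]

  sirnas <- unique(w$sirna)
  screens <- unique(w$screen)
  gi <- match(w$sirna, sirnas)
  si <- match(w$screen, screens)
  G <- length(sirnas); S <- length(screens)
  # per-siRNA, per-screen replicate summary (mean of that siRNA's wells)
  cell <- (si - 1L) * G + gi
  sums <- rowsum(w$y_norm, cell)
  cnt <- tabulate(cell, G * S)
  M <- matrix(NA_real_, G, S)
  ii <- as.integer(rownames(sums))
  M[ii] <- sums[, 1L] / cnt[ii]
  gene <- w$gene[match(sirnas, w$sirna)]

  line_of <- w$cell_line[match(screens, w$screen)]
  Mm <- M[, line_of == mutant, drop = FALSE]
  Mp <- M[, line_of == corrected, drop = FALSE]
  n_minus <- rowSums(!is.na(Mm))
  n_plus <- rowSums(!is.na(Mp))
  usable <- n_minus >= 1L & n_plus >= 1L & (n_minus + n_plus) >= 3L
  n_excluded <- sum(!usable)
  if (n_excluded)
    message(sprintf(
      "moderated_test: excluded %d siRNA(s) missing from one group or with < 1 residual df",
      n_excluded))

  mean_m <- rowMeans(Mm, na.rm = TRUE)
  mean_p <- rowMeans(Mp, na.rm = TRUE)
  effect <- mean_p - mean_m
  ss_m <- rowSums((Mm - mean_m)^2, na.rm = TRUE)
  ss_p <- rowSums((Mp - mean_p)^2, na.rm = TRUE)
  d <- n_minus + n_plus - 2L
  s2 <- ifelse(d > 0, (ss_m + ss_p) / pmax(d, 1L), NA_real_)

  res <- data.frame(sirna = sirnas, gene = gene,
                    n_minus = n_minus, n_plus = n_plus,
                    effect = effect, s2 = s2, df = d,
                    stringsAsFactors = FALSE)
  res <- res[usable, , drop = FALSE]
  if (!nrow(res)) stop("no testable siRNAs")

  if (is.null(prior)) prior <- estimate_prior(res$s2, res$df)
  if (!inherits(prior, "shrinkage_prior")) stop("not a shrinkage_prior")
  res$s2_mod <- shrink_variances(res$s2, res$df, prior)
  se <- sqrt(res$s2_mod * (1 / res$n_minus + 1 / res$n_plus))
  res$t_mod <- res$effect / se
  df_tot <- prior$d0 + res$df
  res$p <- 2 * stats::pt(-abs(res$t_mod), df = df_tot)
  res$q <- bh_fdr(res$p)
  res <- res[order(res$q, res$p, res$sirna), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "prior") <- prior
  attr(res, "n_excluded_one_group") <- n_excluded
  class(res) <- c("differential_result", "data.frame")
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j},
#' capped at 1, returned in the original order (computed via
#' [stats::p.adjust()] with `method = "BH"`). Ties receive identical q.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Select screen hits by FDR and direction
#'
#' Hits are siRNAs with \eqn{q \le} `fdr_max` (the gate is inclusive: a
#' q-value of exactly 0.10 is selected at the default threshold) and, with
#' `direction = "mutant_lethal"`, a positive effect (greater lethality in
#' the mutant line); siRNAs significant in the opposite direction are
#' excluded with reason `"greater lethality in corrected line"`. The result
#' is sorted ascending by q then p, and exclusion counts by reason are
#' attached as attribute `exclusions`.
#'
#' @param results A [moderated_test()] table.
#' @param fdr_max FDR gate (default 0.10).
#' @param direction `"mutant_lethal"` (default) or `"either"`.
#' @return The selected rows, sorted; attribute `exclusions` is a named
#'   integer vector.
#' @export
select_hits <- function(results, fdr_max = 0.10,
                        direction = c("mutant_lethal", "either")) {
  direction <- match.arg(direction)
  if (is.null(results$q)) stop("results carry no q-values")
  pass_fdr <- results$q <= fdr_max
  if (direction == "mutant_lethal") {
    pass_dir <- results$effect > 0
  } else {
    pass_dir <- rep(TRUE, nrow(results))
  }
  hits <- results[pass_fdr & pass_dir, , drop = FALSE]
  o <- order(hits$q, hits$p, hits$sirna)
  hits <- hits[o, , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "exclusions") <- c(
    "fdr above threshold" = sum(!pass_fdr),
    "greater lethality in corrected line" = sum(pass_fdr & !pass_dir))
  hits
}

#' Curate a hit list with manual include/exclude sets
#'
#' Screen hit lists are routinely curated by hand: genes dropped on updated
#' library annotation or wrong-direction lethality, and genes just above
#' the FDR gate cherry-picked back in. This represents those steps as
#' explicit user-supplied label sets so the arithmetic is auditable:
#' `final = (hits \ exclude) + include`.
#'
#' @param hits Character vector of hit labels (genes or siRNAs), or a data
#'   frame with a `gene` column.
#' @param exclude Labels to remove.
#' @param include Labels to add (duplicates with the remaining hits are an
#'   error -- an "addition" already present indicates a bookkeeping slip).
#' @return Character vector of curated labels, with attribute `counts`
#'   (named: `initial`, `excluded`, `added`, `final`).
#' @export
curate_hits <- function(hits, exclude = character(), include = character()) {
  labels <- if (is.data.frame(hits)) as.character(hits$gene)
            else as.character(hits)
  excluded <- intersect(labels, exclude)
  kept <- setdiff(labels, exclude)
  if (any(include %in% kept))
    stop("include list overlaps the remaining hits: ",
         paste(intersect(include, kept), collapse = ", "))
  final <- c(kept, include)
  attr(final, "counts") <- c(initial = length(labels),
                             excluded = length(excluded),
                             added = length(include),
                             final = length(final))
  final
}

#' @export
print.differential_result <- function(x, n = 10L, ...) {
  prior <- attr(x, "prior")
  cat(sprintf("<differential_result> %d siRNAs tested", nrow(x)))
  if (!is.null(prior))
    cat(sprintf(" (prior: d0 = %s, s0^2 = %.4g)",
                if (is.finite(prior$d0)) sprintf("%.2f", prior$d0) else "Inf",
                prior$s0sq))
  cat("\n")
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat(sprintf("  ... %d more rows\n", nrow(x) - n))
  invisible(x)
}
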