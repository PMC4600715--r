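#' Number of cell divisions from viability signals
#'
#' Assuming the viability signal is proportional to cell number, the number
#' of divisions of the untreated culture over the treatment window is
#' \eqn{n_{div} = \log_2(v_{untreated} / v_{t0})}.
#'
#' @param v_t0 Signal at seeding-day assay (vector, > 0).
#' @param v_untreated Signal after the treatment window, vehicle arm (> 0).
#' @return Numeric vector of division counts.
#' @export
divisions <- function(v_t0, v_untreated) {
  if (any(!is.finite(v_t0) | v_t0 <= 0))
    stop("v_t0 must be positive")
  if (any(!is.finite(v_untreated) | v_untreated <= 0))
    stop("v_untreated must be positive")
  log2(v_untreated / v_t0)
}

#' Percent growth inhibition
#'
#' \eqn{GI = 100 (1 - v_{treated} / v_{untreated})}. Treated signal above
#' the untreated signal (drug-stimulated growth) gives a negative GI, which
#' is allowed.
#'
#' @param v_treated Signal after the treatment window, drug arm.
#' @param v_untreated Signal after the treatment window, vehicle arm (> 0).
#' @return Numeric vector of percent growth inhibition (\eqn{\le 100}).
#' @export
growth_inhibition <- function(v_treated, v_untreated) {
  if (any(!is.finite(v_untreated) | v_untreated <= 0))
    stop("v_untreated must be positive")
  100 * (1 - v_treated / v_untreated)
}

#' Division-corrected drug sensitivity
#'
#' Percent growth inhibition per cell division, `gi_percent / n_div`. This
#' makes fast- and slow-growing lines comparable: a drug that removes the
#' same fraction of growth per doubling scores equally in both. Records with
#' `n_div <= 0` (no net growth in the vehicle arm) have no defined
#' per-division sensitivity and return `NA` with a warning; callers should
#' exclude them from group comparisons.
#'
#' @param gi_percent Percent growth inhibition.
#' @param n_div Number of divisions of the untreated culture.
#' @return Numeric vector, `NA` where `n_div <= 0`.
#' @export
corrected_sensitivity <- function(gi_percent, n_div) {
  bad <- !is.finite(n_div) | n_div <= 0
  if (any(bad))
    warning(sprintf(
      "%d record(s) with n_div <= 0: corrected sensitivity undefined, set to NA",
      sum(bad)))
  ifelse(bad, NA_real_, gi_percent / n_div)
}

#' Score a drug-panel table
#'
#' Computes divisions, growth inhibition and division-corrected sensitivity
#' for every row of a panel table (one row per cell line and drug).
#'
#' @param panel Data frame with columns `cell_line`, `cohesion_status`,
#'   `v_t0`, `v_untreated`, `v_treated` (optionally `drug`, carried
#'   through).
#' @return The panel with `n_div`, `gi_percent` and `corrected_sensitivity`
#'   columns appended.
#' @export
drug_sensitivity <- function(panel) {
  need <- c("cell_line", "cohesion_status", "v_t0", "v_untreated",
            "v_treated")
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  panel$n_div <- divisions(panel$v_t0, panel$v_untreated)
  panel$gi_percent <- growth_inhibition(panel$v_treated, panel$v_untreated)
  panel$corrected_sensitivity <- corrected_sensitivity(panel$gi_percent,
                                                       panel$n_div)
  panel
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Mann-Whitney/Wilcoxon rank-sum test. The p-value is exact (full
#' enumeration of rank assignments) when there are no ties and the combined
#' sample size is at most 12; otherwise mid-ranks with the normal
#' approximation and tie-corrected variance are used. The path taken is
#' reported in `method`.
#'
#' @param group_a,group_b Numeric vectors (both non-empty).
#' @param alternative Passed to the test; default two-sided.
#' @return List of class `rank_sum`: `U` (Mann-Whitney U for `group_a`),
#'   `p`, `method` (`"exact"` or `"normal_approximation"`), `n_a`, `n_b`.
#' @export
rank_sum_compare <- function(group_a, group_b,
                             alternative = c("two.sided", "less",
                                             "greater")) {
  alternative <- match.arg(alternative)
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (!length(group_a) || !length(group_b))
    stop("both groups must be non-empty")
  ties <- anyDuplicated(c(group_a, group_b)) > 0L
  exact <- !ties && (length(group_a) + length(group_b)) <= 12L
  wt <- suppressWarnings(stats::wilcox.test(
    group_a, group_b, alternative = alternative,
    exact = exact, correct = !exact))
  structure(list(U = unname(wt$statistic), p = wt$p.value,
                 method = if (exact) "exact" else "normal_approximation",
                 n_a = length(group_a), n_b = length(group_b)),
            class = "rank_sum")
}

#' @export
print.rank_sum <- function(x, ...) {
  cat(sprintf(
    "<rank_sum> U = %g, p = %.4g (%s; n = %d vs %d)\n",
    x$U, x$p, x$method, x$n_a, x$n_b))
  invisible(x)
}

#' Compare division-corrected sensitivity between cohesion groups
#'
#' Runs [rank_sum_compare()] on the `corrected_sensitivity` of a scored
#' panel (see [drug_sensitivity()]), splitting on `cohesion_status`.
#' Records with undefined corrected sensitivity are excluded with a
#' warning.
#'
#' @param scored Output of [drug_sensitivity()].
#' @param groups Length-2 character vector naming the two cohesion-status
#'   levels, first vs second (default `c("defective", "intact")`).
#' @param value Column to compare (default `"corrected_sensitivity"`).
#' @return A `rank_sum` object (first group = `groups[1]`).
#' @export
compare_drug_response <- function(scored,
                                  groups = c("defective", "intact"),
                                  value = "corrected_sensitivity") {
  v <- scored[[value]]
  drop <- is.na(v)
  if (any(drop)) {
    warning(sprintf("%d record(s) with undefined %s excluded", sum(drop),
                    value))
    scored <- scored[!drop, , drop = FALSE]
    v <- v[!drop]
  }
  a <- v[scored$cohesion_status == groups[1L]]
  b <- v[scored$cohesion_status == groups[2L]]
  rank_sum_compare(a, b)
}
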