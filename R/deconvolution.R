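#' Differential ratio and toxicity of a deconvoluted siRNA
#'
#' For a single siRNA retested individually in both cell lines, the
#' differential effect is the ratio of corrected-line to mutant-line percent
#' viability, \eqn{R = v_+ / v_-} (R > 1: more killing in the mutant line),
#' and the toxicity is the percent cell death in the corrected line,
#' \eqn{T = 100 - v_+}. A mutant-line viability of exactly zero (total kill
#' in the mutant only) yields an infinite ratio, flagged rather than raised
#' as an error; negative viabilities are errors.
#'
#' @param viability_plus Percent viability in the corrected line (vector).
#' @param viability_minus Percent viability in the mutant line (vector).
#' @return Data frame with columns `ratio`, `toxicity`, `ratio_infinite`.
#' @export
ratio_toxicity <- function(viability_plus, viability_minus) {
  if (length(viability_plus) != length(viability_minus))
    stop("viability vectors must have equal length")
  if (any(viability_plus < 0, na.rm = TRUE) ||
      any(viability_minus < 0, na.rm = TRUE))
    stop("viabilities must be non-negative")
  ratio <- ifelse(viability_minus == 0,
                  ifelse(viability_plus > 0, Inf, NaN),
                  viability_plus / viability_minus)
  data.frame(ratio = ratio,
             toxicity = 100 - viability_plus,
             ratio_infinite = viability_minus == 0)
}

#' Score a deconvolution rescreen table
#'
#' Takes the long-format deconvolution table (one row per gene, siRNA,
#' cell line and experiment, with control-relative percent viability) and
#' computes, per siRNA: mean and standard deviation of viability per cell
#' line across the replicate experiments, then the ratio and toxicity from
#' the mean viabilities.
#'
#' @param deconv Data frame with columns `gene`, `sirna`, `cell_line`,
#'   `experiment`, `viability` (optionally `accession`, `target_sequence`,
#'   carried through).
#' @param mutant,corrected Cell-line labels.
#' @return Data frame of class `deconvolution_scores`, one row per
#'   (gene, sirna): `viability_minus`, `viability_plus`, `sd_minus`,
#'   `sd_plus`, `n_experiments`, `ratio`, `toxicity`, `ratio_infinite`.
#' @export
deconvolution_score <- function(deconv, mutant = "mutant",
                                corrected = "corrected") {
  need <- c("gene", "sirna", "cell_line", "experiment", "viability")
  missing_cols <- setdiff(need, names(deconv))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (!all(deconv$cell_line %in% c(mutant, corrected)))
    stop("cell_line values must be '", mutant, "' or '", corrected, "'")
  if (any(deconv$viability < 0, na.rm = TRUE))
    stop("viabilities must be non-negative")

  agg_mean <- stats::aggregate(viability ~ gene + sirna + cell_line,
                               data = deconv, FUN = mean)
  agg_sd <- stats::aggregate(viability ~ gene + sirna + cell_line,
                             data = deconv,
                             FUN = function(v) if (length(v) > 1L)
                               stats::sd(v) else NA_real_)
  agg_n <- stats::aggregate(viability ~ gene + sirna + cell_line,
                            data = deconv, FUN = length)
  key <- function(d) paste(d$gene, d$sirna, sep = "\r")
  um <- agg_mean[agg_mean$cell_line == mutant, ]
  up <- agg_mean[agg_mean$cell_line == corrected, ]
  if (!nrow(um) || !nrow(up))
    stop("both cell lines must be present in the deconvolution table")
  i <- match(key(um), key(up))
  if (anyNA(i))
    stop("gene/siRNA '", key(um)[which(is.na(i))[1L]],
         "' measured in only one cell line")
  out <- data.frame(gene = um$gene, sirna = um$sirna,
                    viability_minus = um$viability,
                    viability_plus = up$viability[i],
                    stringsAsFactors = FALSE)
  sm <- agg_sd[agg_sd$cell_line == mutant, ]
  sp <- agg_sd[agg_sd$cell_line == corrected, ]
  out$sd_minus <- sm$viability[match(key(out), key(sm))]
  out$sd_plus <- sp$viability[match(key(out), key(sp))]
  nn <- agg_n[agg_n$cell_line == mutant, ]
  out$n_experiments <- nn$viability[match(key(out), key(nn))]
  for (extra in c("accession", "target_sequence")) {
    if (extra %in% names(deconv))
      out[[extra]] <- deconv[[extra]][match(key(out), key(deconv))]
  }
  rt <- ratio_toxicity(out$viability_plus, out$viability_minus)
  out$ratio <- rt$ratio
  out$toxicity <- rt$toxicity
  out$ratio_infinite <- rt$ratio_infinite
  out <- out[order(out$gene, out$sirna), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("deconvolution_scores", "data.frame")
  out
}

#' Gene-level confirmation from deconvoluted siRNAs
#'
#' A siRNA passes when its ratio strictly exceeds `ratio_min` AND its
#' toxicity is strictly below `toxicity_max` (boundary values fail: a ratio
#' of exactly 2 or a toxicity of exactly 50 does not pass at the defaults).
#' A gene is confirmed when at least `min_pass` of its siRNAs pass. The full
#' per-siRNA audit trail (pass flags) is attached as attribute `per_sirna`.
#'
#' @param scores A [deconvolution_score()] table (any data frame with
#'   `gene`, `sirna`, `ratio`, `toxicity` columns).
#' @param min_pass Minimum number of passing siRNAs to confirm (default 2).
#' @param ratio_min Ratio threshold, strict (default 2).
#' @param toxicity_max Toxicity threshold in percent, strict (default 50).
#' @return Data frame, one row per gene: `gene`, `n_sirnas`, `n_pass`,
#'   `confirmed`; attribute `per_sirna` carries the scored table with a
#'   `pass` column.
#' @export
confirm_genes <- function(scores, min_pass = 2L, ratio_min = 2,
                          toxicity_max = 50) {
  if (!nrow(scores)) {
    out <- data.frame(gene = character(), n_sirnas = integer(),
                      n_pass = integer(), confirmed = logical())
    attr(out, "per_sirna") <- cbind(scores, pass = logical(0))
    return(out)
  }
  pass <- scores$ratio > ratio_min & scores$toxicity < toxicity_max
  pass[is.na(pass)] <- FALSE
  genes <- unique(scores$gene)
  gi <- match(scores$gene, genes)
  out <- data.frame(gene = genes,
                    n_sirnas = tabulate(gi, length(genes)),
                    n_pass = as.integer(rowsum(as.integer(pass), gi)[, 1L]),
                    stringsAsFactors = FALSE)
  out$confirmed <- out$n_pass >= min_pass
  audit <- scores
  audit$pass <- pass
  attr(out, "per_sirna") <- audit
  attr(out, "thresholds") <- c(min_pass = min_pass, ratio_min = ratio_min,
                               toxicity_max = toxicity_max)
  out
}

#' Summarize a deconvolution triage
#'
#' Counts genes with at least one passing siRNA and genes confirmed (at
#' least `min_pass` passing), and returns the gene table sorted by number of
#' passing siRNAs (descending) then maximum ratio (descending).
#'
#' @param confirmations Output of [confirm_genes()].
#' @return The gene table, sorted, with attribute `counts` (named:
#'   `n_genes`, `n_any_pass`, `n_confirmed`); class `triage_summary`.
#' @export
triage_summary <- function(confirmations) {
  audit <- attr(confirmations, "per_sirna")
  if (nrow(confirmations)) {
    finite_ratio <- ifelse(is.finite(audit$ratio), audit$ratio,
                           max(audit$ratio[is.finite(audit$ratio)], 0) + 1)
    max_r <- vapply(split(finite_ratio, audit$gene), max, 0)
    confirmations$max_ratio <- vapply(
      split(audit$ratio, audit$gene), max, 0)[confirmations$gene]
    o <- order(-confirmations$n_pass, -max_r[confirmations$gene],
               confirmations$gene)
    confirmations <- confirmations[o, , drop = FALSE]
    rownames(confirmations) <- NULL
  } else {
    confirmations$max_ratio <- numeric(0)
  }
  attr(confirmations, "counts") <- c(
    n_genes = nrow(confirmations),
    n_any_pass = sum(confirmations$n_pass >= 1L),
    n_confirmed = sum(confirmations$confirmed))
  class(confirmations) <- c("triage_summary", "data.frame")
  confirmations
}

#' @export
print.triage_summary <- function(x, n = 10L, ...) {
  ct <- attr(x, "counts")
  cat(sprintf(
    "<triage_summary> %d genes: %d with >=1 passing siRNA, %d confirmed\n",
    ct["n_genes"], ct["n_any_pass"], ct["n_confirmed"]))
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat(sprintf("  ... %d more rows\n", nrow(x) - n))
  invisible(x)
}
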