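#' Configuration for a synthetic paired screen
#'
#' Defines the generative model of a paired isogenic viability screen on the
#' log2-intensity scale:
#' \deqn{y = \mu + \alpha_{plate} + \beta_{screen} + \gamma_{gene}
#'       - \delta_{gene} 1[line = mutant] + \varepsilon,
#'       \quad \varepsilon \sim N(0, \sigma_{well}^2)}
#' with intensities emitted on the linear scale (\eqn{2^y}). Defaults mirror
#' the screening design being emulated: 384-well plates carrying 8
#' non-targeting negative controls and 2 strong-kill positive controls each,
#' three replicate screens per cell line, genome scale (20,000 genes). Base
#' lethality \eqn{\gamma \le 0} hits a fraction of genes in both lines;
#' synthetic-lethal genes additionally lose \eqn{\delta > 0} log2 units in
#' the mutant line only. Negative controls have \eqn{\gamma = \delta = 0};
#' positive controls have a strong \eqn{\gamma} in both lines.
#'
#' Two independent random streams are used: `truth_seed` fixes the structure
#' (which genes are lethal/synthetic-lethal, planted plate and screen
#' offsets) while the `seed` given to [simulate_screen()] drives only the
#' well noise, so truth tables are stable across noise replicates.
#'
#' @param n_genes Number of library genes (one siRNA pool per gene).
#' @param geometry Plate geometry, default 384-well.
#' @param n_neg_controls,n_pos_controls Control wells per plate.
#' @param n_screens_mutant,n_screens_corrected Replicate screens per line
#'   (set 2 and 3 for an unbalanced design).
#' @param mu Grand mean log2 intensity (default 14, i.e. ~16k RFU).
#' @param sigma_plate,sigma_screen,sigma_well Standard deviations of the
#'   planted plate offsets, screen offsets, and well noise (log2 units).
#' @param frac_lethal Fraction of genes with base lethality in both lines.
#' @param lethal_mean,lethal_sd Half-normal location/spread of base
#'   lethality magnitudes (log2 units).
#' @param n_synthetic_lethal Number of planted synthetic-lethal genes.
#' @param delta Differential effect of synthetic-lethal genes (log2 units of
#'   extra intensity loss in the mutant line; default 3 well-noise sd).
#' @param pos_control_effect Log2 kill of the positive control in both
#'   lines.
#' @param line_mutant,line_corrected Cell-line labels.
#' @param truth_seed Seed of the structure stream.
#' @return Object of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_genes = 20000L,
                              geometry = screen_geometry(),
                              n_neg_controls = 8L,
                              n_pos_controls = 2L,
                              n_screens_mutant = 3L,
                              n_screens_corrected = 3L,
                              mu = 14,
                              sigma_plate = 0.5,
                              sigma_screen = 0.25,
                              sigma_well = 0.3,
                              frac_lethal = 0.05,
                              lethal_mean = 1.0,
                              lethal_sd = 0.5,
                              n_synthetic_lethal = 50L,
                              delta = 3 * sigma_well,
                              pos_control_effect = 4,
                              line_mutant = "mutant",
                              line_corrected = "corrected",
                              truth_seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), geometry = geometry,
              n_neg_controls = as.integer(n_neg_controls),
              n_pos_controls = as.integer(n_pos_controls),
              n_screens_mutant = as.integer(n_screens_mutant),
              n_screens_corrected = as.integer(n_screens_corrected),
              mu = mu, sigma_plate = sigma_plate,
              sigma_screen = sigma_screen, sigma_well = sigma_well,
              frac_lethal = frac_lethal, lethal_mean = lethal_mean,
              lethal_sd = lethal_sd,
              n_synthetic_lethal = as.integer(n_synthetic_lethal),
              delta = delta, pos_control_effect = pos_control_effect,
              line_mutant = line_mutant, line_corrected = line_corrected,
              truth_seed = as.integer(truth_seed))
  wells_per_plate <- geometry$rows * geometry$cols
  n_ctrl <- cfg$n_neg_controls + cfg$n_pos_controls
  if (cfg$n_genes < 1L) stop("n_genes must be positive")
  if (cfg$n_neg_controls < 1L)
    stop("at least one negative-control well per plate is required")
  if (n_ctrl >= wells_per_plate)
    stop("control wells do not fit in the plate geometry")
  if (cfg$n_screens_mutant < 1L || cfg$n_screens_corrected < 1L)
    stop("at least one screen per cell line is required")
  sds <- c(cfg$sigma_plate, cfg$sigma_screen, cfg$sigma_well)
  if (any(!is.finite(sds) | sds < 0)) stop("sigmas must be >= 0")
  if (cfg$frac_lethal < 0 || cfg$frac_lethal > 1)
    stop("frac_lethal must be in [0, 1]")
  if (cfg$n_synthetic_lethal < 0 ||
      cfg$n_synthetic_lethal > cfg$n_genes)
    stop("n_synthetic_lethal must be in 0..n_genes")
  if (cfg$delta < 0) stop("delta must be >= 0")
  cfg$samples_per_plate <- wells_per_plate - n_ctrl
  cfg$n_plates <- as.integer(ceiling(cfg$n_genes / cfg$samples_per_plate))
  class(cfg) <- "screen_sim_config"
  cfg
}

#' @export
print.screen_sim_config <- function(x, ...) {
  cat(sprintf(
    "<screen_sim_config> %d genes on %d plates (%d-well), %d+%d screens\n",
    x$n_genes, x$n_plates, x$geometry$rows * x$geometry$cols,
    x$n_screens_mutant, x$n_screens_corrected))
  cat(sprintf(
    "  mu=%.2f sd(plate)=%.2f sd(screen)=%.2f sd(well)=%.2f; %d SL genes at delta=%.2f\n",
    x$mu, x$sigma_plate, x$sigma_screen, x$sigma_well,
    x$n_synthetic_lethal, x$delta))
  invisible(x)
}

# Deterministic library layout shared by all screens: genes fill the sample
# wells plate by plate; the last wells of each plate hold the negative and
# positive controls; unfilled sample wells on the final plate are empty.
.sim_layout <- function(cfg) {
  g <- cfg$geometry
  wpp <- g$rows * g$cols
  wells <- paste0(rep(LETTERS[seq_len(g$rows)], times = g$cols),
                  rep(seq_len(g$cols), each = g$rows))
  per_plate <- function(p) {
    first_gene <- (p - 1L) * cfg$samples_per_plate + 1L
    n_here <- min(cfg$samples_per_plate, cfg$n_genes - first_gene + 1L)
    gene_idx <- c(seq.int(first_gene, length.out = n_here),
                  rep(NA_integer_, cfg$samples_per_plate - n_here))
    type <- c(ifelse(is.na(gene_idx), "empty", "sample"),
              rep("negative_control", cfg$n_neg_controls),
              rep("positive_control", cfg$n_pos_controls))
    gi <- c(gene_idx, rep(NA_integer_, cfg$n_neg_controls +
                            cfg$n_pos_controls))
    data.frame(plate = sprintf("P%03d", p), well = wells,
               gene_index = gi, well_type = type, stringsAsFactors = FALSE)
  }
  layout <- do.call(rbind, lapply(seq_len(cfg$n_plates), per_plate))
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  layout$gene <- ifelse(is.na(layout$gene_index), NA_character_,
                        genes[layout$gene_index])
  layout$sirna <- ifelse(layout$well_type == "sample",
                         paste0("si", layout$gene),
                  ifelse(layout$well_type == "negative_control", "NTC",
                  ifelse(layout$well_type == "positive_control",
                         "siPOSCTRL", "none")))
  layout
}

# Structure stream: gene effects and planted offsets (centered to sum zero
# so least-squares recovery is well defined).
.sim_truth <- function(cfg) {
  set.seed(cfg$truth_seed)
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  base <- numeric(cfg$n_genes)
  n_lethal <- round(cfg$frac_lethal * cfg$n_genes)
  lethal_idx <- if (n_lethal > 0) sample.int(cfg$n_genes, n_lethal)
                else integer(0)
  base[lethal_idx] <- -abs(stats::rnorm(n_lethal, cfg$lethal_mean,
                                        cfg$lethal_sd))
  non_lethal <- setdiff(seq_len(cfg$n_genes), lethal_idx)
  if (cfg$n_synthetic_lethal > length(non_lethal))
    stop("not enough non-lethal genes to plant synthetic-lethal effects")
  sl_idx <- if (cfg$n_synthetic_lethal > 0)
    sort(sample(non_lethal, cfg$n_synthetic_lethal)) else integer(0)
  delta <- numeric(cfg$n_genes)
  delta[sl_idx] <- cfg$delta
  plates <- sprintf("P%03d", seq_len(cfg$n_plates))
  alpha <- stats::rnorm(cfg$n_plates, 0, cfg$sigma_plate)
  alpha <- stats::setNames(alpha - mean(alpha), plates)
  screens <- c(paste0("M", seq_len(cfg$n_screens_mutant)),
               paste0("C", seq_len(cfg$n_screens_corrected)))
  beta <- stats::rnorm(length(screens), 0, cfg$sigma_screen)
  beta <- stats::setNames(beta - mean(beta), screens)
  list(genes = data.frame(gene = genes, base_effect = base, delta = delta,
                          is_synthetic_lethal = delta > 0,
                          stringsAsFactors = FALSE),
       alpha = alpha, beta = beta,
       screens = data.frame(
         screen = screens,
         cell_line = c(rep(cfg$line_mutant, cfg$n_screens_mutant),
                       rep(cfg$line_corrected, cfg$n_screens_corrected)),
         stringsAsFactors = FALSE))
}

#' Simulate a paired isogenic siRNA screen
#'
#' Generates a full multi-plate, multi-screen dataset from the additive
#' log2-scale model described in [screen_sim_config()], together with the
#' ground truth needed to score any downstream analysis. Deterministic under
#' `(config, seed)`; changing `seed` redraws only the well noise while the
#' truth (gene effects, planted offsets) is governed by
#' `config$truth_seed`.
#'
#' @param config A [screen_sim_config()].
#' @param seed Integer seed of the noise stream.
#' @return List of class `screen_sim`: `dataset` (a validated
#'   [screen_dataset()]) and `truth` (gene table with `base_effect`,
#'   `delta`, `is_synthetic_lethal`; planted `alpha`, `beta`; the screen to
#'   cell-line map; the config and seeds).
#' @export
simulate_screen <- function(config, seed = 1L) {
  if (!inherits(config, "screen_sim_config")) stop("not a screen_sim_config")
  truth <- .sim_truth(config)
  layout <- .sim_layout(config)
  n_per_screen <- nrow(layout)
  screens <- truth$screens

  set.seed(as.integer(seed))
  S <- nrow(screens)
  idx <- rep(seq_len(n_per_screen), S)
  wells <- as.data.frame(lapply(layout, `[`, idx),
                         stringsAsFactors = FALSE)
  wells$screen <- rep(screens$screen, each = n_per_screen)
  wells$cell_line <- rep(screens$cell_line, each = n_per_screen)
  nonempty <- wells$well_type != "empty"

  gamma <- numeric(nrow(wells))
  smp <- wells$well_type == "sample"
  gamma[smp] <- truth$genes$base_effect[wells$gene_index[smp]]
  gamma[wells$well_type == "positive_control"] <- -config$pos_control_effect
  del <- numeric(nrow(wells))
  mut <- wells$cell_line == config$line_mutant
  del[smp & mut] <- truth$genes$delta[wells$gene_index[smp & mut]]

  y <- config$mu + unname(truth$alpha[wells$plate]) +
    unname(truth$beta[wells$screen]) + gamma - del
  eps <- numeric(nrow(wells))
  eps[nonempty] <- stats::rnorm(sum(nonempty), 0, config$sigma_well)
  y <- y + eps
  intensity <- 2^y
  intensity[!nonempty] <- NA_real_
  wells$intensity <- intensity
  wells$sirna[wells$well_type == "empty"] <- "none"
  wells$gene[is.na(wells$gene)] <- ""

  ds <- screen_dataset(
    wells[c("screen", "cell_line", "plate", "well", "sirna", "gene",
            "well_type", "intensity")],
    geometry = config$geometry)
  truth$config <- config
  truth$seed <- as.integer(seed)
  structure(list(dataset = ds, truth = truth), class = "screen_sim")
}

#' @export
print.screen_sim <- function(x, ...) {
  cat("<screen_sim> synthetic paired screen\n")
  print(x$dataset)
  cat(sprintf("  truth: %d lethal, %d synthetic-lethal genes (seed %d / truth %d)\n",
              sum(x$truth$genes$base_effect < 0),
              sum(x$truth$genes$is_synthetic_lethal),
              x$truth$seed, x$truth$config$truth_seed))
  invisible(x)
}

#' Gene panel for a synthetic deconvolution rescreen
#'
#' Builds the truth table of a deconvolution panel: `n_true` genes carrying
#' a synthetic-lethal differential effect of `delta` log2 units (4-fold
#' differential killing at the default 2.0, the magnitude of a strong
#' validated hit) and `n_null` genes with no effect.
#'
#' @param n_true,n_null Gene counts (defaults 5 and 93, a 98-gene panel).
#' @param delta Differential effect of true genes (log2 units).
#' @param base_effect Base lethality of true genes in both lines (log2
#'   units, \eqn{\le 0}; default 0).
#' @return Data frame with columns `gene`, `base_effect`, `delta`.
#' @export
deconv_panel_truth <- function(n_true = 5L, n_null = 93L, delta = 2.0,
                               base_effect = 0) {
  data.frame(
    gene = c(sprintf("TRUE%02d", seq_len(n_true)),
             sprintf("NULL%02d", seq_len(n_null))),
    base_effect = c(rep(base_effect, n_true), rep(0, n_null)),
    delta = c(rep(delta, n_true), rep(0, n_null)),
    stringsAsFactors = FALSE)
}

#' Simulate a single-siRNA deconvolution rescreen
#'
#' For each gene of a truth panel, draws `n_sirnas` individual siRNAs with
#' per-siRNA knockdown efficiency \eqn{\kappa \in [0, 1]} and a half-normal
#' off-target kill shared by both lines, then emits control-relative percent
#' viabilities per cell line and experiment with multiplicative log-normal
#' noise:
#' \deqn{v_{line} = 100 \cdot 2^{-(\kappa \cdot kill_{line} + o)}
#'       \cdot 2^{N(0, \sigma_{noise}^2)}}
#' where \eqn{kill_{corrected} = -base\_effect} and
#' \eqn{kill_{mutant} = -base\_effect + \delta}. Knockdown efficiencies and
#' off-target terms are drawn under `truth_seed` (structure stream); the
#' measurement noise under `seed`.
#'
#' @param genes Truth table (see [deconv_panel_truth()] or the `$genes`
#'   element of a [simulate_screen()] truth, columns `gene`, `base_effect`,
#'   `delta`).
#' @param n_sirnas siRNAs per gene (default 4).
#' @param kappa_fun Function drawing `n` knockdown efficiencies (default
#'   `runif(n, 0.3, 1)`).
#' @param offtarget_sd Half-normal sd of the off-target kill (log2 units).
#' @param noise_sd Multiplicative measurement noise sd (log2 units) per
#'   viability reading.
#' @param n_experiments Replicate experiments (default 2).
#' @param seed Noise-stream seed.
#' @param truth_seed Structure-stream seed.
#' @param line_mutant,line_corrected Cell-line labels.
#' @return List of class `deconv_sim`: `table` (long format: `gene`,
#'   `sirna`, `cell_line`, `experiment`, `viability`) and `truth` (per-siRNA
#'   `kappa`, `offtarget`, merged gene effects).
#' @export
simulate_deconvolution <- function(genes, n_sirnas = 4L,
                                   kappa_fun = function(n)
                                     stats::runif(n, 0.3, 1),
                                   offtarget_sd = 0.25,
                                   noise_sd = 0.1,
                                   n_experiments = 2L,
                                   seed = 1L, truth_seed = 1L,
                                   line_mutant = "mutant",
                                   line_corrected = "corrected") {
  need <- c("gene", "base_effect", "delta")
  if (!all(need %in% names(genes)))
    stop("genes must have columns: ", paste(need, collapse = ", "))
  G <- nrow(genes)
  n_si <- G * n_sirnas

  set.seed(as.integer(truth_seed))
  kappa <- kappa_fun(n_si)
  if (any(kappa < 0 | kappa > 1)) stop("kappa_fun must return values in [0, 1]")
  offtarget <- abs(stats::rnorm(n_si, 0, offtarget_sd))

  truth <- data.frame(
    gene = rep(genes$gene, each = n_sirnas),
    sirna = paste0(rep(genes$gene, each = n_sirnas), "#",
                   rep(seq_len(n_sirnas), G)),
    sirna_index = rep(seq_len(n_sirnas), G),
    kappa = kappa, offtarget = offtarget,
    base_effect = rep(genes$base_effect, each = n_sirnas),
    delta = rep(genes$delta, each = n_sirnas),
    stringsAsFactors = FALSE)

  kill_corr <- truth$kappa * (-truth$base_effect) + truth$offtarget
  kill_mut <- truth$kappa * (-truth$base_effect + truth$delta) +
    truth$offtarget

  set.seed(as.integer(seed))
  rows <- expand.grid(i = seq_len(n_si),
                      cell_line = c(line_mutant, line_corrected),
                      experiment = seq_len(n_experiments),
                      stringsAsFactors = FALSE)
  kill <- ifelse(rows$cell_line == line_mutant, kill_mut[rows$i],
                 kill_corr[rows$i])
  noise <- stats::rnorm(nrow(rows), 0, noise_sd)
  tab <- data.frame(
    gene = truth$gene[rows$i],
    sirna = truth$sirna[rows$i],
    cell_line = rows$cell_line,
    experiment = rows$experiment,
    viability = 100 * 2^(-kill + noise),
    stringsAsFactors = FALSE)
  structure(list(table = tab, truth = truth,
                 seed = as.integer(seed),
                 truth_seed = as.integer(truth_seed)),
            class = "deconv_sim")
}

#' Simulate a drug-response panel
#'
#' Generates a panel of cell lines in two cohesion-status groups with known
#' division-corrected sensitivity structure: per line, the untreated arm
#' grows through `n_div` divisions drawn uniformly from `div_range`, and the
#' drawn per-division sensitivity (normal around the group mean) determines
#' the treated arm via `GI = sensitivity * n_div`.
#'
#' @param n_defective,n_intact Lines per group (default 7 and 7).
#' @param mean_sensitivity Named group means of percent inhibition per
#'   division, `c(defective = , intact = )`.
#' @param sd_sensitivity Within-group sd of per-division sensitivity.
#' @param div_range Range of the uniform division-count draw (3-day window:
#'   roughly 1.5-3.5 doublings).
#' @param v_t0 Seeding-day signal, identical across lines.
#' @param seed Seed.
#' @return List of class `drug_panel_sim`: `panel` (columns `cell_line`,
#'   `cohesion_status`, `v_t0`, `v_untreated`, `v_treated`) and `truth`
#'   (drawn `n_div` and `sensitivity` per line, plus the group parameters).
#' @export
simulate_drug_panel <- function(n_defective = 7L, n_intact = 7L,
                                mean_sensitivity = c(defective = 30,
                                                     intact = 12),
                                sd_sensitivity = 6,
                                div_range = c(1.5, 3.5),
                                v_t0 = 1000, seed = 1L) {
  set.seed(as.integer(seed))
  n <- n_defective + n_intact
  status <- c(rep("defective", n_defective), rep("intact", n_intact))
  n_div <- stats::runif(n, div_range[1L], div_range[2L])
  sens <- stats::rnorm(n, mean_sensitivity[status], sd_sensitivity)
  gi <- pmin(sens * n_div, 99)   # keep treated signal positive
  v_untreated <- v_t0 * 2^n_div
  v_treated <- v_untreated * (1 - gi / 100)
  panel <- data.frame(
    cell_line = c(sprintf("DEF%02d", seq_len(n_defective)),
                  sprintf("INT%02d", seq_len(n_intact))),
    cohesion_status = status,
    v_t0 = rep(v_t0, n),
    v_untreated = v_untreated,
    v_treated = v_treated,
    stringsAsFactors = FALSE)
  truth <- data.frame(cell_line = panel$cell_line,
                      cohesion_status = status,
                      n_div = n_div, sensitivity = sens,
                      stringsAsFactors = FALSE)
  structure(list(panel = panel, truth = truth,
                 mean_sensitivity = mean_sensitivity,
                 sd_sensitivity = sd_sensitivity, seed = as.integer(seed)),
            class = "drug_panel_sim")
}
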