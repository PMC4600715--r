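# Fixture builders. All fixtures are constructed in code; none are stored on
# disk.

# A small valid screen: `values` is a named list mapping "plate\rscreen" to
# the vector of sample-well log2 values for that physical plate. Each plate
# additionally carries one negative-control well (intensity = control_level
# on the linear scale). Screens are split across the two cell lines by
# `lines` (named: screen -> cell line).
make_screen <- function(values, lines, control_level = 100,
                        geometry = screen_geometry(4, 6)) {
  rows <- list()
  for (key in names(values)) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    plate <- parts[1L]; screen <- parts[2L]
    y <- values[[key]]
    n <- length(y)
    wells <- paste0("A", seq_len(n))
    rows[[key]] <- data.frame(
      screen = screen, cell_line = lines[[screen]], plate = plate,
      well = c(wells, "B1"),
      sirna = c(paste0("si", plate, ".", seq_len(n)), "NTC"),
      gene = c(paste0("G", plate, ".", seq_len(n)), ""),
      well_type = c(rep("sample", n), "negative_control"),
      intensity = c(2^y, control_level),
      stringsAsFactors = FALSE)
  }
  screen_dataset(do.call(rbind, rows), geometry = geometry)
}

# The balanced 2-plate x 2-screen toy: every plate-1 well exactly +1 log2
# unit above its plate-2 counterpart, screens identical. Least-squares
# solution: alpha = (+0.5, -0.5), beta = (0, 0).
balanced_toy <- function() {
  base <- c(10, 10.4, 10.8, 11.2)
  make_screen(
    values = list("P1\rS1" = base + 1, "P2\rS1" = base,
                  "P1\rS2" = base + 1, "P2\rS2" = base),
    lines = c(S1 = "mutant", S2 = "corrected"))
}

# Long-format deconvolution fixture: one gene, explicit per-line mean
# viabilities realized over two identical experiments.
make_deconv <- function(gene, vp, vm, n_sirnas = length(vp)) {
  do.call(rbind, lapply(seq_len(n_sirnas), function(i) {
    data.frame(gene = gene, sirna = paste0(gene, "#", i),
               cell_line = rep(c("mutant", "corrected"), each = 2),
               experiment = c(1, 2, 1, 2),
               viability = c(vm[i], vm[i], vp[i], vp[i]),
               stringsAsFactors = FALSE)
  }))
}

# Small config for fast genome-like simulations in tests.
small_sim_config <- function(truth_seed = 7, ...) {
  screen_sim_config(n_genes = 400, n_synthetic_lethal = 8, delta = 2,
                    truth_seed = truth_seed, ...)
}
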