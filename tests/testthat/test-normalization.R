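test_that("log transform is log2 and rejects non-positive intensities", {
  ds <- balanced_toy()
  ds$wells$intensity[1] <- 1024
  ds$wells$intensity[2] <- 1
  logdata <- log_transform(ds)
  expect_equal(logdata$wells$y_log[1], 10)
  expect_equal(logdata$wells$y_log[2], 0)
  bad <- ds
  bad$wells$intensity[3] <- -5
  expect_error(log_transform(bad), "non-positive")
  # empty wells are dropped and counted
  withempty <- ds
  withempty$wells <- rbind(withempty$wells, data.frame(
    screen = c("S1", "S2"), cell_line = c("mutant", "corrected"),
    plate = "P1", well = "C1", sirna = "none", gene = "",
    well_type = "empty", intensity = NA_real_))
  expect_message(out <- log_transform(withempty), "2 empty")
  expect_equal(attr(out, "n_empty_dropped"), 2L)
  expect_false(any(out$wells$well_type == "empty"))
})

test_that("balanced toy recovers the closed-form two-way means solution", {
  ds <- balanced_toy()
  logdata <- log_transform(ds)
  model <- fit_plate_screen_model(logdata)
  expect_equal(unname(model$alpha[c("P1", "P2")]), c(0.5, -0.5),
               tolerance = 1e-12)
  expect_equal(unname(model$beta), c(0, 0), tolerance = 1e-12)
  # against the independent balanced-design oracle
  w <- logdata$wells[logdata$wells$well_type == "sample", ]
  oracle <- balanced_two_way_oracle(w$y_log, w$plate, w$screen)
  expect_equal(model$mu, oracle$mu, tolerance = 1e-12)
  expect_equal(unname(model$alpha),
               as.vector(oracle$alpha[names(model$alpha)]),
               tolerance = 1e-12)
  expect_equal(unname(model$beta),
               as.vector(oracle$beta[names(model$beta)]),
               tolerance = 1e-12)
  # applying the model equalizes physical-plate means at the grand mean
  normd <- apply_normalization(logdata, model)
  wn <- normd$wells[normd$wells$well_type == "sample", ]
  plate_means <- tapply(wn$y_norm, paste(wn$plate, wn$screen), mean)
  expect_true(all(abs(plate_means - model$mu) < 1e-12))
})

test_that("constant data yields mu = c and zero offsets", {
  base <- rep(8, 4)
  ds <- make_screen(list("P1\rS1" = base, "P2\rS1" = base,
                         "P1\rS2" = base, "P2\rS2" = base),
                    lines = c(S1 = "mutant", S2 = "corrected"))
  model <- fit_plate_screen_model(log_transform(ds))
  expect_equal(model$mu, 8)
  expect_true(all(abs(model$alpha) < 1e-12))
  expect_true(all(abs(model$beta) < 1e-12))
})

test_that("fitted offsets sum to zero on random unbalanced designs", {
  for (seed in 1:5) {
    set.seed(seed)
    vals <- list()
    lines <- c(S1 = "mutant", S2 = "mutant", S3 = "corrected")
    for (p in c("P1", "P2", "P3")) for (s in names(lines))
      vals[[paste(p, s, sep = "\r")]] <- rnorm(sample(3:6, 1), 10, 1)
    model <- fit_plate_screen_model(log_transform(make_screen(vals, lines)))
    expect_lt(abs(sum(model$alpha)), 1e-9)
    expect_lt(abs(sum(model$beta)), 1e-9)
  }
})

test_that("unbalanced-design fit agrees with lm() under sum contrasts", {
  set.seed(42)
  vals <- list()
  lines <- c(S1 = "mutant", S2 = "corrected")
  for (p in c("P1", "P2", "P3")) for (s in names(lines))
    vals[[paste(p, s, sep = "\r")]] <- rnorm(sample(3:7, 1), 10, 1)
  ds <- make_screen(vals, lines)
  logdata <- log_transform(ds)
  model <- fit_plate_screen_model(logdata)
  w <- logdata$wells[logdata$wells$well_type == "sample", ]
  lmfit <- lm(y_log ~ plate + screen, data = w,
              contrasts = list(plate = "contr.sum", screen = "contr.sum"))
  cf <- coef(lmfit)
  expect_equal(model$mu, unname(cf[1]), tolerance = 1e-10)
  expect_equal(unname(model$alpha[1:2]), unname(cf[2:3]), tolerance = 1e-10)
  expect_equal(unname(model$beta[1]), unname(cf[4]), tolerance = 1e-10)
  expect_equal(model$residual_scale, summary(lmfit)$sigma, tolerance = 1e-10)
})

test_that("normalization preserves within-plate contrasts exactly", {
  sim <- simulate_screen(small_sim_config(), seed = 21)
  logdata <- log_transform(sim$dataset)
  model <- fit_plate_screen_model(logdata)
  normd <- apply_normalization(logdata, model)
  w <- normd$wells
  for (key in unique(paste(w$screen, w$plate))[1:4]) {
    sub <- w[paste(w$screen, w$plate) == key, ]
    expect_identical(diff(sub$y_norm), diff(sub$y_log))
  }
  # identity model leaves values untouched
  id <- model
  id$alpha[] <- 0; id$beta[] <- 0
  expect_identical(apply_normalization(logdata, id)$wells$y_norm,
                   logdata$wells$y_log)
  # unseen levels are errors
  shrunk <- model
  shrunk$alpha <- shrunk$alpha[-1]
  expect_error(apply_normalization(logdata, shrunk), "not covered")
})

test_that("noiseless synthetic screens recover planted offsets exactly", {
  cfg <- screen_sim_config(n_genes = 200, sigma_well = 0, frac_lethal = 0,
                           n_synthetic_lethal = 0, delta = 0,
                           truth_seed = 13)
  sim <- simulate_screen(cfg, seed = 1)
  model <- fit_plate_screen_model(log_transform(sim$dataset))
  expect_equal(model$alpha[names(sim$truth$alpha)], sim$truth$alpha,
               tolerance = 1e-9)
  expect_equal(model$beta[names(sim$truth$beta)], sim$truth$beta,
               tolerance = 1e-9)
  expect_equal(model$mu, cfg$mu, tolerance = 1e-9)
  # refitting on normalized data is idempotent: offsets collapse to zero
  normd <- apply_normalization(log_transform(sim$dataset), model)
  normd$wells$y_log <- normd$wells$y_norm
  refit <- fit_plate_screen_model(normd)
  expect_true(all(abs(refit$alpha) < 1e-9))
  expect_true(all(abs(refit$beta) < 1e-9))
})

test_that("rank-deficient designs raise errors naming the level", {
  ds <- balanced_toy()
  # make every P2 well a control so P2 has no sample wells
  bad <- ds
  bad$wells$well_type[bad$wells$plate == "P2"] <- "negative_control"
  expect_error(fit_plate_screen_model(log_transform(bad)), "P2")
})

test_that("control-relative viability matches the ratio definition", {
  # 8 controls with mean 100 and a 250-RFU sample well -> 250%
  ctrl <- c(90, 95, 100, 100, 100, 105, 105, 105)
  wells <- data.frame(
    screen = "S1", cell_line = "mutant", plate = "P1",
    well = paste0("A", 1:10),
    sirna = c("s1", "s2", rep("NTC", 8)),
    gene = c("g1", "g2", rep("", 8)),
    well_type = c("sample", "sample", rep("negative_control", 8)),
    intensity = c(250, 50, ctrl), stringsAsFactors = FALSE)
  wells2 <- wells
  wells2$screen <- "S2"; wells2$cell_line <- "corrected"
  ds <- screen_dataset(rbind(wells, wells2))
  cv <- normalize_to_controls(ds)
  expect_equal(cv$wells$viability[cv$wells$sirna == "s1" &
                                    cv$wells$screen == "S1"], 250)
  expect_equal(cv$wells$viability[cv$wells$sirna == "s2" &
                                    cv$wells$screen == "S1"], 50)
  # a control well when all controls are equal is exactly 100%
  eq <- ds
  eq$wells$intensity[eq$wells$well_type == "negative_control"] <- 100
  cve <- normalize_to_controls(eq)
  expect_true(all(cve$wells$viability[
    cve$wells$well_type == "negative_control"] == 100))
  # per-siRNA summary aggregates across screens within cell line
  expect_equal(sort(unique(cv$per_sirna$cell_line)),
               c("corrected", "mutant"))
  expect_equal(cv$per_sirna$mean_viability[cv$per_sirna$sirna == "s1" &
                                             cv$per_sirna$cell_line == "mutant"],
               250)
})

test_that("planted differential effects are recovered without bias", {
  # Normalization + group contrast is unbiased for the planted effect when
  # the synthetic-lethal fraction is small (genome-like 0.25% here). The
  # screen offsets absorb the library-average differential signal, so the
  # structural attenuation is delta * fraction_SL -- negligible at scale.
  deltas <- numeric(200)
  cfg <- screen_sim_config(n_genes = 2000, n_synthetic_lethal = 5,
                           delta = 1.2, truth_seed = 5)
  truth_genes <- simulate_screen(cfg, seed = 1)$truth$genes
  planted <- truth_genes$gene[truth_genes$is_synthetic_lethal]
  for (r in seq_len(200)) {
    sim <- simulate_screen(cfg, seed = 3000 + r)
    suppressMessages({
      logdata <- log_transform(sim$dataset)
      normd <- apply_normalization(logdata, fit_plate_screen_model(logdata))
      res <- moderated_test(normd, "mutant", "corrected")
    })
    deltas[r] <- mean(res$effect[res$gene %in% planted])
  }
  bias <- mean(deltas) - 1.2
  mc_se <- sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(bias), 3 * mc_se + 1e-12)
})
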