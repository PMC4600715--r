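test_that("prior recovery: moment estimator finds planted d0 and s0^2", {
  set.seed(101)
  n <- 20000; d0 <- 4; s0sq <- 1; d <- 3
  s2 <- s0sq * (rchisq(n, d) / d) / (rchisq(n, d0) / d0)
  pr <- estimate_prior(s2, d)
  expect_lt(abs(pr$d0 - d0) / d0, 0.10)
  expect_lt(abs(pr$s0sq - s0sq) / s0sq, 0.05)
  # independent cross-check against limma's F-distribution fit
  skip_if_not_installed("limma")
  f <- limma::fitFDist(s2, df1 = d)
  expect_equal(pr$d0, f$df2, tolerance = 1e-6)
  expect_equal(pr$s0sq, f$scale, tolerance = 1e-6)
})

test_that("equal variances force an infinite-d0 prior at that value", {
  pr <- estimate_prior(rep(0.25, 50), df = 3)
  expect_true(is.infinite(pr$d0))
  # with d0 = Inf the geometric-mean estimate is bias-corrected for the
  # chi-square: log s0^2 = mean(z) - digamma(d/2) + log(d/2)
  expect_equal(log(pr$s0sq), log(0.25) - digamma(1.5) + log(1.5))
  expect_equal(shrink_variances(c(0.1, 0.9), 3, pr), rep(pr$s0sq, 2))
})

test_that("two wildly different variances give a finite prior matching the bisection oracle", {
  s2 <- c(0.001, 10)
  pr <- estimate_prior(s2, df = 3)
  oracle <- prior_moment_oracle(s2, 3)
  expect_true(is.finite(pr$d0) && pr$d0 > 0)
  expect_equal(pr$d0, oracle$d0, tolerance = 1e-6)
  expect_equal(pr$s0sq, oracle$s0sq, tolerance = 1e-6)
  # moderated variances interpolate strictly between raw value and prior
  sm <- shrink_variances(s2, 3, pr)
  expect_true(sm[1] > s2[1] && sm[1] < pr$s0sq)
  expect_true(sm[2] < s2[2] && sm[2] > pr$s0sq)
})

test_that("degenerate variance input is an error", {
  expect_error(estimate_prior(c(0, 0, 0), df = 3), "zero")
})

test_that("moderated toy matches the frozen step-by-step hand calculation", {
  # mutant {0.9, 1.0, 1.1}, corrected {2.0, 2.1}; prior d0 = 4, s0^2 = 0.01
  # delta = 2.05 - 1.0 = 1.05
  # ss_mutant = 0.02, ss_corrected = 0.005 -> s2 = 0.025/3
  # s2_mod = (4*0.01 + 3*(0.025/3)) / 7 = 0.065/7
  # t = 1.05 / sqrt((0.065/7) * (1/3 + 1/2))
  wells <- data.frame(
    screen = c("M1", "M2", "M3", "C1", "C2"),
    cell_line = c(rep("mutant", 3), rep("corrected", 2)),
    plate = "P1",
    well = "A1",
    sirna = "siX", gene = "X", well_type = "sample",
    y_norm = c(0.9, 1.0, 1.1, 2.0, 2.1), stringsAsFactors = FALSE)
  prior <- structure(list(d0 = 4, s0sq = 0.01, n_used = NA),
                     class = "shrinkage_prior")
  res <- moderated_test(wells, "mutant", "corrected", prior = prior)
  s2_hand <- (0.02 + 0.005) / 3
  s2mod_hand <- (4 * 0.01 + 3 * s2_hand) / 7
  t_hand <- 1.05 / sqrt(s2mod_hand * (1 / 3 + 1 / 2))
  expect_equal(res$effect, 1.05)
  expect_equal(res$n_minus, 3L)
  expect_equal(res$n_plus, 2L)
  expect_equal(res$s2, s2_hand)
  expect_equal(res$s2_mod, s2mod_hand)
  expect_equal(res$t_mod, t_hand)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df = 7))
})

test_that("at d0 -> 0 the moderated statistic reduces to the pooled t-test", {
  set.seed(7)
  wells <- data.frame(
    screen = rep(c("M1", "M2", "M3", "C1", "C2", "C3"), times = 20),
    cell_line = rep(rep(c("mutant", "corrected"), each = 3), times = 20),
    plate = "P1", well = "A1",
    sirna = rep(sprintf("si%02d", 1:20), each = 6),
    gene = rep(sprintf("g%02d", 1:20), each = 6),
    well_type = "sample",
    y_norm = rnorm(120), stringsAsFactors = FALSE)
  prior0 <- structure(list(d0 = 1e-12, s0sq = 1, n_used = NA),
                      class = "shrinkage_prior")
  res <- moderated_test(wells, "mutant", "corrected", prior = prior0)
  for (s in res$sirna[1:5]) {
    y <- wells$y_norm[wells$sirna == s]
    grp <- wells$cell_line[wells$sirna == s]
    tt <- t.test(y[grp == "corrected"], y[grp == "mutant"],
                 var.equal = TRUE)
    i <- which(res$sirna == s)
    expect_equal(res$t_mod[i], unname(tt$statistic), tolerance = 1e-6)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-6)
  }
})

test_that("zero effect gives t = 0 and p = 1; infinite d0 uses the normal", {
  wells <- data.frame(
    screen = c("M1", "M2", "C1", "C2"),
    cell_line = c("mutant", "mutant", "corrected", "corrected"),
    plate = "P1", well = "A1", sirna = "siX", gene = "X",
    well_type = "sample",
    y_norm = c(1, 2, 1, 2), stringsAsFactors = FALSE)
  prior <- structure(list(d0 = 4, s0sq = 0.5, n_used = NA),
                     class = "shrinkage_prior")
  res <- moderated_test(wells, "mutant", "corrected", prior = prior)
  expect_equal(res$t_mod, 0)
  expect_equal(res$p, 1)
  prior_inf <- structure(list(d0 = Inf, s0sq = 0.5, n_used = NA),
                         class = "shrinkage_prior")
  wells$y_norm <- c(1, 2, 3, 4)
  res2 <- moderated_test(wells, "mutant", "corrected", prior = prior_inf)
  z <- res2$effect / sqrt(0.5 * (1 / 2 + 1 / 2))
  expect_equal(res2$p, 2 * pnorm(-abs(z)))
})

test_that("siRNAs missing from one group are excluded with a count", {
  wells <- data.frame(
    screen = c("M1", "M2", "C1", "C2", "M1", "M2"),
    cell_line = c("mutant", "mutant", "corrected", "corrected",
                  "mutant", "mutant"),
    plate = "P1", well = c("A1", "A1", "A1", "A1", "A2", "A2"),
    sirna = c(rep("siA", 4), rep("siB", 2)),
    gene = c(rep("A", 4), rep("B", 2)), well_type = "sample",
    y_norm = c(1, 1.2, 2, 2.2, 5, 5.1), stringsAsFactors = FALSE)
  prior <- structure(list(d0 = 4, s0sq = 0.1, n_used = NA),
                     class = "shrinkage_prior")
  expect_message(res <- moderated_test(wells, "mutant", "corrected",
                                       prior = prior), "excluded 1")
  expect_equal(res$sirna, "siA")
  expect_equal(attr(res, "n_excluded_one_group"), 1L)
})

test_that("BH q-values match the brute-force step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(11)
  for (i in 1:500) {
    m <- sample(1:8, 1)
    p <- round(runif(m), 3)
    expect_equal(bh_fdr(p), bh_oracle(p))
  }
  # permutation invariance and monotonicity over ranked p
  set.seed(12)
  p <- runif(30)
  q <- bh_fdr(p)
  perm <- sample(30)
  expect_equal(bh_fdr(p[perm]), q[perm])
  expect_false(is.unsorted(q[order(p)]))
  expect_true(all(q >= p))
})

test_that("hit selection honours the inclusive FDR gate and direction filter", {
  res <- data.frame(
    sirna = c("a", "b", "c", "d"), gene = c("A", "B", "C", "D"),
    effect = c(0.8, -0.9, 0.5, 0.1),
    p = c(0.001, 0.002, 0.04, 0.2),
    q = c(0.05, 0.05, 0.10, 0.40))
  hits <- select_hits(res, fdr_max = 0.10, direction = "mutant_lethal")
  # q = 0.10 exactly is selected; the significant wrong-direction siRNA is not
  expect_setequal(hits$sirna, c("a", "c"))
  excl <- attr(hits, "exclusions")
  expect_equal(unname(excl["greater lethality in corrected line"]), 1L)
  both <- select_hits(res, fdr_max = 0.10, direction = "either")
  expect_setequal(both$sirna, c("a", "b", "c"))
  # sorted ascending by q then p; empty input is valid
  expect_false(is.unsorted(hits$q))
  expect_equal(nrow(select_hits(res[0, ])), 0L)
})

test_that("hit curation arithmetic is auditable", {
  hits <- sprintf("H%03d", 1:113)
  curated <- curate_hits(hits, exclude = hits[1:32],
                         include = sprintf("X%02d", 1:17))
  counts <- attr(curated, "counts")
  expect_equal(unname(counts), c(113L, 32L, 17L, 98L))
  expect_length(curated, 98L)
  expect_error(curate_hits(hits, include = hits[50]), "overlaps")
})

test_that("moderated pipeline agrees with limma lmFit/eBayes on a toy screen", {
  skip_if_not_installed("limma")
  set.seed(33)
  G <- 50
  M <- matrix(rnorm(G * 6, 10), G, 6,
              dimnames = list(sprintf("si%02d", 1:G),
                              c("M1", "M2", "M3", "C1", "C2", "C3")))
  M[1:5, 4:6] <- M[1:5, 4:6] + 2
  wells <- data.frame(
    screen = rep(colnames(M), each = G),
    cell_line = rep(c("mutant", "corrected"), each = 3 * G),
    plate = "P1", well = "A1",
    sirna = rep(rownames(M), 6),
    gene = rep(rownames(M), 6),
    well_type = "sample",
    y_norm = as.vector(M), stringsAsFactors = FALSE)
  res <- moderated_test(wells, "mutant", "corrected")
  design <- cbind(1, rep(c(0, 1), each = 3))
  eb <- limma::eBayes(limma::lmFit(M, design))
  i <- match(res$sirna, rownames(M))
  expect_equal(res$effect, unname(eb$coefficients[i, 2]), tolerance = 1e-9)
  expect_equal(res$s2_mod, unname(eb$s2.post[i]), tolerance = 1e-6)
  expect_equal(res$t_mod, unname(eb$t[i, 2]), tolerance = 1e-6)
  expect_equal(res$p, unname(eb$p.value[i, 2]), tolerance = 1e-6)
})
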