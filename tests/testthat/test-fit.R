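lsched <- csptitr:::default_schedule(0.4, 12, kd = 0.1)

test_that("noiseless fits recover the generating constant to 1e-6 relative", {
  for (kd in c(0.02, 0.1, 0.5)) {
    y <- 0.2 * fraction_bound(kd, 0.4, lsched)
    fit <- fit_residue(y, lsched, 0.4)
    expect_equal(fit$kd, kd, tolerance = 1e-6)
    expect_equal(fit$ddmax, 0.2, tolerance = 1e-6)
    expect_lt(fit$residual_rms, 1e-8)
    expect_true(fit$converged)
  }
})

test_that("the optimum never sits above the truth objective", {
  ## no spurious optimum accepted: on noiseless data the returned objective
  ## must be <= the objective at the true parameters (which is 0)
  y <- 0.15 * fraction_bound(0.05, 0.4, lsched)
  fit <- fit_residue(y, lsched, 0.4)
  rss_true <- sum((y - 0.15 * fraction_bound(0.05, 0.4, lsched))^2)
  expect_lte(fit$residual_rms^2 * length(y), rss_true + 1e-12)
})

test_that("degenerate fit inputs are rejected", {
  expect_error(fit_residue(rep(0, 12), lsched, 0.4), "no signal")
  expect_error(fit_residue(c(0, 0.1, 0.15, 0.18), lsched[1:4], 0.4),
               "at least 5")
})

test_that("single-residue noisy recovery has median within 15% of truth", {
  set.seed(31)
  kds <- replicate(100, {
    y <- 0.15 * fraction_bound(0.0189, 0.4, lsched) + rnorm(12, 0, 0.003)
    y[1] <- 0
    fit_residue(y, lsched, 0.4)$kd
  })
  expect_lt(abs(median(kds) - 0.0189) / 0.0189, 0.15)
})

test_that("reporter selection respects class, completeness and overlap", {
  Y <- rbind(c(0, 0.06, 0.12), c(0, 0.05, 0.10), c(0, 0.045, 0.09),
             c(0, 0.04, 0.08), c(0, 0.001, 0.002), c(0, 0.002, 0.003),
             c(0, 0.001, 0.001), c(0, 0.002, 0.002), c(0, 0.001, 0.002),
             c(0, 0.001, 0.001))
  tr <- make_tracks_from_curves(Y, ligand_totals = c(0, 1, 5))
  tr$overlapped[2] <- TRUE                 # significant but overlapped
  tr$status[3] <- "lost_after_1"           # significant but incomplete
  ## k*sigma rule: with 4 strong responders among 10 residues the
  ## mean-offset threshold would sit above the weakest of them
  tab <- classify_significance(tr, rule = "ksigma")
  sel <- select_reporters(tab, tr)
  expect_true(102 %in% tab$residue[tab$class %in% c("1sigma", "2sigma")])
  expect_false(102 %in% sel)
  expect_false(103 %in% sel)
  expect_true(all(c(101, 104) %in% sel))
  ## all non-significant -> empty set
  flat <- make_tracks_from_curves(matrix(rep(c(0, 0.01, 0.01), 5), 5,
                                         byrow = TRUE),
                                  ligand_totals = c(0, 1, 5))
  expect_length(select_reporters(classify_significance(flat), flat), 0)
})

test_that("identical noiseless reporters give kd_sd 0 and agreeing modes", {
  y <- 0.2 * fraction_bound(0.1, 0.4, lsched)
  Y <- matrix(rep(y, 5), 5, byrow = TRUE)
  tr <- make_tracks_from_curves(Y, ligand_totals = lsched)
  f1 <- fit_binding(tr, reporters = 101:105, mode = "per_residue_average")
  f2 <- fit_binding(tr, reporters = 101:105, mode = "shared_kd")
  expect_equal(f1$kd_mean_uM, 100, tolerance = 1e-5)
  expect_equal(f1$kd_sd_uM, 0, tolerance = 1e-6)
  expect_equal(f2$kd_mean_uM, f1$kd_mean_uM, tolerance = 1e-5)
  expect_equal(f2$kd_sd_uM, 0, tolerance = 1e-6)
  ## normalised curve anchored at zero for no ligand
  expect_equal(f1$curve$mean_norm[1], 0)
  expect_equal(f2$curve$mean_norm[1], 0)
  expect_equal(f1$n, 5L)
  expect_error(fit_binding(tr, reporters = 101:102), "at least 3")
})

test_that("fit methods are coherent: coef, predict, fitted, residuals, simulate", {
  set.seed(41)
  Y <- t(replicate(6, 0.18 * fraction_bound(0.05, 0.4, lsched) +
                     c(0, rnorm(11, 0, 0.003))))
  tr <- make_tracks_from_curves(Y, ligand_totals = lsched)
  fit <- fit_binding(tr, reporters = 101:106)
  expect_s3_class(fit, "csp_fit")
  co <- coef(fit)
  expect_equal(unname(co["n"]), 6)
  expect_equal(unname(co["kd_uM"]), fit$kd_mean_uM)
  p <- predict(fit, ligand_total = c(0, 0.4, 4.8))
  expect_equal(p[1], 0)
  expect_true(all(diff(p) > 0))
  expect_equal(dim(residuals(fit)), dim(Y))
  expect_equal(fitted(fit) + residuals(fit), fit$Y, ignore_attr = TRUE)
  sims <- simulate(fit, nsim = 3, seed = 7)
  expect_equal(dim(sims), c(3L, 12L))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 7))
  expect_output(print(summary(fit)), "Per-residue")
  ## plot method draws without error
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
})

test_that("pooled recovery bias stays within 10% across the kd grid", {
  ## direct estimator check at the default design: 20 reporters with
  ## ddmax 0.05-0.30, noise 0.003 ppm, 12-point schedule to 1:12
  set.seed(53)
  grid <- c(0.005, 0.02, 0.1, 0.3, 0.6)
  relsd <- numeric(length(grid))
  for (g in seq_along(grid)) {
    kd <- grid[g]
    means <- replicate(200, {
      dd <- runif(20, 0.05, 0.30)
      f <- fraction_bound(kd, 0.4, lsched)
      kds <- vapply(dd, function(d) {
        y <- d * f + rnorm(12, 0, 0.003); y[1] <- 0
        fit_residue(y, lsched, 0.4)$kd
      }, 0)
      mean(kds)
    })
    expect_lt(abs(mean(means) - kd) / kd, 0.10)
    relsd[g] <- sd(means) / kd
  }
  ## identifiability degrades at the tight end, where the curve saturates
  ## stoichiometrically and barely depends on kd
  expect_gt(relsd[1], relsd[3])
  ## ... and once kd exceeds the maximum ligand concentration (4.8 mM
  ## here), where the curve is never saturated and amplitude trades off
  ## against kd until identifiability is lost altogether
  weak <- vapply(c(1, 2, 8), function(kd) {
    means <- replicate(100, {
      dd <- runif(20, 0.05, 0.30)
      f <- fraction_bound(kd, 0.4, lsched)
      mean(vapply(dd, function(d) {
        y <- d * f + rnorm(12, 0, 0.003); y[1] <- 0
        fit_residue(y, lsched, 0.4)$kd
      }, 0))
    })
    sd(means) / kd
  }, 0)
  expect_true(all(diff(weak) > 0))
})

test_that("shared-kd and per-residue pooling agree on well-behaved data", {
  set.seed(61)
  f <- fraction_bound(0.08, 0.4, lsched)
  Y <- t(sapply(runif(12, 0.08, 0.3), function(d) {
    y <- d * f + rnorm(12, 0, 0.003); y[1] <- 0; y
  }))
  tr <- make_tracks_from_curves(Y, ligand_totals = lsched)
  f1 <- fit_binding(tr, reporters = tr$residues, mode = "per_residue_average")
  f2 <- fit_binding(tr, reporters = tr$residues, mode = "shared_kd")
  tol <- 2 * sqrt(f1$kd_sd_uM^2 / f1$n + f2$kd_sd_uM^2)
  expect_lt(abs(f1$kd_mean_uM - f2$kd_mean_uM), max(tol, 5))
})
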