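test_that("scaled distance evaluates the combined-shift metric", {
  a <- list(h_ppm = 8.00, n_ppm = 120.0)
  b <- list(h_ppm = 8.03, n_ppm = 120.2)
  expect_equal(scaled_distance(a, b, alpha = 0.154), 0.0429958137,
               tolerance = 1e-8)
  expect_equal(scaled_distance(a, a), 0)
  expect_equal(scaled_distance(a, b), scaled_distance(b, a))
  ## pure-1H displacement is alpha-independent
  c1 <- list(h_ppm = 8.05, n_ppm = 120.0)
  for (al in c(0.1, 0.154, 0.5))
    expect_equal(scaled_distance(a, c1, alpha = al), 0.05)
  expect_error(scaled_distance(a, b, alpha = -1), "alpha")
})

test_that("noiseless tracking recovers the ground-truth correspondence exactly", {
  truth <- make_truth(resno = 101:115, kd = 0.05,
                      ddmax = seq(0.01, 0.29, length.out = 15),
                      theta = seq(0.1, 6, length.out = 15))
  series <- simulate_titration(truth)
  tracks <- track_series(series)
  expect_true(all(tracks$status == "complete"))
  expect_true(all(tracks_correct(tracks, series, truth$residues$resno)))
  ## endpoint deltas equal f * ddmax * direction to machine precision
  f_end <- fraction_bound(0.05, 0.4, max(truth$model$ligand_schedule))
  K <- ncol(tracks$h)
  ord <- match(truth$residues$resno, tracks$residues)
  expect_equal(tracks$ddh[ord, K],
               f_end * truth$residues$ddmax * cos(truth$residues$theta),
               tolerance = 1e-12)
  expect_equal(tracks$ddn[ord, K],
               f_end * truth$residues$ddmax * sin(truth$residues$theta) / 0.154,
               tolerance = 1e-12)
  expect_equal(unname(tracks$ddh[, 1]), rep(0, 15))
})

test_that("tracking is one-to-one and invariant to peak order", {
  truth <- default_scenario("fc14-like", seed = 4)
  series <- simulate_titration(truth)
  tracks <- track_series(series)
  for (k in seq_along(series$points)) {
    j <- tracks$peak_index[, k]
    expect_false(any(duplicated(j[!is.na(j)])))
  }
  ## permute every point's peaks: same residue trajectories
  set.seed(99)
  shuffled <- titration_series(lapply(series$points, function(pl) {
    pl$peaks <- pl$peaks[sample.int(nrow(pl$peaks)), , drop = FALSE]
    rownames(pl$peaks) <- NULL
    pl
  }))
  t2 <- track_series(shuffled)
  ord <- match(tracks$residues, t2$residues)
  expect_equal(t2$h[ord, ], tracks$h, ignore_attr = TRUE)
  expect_equal(t2$status[ord], tracks$status)
})

test_that("a step exceeding max_step loses the track from that point on", {
  mk <- function(h2) {
    p1 <- peak_list(data.frame(id = c("a", "b"), h_ppm = c(8.0, 9.0),
                               n_ppm = 115, resno = c(1L, 2L), restype = "A"),
                    point_index = 0L, ligand_total = 0)
    p2 <- peak_list(data.frame(id = c("a", "b"), h_ppm = c(8.01, h2),
                               n_ppm = 115), point_index = 1L,
                    ligand_total = 1)
    p3 <- peak_list(data.frame(id = c("a", "b"), h_ppm = c(8.02, h2),
                               n_ppm = 115), point_index = 2L,
                    ligand_total = 2)
    titration_series(list(p1, p2, p3))
  }
  tr <- track_series(mk(9.2), max_step = 0.05)   # 0.2 ppm jump at point 1
  expect_equal(tr$status[tr$residues == 2], "lost_after_0")
  expect_true(all(is.na(tr$h[tr$residues == 2, 2:3])))
  expect_equal(tr$status[tr$residues == 1], "complete")
  tr2 <- track_series(mk(9.04), max_step = 0.05) # within max_step: kept
  expect_true(all(tr2$status == "complete"))
  expect_error(track_series(titration_series(list(
    peak_list(data.frame(id = "a", h_ppm = 8, n_ppm = 115, resno = 1L,
                         restype = "A"))))), "at least two")
})

test_that("binder tracks are >=98% fully correct under default noise", {
  n_ok <- 0L; n_tot <- 0L
  for (seed in 1:20) {
    truth <- default_scenario("fc14-like", seed = seed)
    series <- simulate_titration(truth)
    tracks <- track_series(series)
    binders <- truth$residues$resno[truth$residues$binder]
    ok <- tracks_correct(tracks, series, binders)
    n_ok <- n_ok + sum(ok); n_tot <- n_tot + length(ok)
  }
  expect_gte(n_ok / n_tot, 0.98)
})

test_that("overlap flags mark co-resident peaks symmetrically", {
  p1 <- peak_list(data.frame(id = c("a", "b", "c"),
                             h_ppm = c(8.000, 8.005, 9.0), n_ppm = 115,
                             resno = 1:3, restype = "A"),
                  point_index = 0L, ligand_total = 0)
  p2 <- peak_list(data.frame(id = c("a", "b", "c"),
                             h_ppm = c(8.000, 8.005, 9.0), n_ppm = 115),
                  point_index = 1L, ligand_total = 1)
  series <- titration_series(list(p1, p2))
  tracks <- flag_overlap(series, track_series(series), overlap_tol = 0.01)
  expect_equal(tracks$overlapped, c(TRUE, TRUE, FALSE))
})

test_that("well-separated noiseless simulations have no overlap flags", {
  truth <- make_truth(resno = 101:120, ddmax = rep(0.02, 20))
  series <- simulate_titration(truth)
  tracks <- flag_overlap(series, track_series(series))
  expect_equal(sum(tracks$overlapped), 0L)
})

test_that("decoy crowding raises the overlapped count monotonically", {
  ## residue noise is independent of the decoy stream and decoy sets are
  ## nested across counts, so crowding is the only thing that varies;
  ## aggregated over seeds the overlapped count grows with decoy density
  counts <- vapply(c(0L, 20L, 50L), function(dc) {
    sum(vapply(1:10, function(seed) {
      truth <- default_scenario("fc14-like", seed = seed, decoy_count = dc)
      series <- simulate_titration(truth)
      sum(flag_overlap(series, track_series(series))$overlapped)
    }, 0L))
  }, 0L)
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[3], counts[1])
})
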