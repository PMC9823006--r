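test_that("PDB reading: residues, altloc resolution, coordinate round trip", {
  f <- withr::local_tempfile(fileext = ".pdb")
  co <- extended_chain(3)
  write_test_pdb(co, f)
  m <- read_structure(f)
  expect_s3_class(m, "structure_model")
  ca <- csptitr:::chain_ca(m, "A")
  expect_equal(nrow(ca), 3L)
  expect_equal(ca$x, co$x, tolerance = 1e-3)
  ## altloc A/B on one residue: the higher-occupancy conformer wins
  co2 <- rbind(
    data.frame(chain = "A", resno = 1, x = 1, y = 0, z = 0,
               alt = "A", occ = 0.3),
    data.frame(chain = "A", resno = 1, x = 2, y = 0, z = 0,
               alt = "B", occ = 0.7),
    data.frame(chain = "A", resno = 2, x = 5, y = 0, z = 0,
               alt = "", occ = 1),
    data.frame(chain = "A", resno = 3, x = 9, y = 0, z = 0,
               alt = "", occ = 1))
  write_test_pdb(co2, f)
  m2 <- read_structure(f)
  ca2 <- csptitr:::chain_ca(m2, "A")
  expect_equal(nrow(ca2), 3L)
  expect_equal(ca2$x[ca2$resno == 1], 2)
  expect_error(read_structure(f, format = "xyz"), "unknown format")
})

test_that("superposition: identity, rigid invariance, proper rotation", {
  f <- withr::local_tempfile(fileext = ".pdb")
  a <- walk_chain(40, "A", seed = 5)
  ## b: rigidly rotated + translated copy of a
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz_b <- as.matrix(a[, c("x", "y", "z")]) %*% R +
    matrix(rep(c(10, -4, 2), each = 40), ncol = 3)
  b <- data.frame(chain = "B", resno = a$resno,
                  x = xyz_b[, 1], y = xyz_b[, 2], z = xyz_b[, 3])
  write_test_pdb(rbind(a, b), f)
  m <- read_structure(f)
  s_self <- superpose(m, "A", "A")
  expect_lt(s_self$rmsd, 1e-9)
  ## the exact-coordinate algorithm recovers a rigid transform to machine
  ## precision; through the 3-decimal PDB fields the floor is ~0.5 mA
  k <- csptitr:::kabsch(as.matrix(a[, c("x", "y", "z")]), xyz_b)
  expect_lt(k$rmsd, 1e-9)
  expect_equal(det(k$rotation), 1, tolerance = 1e-9)
  s <- superpose(m, "A", "B")
  expect_lt(s$rmsd, 2e-3)
  expect_equal(det(s$rotation), 1, tolerance = 1e-9)
  expect_equal(s$n_atoms, 40L)
  ## symmetric in its arguments
  expect_equal(superpose(m, "B", "A")$rmsd, s$rmsd, tolerance = 1e-6)
})

test_that("superposition rmsd matches the bio3d fit and the jitter oracle", {
  sigma <- 0.5; N <- 60
  a <- walk_chain(N, "A", seed = 11)
  xa <- as.matrix(a[, c("x", "y", "z")])
  set.seed(12)
  my_rmsd <- replicate(40, {
    xb <- xa + rnorm(3 * N, 0, sigma)
    f <- withr::local_tempfile(fileext = ".pdb")
    b <- data.frame(chain = "B", resno = a$resno,
                    x = xb[, 1], y = xb[, 2], z = xb[, 3])
    write_test_pdb(rbind(a, b), f)
    m <- read_structure(f)
    s <- superpose(m, "A", "B")
    ## dual route: bio3d least-squares fit must agree on the same pair
    xyz_fit <- suppressWarnings(
      bio3d::fit.xyz(fixed = as.vector(t(xb)), mobile = as.vector(t(xa))))
    bio_rmsd <- sqrt(mean(colSums(matrix((xyz_fit - as.vector(t(xb)))^2,
                                         nrow = 3))))
    ## both routes see the 3-decimal PDB coordinates; agreement to ~1e-4
    expect_equal(s$rmsd, bio_rmsd, tolerance = 1e-3)
    s$rmsd
  })
  ## Monte-Carlo oracle for the expected post-fit rmsd under the jitter model
  mc <- replicate(300, {
    xb <- xa + rnorm(3 * N, 0, sigma)
    csptitr:::kabsch(xa, xb)$rmsd
  })
  se <- sqrt(var(mc) / length(mc) + var(my_rmsd) / length(my_rmsd))
  expect_lt(abs(mean(my_rmsd) - mean(mc)), 4 * se + 0.01)
})

test_that("mean pairwise rmsd over chains: duplicates, symmetry, jitter", {
  f <- withr::local_tempfile(fileext = ".pdb")
  a <- walk_chain(30, "A", seed = 21)
  b <- a; b$chain <- "B"
  set.seed(22)
  c3 <- a; c3$chain <- "C"
  c3$x <- c3$x + rnorm(30, 0, 0.3)
  c3$y <- c3$y + rnorm(30, 0, 0.3)
  c3$z <- c3$z + rnorm(30, 0, 0.3)
  write_test_pdb(rbind(a, b, c3), f)
  m <- read_structure(f)
  dup <- mean_pairwise_rmsd(m, chains = c("A", "B"))
  expect_lt(dup$mean_rmsd, 1e-9)
  all3 <- mean_pairwise_rmsd(m)
  expect_equal(all3$matrix, t(all3$matrix))
  expect_equal(diag(all3$matrix), rep(0, 3), ignore_attr = TRUE)
  expect_equal(all3$common_residues, 30L)
  expect_gt(all3$matrix["A", "C"], 0.1)
  expect_error(mean_pairwise_rmsd(m, chains = "A"), "at least 2")
})

test_that("CSP painting fills the B-factor field without moving atoms", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_test_pdb(extended_chain(5, "B"), f)
  m <- read_structure(f)
  tab <- csptitr:::new_csp_table(
    data.frame(residue = c(1L, 2L, 3L, 9L),
               dd_h = NA_real_, dd_n = NA_real_,
               dd = c(0.043, 0.30, NA, 0.1),
               class = c("2sigma", "1sigma", "unassigned", "ns")),
    rule = "mean_plus_ksigma", alpha = 0.154)
  out <- withr::local_tempfile(fileext = ".pdb")
  r <- paint_csp(m, tab, chain = "B", path = out)
  painted <- read_structure(out)
  ca <- painted$atoms[painted$atoms$elety == "CA", ]
  expect_equal(ca$b[ca$resno == 1], 4.30, tolerance = 1e-6)
  expect_equal(ca$b[ca$resno == 2], 30.0, tolerance = 1e-6)
  expect_equal(ca$b[ca$resno == 3], 0)     # unassigned -> 0
  ## coordinates untouched, scale documented in the header
  expect_equal(ca$x, csptitr:::chain_ca(m, "B")$x, tolerance = 1e-3)
  expect_match(readLines(out)[1], "X 100")
  rep_lines <- readLines(r$report_path)
  expect_true(any(grepl("table_only\t9", rep_lines)))
  expect_true(any(grepl("model_only\t3", rep_lines)))
  expect_error(paint_csp(m, tab, chain = "Z", path = out), "chain Z")
})

test_that("patch clustering: adjacent residues are compact, full set is null", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_test_pdb(extended_chain(10), f)
  m <- read_structure(f)
  ## three sequence-adjacent residues on an extended chain: the exact null
  ## tail is 8 consecutive triples / choose(10,3) = 120 subsets = 0.0667
  pc <- patch_clustering(m, "A", significant = 1:3, n_perm = 2000, seed = 5)
  expect_equal(pc$observed, mean(c(3.8, 3.8, 7.6)), tolerance = 1e-6)
  expect_gt(pc$p_value, 0.0667 - 0.03)
  expect_lt(pc$p_value, 0.0667 + 0.03)
  ## scattered set is not compact
  ps <- patch_clustering(m, "A", significant = c(1, 5, 10), n_perm = 500,
                         seed = 5)
  expect_gt(ps$p_value, 0.5)
  ## the full residue set can only match itself -> p = 1
  pa <- patch_clustering(m, "A", significant = 1:10, n_perm = 500, seed = 5)
  expect_equal(pa$p_value, 1)
  ## reproducible under fixed seed, p in (0, 1]
  pc2 <- patch_clustering(m, "A", significant = 1:3, n_perm = 2000, seed = 5)
  expect_identical(pc$p_value, pc2$p_value)
  expect_true(pc$p_value > 0 && pc$p_value <= 1)
  expect_error(patch_clustering(m, "A", 1:3, n_perm = 0), "n_perm")
  expect_error(patch_clustering(m, "A", 1:2), "fewer than 3")
})
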