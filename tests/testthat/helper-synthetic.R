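## Shared fixtures: all synthetic inputs are built in code at test time.

## Independent bisection oracle for the bound fraction: solves the mass
## balance Kd = [P][L]/[PL] at fixed totals by root finding, without using
## the closed-form quadratic that fraction_bound() implements.
frac_oracle <- function(kd, pt, lt) {
  if (lt == 0) return(0)
  g <- function(pl) kd * pl - (pt - pl) * (lt - pl)
  stats::uniroot(g, c(0, min(pt, lt)), tol = 1e-15)$root / pt
}

## Hand-built ground truth with explicit geometry (deterministic free
## positions on a grid, so peaks are well separated unless stated).
make_truth <- function(resno = 101:110,
                       ddmax = rep(0.2, length(resno)),
                       theta = rep(pi / 4, length(resno)),
                       kd = 0.1, protein_total = 0.4,
                       ligand_schedule = csptitr:::default_schedule(0.4, 12, kd),
                       noise_sigma = 0, decoy_count = 0L,
                       alpha = 0.154, seed = 1L) {
  n <- length(resno)
  grid <- expand.grid(h = seq(7, 10, by = 0.5), n = seq(106, 129, by = 2.5))
  stopifnot(n <= nrow(grid))
  residues <- data.frame(
    resno = resno, restype = rep("A", n),
    free_h = grid$h[seq_len(n)], free_n = grid$n[seq_len(n)],
    ddmax = ddmax, theta = theta, binder = ddmax >= 0.05,
    stringsAsFactors = FALSE
  )
  structure(list(
    model = binding_model(kd, protein_total, ligand_schedule),
    residues = residues, missing_residues = integer(0),
    noise_sigma = noise_sigma, decoy_count = as.integer(decoy_count),
    decoys = data.frame(h_ppm = numeric(0), n_ppm = numeric(0))[
      seq_len(0), , drop = FALSE],
    alpha = alpha, seed = as.integer(seed), scenario = "manual"
  ), class = "ground_truth")
}

## Minimal shift_tracks object holding given CSP curves on the 1H axis,
## for testing the fitting layer in isolation.
make_tracks_from_curves <- function(Y, ligand_totals, protein_total = 0.4,
                                    alpha = 0.154,
                                    residues = seq_len(nrow(Y)) + 100L) {
  structure(list(
    residues = as.integer(residues),
    restype = rep("A", nrow(Y)),
    h = Y + 8, n = matrix(115, nrow(Y), ncol(Y)),
    ddh = Y, ddn = matrix(0, nrow(Y), ncol(Y)),
    peak_index = matrix(1L, nrow(Y), ncol(Y)),
    status = rep("complete", nrow(Y)),
    lost_at = rep(NA_integer_, nrow(Y)),
    overlapped = rep(FALSE, nrow(Y)),
    ligand_totals = ligand_totals,
    protein_total = protein_total,
    alpha = alpha
  ), class = "shift_tracks")
}

## Write a minimal PDB file: one CA (optionally more atoms) per residue.
## coords: data.frame(chain, resno, x, y, z); alt/occ optional columns.
write_test_pdb <- function(coords, path) {
  alt <- if ("alt" %in% names(coords)) coords$alt else rep("", nrow(coords))
  occ <- if ("occ" %in% names(coords)) coords$occ else rep(1, nrow(coords))
  elety <- if ("elety" %in% names(coords)) coords$elety else rep("CA", nrow(coords))
  lines <- sprintf(
    "ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s",
    seq_len(nrow(coords)),
    paste0(" ", formatC(elety, width = -3)), alt, "ALA",
    coords$chain, coords$resno, coords$x, coords$y, coords$z, occ, 0,
    substr(elety, 1, 1))
  writeLines(c(lines, "END"), path)
  path
}

## Extended (colinear) chain: residue i at (3.8*i, 0, 0).
extended_chain <- function(n, chain = "A") {
  data.frame(chain = chain, resno = seq_len(n),
             x = 3.8 * seq_len(n), y = 0, z = 0)
}

## Compact random-walk chain with fixed 3.8 A steps.
walk_chain <- function(n, chain = "A", seed = 1) {
  set.seed(seed)
  steps <- matrix(stats::rnorm(3 * (n - 1)), ncol = 3)
  steps <- steps / sqrt(rowSums(steps^2)) * 3.8
  xyz <- rbind(c(0, 0, 0), apply(steps, 2, cumsum))
  data.frame(chain = chain, resno = seq_len(n),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

## Correct-track indicator: TRUE when a residue's matched peak at every
## point is the peak the generator emitted for it (peak ids encode the
## residue and survive shuffling).
tracks_correct <- function(tracks, series, residues) {
  vapply(residues, function(rn) {
    r <- match(rn, tracks$residues)
    if (is.na(r) || tracks$status[r] != "complete") return(FALSE)
    all(vapply(seq_along(series$points), function(k) {
      j <- tracks$peak_index[r, k]
      !is.na(j) &&
        series$points[[k]]$peaks$id[j] == sprintf("res%03d", rn)
    }, TRUE))
  }, TRUE)
}
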