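#' Scaled 1H/15N distance between two peaks
#'
#' Distance in the combined chemical-shift metric,
#' `sqrt(dH^2 + (alpha * dN)^2)`, in which 15N differences are scaled by
#' `alpha` so both axes are commensurate. This is the same metric as the
#' combined CSP ([compute_csp()]) evaluated on the position difference.
#'
#' @param a,b peaks: [peak_list()] rows, or any list/data frame with
#'   `h_ppm` and `n_ppm` fields (vectorised over rows).
#' @param alpha 15N scaling factor (> 0), default 0.154.
#' @return Non-negative distance(s) in ppm.
#' @export
scaled_distance <- function(a, b, alpha = 0.154) {
  if (alpha <= 0) stop("alpha must be > 0")
  sqrt((a$h_ppm - b$h_ppm)^2 + (alpha * (a$n_ppm - b$n_ppm))^2)
}

## Rectangular scaled-distance matrix between two peak sets.
scaled_distance_matrix <- function(h1, n1, h2, n2, alpha) {
  dh <- outer(h1, h2, "-")
  dn <- outer(n1, n2, "-")
  sqrt(dh^2 + (alpha * dn)^2)
}

## One-to-one pairing of rows to columns of a distance matrix:
## mutual nearest neighbours within max_dist first, then a greedy
## distance-ordered fallback over the remaining candidates. A row or column
## whose best and second-best distances differ by <= tie_tol is ambiguous
## and left unmatched on both sides.
mutual_nn_pairs <- function(D, max_dist, tie_tol = 1e-9) {
  nr <- nrow(D); nc <- ncol(D)
  empty <- list(rows = integer(0), cols = integer(0),
                ambiguous_rows = integer(0))
  if (!nr || !nc) return(empty)
  two_smallest <- function(d) {
    if (length(d) == 1L) return(c(d, Inf))
    i <- which.min(d); m1 <- d[i]; d[i] <- Inf
    c(m1, min(d))
  }
  rs <- apply(D, 1L, two_smallest)          # 2 x nr
  cs <- apply(D, 2L, two_smallest)          # 2 x nc
  amb_row <- rs[1, ] <= max_dist & (rs[2, ] - rs[1, ]) <= tie_tol
  amb_col <- cs[1, ] <= max_dist & (cs[2, ] - cs[1, ]) <= tie_tol
  nn_of_row <- apply(D, 1L, which.min)
  nn_of_col <- apply(D, 2L, which.min)
  rows <- integer(0); cols <- integer(0)
  taken_r <- rep(FALSE, nr); taken_c <- rep(FALSE, nc)
  for (i in seq_len(nr)) {
    j <- nn_of_row[i]
    if (D[i, j] <= max_dist && nn_of_col[j] == i &&
        !amb_row[i] && !amb_col[j]) {
      rows <- c(rows, i); cols <- c(cols, j)
      taken_r[i] <- TRUE; taken_c[j] <- TRUE
    }
  }
  ## greedy fallback for conflicted (non-mutual) candidates
  free_r <- which(!taken_r & !amb_row)
  free_c <- which(!taken_c & !amb_col)
  if (length(free_r) && length(free_c)) {
    sub <- D[free_r, free_c, drop = FALSE]
    cand <- which(sub <= max_dist, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(sub[cand]), , drop = FALSE]
      for (k in seq_len(nrow(cand))) {
        i <- free_r[cand[k, 1]]; j <- free_c[cand[k, 2]]
        if (!taken_r[i] && !taken_c[j]) {
          rows <- c(rows, i); cols <- c(cols, j)
          taken_r[i] <- TRUE; taken_c[j] <- TRUE
        }
      }
    }
  }
  list(rows = rows, cols = cols, ambiguous_rows = which(amb_row))
}

## Linear-trajectory residual of one chain: per-axis least-squares line of
## position against point index, summed squared deviations in the scaled
## metric. Under two-state fast exchange with (approximately) even response
## increments the true trajectory is a straight line, so this residual is
## the natural goodness-of-chain statistic.
chain_rss <- function(h, n, alpha) {
  ok <- !is.na(h)
  if (sum(ok) < 3) return(0)
  x <- which(ok)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  rss_axis <- function(y) {
    yc <- y - mean(y)
    sum(yc^2) - sum(xc * yc)^2 / sxx
  }
  rss_axis(h[ok]) + rss_axis(alpha * n[ok])
}

#' Track assigned residues across a titration series
#'
#' Establishes peak correspondence across titration points by chained
#' nearest-neighbour matching in the scaled metric (see
#' [scaled_distance()]): every apo peak starts a chain, and at each point k
#' the chains' predicted positions are matched one-to-one to the point-k
#' peaks (mutual nearest neighbours within `max_step`, greedy
#' distance-ordered fallback for conflicts, exact ties left unmatched).
#' The prediction extrapolates each chain's motion from its history -
#' under two-state fast exchange peaks move along straight lines, so after
#' the first step the expected position is well determined. After the
#' forward pass, chains that passed within `2 * max_step` of one another
#' are tested for tail swaps: if exchanging their chains from some point
#' onward reduces the combined deviation from straight-line trajectories,
#' the swap is applied. This resolves the genuinely ambiguous case of two
#' peaks crossing within the noise radius, which no per-step rule can.
#'
#' A residue whose chain breaks at point k is flagged `lost_after_k` and
#' excluded from later points. Shift differences are reported relative to
#' the apo point.
#'
#' @param series a [titration_series()] whose first point carries residue
#'   assignments.
#' @param alpha 15N scaling factor, default 0.154.
#' @param max_step maximum scaled step (ppm) between consecutive points,
#'   default 0.05.
#' @return An object of class `"shift_tracks"`: residue vector, position
#'   matrices `h`/`n` (residue x point, NA after loss), delta matrices
#'   `ddh`/`ddn` relative to point 0, `status` (`"complete"` or
#'   `"lost_after_k"`), `lost_at`, `overlapped` (all `FALSE` until
#'   [flag_overlap()] is applied), and the series metadata
#'   (`ligand_totals`, `protein_total`, `alpha`).
#' @export
track_series <- function(series, alpha = 0.154, max_step = 0.05) {
  stopifnot(inherits(series, "titration_series"))
  if (alpha <= 0) stop("alpha must be > 0")
  if (max_step <= 0) stop("max_step must be > 0")
  K <- length(series$points)
  if (K < 2) stop("a titration series must have at least two points")
  apo <- series$points[[1]]$peaks
  keep <- !is.na(apo$resno)
  if (!any(keep)) stop("no assigned peaks at the apo point")
  ## every apo peak (assigned or not) starts a chain; unassigned chains
  ## keep decoys and stray peaks from stealing residue matches and give
  ## the swap repair a partner to trade tails with
  C <- nrow(apo)
  h <- matrix(NA_real_, C, K)
  n <- matrix(NA_real_, C, K)
  idx <- matrix(NA_integer_, C, K)
  h[, 1] <- apo$h_ppm
  n[, 1] <- apo$n_ppm
  idx[, 1] <- seq_len(C)
  lost_at <- rep(NA_integer_, C)
  for (k in 2:K) {
    cur <- series$points[[k]]$peaks
    active <- which(is.na(lost_at))
    ## predicted position: mean-velocity extrapolation of the chain
    ph <- h[active, k - 1]
    pn <- n[active, k - 1]
    if (k > 2) {
      span <- k - 2
      ph <- ph + (h[active, k - 1] - h[active, 1]) / span
      pn <- pn + (n[active, k - 1] - n[active, 1]) / span
    }
    D <- scaled_distance_matrix(ph, pn, cur$h_ppm, cur$n_ppm, alpha)
    pairing <- mutual_nn_pairs(D, max_dist = max_step)
    matched <- rep(NA_integer_, length(active))
    matched[pairing$rows] <- pairing$cols
    for (i in seq_along(active)) {
      r <- active[i]
      j <- matched[i]
      if (is.na(j)) {
        lost_at[r] <- k - 1L    # last matched point (0-based ordinal k-2)
      } else {
        idx[r, k] <- j
        h[r, k] <- cur$h_ppm[j]
        n[r, k] <- cur$n_ppm[j]
      }
    }
  }
  ## tail-swap repair: chains that came close at some point may have
  ## exchanged identities there; prefer the pairing with straighter lines
  for (k in 2:K) {
    both <- which(!is.na(idx[, k]) & !is.na(idx[, k - 1]))
    if (length(both) < 2) next
    Dk <- scaled_distance_matrix(h[both, k], n[both, k],
                                 h[both, k], n[both, k], alpha)
    Dk1 <- scaled_distance_matrix(h[both, k - 1], n[both, k - 1],
                                  h[both, k - 1], n[both, k - 1], alpha)
    close <- which(upper.tri(Dk) & (Dk <= 2 * max_step | Dk1 <= 2 * max_step),
                   arr.ind = TRUE)
    for (p in seq_len(nrow(close))) {
      a <- both[close[p, 1]]; b <- both[close[p, 2]]
      rss0 <- chain_rss(h[a, ], n[a, ], alpha) +
        chain_rss(h[b, ], n[b, ], alpha)
      ## try exchanging every segment [k, m]; transient identity swaps
      ## (exchange and re-exchange within a point or two) need m < K,
      ## a definitive crossing needs m = K
      best <- list(rss = rss0, seg = NULL)
      ## transient identity swaps are short; a definitive crossing is a
      ## whole-tail exchange - intermediate lengths add nothing
      for (m in unique(c(k:min(k + 3L, K), K))) {
        seg <- k:m
        ha <- h[a, ]; hb <- h[b, ]; na_ <- n[a, ]; nb <- n[b, ]
        ha[seg] <- h[b, seg]; hb[seg] <- h[a, seg]
        na_[seg] <- n[b, seg]; nb[seg] <- n[a, seg]
        rss1 <- chain_rss(ha, na_, alpha) + chain_rss(hb, nb, alpha)
        if (rss1 < best$rss - 1e-12) best <- list(rss = rss1, seg = seg)
      }
      if (!is.null(best$seg)) {
        seg <- best$seg
        tmp <- h[a, seg]; h[a, seg] <- h[b, seg]; h[b, seg] <- tmp
        tmp <- n[a, seg]; n[a, seg] <- n[b, seg]; n[b, seg] <- tmp
        tmpi <- idx[a, seg]; idx[a, seg] <- idx[b, seg]
        idx[b, seg] <- tmpi
      }
    }
  }
  ## losses may have moved between chains during repair
  lost_at <- apply(idx, 1L, function(r) {
    na <- which(is.na(r))
    if (length(na)) na[1] - 1L else NA_integer_
  })
  ## report only the assigned chains
  sel <- which(keep)
  residues <- apo$resno[sel]
  h <- h[sel, , drop = FALSE]
  n <- n[sel, , drop = FALSE]
  idx <- idx[sel, , drop = FALSE]
  lost_at <- lost_at[sel]
  status <- ifelse(is.na(lost_at), "complete",
                   sprintf("lost_after_%d", lost_at - 1L))
  structure(list(
    residues = residues,
    restype = apo$restype[sel],
    h = h, n = n,
    ddh = h - h[, 1],
    ddn = n - n[, 1],
    peak_index = idx,
    status = status,
    lost_at = lost_at,
    overlapped = rep(FALSE, length(sel)),
    ligand_totals = series$ligand_totals,
    protein_total = series$protein_total,
    alpha = alpha
  ), class = "shift_tracks")
}

#' @export
print.shift_tracks <- function(x, ...) {
  cat(sprintf("<shift_tracks> %d residues over %d points (%d complete, %d lost, %d overlapped)\n",
              length(x$residues), ncol(x$h), sum(x$status == "complete"),
              sum(x$status != "complete"), sum(x$overlapped)))
  invisible(x)
}

#' Flag tracks whose peaks overlap another peak
#'
#' A track is overlapped if, at any matched point, another peak of that
#' point's list lies within `overlap_tol` (scaled metric) of its matched
#' peak. Overlapped tracks are excluded from reporter selection because
#' their measured positions are unreliable.
#'
#' @param series the [titration_series()] the tracks came from.
#' @param tracks a `"shift_tracks"` object from [track_series()].
#' @param overlap_tol scaled distance threshold (ppm), default 0.01.
#' @return `tracks` with the `overlapped` flags set.
#' @export
flag_overlap <- function(series, tracks, overlap_tol = 0.01) {
  stopifnot(inherits(series, "titration_series"),
            inherits(tracks, "shift_tracks"))
  if (overlap_tol <= 0) stop("overlap_tol must be > 0")
  K <- ncol(tracks$h)
  overlapped <- rep(FALSE, length(tracks$residues))
  for (k in seq_len(K)) {
    p <- series$points[[k]]$peaks
    if (nrow(p) < 2) next
    D <- scaled_distance_matrix(p$h_ppm, p$n_ppm, p$h_ppm, p$n_ppm,
                                tracks$alpha)
    diag(D) <- Inf
    nn <- apply(D, 1L, min)
    j <- tracks$peak_index[, k]
    hit <- !is.na(j) & nn[ifelse(is.na(j), 1L, j)] <= overlap_tol
    overlapped <- overlapped | hit
  }
  tracks$overlapped <- overlapped
  tracks
}

#' Export tracks as a long-format data frame
#'
#' @param x a `"shift_tracks"` object.
#' @param ... unused.
#' @return Data frame with one row per (residue, point): positions, deltas
#'   relative to apo, ligand concentration and status flags.
#' @export
as.data.frame.shift_tracks <- function(x, ...) {
  K <- ncol(x$h)
  R <- length(x$residues)
  data.frame(
    residue = rep(x$residues, each = K),
    point = rep(seq_len(K) - 1L, times = R),
    ligand_total = rep(x$ligand_totals, times = R),
    h_ppm = as.vector(t(x$h)),
    n_ppm = as.vector(t(x$n)),
    dd_h = as.vector(t(x$ddh)),
    dd_n = as.vector(t(x$ddn)),
    status = rep(x$status, each = K),
    overlapped = rep(x$overlapped, each = K)
  )
}
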