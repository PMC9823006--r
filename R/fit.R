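#' Select reporter residues for K_D fitting
#'
#' Reporters are the residues whose titration curves feed the binding fit:
#' classified at least `1sigma`, tracked to the last point, and not
#' overlapped by another peak at any point (well-resolved, non-overlapped
#' perturbations; in practice most of the 2-sigma and some of the 1-sigma
#' residues).
#'
#' @param table a `"csp_table"` from [classify_significance()].
#' @param tracks the `"shift_tracks"` the table was computed from
#'   (preferably after [flag_overlap()]).
#' @return Sorted integer vector of residue numbers (possibly empty).
#' @export
select_reporters <- function(table, tracks) {
  stopifnot(inherits(table, "csp_table"), inherits(tracks, "shift_tracks"))
  sig <- table$residue[table$class %in% c("1sigma", "2sigma")]
  ok <- tracks$residues[tracks$status == "complete" & !tracks$overlapped]
  sort(intersect(sig, ok))
}

## Profiled least-squares objective: for fixed kd the amplitude ddmax is
## linear, so the 2-parameter fit reduces to a 1-D search over log(kd).
profile_ddmax <- function(kd, y, lt, pt) {
  f <- fraction_bound(kd, pt, lt)
  sf2 <- sum(f^2)
  if (sf2 == 0) return(list(ddmax = 0, rss = sum(y^2), f = f))
  b <- sum(f * y) / sf2
  list(ddmax = b, rss = sum((y - b * f)^2), f = f)
}

#' Fit the two-state ligand-depletion isotherm to one residue's CSPs
#'
#' Minimises `sum_k (dd_obs_k - ddmax * f(kd, Pt, L_k))^2` where `f` is
#' [fraction_bound()]. `kd` is parameterised on a log scale to enforce
#' positivity and `ddmax` is profiled out (it enters linearly), so the
#' optimisation is one-dimensional; five multi-starts log-spaced over
#' `[L_min > 0, 10 * L_max]` guard against local minima, ties broken toward
#' the smaller `kd`.
#'
#' @param dd_obs combined CSPs relative to apo at each titration point
#'   (first element 0).
#' @param ligand_totals total ligand concentrations (mM), same length.
#' @param protein_total total protein concentration (mM).
#' @param objective_tol convergence tolerance on the objective, default 1e-10.
#' @return List: `kd` (mM), `ddmax` (ppm), `residual_rms` (ppm),
#'   `n_points`, `converged`.
#' @export
fit_residue <- function(dd_obs, ligand_totals, protein_total,
                        objective_tol = 1e-10) {
  keep <- !is.na(dd_obs)
  y <- dd_obs[keep]; lt <- ligand_totals[keep]
  if (length(y) < 5) stop("at least 5 matched points are required")
  if (max(abs(y)) == 0) stop("no signal: CSP is zero at every point")
  obj <- function(logkd) profile_ddmax(exp(logkd), y, lt, protein_total)$rss
  lmin <- min(lt[lt > 0]); lmax <- max(lt)
  starts <- log(exp(seq(log(lmin), log(10 * lmax), length.out = 5)))
  ## data-driven start: ligand concentration at half the endpoint response
  half <- utils::tail(y, 1) / 2
  k0 <- lt[which.min(abs(y - half))]
  if (k0 > 0) starts <- c(starts, log(k0))
  best <- NULL
  for (s in starts) {
    r <- stats::nlminb(s, obj, control = list(abs.tol = 0, rel.tol = 1e-14,
                                              x.tol = 1e-12, iter.max = 300))
    if (is.null(best) || r$objective < best$objective - objective_tol ||
        (abs(r$objective - best$objective) <= objective_tol &&
         r$par < best$par))
      best <- r
  }
  kd <- exp(best$par)
  pr <- profile_ddmax(kd, y, lt, protein_total)
  list(kd = kd, ddmax = pr$ddmax,
       residual_rms = sqrt(pr$rss / length(y)),
       n_points = length(y),
       converged = is.finite(best$objective) && pr$ddmax > 0)
}

#' Fit the binding isotherm across reporter residues
#'
#' The central model of the package: two-state binding with ligand
#' depletion, fit by nonlinear least squares to the combined CSP curves of
#' the reporter residues. Two pooling modes are available:
#' \describe{
#'   \item{`per_residue_average` (default)}{each reporter is fit
#'     independently; the pooled K_D is the mean over reporters with its
#'     SD, and the normalised binding curve averages the per-residue
#'     `dd_obs/ddmax` at each point.}
#'   \item{`shared_kd`}{one K_D shared by all reporters with per-residue
#'     `ddmax` nuisance amplitudes; the SD comes from a leave-one-residue-
#'     out jackknife.}
#' }
#'
#' @param tracks a `"shift_tracks"` object from [track_series()] (after
#'   [flag_overlap()] if overlap filtering is wanted).
#' @param reporters residue numbers to fit, or a `"csp_table"` from which
#'   reporters are selected via [select_reporters()]. At least 3 required.
#' @param mode `"per_residue_average"` or `"shared_kd"`.
#' @return An object of class `"csp_fit"` with per-residue estimates,
#'   pooled `kd_mean_uM` and `kd_sd_uM`, reporter count `n`, the normalised
#'   binding curve, and the data needed by the methods
#'   ([predict.csp_fit()], [plot.csp_fit()], [residuals.csp_fit()],
#'   [simulate.csp_fit()]).
#' @export
fit_binding <- function(tracks, reporters,
                        mode = c("per_residue_average", "shared_kd")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tracks, "shift_tracks"))
  if (inherits(reporters, "csp_table"))
    reporters <- select_reporters(reporters, tracks)
  reporters <- sort(unique(as.integer(reporters)))
  if (length(reporters) < 3)
    stop("at least 3 reporter residues are required (got ",
         length(reporters), ")")
  ri <- match(reporters, tracks$residues)
  if (anyNA(ri)) stop("reporter residue(s) absent from tracks: ",
                      paste(reporters[is.na(ri)], collapse = ", "))
  lt <- tracks$ligand_totals
  pt <- tracks$protein_total
  Y <- compute_csp(tracks$ddh[ri, , drop = FALSE],
                   tracks$ddn[ri, , drop = FALSE], tracks$alpha)
  rownames(Y) <- reporters
  fits <- vector("list", length(reporters))
  for (i in seq_along(reporters)) {
    fits[[i]] <- tryCatch(fit_residue(Y[i, ], lt, pt),
                          error = function(e) {
                            warning("residue ", reporters[i], " skipped: ",
                                    conditionMessage(e), call. = FALSE)
                            NULL
                          })
  }
  ok <- !vapply(fits, is.null, TRUE) &
    vapply(fits, function(f) is.null(f) || f$converged, TRUE)
  if (sum(ok) < 3) stop("fewer than 3 reporters produced a converged fit")
  per <- data.frame(
    residue = reporters[ok],
    kd_uM = vapply(fits[ok], function(f) f$kd * 1000, 0),
    ddmax_ppm = vapply(fits[ok], function(f) f$ddmax, 0),
    residual_rms = vapply(fits[ok], function(f) f$residual_rms, 0),
    n_points = vapply(fits[ok], function(f) f$n_points, 0L)
  )
  Y <- Y[ok, , drop = FALSE]
  if (mode == "per_residue_average") {
    kd_mean <- mean(per$kd_uM)
    kd_sd <- stats::sd(per$kd_uM)
    norm <- Y / per$ddmax_ppm
  } else {
    shared <- function(rows) {
      obj <- function(logkd) {
        f <- fraction_bound(exp(logkd), pt, lt)
        sf2 <- sum(f^2)
        sum(apply(Y[rows, , drop = FALSE], 1L, function(y) {
          b <- sum(f * y) / sf2
          sum((y - b * f)^2)
        }))
      }
      starts <- seq(log(min(lt[lt > 0])), log(10 * max(lt)), length.out = 5)
      best <- NULL
      for (s in starts) {
        r <- stats::nlminb(s, obj, control = list(abs.tol = 0,
                                                  rel.tol = 1e-14,
                                                  x.tol = 1e-12,
                                                  iter.max = 300))
        if (is.null(best) || r$objective < best$objective ||
            (r$objective == best$objective && r$par < best$par)) best <- r
      }
      exp(best$par)
    }
    all_rows <- seq_len(nrow(Y))
    kd_hat <- shared(all_rows)
    jack <- vapply(all_rows, function(i) shared(all_rows[-i]), 0)
    nr <- length(jack)
    kd_mean <- kd_hat * 1000
    kd_sd <- sqrt((nr - 1) / nr * sum((jack - mean(jack))^2)) * 1000
    f <- fraction_bound(kd_hat, pt, lt)
    bshared <- apply(Y, 1L, function(y) sum(f * y) / sum(f^2))
    per$ddmax_ppm <- bshared
    per$kd_uM <- kd_hat * 1000
    norm <- Y / bshared
  }
  curve <- data.frame(
    ligand_total = lt,
    mean_norm = apply(norm, 2L, mean, na.rm = TRUE),
    sd_norm = apply(norm, 2L, stats::sd, na.rm = TRUE)
  )
  structure(list(
    per_residue = per,
    kd_mean_uM = kd_mean,
    kd_sd_uM = kd_sd,
    n = nrow(per),
    mode = mode,
    curve = curve,
    protein_total = pt,
    ligand_totals = lt,
    alpha = tracks$alpha,
    Y = Y,
    call = match.call()
  ), class = "csp_fit")
}

#' @export
print.csp_fit <- function(x, digits = 3, ...) {
  cat("Two-state ligand-depletion binding fit\n")
  cat(sprintf("  mode: %s, reporters: n = %d\n", x$mode, x$n))
  cat(sprintf("  K_D = %s +/- %s uM\n",
              format(x$kd_mean_uM, digits = digits),
              format(x$kd_sd_uM, digits = digits)))
  invisible(x)
}

#' @export
summary.csp_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.csp_fit")
}

#' @export
print.summary.csp_fit <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  cat("\nPer-residue estimates:\n")
  print(format(x$fit$per_residue, digits = digits), row.names = FALSE)
  cat("\nNormalised binding curve (dd_obs/dd_max):\n")
  print(format(x$fit$curve, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
coef.csp_fit <- function(object, ...) {
  c(kd_uM = object$kd_mean_uM, kd_sd_uM = object$kd_sd_uM, n = object$n)
}

#' Predicted bound fraction at new ligand concentrations
#'
#' @param object a `"csp_fit"`.
#' @param ligand_total total ligand concentrations (mM); defaults to the
#'   fitted schedule.
#' @param ... unused.
#' @return Predicted normalised response `dd_obs/dd_max` (equal to the
#'   bound fraction) at the pooled K_D.
#' @export
predict.csp_fit <- function(object, ligand_total = object$ligand_totals, ...) {
  fraction_bound(object$kd_mean_uM / 1000, object$protein_total, ligand_total)
}

#' @export
fitted.csp_fit <- function(object, ...) {
  f <- predict(object)
  object$per_residue$ddmax_ppm %o% f
}

#' @export
residuals.csp_fit <- function(object, ...) {
  r <- object$Y - fitted(object)
  rownames(r) <- object$per_residue$residue
  r
}

#' Simulate replicate normalised titration curves from a fit
#'
#' Draws `nsim` replicates of the averaged normalised curve using the
#' fitted pooled K_D and the per-residue residual scatter, mimicking a
#' repeat of the experiment under the fitted model.
#'
#' @param object a `"csp_fit"`.
#' @param nsim number of replicates.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return Matrix `nsim x n_points` of simulated mean normalised responses.
#' @export
simulate.csp_fit <- function(object, nsim = 1, seed = NULL, ...) {
  run <- function() {
    f <- predict(object)
    t(vapply(seq_len(nsim), function(i) {
      norm <- vapply(seq_len(object$n), function(r) {
        dd <- object$per_residue$ddmax_ppm[r]
        y <- dd * f + stats::rnorm(length(f), 0,
                                   object$per_residue$residual_rms[r])
        y / dd
      }, numeric(length(f)))
      rowMeans(norm)
    }, numeric(length(object$ligand_totals))))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Plot the normalised binding curve of a fit
#'
#' Points with error bars are the per-point mean and SD of the reporters'
#' normalised CSPs; the line is the ligand-depletion isotherm at the pooled
#' K_D.
#'
#' @param x a `"csp_fit"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.csp_fit <- function(x, ...) {
  cv <- x$curve
  lgrid <- seq(0, max(cv$ligand_total), length.out = 200)
  graphics::plot(cv$ligand_total, cv$mean_norm,
                 xlab = "[L]t (mM)",
                 ylab = expression(Delta * delta[obs] / Delta * delta[max]),
                 ylim = range(0, cv$mean_norm + cv$sd_norm, 1), pch = 19, ...)
  has_sd <- !is.na(cv$sd_norm) & cv$sd_norm > 0
  if (any(has_sd))
    graphics::arrows(cv$ligand_total[has_sd],
                     (cv$mean_norm - cv$sd_norm)[has_sd],
                     cv$ligand_total[has_sd],
                     (cv$mean_norm + cv$sd_norm)[has_sd],
                     angle = 90, code = 3, length = 0.03)
  graphics::lines(lgrid, fraction_bound(x$kd_mean_uM / 1000,
                                        x$protein_total, lgrid))
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("K_D = %.3g +/- %.2g uM (n = %d)",
                                    x$kd_mean_uM, x$kd_sd_uM, x$n))
  invisible(x)
}

#' Write a fit report
#'
#' Writes per-residue and pooled results as TSV plus JSON, and the
#' normalised binding curve as TSV.
#'
#' @param fit a `"csp_fit"`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return Character vector of the written paths, invisibly.
#' @export
write_fit_report <- function(fit, dir, prefix = "fit") {
  stopifnot(inherits(fit, "csp_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(prefix, "_per_residue.tsv"))
  utils::write.table(fit$per_residue, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p2 <- file.path(dir, paste0(prefix, "_curve.tsv"))
  utils::write.table(fit$curve, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p3 <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(list(
    kd_mean_uM = fit$kd_mean_uM, kd_sd_uM = fit$kd_sd_uM, n = fit$n,
    mode = fit$mode, protein_total_mM = fit$protein_total,
    per_residue = fit$per_residue, curve = fit$curve
  ), p3, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3))
}
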