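#' Bound protein fraction under ligand depletion
#'
#' Two-state binding of one ligand to one site, solving the mass balance
#' exactly (the "ligand depletion" quadratic isotherm):
#' \deqn{f = \frac{(K_D + L_t + P_t) - \sqrt{(K_D + L_t + P_t)^2 - 4 L_t P_t}}{2 P_t}}
#' where \eqn{L_t} and \eqn{P_t} are total ligand and protein
#' concentrations. This is the fraction of protein bound, equal under fast
#' exchange to the observed combined shift divided by the shift at
#' saturation. The physically meaningful (smaller) root is returned; the
#' expression is evaluated in a numerically stable form so the result stays
#' in [0, 1] and is continuous in every argument, including the tight
#' binding limit `kd -> 0` where `f -> min(L_t, P_t) / P_t`.
#'
#' @param kd dissociation constant (mM), `>= 0` (0 is the tight limit).
#' @param protein_total total protein concentration (mM), `> 0`.
#' @param ligand_total total ligand concentration (mM), `>= 0`; vectorised.
#' @return Bound fraction(s) in [0, 1].
#' @export
fraction_bound <- function(kd, protein_total, ligand_total) {
  if (any(kd < 0)) stop("kd must be >= 0")
  if (any(protein_total <= 0)) stop("protein_total must be > 0")
  if (any(ligand_total < 0)) stop("ligand_total must be >= 0")
  s <- kd + ligand_total + protein_total
  disc <- s^2 - 4 * ligand_total * protein_total
  disc[disc < 0] <- 0          # guard tiny negative round-off at kd = 0
  root <- sqrt(disc)
  ## (s - root)/2 loses precision when L_t*P_t << s^2; use the conjugate
  pl <- ifelse(s + root > 0, 2 * ligand_total * protein_total / (s + root), 0)
  f <- pl / protein_total
  pmin(pmax(f, 0), 1)
}

#' Two-state binding model for a titration design
#'
#' @param kd dissociation constant (mM), `> 0`.
#' @param protein_total total protein concentration (mM), `> 0`.
#' @param ligand_schedule ordered total ligand concentrations (mM), starting
#'   at 0 and strictly increasing.
#' @return An object of class `"binding_model"`.
#' @export
binding_model <- function(kd, protein_total, ligand_schedule) {
  if (kd <= 0) stop("kd must be > 0")
  if (protein_total <= 0) stop("protein_total must be > 0")
  if (any(ligand_schedule < 0) || ligand_schedule[1] != 0 ||
      (length(ligand_schedule) > 1 && any(diff(ligand_schedule) <= 0)))
    stop("ligand_schedule must be non-negative, start at 0 and be strictly increasing")
  structure(list(kd = kd, protein_total = protein_total,
                 ligand_schedule = as.numeric(ligand_schedule)),
            class = "binding_model")
}

## Run code under a temporary RNG state seeded with `seed`, restoring the
## caller's stream afterwards so simulation calls are reproducible without
## side effects.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

## 12-point ligand schedule to a final [L]t/[P]t molar ratio, spaced in
## equal increments of the binding response rather than of ligand volume:
## point k sits at the total ligand concentration where the bound fraction
## reaches k/(n-1) of its final value. This mirrors how a fast-exchange
## titration is actually run - ligand is added gradually, watching the
## peaks, until shifts stop - and it keeps consecutive peak positions close
## enough to chain-track even for near-stoichiometric binders, whose
## response would otherwise jump across the equivalence point.
## Inverting the mass balance: [L]t(f) = f*[P]t + Kd*f/(1-f).
default_schedule <- function(protein_total, final_ratio, kd,
                             n_points = 12L) {
  l_end <- protein_total * final_ratio
  f_end <- fraction_bound(kd, protein_total, l_end)
  f <- f_end * seq(0, 1, length.out = n_points)
  l <- f * protein_total + kd * f / (1 - f)
  l[n_points] <- l_end          # exact by self-consistency; avoid round-off
  l
}

#' Ground truth for a synthetic titration scenario
#'
#' Builds the complete generative description of a titration experiment:
#' the binding model, each residue's response (free peak position, maximal
#' combined shift at saturation, and the fixed direction its peak moves),
#' the positional noise level, unassignable residues, and non-titrating
#' decoy peaks crowding the 8.0-8.5 ppm 1H region. Scenario defaults
#' emulate the study conditions: ~160 assignable backbone amides of a
#' 0.4 mM protein, 12 titration points, 10-25 true binders with maximal
#' shifts of 0.05-0.30 ppm, and positional noise of 0.003 ppm in the scaled
#' metric.
#'
#' @param name `"fc14-like"` (K_D 17.1 uM, final molar ratio 1:12, 20
#'   binders), `"lpc14-like"` (K_D 18.9 uM, 1:7, 13 binders) or
#'   `"mutant-like"` (K_D 129 uM, 1:24, 12 binders).
#' @param seed integer seed; the scenario is fully reproducible from it.
#' @param kd,final_ratio,n_binders,noise_sigma,decoy_count optional
#'   overrides of the scenario defaults (`kd` in mM).
#' @param alpha 15N scaling factor used for the scaled-metric geometry.
#' @return An object of class `"ground_truth"`: `model`
#'   ([binding_model()]), `residues` data frame (`resno`, `restype`,
#'   `free_h`, `free_n`, `ddmax`, `theta` direction angle, `binder`),
#'   `missing_residues`, `noise_sigma`, `decoy_count`, `decoys` data frame,
#'   `alpha`, `seed`.
#' @export
default_scenario <- function(name = c("fc14-like", "lpc14-like", "mutant-like"),
                             seed = 1L, kd = NULL, final_ratio = NULL,
                             n_binders = NULL, noise_sigma = 0.003,
                             decoy_count = 15L, alpha = 0.154) {
  name <- match.arg(name)
  defaults <- switch(name,
    "fc14-like" = list(kd = 0.0171, final_ratio = 12, n_binders = 20L),
    "lpc14-like" = list(kd = 0.0189, final_ratio = 7, n_binders = 13L),
    "mutant-like" = list(kd = 0.129, final_ratio = 24, n_binders = 12L))
  kd <- if (is.null(kd)) defaults$kd else kd
  final_ratio <- if (is.null(final_ratio)) defaults$final_ratio else final_ratio
  n_binders <- if (is.null(n_binders)) defaults$n_binders else as.integer(n_binders)
  protein_total <- 0.4
  model <- binding_model(kd, protein_total,
                         default_schedule(protein_total, final_ratio, kd))
  with_seed(seed, {
    ## residues 18..192 (175 total, the span resolved in the crystal);
    ## 7 prolines plus two unassigned clusters of 4 leave 160 assignable
    resno <- 18:192
    prolines <- sort(sample(resno, 7))
    rest <- setdiff(resno, prolines)
    c1 <- sample(rest[rest < 96], 1); c2 <- sample(rest[rest >= 100 & rest <= 186], 1)
    w1 <- setdiff(c1 + 0:6, prolines)[1:4]
    w2 <- setdiff(c2 + 0:6, prolines)[1:4]
    missing <- sort(unique(c(prolines, w1, w2)))
    missing <- missing[!is.na(missing)]
    topup <- setdiff(rest, missing)
    while (length(missing) < 15) {      # keep exactly 160 assignable
      missing <- sort(c(missing, topup[1])); topup <- topup[-1]
    }
    assignable <- setdiff(resno, missing)
    n_res <- length(assignable)
    binders <- sort(sample(assignable, n_binders))
    is_binder <- assignable %in% binders
    ddmax <- ifelse(is_binder,
                    stats::runif(n_res, 0.05, 0.30),
                    abs(stats::rnorm(n_res, 0, 0.005)))
    theta <- stats::runif(n_res, 0, 2 * pi)
    residues <- data.frame(
      resno = assignable,
      restype = sample(setdiff(names(AA_3TO1), "PRO"), n_res, replace = TRUE),
      free_h = stats::runif(n_res, 7.0, 10.0),
      free_n = stats::runif(n_res, 105, 130),
      ddmax = ddmax,
      theta = theta,
      binder = is_binder,
      stringsAsFactors = FALSE
    )
    residues$restype <- unname(AA_3TO1[residues$restype])
    ## drawn pairwise per decoy so decoy sets are nested across counts
    u <- matrix(stats::runif(2 * decoy_count), nrow = 2)
    decoys <- data.frame(
      h_ppm = 8.0 + 0.5 * u[1, ],
      n_ppm = 115 + 10 * u[2, ]
    )
    structure(list(model = model, residues = residues,
                   missing_residues = missing,
                   noise_sigma = noise_sigma,
                   decoy_count = as.integer(decoy_count),
                   decoys = decoys, alpha = alpha,
                   seed = as.integer(seed), scenario = name),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> '%s': %d residues (%d binders), K_D = %g uM, %d points to %g mM, noise %g ppm, %d decoys, seed %d\n",
              x$scenario, nrow(x$residues), sum(x$residues$binder),
              x$model$kd * 1000, length(x$model$ligand_schedule),
              max(x$model$ligand_schedule), x$noise_sigma,
              x$decoy_count, x$seed))
  invisible(x)
}

#' Simulate a titration series from ground truth
#'
#' Under two-state fast exchange each residue's cross peak sits at the
#' population-weighted average of its free and bound positions: free
#' position plus `fraction_bound * ddmax` along the residue's fixed
#' direction, plus isotropic Gaussian noise of SD `noise_sigma` in the
#' scaled metric. Decoy peaks do not titrate. The apo point carries the
#' residue assignments; later points are unassigned and their peaks are
#' emitted in random order. Fully reproducible from the ground-truth seed.
#'
#' @param truth a `"ground_truth"` from [default_scenario()].
#' @return A [titration_series()]; the residue identity of every peak is
#'   retained in the ground truth, not in the emitted lists.
#' @export
simulate_titration <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  rs <- truth$residues
  md <- truth$model
  f <- fraction_bound(md$kd, md$protein_total, md$ligand_schedule)
  K <- length(md$ligand_schedule)
  alpha <- truth$alpha
  ## independent noise substreams: residue positions do not depend on the
  ## decoy count, and decoy noise is drawn per decoy (nested decoy sets
  ## share positions), so crowding can be varied with everything else fixed
  n_res <- nrow(rs)
  res_noise <- with_seed(truth$seed + 1L,
    array(stats::rnorm(2L * n_res * K, 0, truth$noise_sigma),
          dim = c(n_res, 2L, K)))
  dk_noise <- with_seed(truth$seed + 2L,
    if (truth$decoy_count)
      array(stats::rnorm(2L * K * truth$decoy_count, 0, truth$noise_sigma),
            dim = c(2L, K, truth$decoy_count))
    else array(0, dim = c(2L, K, 0L)))
  with_seed(truth$seed + 3L, {
    points <- vector("list", K)
    for (k in seq_len(K)) {
      ## displacement of ddmax*f along theta, expressed in ppm on each axis
      dh <- f[k] * rs$ddmax * cos(rs$theta)
      dn <- f[k] * rs$ddmax * sin(rs$theta) / alpha
      h <- rs$free_h + dh + res_noise[, 1, k]
      n <- rs$free_n + dn + res_noise[, 2, k] / alpha
      hd <- truth$decoys$h_ppm + dk_noise[1, k, ]
      nd <- truth$decoys$n_ppm + dk_noise[2, k, ] / alpha
      peaks <- data.frame(
        id = c(sprintf("res%03d", rs$resno),
               if (truth$decoy_count) sprintf("dcy%03d", seq_len(truth$decoy_count))),
        h_ppm = c(h, hd), n_ppm = c(n, nd),
        height = 1e6,
        resno = c(if (k == 1) rs$resno else rep(NA_integer_, nrow(rs)),
                  rep(NA_integer_, truth$decoy_count)),
        restype = c(if (k == 1) rs$restype else rep(NA_character_, nrow(rs)),
                    rep(NA_character_, truth$decoy_count)),
        stringsAsFactors = FALSE
      )
      if (k > 1) peaks <- peaks[sample.int(nrow(peaks)), , drop = FALSE]
      rownames(peaks) <- NULL
      points[[k]] <- peak_list(peaks, point_index = k - 1L,
                               ligand_total = md$ligand_schedule[k],
                               protein_total = md$protein_total,
                               label = sprintf("%s point %d", truth$scenario, k - 1L))
    }
    titration_series(points)
  })
}

#' Export a ground truth object as JSON
#'
#' @param truth a `"ground_truth"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(list(
    scenario = truth$scenario,
    seed = truth$seed,
    kd_mM = truth$model$kd,
    protein_total_mM = truth$model$protein_total,
    ligand_schedule_mM = truth$model$ligand_schedule,
    noise_sigma = truth$noise_sigma,
    alpha = truth$alpha,
    missing_residues = truth$missing_residues,
    decoys = truth$decoys,
    residues = truth$residues
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
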