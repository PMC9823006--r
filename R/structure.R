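#' Read a protein structure
#'
#' Loads PDB or mmCIF coordinates via bio3d, keeping all chains, preserving
#' insertion codes and resolving alternate locations to the highest
#' occupancy conformer.
#'
#' @param path coordinate file path.
#' @param format `"pdb"` or `"mmcif"`; guessed from the extension when
#'   omitted.
#' @return An object of class `"structure_model"` wrapping the bio3d `pdb`
#'   object: `atoms` (the atom table), `format`, `path`.
#' @export
read_structure <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  if (!format %in% c("pdb", "mmcif")) stop("unknown format: ", format)
  pdb <- if (format == "pdb")
    bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  else bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  ## resolve altlocs: keep the highest-occupancy conformer per atom site
  alt <- at$alt
  if (!is.null(alt) && any(!is.na(alt) & alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$elety)
    occ <- at$o; occ[is.na(occ)] <- 1
    ord <- order(key, -occ)
    at <- at[ord[!duplicated(key[ord])], , drop = FALSE]
    at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  }
  if (!any(at$elety == "CA" & at$type == "ATOM"))
    stop("no C-alpha atoms in ", path)
  ## keep the coordinate vector in step with the (possibly deduplicated)
  ## atom table so painted output stays consistent
  pdb$atom <- at
  pdb$xyz <- bio3d::as.xyz(as.vector(t(as.matrix(at[, c("x", "y", "z")]))))
  structure(list(atoms = at, pdb = pdb, format = format, path = path),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  ca <- x$atoms[x$atoms$elety == "CA" & x$atoms$type == "ATOM", ]
  ch <- table(ca$chain)
  cat(sprintf("<structure_model> %d chains (%s), %d residues, %d atoms [%s]\n",
              length(ch),
              paste(sprintf("%s:%d", names(ch), as.integer(ch)), collapse = ", "),
              nrow(ca), nrow(x$atoms), x$format))
  invisible(x)
}

#' Chain identifiers of a structure
#' @param model a `"structure_model"`.
#' @return Character vector of chain ids.
#' @export
structure_chains <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  unique(model$atoms$chain[model$atoms$type == "ATOM"])
}

## C-alpha coordinate table for one chain: resno, x, y, z
chain_ca <- function(model, chain) {
  at <- model$atoms
  sel <- at$type == "ATOM" & at$chain == chain & at$elety == "CA"
  if (!any(sel)) stop("chain ", chain, " absent or has no C-alpha atoms")
  ca <- at[sel, , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  data.frame(resno = ca$resno, x = ca$x, y = ca$y, z = ca$z)
}

## Kabsch superposition of x onto y (n x 3 matrices, rows paired):
## returns the proper rotation R and translation t minimising
## ||x R + t - y||, with the post-fit rmsd.
kabsch <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  x0 <- sweep(x, 2, cx); y0 <- sweep(y, 2, cy)
  s <- svd(crossprod(x0, y0))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  t <- cy - as.vector(cx %*% R)
  fit <- sweep(x %*% R, 2, t, "+")
  list(rotation = R, translation = t,
       rmsd = sqrt(mean(rowSums((fit - y)^2))))
}

#' Superpose two chains on their common C-alpha atoms
#'
#' Least-squares rigid-body superposition (Kabsch algorithm) of chain `a`
#' onto chain `b` over the residues the two chains share (intersection of
#' residue numbers), returning a proper rotation.
#'
#' @param model a `"structure_model"`, or a list of two models.
#' @param a,b chain identifiers (of `model`, or of `model[[1]]` /
#'   `model[[2]]` when two models are given).
#' @return List: `rotation` (3x3, det +1), `translation` (length 3),
#'   `rmsd` (Angstrom), `n_atoms` (common C-alpha count).
#' @export
superpose <- function(model, a, b) {
  if (inherits(model, "structure_model")) {
    ma <- model; mb <- model
  } else {
    ma <- model[[1]]; mb <- model[[2]]
  }
  ca <- chain_ca(ma, a); cb <- chain_ca(mb, b)
  shared <- intersect(ca$resno, cb$resno)
  if (length(shared) < 3)
    stop("fewer than 3 shared C-alpha residues between chains ",
         a, " and ", b)
  xa <- as.matrix(ca[match(shared, ca$resno), c("x", "y", "z")])
  xb <- as.matrix(cb[match(shared, cb$resno), c("x", "y", "z")])
  k <- kabsch(xa, xb)
  k$n_atoms <- length(shared)
  k
}

#' Mean pairwise C-alpha rmsd over chains
#'
#' Superposes every unordered pair of chains on their common C-alpha set
#' and reports the mean rmsd, the full symmetric pair matrix, and the
#' number of residues common to all requested chains. For a crystal
#' asymmetric unit with several copies of one molecule this measures how
#' structurally identical the copies are.
#'
#' @param model a `"structure_model"`.
#' @param chains chain ids; default all chains.
#' @return List: `mean_rmsd` (Angstrom), `matrix` (chains x chains, zero
#'   diagonal), `common_residues` (count common to every chain).
#' @export
mean_pairwise_rmsd <- function(model, chains = structure_chains(model)) {
  stopifnot(inherits(model, "structure_model"))
  if (length(chains) < 2) stop("at least 2 chains are required")
  M <- matrix(0, length(chains), length(chains),
              dimnames = list(chains, chains))
  for (i in seq_along(chains)) for (j in seq_along(chains)) {
    if (j <= i) next
    s <- superpose(model, chains[i], chains[j])
    M[i, j] <- M[j, i] <- s$rmsd
  }
  common <- Reduce(intersect, lapply(chains, function(c) chain_ca(model, c)$resno))
  list(mean_rmsd = mean(M[upper.tri(M)]), matrix = M,
       common_residues = length(common))
}

#' Paint per-residue CSPs into the temperature-factor field
#'
#' Writes each residue's combined CSP, multiplied by 100 and capped at
#' 999.99 so small ppm values survive the two-decimal B-factor field, into
#' every atom of that residue in the chosen chain. Residues absent from the
#' table (or unassigned) get 0 and are listed in a sidecar report.
#' Coordinates are never altered. Output is written in PDB format.
#'
#' @param model a `"structure_model"`.
#' @param table a `"csp_table"`.
#' @param chain chain identifier; default `"B"`.
#' @param path output coordinate path.
#' @return Invisibly, a list with the output `path`, the sidecar
#'   `report_path`, and the `unmatched` residue numbers.
#' @export
paint_csp <- function(model, table, chain = "B", path) {
  stopifnot(inherits(model, "structure_model"), inherits(table, "csp_table"))
  if (!chain %in% structure_chains(model))
    stop("chain ", chain, " absent from structure")
  at <- model$atoms
  b <- at$b
  b[at$chain == chain] <- 0
  sel <- at$type == "ATOM" & at$chain == chain
  chain_res <- unique(at$resno[sel])
  assigned <- table[table$class != "unassigned" & !is.na(table$dd), ]
  painted <- integer(0)
  for (i in seq_len(nrow(assigned))) {
    rows <- sel & at$resno == assigned$residue[i]
    if (any(rows)) {
      b[rows] <- min(assigned$dd[i] * 100, 999.99)
      painted <- c(painted, assigned$residue[i])
    }
  }
  unmatched_in_model <- setdiff(chain_res, painted)
  unmatched_in_table <- setdiff(assigned$residue, chain_res)
  pdb <- model$pdb
  pdb$atom$b <- b
  bio3d::write.pdb(pdb, file = path)
  ## prepend the scale convention so downstream viewers know the encoding
  lines <- readLines(path, warn = FALSE)
  writeLines(c("REMARK   3 B-FACTOR FIELD HOLDS COMBINED CSP (PPM) X 100, CAP 999.99",
               lines), path)
  report_path <- paste0(path, ".unmatched.txt")
  writeLines(c("# residues with no CSP value (set to 0) or absent from the model",
               sprintf("model_only\t%d", unmatched_in_model),
               sprintf("table_only\t%d", unmatched_in_table)), report_path)
  invisible(list(path = path, report_path = report_path,
                 unmatched = unmatched_in_model))
}

#' Spatial clustering of significant residues: permutation test
#'
#' Tests whether a set of residues (typically the significant CSPs) sits
#' closer together on the structure than a same-size random set. The
#' statistic is the mean pairwise C-alpha distance within the set; the null
#' distribution comes from `n_perm` uniform random same-size subsets of the
#' chain's residues. The p-value is `(1 + #{null <= observed}) /
#' (n_perm + 1)` (small when the set is more compact than random).
#'
#' @param model a `"structure_model"`.
#' @param chain chain identifier.
#' @param significant residue numbers (>= 3 present in the chain).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for reproducibility.
#' @return List: `observed` (mean pairwise distance, Angstrom), `p_value`,
#'   `n_set`, `null` (the permuted statistics).
#' @export
patch_clustering <- function(model, chain, significant, n_perm = 1000,
                             seed = 1L) {
  stopifnot(inherits(model, "structure_model"))
  if (n_perm < 100) stop("n_perm must be >= 100")
  ca <- chain_ca(model, chain)
  set <- intersect(significant, ca$resno)
  if (length(set) < 3)
    stop("fewer than 3 significant residues present in chain ", chain)
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  mean_pair_dist <- function(idx) {
    d <- stats::dist(xyz[idx, , drop = FALSE])
    mean(d)
  }
  obs <- mean_pair_dist(match(set, ca$resno))
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i)
      mean_pair_dist(sample.int(nrow(ca), length(set))), 0)
  })
  list(observed = obs,
       p_value = (1 + sum(null <= obs)) / (n_perm + 1),
       n_set = length(set),
       null = null)
}
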