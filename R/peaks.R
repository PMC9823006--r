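#' Construct a peak list
#'
#' A peak list holds the cross peaks of one 2D 1H-15N HSQC spectrum at one
#' titration point, together with the titration metadata needed downstream:
#' the ordinal point index (0 = apo), the total ligand concentration and the
#' total protein concentration (both mM).
#'
#' @param peaks data frame with columns `id` (unique character), `h_ppm`,
#'   `n_ppm` (finite numeric, ppm), and optionally `height` (numeric) and
#'   `resno`/`restype` (integer residue number and one-letter residue type;
#'   `NA` for unassigned peaks).
#' @param point_index non-negative integer ordinal of the titration point.
#' @param ligand_total total ligand concentration (mM), `>= 0`.
#' @param protein_total total protein concentration (mM), `> 0`.
#' @param label free-text label.
#' @return An object of class `"peak_list"`.
#' @export
peak_list <- function(peaks, point_index = 0L, ligand_total = 0,
                      protein_total = 0.4, label = "") {
  stopifnot(is.data.frame(peaks))
  required <- c("id", "h_ppm", "n_ppm")
  missing_cols <- setdiff(required, names(peaks))
  if (length(missing_cols))
    stop("peak data frame lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (!"height" %in% names(peaks)) peaks$height <- NA_real_
  if (!"resno" %in% names(peaks)) peaks$resno <- NA_integer_
  if (!"restype" %in% names(peaks)) peaks$restype <- NA_character_
  peaks$id <- as.character(peaks$id)
  peaks$resno <- as.integer(peaks$resno)
  if (anyDuplicated(peaks$id))
    stop("peak ids must be unique within a peak list")
  if (nrow(peaks) && (!all(is.finite(peaks$h_ppm)) || !all(is.finite(peaks$n_ppm))))
    stop("peak positions must be finite")
  if (point_index < 0) stop("point_index must be >= 0")
  if (ligand_total < 0) stop("ligand_total must be >= 0")
  if (protein_total <= 0) stop("protein_total must be > 0")
  structure(list(
    peaks = peaks[, c("id", "h_ppm", "n_ppm", "height", "resno", "restype")],
    point_index = as.integer(point_index),
    ligand_total = as.numeric(ligand_total),
    protein_total = as.numeric(protein_total),
    label = as.character(label)
  ), class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  n_assigned <- sum(!is.na(x$peaks$resno))
  cat(sprintf("<peak_list> %d peaks (%d assigned), point %d, [L]t = %g mM, [P]t = %g mM%s\n",
              nrow(x$peaks), n_assigned, x$point_index,
              x$ligand_total, x$protein_total,
              if (nzchar(x$label)) paste0(" - ", x$label) else ""))
  invisible(x)
}

#' Construct a titration series
#'
#' An ordered collection of peak lists, one per titration point, sharing a
#' protein concentration and carrying a strictly increasing ligand schedule
#' starting from the apo point.
#'
#' @param points list of [peak_list()] objects ordered by titration point;
#'   the first must be the apo point (ligand_total 0).
#' @return An object of class `"titration_series"` with elements `points`,
#'   `ligand_totals`, `protein_total`.
#' @export
titration_series <- function(points) {
  if (!length(points) || !all(vapply(points, inherits, TRUE, "peak_list")))
    stop("points must be a non-empty list of peak_list objects")
  lt <- vapply(points, `[[`, 0, "ligand_total")
  pt <- unique(vapply(points, `[[`, 0, "protein_total"))
  if (length(pt) != 1L)
    stop("all points must share one protein_total")
  if (lt[1] != 0) stop("the first point must be the apo point (ligand_total 0)")
  if (length(lt) > 1 && any(diff(lt) <= 0))
    stop("ligand_totals must be strictly increasing")
  structure(list(points = points, ligand_totals = lt, protein_total = pt),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("<titration_series> %d points, [L]t %g-%g mM, [P]t = %g mM\n",
              length(x$points), min(x$ligand_totals), max(x$ligand_totals),
              x$protein_total))
  invisible(x)
}

#' @export
length.titration_series <- function(x) length(x$points)

## Parse assignment labels of the form "L113N-H" (one-letter residue type,
## residue number, optional atom suffix). Anything else is a placeholder and
## yields an unassigned peak.
parse_assignment <- function(labels) {
  m <- regmatches(labels, regexec("^([A-Za-z])([0-9]+)([A-Za-z].*)?$", labels))
  resno <- vapply(m, function(g) if (length(g)) as.integer(g[3]) else NA_integer_,
                  integer(1))
  restype <- vapply(m, function(g) if (length(g)) toupper(g[2]) else NA_character_,
                    character(1))
  restype[is.na(resno)] <- NA_character_
  data.frame(resno = resno, restype = restype, stringsAsFactors = FALSE)
}

format_assignment <- function(restype, resno) {
  out <- rep("?", length(resno))
  ok <- !is.na(resno)
  ty <- ifelse(is.na(restype), "X", restype)
  out[ok] <- paste0(ty[ok], resno[ok], "N-H")
  out
}

#' Read a peak list file
#'
#' Reads Sparky-style `.list` files (assignment label, two shift columns,
#' optional height) or plain TSV (`id`, `h_ppm`, `n_ppm`, optional `height`,
#' `resno`, `restype` columns). Assignment labels of the form `"L113N-H"`
#' are parsed into residue number and type; placeholders (`"?"` or any
#' unparseable label) yield unassigned peaks rather than an error. Line
#' order is preserved.
#'
#' @param path file path.
#' @param dialect `"sparky-list"` or `"tsv"`.
#' @param axis_order `"hn"` if the first shift column is 1H (default),
#'   `"nh"` if the exporter lists 15N first. Sparky dialect only.
#' @param point_index,ligand_total,protein_total,label titration metadata
#'   attached to the returned list (not stored in the file formats).
#' @return A [peak_list()].
#' @export
read_peak_list <- function(path, dialect = c("sparky-list", "tsv"),
                           axis_order = c("hn", "nh"),
                           point_index = 0L, ligand_total = 0,
                           protein_total = 0.4, label = basename(path)) {
  dialect <- match.arg(dialect)
  axis_order <- match.arg(axis_order)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (!nrow(df)) stop("empty peak list file: ", path)
    return(peak_list(df, point_index = point_index,
                     ligand_total = ligand_total,
                     protein_total = protein_total, label = label))
  }
  lines <- readLines(path, warn = FALSE)
  ## drop Sparky header ("Assignment  w1  w2 ...") and blank lines
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^\\s*Assignment\\b", lines)]
  if (!length(lines)) stop("empty peak list file: ", path)
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(f) < 3)
      stop("line ", i, ": expected at least 3 fields, got ", length(f))
    w1 <- suppressWarnings(as.numeric(f[2]))
    w2 <- suppressWarnings(as.numeric(f[3]))
    if (is.na(w1) || is.na(w2))
      stop("line ", i, ": malformed numeric field in '", lines[[i]], "'")
    height <- if (length(f) >= 4) suppressWarnings(as.numeric(f[4])) else NA_real_
    if (length(f) >= 4 && is.na(height))
      stop("line ", i, ": malformed height field in '", lines[[i]], "'")
    c(label = f[1], w1 = w1, w2 = w2, height = height)
  })
  labs <- vapply(rows, `[[`, "", "label")
  w1 <- as.numeric(vapply(rows, `[[`, "", "w1"))
  w2 <- as.numeric(vapply(rows, `[[`, "", "w2"))
  height <- as.numeric(vapply(rows, `[[`, "", "height"))
  if (axis_order == "hn") { h <- w1; n <- w2 } else { h <- w2; n <- w1 }
  asn <- parse_assignment(labs)
  peaks <- data.frame(id = sprintf("pk%03d", seq_along(labs)),
                      h_ppm = h, n_ppm = n, height = height,
                      resno = asn$resno, restype = asn$restype,
                      stringsAsFactors = FALSE)
  peak_list(peaks, point_index = point_index, ligand_total = ligand_total,
            protein_total = protein_total, label = label)
}

#' Write a peak list file
#'
#' Inverse of [read_peak_list()]; the Sparky dialect stores assignment
#' label, 1H, 15N and height columns, the TSV dialect stores every field.
#'
#' @param pl a [peak_list()].
#' @param path output path.
#' @param dialect `"sparky-list"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_peak_list <- function(pl, path, dialect = c("sparky-list", "tsv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(pl, "peak_list"))
  if (dialect == "tsv") {
    utils::write.table(pl$peaks, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  p <- pl$peaks
  lab <- format_assignment(p$restype, p$resno)
  ht <- ifelse(is.na(p$height), "", sprintf(" %.6g", p$height))
  lines <- c(" Assignment         w1         w2   Height",
             sprintf("%s %.6f %.6f%s", lab, p$h_ppm, p$n_ppm, ht))
  writeLines(lines, path)
  invisible(path)
}

#' Transfer assignments between spectra of related constructs
#'
#' Each unassigned target peak inherits the assignment of its nearest
#' reference peak under the scaled 1H/15N distance (see [scaled_distance()])
#' provided the two peaks are mutual nearest neighbours and their distance
#' is at most `tol`. Each reference assignment is used at most once; exact
#' distance ties (within 1e-9 ppm) leave the peak unassigned and flagged
#' ambiguous. Inputs are not modified.
#'
#' @param reference assigned [peak_list()].
#' @param target [peak_list()] to receive assignments.
#' @param alpha 15N scaling factor (> 0), default 0.154.
#' @param tol maximum scaled distance (ppm) for a transfer.
#' @return A copy of `target` with assignments filled in; the character
#'   vector of ambiguous peak ids is attached as attribute `"ambiguous"`.
#' @export
transfer_assignments <- function(reference, target, alpha = 0.154, tol = 0.02) {
  stopifnot(inherits(reference, "peak_list"), inherits(target, "peak_list"))
  if (alpha <= 0) stop("alpha must be > 0")
  if (tol <= 0) stop("tol must be > 0")
  ref <- reference$peaks[!is.na(reference$peaks$resno), , drop = FALSE]
  tgt <- target$peaks
  out <- target
  if (!nrow(ref) || !nrow(tgt)) return(out)
  D <- scaled_distance_matrix(tgt$h_ppm, tgt$n_ppm, ref$h_ppm, ref$n_ppm, alpha)
  pairing <- mutual_nn_pairs(D, max_dist = tol, tie_tol = 1e-9)
  resno <- out$peaks$resno
  restype <- out$peaks$restype
  resno[pairing$rows] <- ref$resno[pairing$cols]
  restype[pairing$rows] <- ref$restype[pairing$cols]
  out$peaks$resno <- resno
  out$peaks$restype <- restype
  attr(out, "ambiguous") <- tgt$id[pairing$ambiguous_rows]
  out
}

#' Write a CSP table to TSV
#'
#' One row per residue, ordered by residue number, columns `residue`,
#' `dd_h`, `dd_n`, `dd` (ppm, 6 decimals) and `class` (one of `ns`,
#' `1sigma`, `2sigma`, `unassigned`).
#'
#' @param table a [csp_table] (see [classify_significance()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_csp_table <- function(table, path) {
  stopifnot(inherits(table, "csp_table"))
  df <- as.data.frame(table)
  df <- df[order(df$residue), , drop = FALSE]
  num <- function(x) ifelse(is.na(x), "NA", sprintf("%.6f", x))
  lines <- c("residue\tdd_h\tdd_n\tdd\tclass",
             sprintf("%d\t%s\t%s\t%s\t%s", df$residue, num(df$dd_h),
                     num(df$dd_n), num(df$dd), df$class))
  writeLines(lines, path)
  invisible(path)
}

#' Read a CSP table written by [write_csp_table()]
#'
#' @param path TSV path.
#' @return A `csp_table` (distribution statistics recomputed from the
#'   assigned rows).
#' @export
read_csp_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  new_csp_table(df, rule = "mean_plus_ksigma", alpha = NA_real_)
}
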