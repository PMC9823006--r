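#' Read a backbone amide chemical shift table
#'
#' Reads either an NMR-STAR v3 chemical-shift loop (the `Atom_chem_shift`
#' category used by BMRB depositions) or a plain TSV with columns `resno`,
#' `restype`, `atom`, `shift_ppm`. Only backbone amide H and N rows are
#' retained. Residue numbering is taken as-is from the file (the study
#' convention counts from the initiator Met of the expressed construct);
#' no renumbering is applied.
#'
#' @param path file path.
#' @param dialect `"nmrstar3"` or `"tsv"`.
#' @return A data frame of class `"assignment_table"` with one row per
#'   residue: `resno`, `restype`, `h_ppm`, `n_ppm` (NA where the atom is
#'   missing) and logical `amide_complete`.
#' @export
read_shift_table <- function(path, dialect = c("nmrstar3", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  long <- if (dialect == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    need <- c("resno", "restype", "atom", "shift_ppm")
    if (!all(need %in% names(df)))
      stop("shift table lacks required column(s): ",
           paste(setdiff(need, names(df)), collapse = ", "))
    df[, need]
  } else {
    parse_star_shift_loop(path)
  }
  long <- long[long$atom %in% c("H", "N"), , drop = FALSE]
  if (!nrow(long)) stop("no backbone amide H/N rows found in ", path)
  key <- paste(long$resno, long$atom)
  if (anyDuplicated(key))
    stop("duplicate (residue, atom) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  resnos <- sort(unique(long$resno))
  pick <- function(rn, at) {
    i <- which(long$resno == rn & long$atom == at)
    if (length(i)) long$shift_ppm[i] else NA_real_
  }
  out <- data.frame(
    resno = resnos,
    restype = vapply(resnos, function(rn)
      long$restype[match(rn, long$resno)], character(1)),
    h_ppm = vapply(resnos, pick, numeric(1), at = "H"),
    n_ppm = vapply(resnos, pick, numeric(1), at = "N"),
    stringsAsFactors = FALSE
  )
  out$amide_complete <- !is.na(out$h_ppm) & !is.na(out$n_ppm)
  class(out) <- c("assignment_table", "data.frame")
  out
}

## Minimal NMR-STAR v3 loop parser for the Atom_chem_shift category:
## scans for a loop_ whose tag block contains _Atom_chem_shift.* tags, maps
## the Seq_ID/Comp_ID/Atom_ID/Val columns, and reads whitespace-delimited
## data rows until the stop_ keyword.
parse_star_shift_loop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (grepl("^\\s*loop_\\s*$", lines[i])) {
      j <- i + 1L
      tags <- character(0)
      while (j <= n && grepl("^\\s*_", lines[j])) {
        tags <- c(tags, trimws(lines[j])); j <- j + 1L
      }
      if (any(grepl("^_Atom_chem_shift\\.", tags))) {
        short <- sub("^_Atom_chem_shift\\.", "", tags)
        col_seq <- match_first(short, c("Seq_ID", "Comp_index_ID"))
        col_comp <- match_first(short, "Comp_ID")
        col_atom <- match_first(short, "Atom_ID")
        col_val <- match_first(short, "Val")
        if (anyNA(c(col_seq, col_comp, col_atom, col_val)))
          stop("chemical-shift loop lacks a required tag ",
               "(Seq_ID/Comp_index_ID, Comp_ID, Atom_ID, Val)")
        rows <- list()
        while (j <= n && !grepl("^\\s*stop_\\s*$", lines[j])) {
          f <- strsplit(trimws(lines[j]), "\\s+")[[1]]
          if (length(f) >= length(tags)) rows[[length(rows) + 1L]] <- f
          j <- j + 1L
        }
        if (!length(rows)) stop("empty chemical-shift loop in ", path)
        val <- suppressWarnings(
          as.numeric(vapply(rows, `[[`, "", col_val)))
        if (anyNA(val)) stop("non-numeric shift value in chemical-shift loop")
        return(data.frame(
          resno = as.integer(vapply(rows, `[[`, "", col_seq)),
          restype = aa3to1(vapply(rows, `[[`, "", col_comp)),
          atom = vapply(rows, `[[`, "", col_atom),
          shift_ppm = val,
          stringsAsFactors = FALSE
        ))
      }
      i <- j
    }
    i <- i + 1L
  }
  stop("no Atom_chem_shift loop found in ", path)
}

match_first <- function(x, candidates) {
  for (c in candidates) {
    i <- match(c, x)
    if (!is.na(i)) return(i)
  }
  NA_integer_
}

AA_3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

aa3to1 <- function(x) {
  x <- toupper(x)
  out <- unname(AA_3TO1[x])
  out[is.na(out) & nchar(x) == 1] <- x[is.na(out) & nchar(x) == 1]
  out[is.na(out)] <- "X"
  out
}

aa1to3 <- function(x) {
  rev3 <- stats::setNames(names(AA_3TO1), unname(AA_3TO1))
  out <- unname(rev3[toupper(x)])
  out[is.na(out)] <- "UNK"
  out
}

#' Write a backbone amide shift table
#'
#' Inverse of [read_shift_table()]; the `nmrstar3` dialect writes a minimal
#' BMRB-compatible `Atom_chem_shift` loop, the `tsv` dialect a long-format
#' table with one row per (residue, atom).
#'
#' @param table an `assignment_table`.
#' @param path output path.
#' @param dialect `"nmrstar3"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_shift_table <- function(table, path, dialect = c("nmrstar3", "tsv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(table, "assignment_table"))
  long <- do.call(rbind, lapply(seq_len(nrow(table)), function(i) {
    r <- table[i, ]
    rows <- list()
    if (!is.na(r$h_ppm))
      rows[[length(rows) + 1L]] <- data.frame(
        resno = r$resno, restype = r$restype, atom = "H",
        shift_ppm = r$h_ppm, stringsAsFactors = FALSE)
    if (!is.na(r$n_ppm))
      rows[[length(rows) + 1L]] <- data.frame(
        resno = r$resno, restype = r$restype, atom = "N",
        shift_ppm = r$n_ppm, stringsAsFactors = FALSE)
    do.call(rbind, rows)
  }))
  if (dialect == "tsv") {
    utils::write.table(long, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  hdr <- c("data_shifts", "", "save_assigned_chemical_shifts", "loop_",
           "   _Atom_chem_shift.ID",
           "   _Atom_chem_shift.Seq_ID",
           "   _Atom_chem_shift.Comp_ID",
           "   _Atom_chem_shift.Atom_ID",
           "   _Atom_chem_shift.Val")
  body <- sprintf("   %d %d %s %s %.4f", seq_len(nrow(long)), long$resno,
                  aa1to3(long$restype), long$atom, long$shift_ppm)
  writeLines(c(hdr, body, "stop_", "save_"), path)
  invisible(path)
}

#' Build the apo peak list from an assignment table
#'
#' Residues with both amide shifts become assigned peaks at their table
#' positions; amide-incomplete residues are dropped.
#'
#' @param table an `assignment_table`.
#' @param protein_total total protein concentration (mM).
#' @param label free-text label.
#' @return A [peak_list()] at point 0.
#' @export
peaks_from_shift_table <- function(table, protein_total = 0.4,
                                   label = "apo from assignments") {
  stopifnot(inherits(table, "assignment_table"))
  tb <- table[table$amide_complete, , drop = FALSE]
  peak_list(data.frame(id = sprintf("res%03d", tb$resno),
                       h_ppm = tb$h_ppm, n_ppm = tb$n_ppm,
                       resno = tb$resno, restype = tb$restype,
                       stringsAsFactors = FALSE),
            point_index = 0L, ligand_total = 0,
            protein_total = protein_total, label = label)
}
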