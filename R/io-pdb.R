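#' Read a PDB-format coordinate file into an atom table
#'
#' Reads the polymer `ATOM` records of a PDB fixed-column file. The dialect
#' is deliberately narrow — it keeps exactly what a molecular-replacement
#' search model needs:
#' \itemize{
#'   \item `HETATM` records, waters (`HOH`, `WAT`, `DOD`) and hydrogen /
#'     deuterium atoms are discarded;
#'   \item where alternate locations duplicate an atom, the highest-occupancy
#'     conformer is kept (ties broken by the alphabetically first alt-loc);
#'   \item if `MODEL`/`ENDMDL` blocks are present only the first model is
#'     read (use [read_ensemble_pdb()] for multi-model ensembles).
#' }
#'
#' @param text character vector of lines, a single string with newlines, or
#'   a file path to a PDB file
#' @param id identifier for the resulting structure (default: `"model"`)
#' @param resolution,r_value optional entry metadata
#' @return an [mr_structure] atom tibble
#' @export
read_pdb <- function(text, id = "model", resolution = NA_real_,
                     r_value = NA_real_) {
  lines <- as_pdb_lines(text)
  atoms <- parse_atom_lines(lines)
  if (nrow(atoms) == 0) abort("no polymer ATOM records found (empty structure)")
  mr_structure(resolve_altlocs(atoms), id = id,
               resolution = resolution, r_value = r_value)
}

as_pdb_lines <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    text <- readLines(text, warn = FALSE)
  }
  unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
}

WATER_RESIDUES <- c("HOH", "WAT", "DOD")

parse_atom_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  in_model <- 0L
  keep <- logical(length(lines))
  for (i in seq_along(lines)) {
    if (rec[i] == "MODEL ") in_model <- in_model + 1L
    keep[i] <- rec[i] == "ATOM  " && in_model <= 1L
  }
  idx <- which(keep)
  if (length(idx) == 0) {
    return(tibble(chain = character(), resno = integer(), ins = character(),
                  resid = character(), atom = character(),
                  element = character(), alt = character(),
                  x = double(), y = double(), z = double(),
                  occ = double(), b = double()))
  }
  ln <- lines[idx]
  num <- function(s) {
    v <- suppressWarnings(as.numeric(str_trim(s)))
    if (any(is.na(v))) {
      abort(sprintf("malformed fixed-column numeric field at line %d",
                    idx[which(is.na(v))[1]]))
    }
    v
  }
  if (any(nchar(ln) < 54)) {
    abort(sprintf("ATOM record shorter than coordinate columns at line %d",
                  idx[which(nchar(ln) < 54)[1]]))
  }
  atoms <- tibble(
    chain = substr(ln, 22, 22),
    resno = as.integer(num(substr(ln, 23, 26))),
    ins = str_trim(substr(ln, 27, 27)),
    resid = str_trim(substr(ln, 18, 20)),
    atom = str_trim(substr(ln, 13, 16)),
    element = str_trim(substr(ln, 77, 78)),
    alt = str_trim(substr(ln, 17, 17)),
    x = num(substr(ln, 31, 38)),
    y = num(substr(ln, 39, 46)),
    z = num(substr(ln, 47, 54)),
    occ = ifelse(nchar(ln) >= 60, suppressWarnings(as.numeric(substr(ln, 55, 60))), 1),
    b = ifelse(nchar(ln) >= 66, suppressWarnings(as.numeric(substr(ln, 61, 66))), 0)
  )
  atoms$occ[is.na(atoms$occ)] <- 1
  atoms$b[is.na(atoms$b)] <- 0
  # infer element from the atom name when columns 77-78 are blank
  blank <- atoms$element == ""
  atoms$element[blank] <- substr(gsub("[0-9]", "", atoms$atom[blank]), 1, 1)
  atoms <- atoms[!(atoms$resid %in% WATER_RESIDUES), , drop = FALSE]
  atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  atoms
}

resolve_altlocs <- function(atoms) {
  if (nrow(atoms) == 0) return(atoms[, setdiff(names(atoms), "alt")])
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$atom, sep = "|")
  ord <- order(match(key, unique(key)), -atoms$occ, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$ins,
                                   atoms$atom, sep = "|")), , drop = FALSE]
  atoms[, setdiff(names(atoms), "alt"), drop = FALSE]
}

format_atom_line <- function(serial, atom, resid, chain, resno, ins,
                             x, y, z, occ, b, element) {
  if (nchar(atom) > 4) abort(sprintf("atom name '%s' longer than 4 characters", atom))
  name_field <- if (nchar(atom) == 4) atom else str_pad(paste0(" ", atom), 4, "right")
  sprintf("ATOM  %5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name_field, resid, chain, resno,
          ifelse(ins == "", " ", ins), x, y, z, occ, b,
          str_pad(element, 2, "left"))
}

structure_atom_lines <- function(model, serial_start = 1L) {
  tb <- as_tibble(model)
  ord <- order(tb$chain, tb$resno, tb$ins)
  tb <- tb[ord, , drop = FALSE]
  serial <- seq_len(nrow(tb)) + serial_start - 1L
  lines <- character(0)
  for (ch in unique(tb$chain)) {
    sel <- tb$chain == ch
    lines <- c(lines,
               mapply(format_atom_line, serial[sel], tb$atom[sel],
                      tb$resid[sel], tb$chain[sel], tb$resno[sel],
                      tb$ins[sel], tb$x[sel], tb$y[sel], tb$z[sel],
                      tb$occ[sel], tb$b[sel], tb$element[sel],
                      USE.NAMES = FALSE),
               "TER")
  }
  lines
}

#' Write a structure as PDB fixed-column text
#'
#' Emits `ATOM` records (coordinates to 3 decimals), a `TER` per chain and a
#' final `END`. Output is deterministic: the same structure always produces
#' byte-identical text, and `read_pdb(write_pdb(m))` reproduces coordinates
#' to 0.001 Angstrom.
#'
#' @param model an [mr_structure]
#' @param path optional file path; when given the text is also written there
#' @return the PDB text as a single string (invisibly when `path` is given)
#' @export
write_pdb <- function(model, path = NULL) {
  if (nrow(model) == 0) abort("cannot write a structure with no atoms")
  txt <- paste(c(structure_atom_lines(model), "END", ""), collapse = "\n")
  if (!is.null(path)) {
    writeLines(sub("\n$", "", txt), path)
    return(invisible(txt))
  }
  txt
}

#' Write an ensemble search model as an annotated multi-model PDB
#'
#' Each member is emitted as a `MODEL i` / `ENDMDL` block, preceded by one
#' annotation line per member of the form
#' `REMARK PHASER ENSEMBLE MODEL <i> RMS <r.mmm>` carrying that member's
#' r.m.s.d. from the ensemble centroid. MR programs read these cards as the
#' coordinate-error estimate for each member.
#'
#' @param members list of [mr_structure] members, in output order
#' @param rmsd numeric vector of per-member r.m.s.d. values (Angstrom)
#' @param path optional file path
#' @return the PDB text as a single string
#' @export
write_ensemble_pdb <- function(members, rmsd, path = NULL) {
  if (length(members) < 1) abort("ensemble must have at least one member")
  if (length(rmsd) != length(members) || any(is.na(rmsd))) {
    abort("every ensemble member needs an r.m.s.d. annotation")
  }
  remark <- sprintf("REMARK PHASER ENSEMBLE MODEL %d RMS %.3f",
                    seq_along(members), rmsd)
  blocks <- unlist(lapply(seq_along(members), function(i) {
    c(sprintf("MODEL %8d", i), structure_atom_lines(members[[i]]), "ENDMDL")
  }))
  txt <- paste(c(remark, blocks, "END", ""), collapse = "\n")
  if (!is.null(path)) {
    writeLines(sub("\n$", "", txt), path)
    return(invisible(txt))
  }
  txt
}

#' Read back a multi-model ensemble PDB
#'
#' Parses `MODEL`/`ENDMDL` blocks and the `REMARK PHASER ENSEMBLE MODEL`
#' annotation cards written by [write_ensemble_pdb()].
#'
#' @param text lines, string or file path
#' @return a list with `members` (list of [mr_structure]) and `rmsd`
#'   (numeric vector, `NA` where no annotation was present)
#' @export
read_ensemble_pdb <- function(text) {
  lines <- as_pdb_lines(text)
  rem <- grep("^REMARK PHASER ENSEMBLE MODEL", lines, value = TRUE)
  ann <- list()
  for (r in rem) {
    parts <- strsplit(str_trim(r), "\\s+")[[1]]
    ann[[parts[5]]] <- as.numeric(parts[7])
  }
  starts <- grep("^MODEL ", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) == 0) {
    m <- read_pdb(lines)
    return(list(members = list(m), rmsd = unname(unlist(ann))[1] %||% NA_real_))
  }
  if (length(starts) != length(ends)) abort("unbalanced MODEL/ENDMDL blocks")
  members <- vector("list", length(starts))
  rmsd <- rep(NA_real_, length(starts))
  for (i in seq_along(starts)) {
    num <- str_trim(substr(lines[starts[i]], 7, 14))
    members[[i]] <- read_pdb(lines[(starts[i] + 1):(ends[i] - 1)],
                             id = paste0("model_", num))
    if (!is.null(ann[[num]])) rmsd[i] <- ann[[num]]
  }
  list(members = members, rmsd = rmsd)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
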