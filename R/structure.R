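#' Atom-table representation of a protein structure
#'
#' A structure is stored as a tibble with one row per atom, the idiom used
#' throughout the package. Columns:
#' \describe{
#'   \item{chain}{chain identifier (single character)}
#'   \item{resno}{residue number; after renumbering to the target this is
#'     the aligned target position}
#'   \item{ins}{insertion code, `""` when absent}
#'   \item{resid}{three-letter residue name}
#'   \item{source_resno}{the residue number carried by the original
#'     homologue coordinates (preserved across renumbering)}
#'   \item{target_resid}{three-letter code of the aligned target residue,
#'     recorded as an annotation by the editing step; `NA` otherwise}
#'   \item{atom}{atom name, e.g. `"CA"`, `"OG1"`}
#'   \item{element}{element symbol}
#'   \item{x,y,z}{coordinates in Angstrom}
#'   \item{occ}{occupancy in \[0, 1\]}
#'   \item{b}{isotropic B factor in Angstrom^2}
#' }
#' Entry-level metadata (identifier, resolution in Angstrom, crystallographic
#' R value) travels in attributes `id`, `resolution` and `r_value`.
#'
#' @param atoms a data frame with the columns above (missing bookkeeping
#'   columns are filled with defaults)
#' @param id identifier string, e.g. `"3pf8_A1"`
#' @param resolution resolution in Angstrom, or `NA`
#' @param r_value crystallographic R value as a fraction, or `NA`
#' @return a tibble of class `mr_structure`
#' @export
mr_structure <- function(atoms, id = "model", resolution = NA_real_,
                         r_value = NA_real_) {
  atoms <- as_tibble(atoms)
  needed <- c("chain", "resno", "resid", "atom", "element", "x", "y", "z")
  miss <- setdiff(needed, names(atoms))
  if (length(miss) > 0) {
    abort(paste0("atom table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"ins" %in% names(atoms)) atoms$ins <- ""
  if (!"occ" %in% names(atoms)) atoms$occ <- 1
  if (!"b" %in% names(atoms)) atoms$b <- 0
  if (!"source_resno" %in% names(atoms)) atoms$source_resno <- atoms$resno
  if (!"target_resid" %in% names(atoms)) atoms$target_resid <- NA_character_
  atoms$resno <- as.integer(atoms$resno)
  atoms$source_resno <- as.integer(atoms$source_resno)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort("non-finite coordinates in atom table")
  }
  if (any(atoms$occ < 0 | atoms$occ > 1)) abort("occupancy outside [0, 1]")
  if (any(atoms$b < 0)) abort("negative B factor")
  atoms <- atoms[, c("chain", "resno", "ins", "resid", "source_resno",
                     "target_resid", "atom", "element", "x", "y", "z",
                     "occ", "b")]
  structure(atoms,
            id = id, resolution = resolution, r_value = r_value,
            class = c("mr_structure", class(as_tibble(atoms))))
}

#' Rewrap an atom tibble as an `mr_structure`, copying metadata from a template
#'
#' dplyr verbs strip custom attributes; internal code uses this to restore
#' them after a transformation.
#' @param atoms transformed atom table
#' @param template the structure the metadata comes from
#' @return an `mr_structure`
#' @keywords internal
rewrap <- function(atoms, template) {
  mr_structure(atoms,
               id = attr(template, "id"),
               resolution = attr(template, "resolution"),
               r_value = attr(template, "r_value"))
}

#' @export
print.mr_structure <- function(x, ...) {
  cat(sprintf("<mr_structure '%s'>  %d atoms, %d residues, %d chain(s)\n",
              attr(x, "id"), nrow(x), n_residues(x),
              length(unique(x$chain))))
  if (!is.na(attr(x, "resolution"))) {
    cat(sprintf("  resolution %.2f A", attr(x, "resolution")))
    if (!is.na(attr(x, "r_value"))) cat(sprintf(", R %.3f", attr(x, "r_value")))
    cat("\n")
  }
  NextMethod()
  invisible(x)
}

#' Structure identifier
#' @param model an `mr_structure`
#' @return the identifier string
#' @export
structure_id <- function(model) attr(model, "id")

#' Number of residues in a structure
#' @param model an `mr_structure`
#' @return integer count of distinct (chain, resno, ins) triples
#' @export
n_residues <- function(model) {
  nrow(dplyr::distinct(as_tibble(model)[, c("chain", "resno", "ins")]))
}

#' Per-residue atom table split
#'
#' Residues are ordered by chain, then residue number, with insertion codes
#' sorted alphabetically after their parent number.
#' @param model an `mr_structure` (or plain atom tibble)
#' @return list of atom tibbles, one per residue, in chain order
#' @keywords internal
split_residues <- function(model) {
  tb <- as_tibble(model)
  key <- paste(tb$chain, sprintf("%06d", tb$resno), tb$ins, sep = "|")
  split(tb, factor(key, levels = unique(key[order(tb$chain, tb$resno, tb$ins)])))
}

#' CA coordinates of a structure keyed by residue number
#'
#' @param model an `mr_structure` renumbered to target numbering
#' @return tibble with columns resno, x, y, z (one row per residue with a CA)
#' @export
ca_coords <- function(model) {
  tb <- as_tibble(model)
  ca <- tb[tb$atom == "CA", c("resno", "x", "y", "z")]
  ca[order(ca$resno), , drop = FALSE]
}

#' Apply a rigid transform to a structure
#'
#' @param model an `mr_structure`
#' @param transform a list with `rotation` (3x3) and `translation` (length 3)
#'   as returned by [kabsch()]
#' @return the transformed structure
#' @export
transform_structure <- function(model, transform) {
  xyz <- as.matrix(as_tibble(model)[, c("x", "y", "z")])
  new_xyz <- xyz %*% t(transform$rotation)
  new_xyz <- sweep(new_xyz, 2, transform$translation, `+`)
  tb <- as_tibble(model)
  tb$x <- new_xyz[, 1]; tb$y <- new_xyz[, 2]; tb$z <- new_xyz[, 3]
  rewrap(tb, model)
}
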