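#' Renumber a homologue onto target numbering via a pairwise alignment
#'
#' The i-th residue of the (single-chain) model corresponds to the i-th
#' position of the hit sequence in the alignment. Residues whose hit
#' position maps to a target position take that target position as their
#' new residue number (original numbering is preserved in `source_resno`);
#' residues with no aligned target position — insertions relative to the
#' target — are deleted. The aligned target residue type is recorded in
#' `target_resid` for use by the pruning step.
#'
#' @param model single-chain [mr_structure]
#' @param aln `pairwise_aln` from [extract_pairwise()] whose hit row is the
#'   model's sequence
#' @return the renumbered structure
#' @export
renumber_to_target <- function(model, aln) {
  res <- split_residues(model)
  map <- aln$mapping
  if (anyDuplicated(map$target_pos) > 0) {
    abort("alignment maps two model residues to one target position")
  }
  out <- purrr::imap(res, function(atoms, key) {
    i <- match(key, names(res))  # hit-sequence position of this residue
    row <- match(i, map$hit_pos)
    if (is.na(row)) return(NULL)
    atoms$source_resno <- atoms$resno
    atoms$resno <- as.integer(map$target_pos[row])
    atoms$ins <- ""
    atoms$target_resid <- one_to_three(map$target_resid1[row])
    atoms
  })
  out <- dplyr::bind_rows(out[!vapply(out, is.null, logical(1))])
  if (nrow(out) == 0) abort("no residues remain after renumbering")
  rewrap(out[order(out$resno), , drop = FALSE], model)
}

AA_THREE <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
              Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
              L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
              S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL",
              X = "UNK")

one_to_three <- function(aa) unname(AA_THREE[toupper(aa)])

three_to_one <- function(res) {
  inv <- setNames(names(AA_THREE), AA_THREE)
  out <- inv[toupper(res)]
  out[is.na(out)] <- "X"
  unname(out)
}

# the single gamma-position atom retained when a side chain is pruned
GAMMA_ATOM <- c(SER = "OG", THR = "OG1", CYS = "SG", ILE = "CG1", VAL = "CG1")

gamma_atom_for <- function(resid) {
  unname(ifelse(resid %in% names(GAMMA_ATOM), GAMMA_ATOM[resid], "CG"))
}

BACKBONE_CB <- c("N", "CA", "C", "O", "CB")

#' Prune non-identical side chains to the gamma atom (mixed model)
#'
#' Produces a "mixed" MR search model: residues whose homologue type equals
#' the aligned target type keep all their atoms; non-identical residues are
#' pruned to the backbone plus C-beta plus the single gamma-position atom of
#' the homologue residue type (`OG` for Ser, `OG1` for Thr, `SG` for Cys,
#' `CG1` for Ile/Val, `CG` otherwise), where present. Residue names stay
#' those of the homologue (no coordinates are ever invented); the aligned
#' target type remains in `target_resid`. B factors and coordinates of
#' retained atoms are untouched.
#'
#' @param model single-chain [mr_structure]; renumbered via
#'   [renumber_to_target()] first when `aln` is supplied
#' @param aln optional `pairwise_aln`; omit if `model` is already
#'   renumbered and carries `target_resid` annotations
#' @return the pruned structure
#' @export
sculpt_cgamma <- function(model, aln = NULL) {
  if (!is.null(aln)) model <- renumber_to_target(model, aln)
  res <- split_residues(model)
  out <- purrr::map(res, function(atoms) {
    if (!"CA" %in% atoms$atom) {
      abort(sprintf("residue %s %d lacks a CA atom", atoms$resid[1], atoms$resno[1]))
    }
    identical_type <- !is.na(atoms$target_resid[1]) &&
      atoms$resid[1] == atoms$target_resid[1]
    if (identical_type) return(atoms)
    keep <- c(BACKBONE_CB, gamma_atom_for(atoms$resid[1]))
    atoms[atoms$atom %in% keep, , drop = FALSE]
  })
  rewrap(dplyr::bind_rows(out), model)
}

#' Reduce a model to a polyalanine backbone
#'
#' Every residue keeps its backbone atoms `N`, `CA`, `C`, `O` plus `CB`
#' where one exists (none is fabricated for glycine), and is renamed `ALA`.
#' Coordinates and B factors are preserved.
#'
#' @param model an [mr_structure]
#' @return the polyalanine structure
#' @export
make_polyalanine <- function(model) {
  tb <- as_tibble(model)
  tb <- tb[tb$atom %in% BACKBONE_CB, , drop = FALSE]
  tb$resid <- "ALA"
  rewrap(tb, model)
}

#' Apply a model-editing protocol
#'
#' Dispatches to one of the three homologue-modification modes used when
#' preparing MR search models: `"cgamma"` (mixed model via
#' [sculpt_cgamma()]), `"polyala"` ([make_polyalanine()] after
#' renumbering), or `"unmod"` (renumbering only, atoms untouched). All
#' three first renumber the model onto target numbering, so the residue
#' span is identical across protocols and only atom content differs.
#'
#' @param model single-chain [mr_structure]
#' @param aln `pairwise_aln` to the target
#' @param protocol `"cgamma"`, `"polyala"` or `"unmod"`
#' @return the edited structure
#' @export
apply_protocol <- function(model, aln, protocol = c("cgamma", "polyala", "unmod")) {
  protocol <- match.arg(protocol)
  renum <- renumber_to_target(model, aln)
  switch(protocol,
         cgamma = sculpt_cgamma(renum),
         polyala = make_polyalanine(renum),
         unmod = renum)
}
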