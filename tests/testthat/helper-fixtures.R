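# Hand-built fixtures used across the suite. Everything is generated in
# code; nothing is read from disk except the example hit table.

# a 3-residue, 1-chain toy PDB text with known atom counts (3/2/4)
toy_pdb_text <- function() {
  c("REMARK toy fixture",
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00 10.00           C",
    "ATOM      3  C   ALA A   1      10.674   5.329  -4.228  1.00 10.00           C",
    "ATOM      4  N   GLY A   2       9.412   5.743  -4.166  1.00 11.00           N",
    "ATOM      5  CA  GLY A   2       8.388   5.083  -3.364  1.00 11.00           C",
    "ATOM      6  N   SER A   3       7.925   3.870  -3.075  1.00 12.00           N",
    "ATOM      7  CA  SER A   3       7.002   3.116  -2.233  1.00 12.00           C",
    "ATOM      8  CB  SER A   3       7.725   2.597  -0.985  1.00 12.00           C",
    "ATOM      9  OG  SER A   3       8.263   3.669  -0.222  1.00 12.00           O",
    "END")
}

# a tiny structure built directly from an atom tibble; residues are built
# from per-residue atom-name vectors
build_structure <- function(residues, id = "toy", chain = "A",
                            resolution = NA_real_, r_value = NA_real_) {
  rows <- list()
  serial <- 0
  for (i in seq_along(residues)) {
    res <- residues[[i]]
    for (a in res$atoms) {
      serial <- serial + 1
      rows[[serial]] <- tibble::tibble(
        chain = chain, resno = res$resno, ins = "", resid = res$resid,
        atom = a, element = substr(gsub("[0-9]", "", a), 1, 1),
        x = serial * 1.7, y = sin(serial), z = cos(serial) + i,
        occ = 1, b = 15 + i)
    }
  }
  mr_structure(dplyr::bind_rows(rows), id = id,
               resolution = resolution, r_value = r_value)
}

res_spec <- function(resno, resid, atoms) {
  list(resno = resno, resid = resid, atoms = atoms)
}

LEU_ATOMS <- c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2")
LYS_ATOMS <- c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ")
GLY_ATOMS <- c("N", "CA", "C", "O")
SER_ATOMS <- c("N", "CA", "C", "O", "CB", "OG")

# an MSA tibble whose hit row is the model's sequence aligned 1:1
msa_for <- function(target_seq, hit_seq, target_id = "target", hit_id = "hit") {
  tibble::tibble(id = c(target_id, hit_id), aligned = c(target_seq, hit_seq))
}

# random compact coordinate set (not collinear)
rand_coords <- function(n, scale = 10) {
  matrix(stats::runif(3 * n, -scale, scale), n, 3)
}

rotation_about_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

random_rotation <- function() {
  R <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

rewrap <- mrprep:::rewrap

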