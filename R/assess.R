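#' Unit-cell volume from cell parameters
#'
#' `V = abc * sqrt(1 - cos^2(alpha) - cos^2(beta) - cos^2(gamma)
#'  + 2 cos(alpha) cos(beta) cos(gamma))`, with lengths in Angstrom and
#' angles in degrees.
#'
#' @param a,b,c cell edge lengths (Angstrom)
#' @param alpha,beta,gamma cell angles (degrees)
#' @return cell volume in cubic Angstrom
#' @export
cell_volume <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  if (any(c(a, b, c) <= 0)) abort("cell lengths must be positive")
  if (any(c(alpha, beta, gamma) <= 0) || any(c(alpha, beta, gamma) >= 180)) {
    abort("cell angles must lie in (0, 180) degrees")
  }
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180); cg <- cos(gamma * pi / 180)
  disc <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (disc <= 0) abort("cell angles give a non-positive metric discriminant")
  a * b * c * sqrt(disc)
}

#' Matthews coefficient and solvent content
#'
#' `Vm = V / (Z * M)` in Angstrom^3 per Dalton, where `Z` is the number of
#' asymmetric units per cell and `M` the asymmetric-unit mass, with
#' solvent fraction `1 - 1.23 / Vm`. A `Vm` at or below 1.23 would imply
#' non-positive solvent; the value is still returned, flagged by a warning
#' attribute.
#'
#' @param a,b,c,alpha,beta,gamma unit-cell parameters as in [cell_volume()]
#' @param z_asu number of asymmetric units per unit cell (space-group
#'   multiplicity)
#' @param asu_mass asymmetric-unit mass in Dalton
#' @return tibble with `vm` (Angstrom^3/Da), `solvent` (fraction) and
#'   `plausible` (logical, `FALSE` when solvent <= 0)
#' @export
matthews <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                     z_asu = 1, asu_mass) {
  if (asu_mass <= 0) abort("asymmetric-unit mass must be positive")
  if (z_asu < 1) abort("z_asu must be at least 1")
  vm <- cell_volume(a, b, c, alpha, beta, gamma) / (z_asu * asu_mass)
  solvent <- 1 - 1.23 / vm
  if (solvent <= 0) {
    warn(sprintf("Vm = %.2f implies solvent fraction <= 0; contents too heavy for the cell", vm))
  }
  tibble(vm = vm, solvent = solvent, plausible = solvent > 0)
}

#' Estimate the number of copies in the asymmetric unit
#'
#' Evaluates the Matthews coefficient for `n = 1, 2, ...` copies of the
#' molecule while the solvent fraction stays at or above 0.25, and selects
#' the copy number whose solvent content lies closest to 0.50 (ties going
#' to the larger `n`). If even a single copy leaves less than 25% solvent
#' the estimate falls back to `n = 1` with `plausible = FALSE`.
#'
#' @param a,b,c,alpha,beta,gamma unit-cell parameters
#' @param z_asu asymmetric units per cell (space-group multiplicity)
#' @param residue_count residues per molecule
#' @param mean_residue_mass average residue mass in Dalton (default 110)
#' @return tibble with `n_copies`, `vm`, `solvent`, `plausible`, plus the
#'   scanned table in attribute `scan`
#' @export
estimate_copies <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                            z_asu = 1, residue_count,
                            mean_residue_mass = 110) {
  if (residue_count < 1) abort("residue_count must be at least 1")
  mono_mass <- residue_count * mean_residue_mass
  scan <- list()
  n <- 1L
  repeat {
    mt <- suppressWarnings(
      matthews(a, b, c, alpha, beta, gamma, z_asu, n * mono_mass))
    scan[[n]] <- dplyr::mutate(mt, n_copies = n, .before = 1)
    if (mt$solvent < 0.25 || n > 1000L) break
    n <- n + 1L
  }
  scan <- dplyr::bind_rows(scan)
  ok <- scan[scan$solvent >= 0.25, , drop = FALSE]
  if (nrow(ok) == 0) {
    warn("no copy number leaves at least 25% solvent; reporting n = 1")
    out <- scan[1, , drop = FALSE]
    out$plausible <- FALSE
  } else {
    # closest to 50% solvent, ties resolved towards the larger copy number
    ord <- order(abs(ok$solvent - 0.50), -ok$n_copies)
    out <- ok[ord[1], , drop = FALSE]
  }
  attr(out, "scan") <- scan
  out
}

#' Categorise an MR solution from its scores
#'
#' Applies the standard triage thresholds to a row (or rows) of
#' molecular-replacement, refinement and tracing scores:
#' \itemize{
#'   \item category from the refined `r_free`: `GOOD` (< 0.35), `MARGINAL`
#'     (0.35 to 0.5 inclusive), `POOR` (> 0.5), `UNKNOWN` when absent;
#'   \item `phaser_llg_strong`: log-likelihood gain of at least 60;
#'   \item `molrep_tf_strong`: translation-function peak above 8 sigma;
#'   \item `shelxe_success`: trace correlation coefficient above 25% with a
#'     mean traced chain length of ten residues or more.
#' }
#' Flags are `NA` where the underlying score is absent.
#'
#' @param scores tibble with any of the columns `model_id`, `phaser_llg`,
#'   `phaser_tfz`, `molrep_rf_sigma`, `molrep_tf_sigma`, `r_work`,
#'   `r_free`, `shelxe_cc`, `shelxe_acl`
#' @return the input with `category` and flag columns appended
#' @export
categorize <- function(scores) {
  tb <- as_tibble(scores)
  col <- function(nm) if (nm %in% names(tb)) tb[[nm]] else rep(NA_real_, nrow(tb))
  r_free <- col("r_free")
  tb$category <- dplyr::case_when(
    is.na(r_free) ~ "UNKNOWN",
    r_free < 0.35 ~ "GOOD",
    r_free <= 0.5 ~ "MARGINAL",
    TRUE ~ "POOR"
  )
  tb$phaser_llg_strong <- col("phaser_llg") >= 60
  tb$molrep_tf_strong <- col("molrep_tf_sigma") > 8
  tb$shelxe_success <- col("shelxe_cc") > 25 & col("shelxe_acl") >= 10
  tb
}

#' Rank triaged MR solutions into a summary table
#'
#' Sorts by ascending refined `r_free` (the most reliable overall ordering
#' of trials), with ties broken by `model_id`; rows without an `r_free`
#' keep their input order at the bottom of the table. Categories and flags
#' are (re)computed via [categorize()].
#'
#' @param scores score tibble as for [categorize()]
#' @return ranked tibble with `rank` first
#' @export
rank_solutions <- function(scores) {
  tb <- categorize(scores)
  r_free <- if ("r_free" %in% names(tb)) tb$r_free else rep(NA_real_, nrow(tb))
  has <- which(!is.na(r_free))
  lacks <- which(is.na(r_free))
  ord <- c(has[order(r_free[has], tb$model_id[has])], lacks)
  out <- tb[ord, , drop = FALSE]
  dplyr::mutate(out, rank = dplyr::row_number(), .before = 1)
}
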