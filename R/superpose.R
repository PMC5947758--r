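#' Least-squares rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation that minimise the summed
#' squared distances between `moving` and `fixed` coordinate sets after
#' applying the transform to `moving`. The SVD solution is used, with the
#' reflection corrected so the rotation determinant is +1.
#'
#' @param fixed,moving n x 3 coordinate matrices (n >= 3), matched row-wise
#' @return list with `rotation` (3 x 3), `translation` (length 3) and
#'   `rmsd` (Angstrom); `transform_structure()` applies it as
#'   `x R' + t`
#' @export
kabsch <- function(fixed, moving) {
  fixed <- as.matrix(fixed); moving <- as.matrix(moving)
  if (!all(dim(fixed) == dim(moving))) abort("coordinate sets differ in size")
  n <- nrow(fixed)
  if (n < 3) abort("need at least 3 points for superposition")
  cf <- colMeans(fixed); cm <- colMeans(moving)
  X <- sweep(fixed, 2, cf); Y <- sweep(moving, 2, cm)
  sv_y <- svd(Y)$d
  if (sv_y[2] < 1e-8 * max(sv_y[1], 1)) {
    abort("degenerate (collinear) coordinates: superposition is ill-defined")
  }
  H <- t(Y) %*% X
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- as.numeric(cf - R %*% cm)
  moved <- Y %*% t(R)
  rmsd <- sqrt(mean(rowSums((X - moved)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

#' Core positions common to all ensemble members
#'
#' The core of an aligned family is the set of target-numbered residue
#' positions that carry a CA atom in every member. Truncation levels are
#' defined over this core.
#'
#' @param members list of renumbered [mr_structure] objects
#' @return ascending integer vector of core positions
#' @export
core_positions <- function(members) {
  if (length(members) == 0) abort("no members supplied")
  pos_sets <- purrr::map(members, function(m) unique(ca_coords(m)$resno))
  core <- Reduce(intersect, pos_sets)
  if (length(core) == 0) abort("members share no common CA positions (empty core)")
  sort(core)
}

#' Superpose a family of models onto a calculated centroid
#'
#' Iterative least-squares multi-model alignment: the frame is anchored on
#' the first member, every member is Kabsch-superposed onto the current
#' centroid over the core positions, and the centroid is recomputed as the
#' per-position mean of the member CA coordinates; this repeats until the
#' largest centroid shift drops below `tol` (default 1e-6 Angstrom) or
#' `max_iter` iterations. The result carries the per-position variance of
#' the aligned CA positions (mean squared deviation from the centroid,
#' divisor n) — the statistic the ensemble truncation slider ranks — and
#' each member's r.m.s.d. from the centroid over the core.
#'
#' @param members list (optionally named) of renumbered [mr_structure]
#'   objects, at least 2, sharing at least 3 core positions
#' @param tol convergence threshold on the centroid shift (Angstrom)
#' @param max_iter iteration cap
#' @return a `superposed_ensemble`: `members` (transformed structures),
#'   `core` (positions), `centroid` (tibble `resno`,`x`,`y`,`z`),
#'   `variance` (tibble `resno`,`variance`), `member_rmsd` (tibble
#'   `member`,`rmsd`), `iterations`
#' @export
superpose_to_centroid <- function(members, tol = 1e-6, max_iter = 100) {
  if (length(members) < 2) abort("need at least 2 members to build an ensemble")
  if (is.null(names(members)) || any(names(members) == "")) {
    names(members) <- vapply(members, structure_id, character(1))
  }
  core <- core_positions(members)
  if (length(core) < 3) abort("fewer than 3 shared core positions")
  core_ca <- function(m) {
    ca <- ca_coords(m)
    as.matrix(ca[match(core, ca$resno), c("x", "y", "z")])
  }
  centroid <- core_ca(members[[1]])
  iter <- 0L
  repeat {
    iter <- iter + 1L
    members <- purrr::map(members, function(m) {
      tr <- kabsch(centroid, core_ca(m))
      transform_structure(m, tr)
    })
    stack <- lapply(members, core_ca)
    new_centroid <- Reduce(`+`, stack) / length(stack)
    shift <- max(sqrt(rowSums((new_centroid - centroid)^2)))
    centroid <- new_centroid
    if (shift < tol || iter >= max_iter) break
  }
  stack <- lapply(members, core_ca)
  sq_dev <- vapply(stack, function(s) rowSums((s - centroid)^2),
                   numeric(length(core)))
  sq_dev <- matrix(sq_dev, nrow = length(core))
  variance <- rowMeans(sq_dev)
  member_rmsd <- sqrt(colMeans(sq_dev))
  structure(list(
    members = members,
    core = core,
    centroid = tibble(resno = core, x = centroid[, 1], y = centroid[, 2],
                      z = centroid[, 3]),
    variance = tibble(resno = core, variance = variance),
    member_rmsd = tibble(member = names(members), rmsd = unname(member_rmsd)),
    iterations = iter
  ), class = "superposed_ensemble")
}

#' @export
print.superposed_ensemble <- function(x, ...) {
  cat(sprintf(paste0("<superposed_ensemble>  %d members, %d core positions, ",
                     "mean r.m.s.d. %.3f A (converged in %d iteration(s))\n"),
              length(x$members), length(x$core), mean(x$member_rmsd$rmsd),
              x$iterations))
  invisible(x)
}

#' @describeIn superpose_to_centroid per-position variance table (tidy method)
#' @param x a `superposed_ensemble`
#' @param ... unused
#' @export
tidy.superposed_ensemble <- function(x, ...) x$variance

#' @describeIn superpose_to_centroid one-row summary (glance method)
#' @export
glance.superposed_ensemble <- function(x, ...) {
  tibble(n_members = length(x$members), n_core = length(x$core),
         mean_rmsd = mean(x$member_rmsd$rmsd),
         mean_variance = mean(x$variance$variance),
         iterations = x$iterations)
}

#' Pairwise CA r.m.s.d. between two renumbered structures
#'
#' Kabsch-superposes the CA atoms shared by residue number between the two
#' models and reports the minimised r.m.s.d.
#'
#' @param a,b renumbered [mr_structure] objects sharing >= 3 positions
#' @return r.m.s.d. in Angstrom
#' @export
pairwise_rmsd <- function(a, b) {
  ca_a <- ca_coords(a); ca_b <- ca_coords(b)
  shared <- intersect(ca_a$resno, ca_b$resno)
  if (length(shared) < 3) abort("fewer than 3 shared CA positions")
  A <- as.matrix(ca_a[match(shared, ca_a$resno), c("x", "y", "z")])
  B <- as.matrix(ca_b[match(shared, ca_b$resno), c("x", "y", "z")])
  kabsch(A, B)$rmsd
}
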