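#' Truncation levels for derived ensembles
#'
#' Derived ensembles are generated by truncating the most variable parts of
#' the base alignment in steps of `step` percent: the first level keeps
#' 100% of the core, the last keeps only the most conserved `step` percent.
#' The default step of 5 gives 20 derived levels.
#'
#' @param step step size in percent; must divide 100
#' @return descending integer vector of levels, `100, 100-step, ..., step`
#' @export
truncation_levels <- function(step = 5) {
  if (step < 1 || step > 100 || 100 %% step != 0) {
    abort("step must be a divisor of 100 between 1 and 100")
  }
  seq(100L, as.integer(step), by = -as.integer(step))
}

#' Core positions retained at a truncation level
#'
#' Selects the `ceiling(percent/100 * n_core)` core positions of lowest
#' CA variance (ties broken by ascending residue number, which also makes
#' the retained sets nest across levels), returned in residue order.
#' Ceiling rounding means a 184-residue core keeps 19 positions at the
#' 10% level.
#'
#' @param x a `superposed_ensemble`, or a tibble with columns `resno` and
#'   `variance`
#' @param percent truncation level in (0, 100\]
#' @return ascending integer vector of retained positions
#' @export
retained_at <- function(x, percent) {
  if (inherits(x, "superposed_ensemble")) x <- x$variance
  if (!is.numeric(percent) || percent <= 0 || percent > 100) {
    abort("percent must lie in (0, 100]")
  }
  k <- as.integer(ceiling(percent / 100 * nrow(x)))
  ord <- order(x$variance, x$resno)
  sort(x$resno[ord[seq_len(k)]])
}

#' Build the base ensemble and its truncated derivatives
#'
#' From a superposed family this produces the base ensemble — every residue
#' of every member, including residues outside the common core (labelled
#' `"base"`; interfaces elsewhere call it "110%") — plus one derived
#' ensemble per truncation level. Members of a numeric level contain
#' exactly the retained core positions for that level; each member is
#' re-superposed onto the centroid restricted to those positions so that
#' its r.m.s.d. annotation describes the model actually written (when
#' fewer than 3 positions remain the base frame is kept and only the
#' r.m.s.d. is recomputed).
#'
#' @param superposed a `superposed_ensemble`
#' @param step truncation step in percent (default 5)
#' @param domain optional domain (cluster) number carried into the result
#' @return an `ensemble_set` tibble with one row per ensemble: `level`
#'   (`"base"`, `"100"`, ... ), `percent` (`NA` for base), `n_retained`,
#'   `members` (list-column of structure lists) and `member_rmsd`
#'   (list-column of tibbles)
#' @export
build_ensembles <- function(superposed, step = 5, domain = NA_integer_) {
  stopifnot(inherits(superposed, "superposed_ensemble"))
  levels <- truncation_levels(step)
  centroid <- superposed$centroid
  base_row <- tibble(
    level = "base", percent = NA_integer_,
    n_retained = length(superposed$core),
    members = list(superposed$members),
    member_rmsd = list(superposed$member_rmsd)
  )
  derived <- purrr::map(levels, function(p) {
    retained <- retained_at(superposed, p)
    cen <- centroid[match(retained, centroid$resno), , drop = FALSE]
    cen_mat <- as.matrix(cen[, c("x", "y", "z")])
    trunc <- purrr::imap(superposed$members, function(m, nm) {
      tb <- as_tibble(m)
      tb <- tb[tb$resno %in% retained, , drop = FALSE]
      kept <- rewrap(tb, m)
      ca <- ca_coords(kept)
      mat <- as.matrix(ca[match(retained, ca$resno), c("x", "y", "z")])
      if (length(retained) >= 3) {
        tr <- kabsch(cen_mat, mat)
        kept <- transform_structure(kept, tr)
        rmsd <- tr$rmsd
      } else {
        rmsd <- sqrt(mean(rowSums((mat - cen_mat)^2)))
      }
      list(model = kept, rmsd = rmsd)
    })
    tibble(
      level = as.character(p), percent = as.integer(p),
      n_retained = length(retained),
      members = list(purrr::map(trunc, "model")),
      member_rmsd = list(tibble(member = names(trunc),
                                rmsd = purrr::map_dbl(trunc, "rmsd")))
    )
  })
  out <- dplyr::bind_rows(c(list(base_row), derived))
  attr(out, "domain") <- domain
  class(out) <- c("ensemble_set", class(out))
  out
}

#' @export
print.ensemble_set <- function(x, ...) {
  cat(sprintf("<ensemble_set>  %d ensembles (base + %d derived), %d member(s) each\n",
              nrow(x), sum(!is.na(x$percent)), length(x$members[[1]])))
  NextMethod()
  invisible(x)
}

#' @describeIn build_ensembles long per-member r.m.s.d. table (tidy method)
#' @param x an `ensemble_set`
#' @param ... unused
#' @export
tidy.ensemble_set <- function(x, ...) {
  tidyr::unnest(
    dplyr::select(as_tibble(x), "level", "percent", "n_retained", "member_rmsd"),
    "member_rmsd")
}

#' @describeIn build_ensembles one-row summary (glance method)
#' @export
glance.ensemble_set <- function(x, ...) {
  tb <- tidy(x)
  tibble(n_ensembles = nrow(x), n_derived = sum(!is.na(x$percent)),
         n_members = length(x$members[[1]]),
         base_mean_rmsd = mean(tb$rmsd[tb$level == "base"]),
         min_mean_rmsd = min(tapply(tb$rmsd, tb$level, mean)))
}

#' Extract one member of an ensemble as a standalone search model
#'
#' Pulls the truncated coordinates of a single member out of an
#' `ensemble_set` row — for instance the component deriving from the
#' highest-scoring homologue — for use as a single-model search model. The
#' member's r.m.s.d.-from-centroid annotation travels along in attribute
#' `rmsd`.
#'
#' @param ensembles an `ensemble_set` from [build_ensembles()]
#' @param member_id member name
#' @param level level label (`"base"`, `"50"`, ...) or numeric percent
#' @return the member [mr_structure] with attribute `rmsd`
#' @export
extract_single <- function(ensembles, member_id, level = "base") {
  level <- as.character(level)
  row <- which(ensembles$level == level)
  if (length(row) != 1) abort(sprintf("no ensemble at level '%s'", level))
  members <- ensembles$members[[row]]
  if (!member_id %in% names(members)) {
    abort(sprintf("no member '%s' in ensemble", member_id))
  }
  rmsd_tb <- ensembles$member_rmsd[[row]]
  model <- members[[member_id]]
  attr(model, "rmsd") <- rmsd_tb$rmsd[match(member_id, rmsd_tb$member)]
  model
}

#' Initial r.m.s.d. estimate from sequence identity
#'
#' MR programs weight a search model by its expected coordinate error; when
#' no structural superposition is available an initial estimate can be made
#' from the sequence identity between search model and target, using the
#' exponential identity-to-deviation relationship familiar from
#' homology-modelling calibrations: `0.4 * exp(1.87 * (1 - identity))`
#' Angstrom. At 100% identity this floors at 0.40 Angstrom; at 25% identity
#' it reaches about 1.6 Angstrom, of the same order as pairwise core
#' r.m.s.d. values observed for distant homologues.
#'
#' @param identity sequence identity fraction in (0, 1]
#' @return estimated r.m.s.d. in Angstrom
#' @export
rmsd_from_identity <- function(identity) {
  if (any(!is.finite(identity)) || any(identity <= 0) || any(identity > 1)) {
    abort("identity must lie in (0, 1]")
  }
  0.4 * exp(1.87 * (1 - identity))
}
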