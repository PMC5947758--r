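#' Default run configuration for search-model preparation
#'
#' Collects every tunable the pipeline honours, at its standard value:
#' \describe{
#'   \item{score_cutoff}{minimum hit score retained (20; keyword alias
#'     `PMRCUTOFF`)}
#'   \item{redundancy_level}{sequence-database redundancy level in percent
#'     (95; one of 100, 95, 90, 70, 50)}
#'   \item{mid_tol, ext_tol}{domain-clustering tolerances on alignment
#'     midpoint and extent, in residues (10 and 25)}
#'   \item{truncation_step}{ensemble truncation step in percent (5, giving
#'     20 derived ensembles)}
#'   \item{protocol}{model-editing protocol (`"cgamma"` mixed models)}
#'   \item{mean_residue_mass}{average residue mass in Dalton for
#'     copy-number estimation (110)}
#'   \item{good_rfree, marginal_rfree}{solution-triage boundaries on the
#'     refined R-free (0.35 and 0.5)}
#'   \item{llg_strong, tf_sigma_strong, shelxe_cc_min, shelxe_acl_min}{flag
#'     thresholds (60, 8, 25, 10)}
#'   \item{seed}{RNG seed used by any stochastic fixture generation}
#' }
#'
#' @param ... named overrides of the defaults
#' @return a named list of configuration values
#' @export
default_config <- function(...) {
  cfg <- list(
    score_cutoff = 20,
    redundancy_level = 95,
    mid_tol = 10,
    ext_tol = 25,
    truncation_step = 5,
    protocol = "cgamma",
    mean_residue_mass = 110,
    good_rfree = 0.35,
    marginal_rfree = 0.5,
    llg_strong = 60,
    tf_sigma_strong = 8,
    shelxe_cc_min = 25,
    shelxe_acl_min = 10,
    seed = 1
  )
  # legacy pipeline keyword alias
  dots <- list(...)
  if ("PMRCUTOFF" %in% names(dots)) {
    dots$score_cutoff <- dots$PMRCUTOFF
    dots$PMRCUTOFF <- NULL
  }
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  if (!cfg$redundancy_level %in% c(100, 95, 90, 70, 50)) {
    abort("redundancy_level must be one of 100, 95, 90, 70, 50")
  }
  cfg
}
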