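#' Run the search-model preparation pipeline
#'
#' Ties the stages together in model-search-and-preparation mode: hit
#' filtering by score, His-tag/length preprocessing and redundancy
#' reduction of the hit sequences, pairwise-alignment extraction from the
#' search MSA, domain clustering by midpoint/extent, alignment-guided
#' editing of each homologue, superposition onto a calculated centroid,
#' and variance-ranked ensemble truncation. When `output_dir` is given the
#' standard tree is written:
#' `"<output_dir>/models/domain_<n>/ensembles/ensemble_<level>.pdb"` plus
#' per-hit FASTA and PIR pairwise alignment files under each domain
#' folder.
#'
#' @param target one-row sequence tibble for the target (id + sequence)
#' @param structures named list of homologue [mr_structure] objects, named
#'   by hit id
#' @param msa alignment tibble from [read_stockholm()] containing the
#'   target row and one row per hit
#' @param hits hit tibble (`id`, `score`) from [read_hit_table()]
#' @param config configuration list from [default_config()]
#' @param output_dir optional directory for the output tree
#' @return an `mr_prepare_run`: `report` (per-stage counts), `hits` (the
#'   clustered hit table with spans, domains and identities), `domains`
#'   (list of per-domain results, each with the superposition and
#'   `ensemble_set`), and `output_dir`
#' @export
run_prepare <- function(target, structures, msa, hits,
                        config = default_config(), output_dir = NULL) {
  n_input <- nrow(hits)
  hits <- filter_hits(hits, cutoff = config$score_cutoff)
  n_scored <- nrow(hits)

  # hit sequences, de-gapped from the MSA, with entry metadata
  seqs <- purrr::map(hits$id, function(id) {
    if (!id %in% msa$id) abort(sprintf("hit '%s' missing from the alignment", id))
    s <- gsub("-", "", msa$aligned[match(id, msa$id)])
    st <- structures[[id]]
    tibble(id = id, sequence = s,
           resolution = if (is.null(st)) NA_real_ else attr(st, "resolution"),
           r_value = if (is.null(st)) NA_real_ else attr(st, "r_value"))
  })
  seqs <- dplyr::bind_rows(c(list(tibble(id = character(),
                                         sequence = character(),
                                         resolution = double(),
                                         r_value = double())), seqs))
  seqs <- preprocess_sequence_db(seqs)
  seqs <- reduce_redundancy(seqs, level = config$redundancy_level)
  hits <- hits[hits$id %in% seqs$id, , drop = FALSE]
  n_nonredundant <- nrow(hits)

  if (nrow(hits) > 0) {
    aln <- purrr::map(hits$id, ~ extract_pairwise(msa, target$id, .x))
    names(aln) <- hits$id
    spans <- purrr::map(aln, hit_span)
    hits$midpoint <- purrr::map_int(spans, "midpoint")
    hits$extent <- purrr::map_int(spans, "extent")
    hits$identity <- purrr::map_dbl(aln, "identity")
    hits <- cluster_domains(hits, mid_tol = config$mid_tol,
                            ext_tol = config$ext_tol)
  } else {
    aln <- list()
    hits <- dplyr::mutate(hits, midpoint = integer(), extent = integer(),
                          identity = double(), domain = integer(),
                          seed = logical())
  }
  n_domains <- length(unique(hits$domain))

  domains <- list()
  n_ensembles <- 0L
  for (d in sort(unique(hits$domain))) {
    ids <- hits$id[hits$domain == d]
    ids <- ids[ids %in% names(structures)]
    if (length(ids) == 0) next
    edited <- purrr::map(setNames(ids, ids), function(id) {
      apply_protocol(structures[[id]], aln[[id]], protocol = config$protocol)
    })
    dom <- list(domain = d, members = edited, alignments = aln[ids],
                superposed = NULL, ensembles = NULL)
    if (length(edited) >= 2 &&
        length(Reduce(intersect, purrr::map(edited, ~ ca_coords(.x)$resno))) >= 3) {
      dom$superposed <- superpose_to_centroid(edited)
      dom$ensembles <- build_ensembles(dom$superposed,
                                       step = config$truncation_step,
                                       domain = d)
      n_ensembles <- n_ensembles + nrow(dom$ensembles)
    }
    domains[[paste0("domain_", d)]] <- dom
  }

  if (!is.null(output_dir)) {
    write_run_tree(output_dir, target, hits, aln, domains)
  }

  report <- tibble(
    stage = c("input_hits", "score_filtered", "nonredundant", "domains",
              "ensembles"),
    count = c(n_input, n_scored, n_nonredundant, n_domains, n_ensembles)
  )
  structure(list(report = report, hits = hits, domains = domains,
                 config = config, output_dir = output_dir),
            class = "mr_prepare_run")
}

write_run_tree <- function(output_dir, target, hits, aln, domains) {
  for (dom in domains) {
    ddir <- file.path(output_dir, "models", paste0("domain_", dom$domain))
    edir <- file.path(ddir, "ensembles")
    dir.create(edir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(dom$alignments)) {
      a <- dom$alignments[[id]]
      write_fasta(tibble(id = c(target$id, id),
                         sequence = c(a$target_row, a$hit_row)),
                  path = file.path(ddir, paste0(id, "_alignment.fasta")))
      write_pir_pairwise(c(target$id, id), c(a$target_row, a$hit_row),
                         path = file.path(ddir, paste0(id, "_alignment.pir")))
      write_pdb(dom$members[[id]], path = file.path(ddir, paste0(id, ".pdb")))
    }
    if (!is.null(dom$ensembles)) {
      for (i in seq_len(nrow(dom$ensembles))) {
        lvl <- dom$ensembles$level[i]
        write_ensemble_pdb(dom$ensembles$members[[i]],
                           dom$ensembles$member_rmsd[[i]]$rmsd,
                           path = file.path(edir, sprintf("ensemble_%s.pdb", lvl)))
      }
    }
  }
  invisible(NULL)
}

#' @export
print.mr_prepare_run <- function(x, ...) {
  cat("<mr_prepare_run>\n")
  for (i in seq_len(nrow(x$report))) {
    cat(sprintf("  %-16s %d\n", x$report$stage[i], x$report$count[i]))
  }
  if (!is.null(x$output_dir)) cat("  written to", x$output_dir, "\n")
  invisible(x)
}

#' @describeIn run_prepare clustered hit table (tidy method)
#' @param x an `mr_prepare_run`
#' @param ... unused
#' @export
tidy.mr_prepare_run <- function(x, ...) as_tibble(x$hits)

#' @describeIn run_prepare one-row stage-count summary (glance method)
#' @export
glance.mr_prepare_run <- function(x, ...) {
  tidyr::pivot_wider(x$report, names_from = "stage", values_from = "count")
}

#' Triage a score table and write the ranked summary
#'
#' Thin assessment entry point: reads (or accepts) a solution-score table,
#' applies [categorize()] and [rank_solutions()], and optionally writes the
#' ranked table as TSV.
#'
#' @param scores a score tibble, or a path to a TSV file with columns named
#'   as in [categorize()]
#' @param path optional output TSV path
#' @return the ranked tibble
#' @export
run_assess <- function(scores, path = NULL) {
  if (is.character(scores) && length(scores) == 1) {
    scores <- as_tibble(utils::read.delim(scores, sep = "\t",
                                          stringsAsFactors = FALSE))
  }
  ranked <- rank_solutions(scores)
  if (!is.null(path)) {
    utils::write.table(ranked, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  ranked
}
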