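#' Clean a sequence database for homology searching
#'
#' Strips terminal polyhistidine purification tags (runs of four or more
#' consecutive `H` at either end of the chain) and then removes entries
#' shorter than ten residues. Both steps prevent search results being
#' dominated by false-positive matches to tags or short fragments.
#'
#' @param records sequence tibble (`id`, `sequence`, optional metadata)
#' @param min_his minimum terminal histidine run treated as a tag (default 4)
#' @param min_length minimum retained sequence length (default 10)
#' @return the filtered tibble, same columns, original order preserved
#' @export
preprocess_sequence_db <- function(records, min_his = 4, min_length = 10) {
  recs <- as_tibble(records)
  strip <- function(s) {
    s <- sub(sprintf("^H{%d,}", min_his), "", s)
    sub(sprintf("H{%d,}$", min_his), "", s)
  }
  recs$sequence <- vapply(recs$sequence, strip, character(1), USE.NAMES = FALSE)
  recs[nchar(recs$sequence) >= min_length, , drop = FALSE]
}

#' Reduce a sequence database to a chosen redundancy level
#'
#' Clusters sequences whose pairwise identity exceeds `level`% by greedy
#' single-linkage (identity from [sequence_identity()]) and keeps one
#' representative per cluster: the entry with the best (numerically
#' smallest) resolution, then the lowest R value, then the
#' lexicographically first identifier. Level 100 means no redundancy
#' removal and returns the input unchanged.
#'
#' @param records sequence tibble with optional `resolution`/`r_value`
#' @param level one of 100, 95, 90, 70, 50 (percent identity threshold)
#' @return tibble of representatives, in input order
#' @export
reduce_redundancy <- function(records, level = 95) {
  if (!level %in% c(100, 95, 90, 70, 50)) {
    abort("redundancy level must be one of 100, 95, 90, 70, 50")
  }
  recs <- as_tibble(records)
  if (level == 100 || nrow(recs) <= 1) return(recs)
  n <- nrow(recs)
  # single-linkage components over the identity > level/100 graph
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  thr <- level / 100
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (find(i) == find(j)) next
      if (sequence_identity(recs$sequence[i], recs$sequence[j]) > thr) {
        comp[find(j)] <- find(i)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  res <- if ("resolution" %in% names(recs)) recs$resolution else rep(NA_real_, n)
  rv <- if ("r_value" %in% names(recs)) recs$r_value else rep(NA_real_, n)
  res[is.na(res)] <- Inf
  rv[is.na(rv)] <- Inf
  keep <- vapply(unique(roots), function(r) {
    members <- which(roots == r)
    members[order(res[members], rv[members], recs$id[members])][1]
  }, integer(1))
  recs[sort(keep), , drop = FALSE]
}

#' Filter sequence-search hits by score
#'
#' Retains hits whose score is at least `cutoff` (boundary inclusive) and
#' returns them in descending-score order (stable for ties). The default
#' cutoff of 20 discards unrelated proteins and homologues too dissimilar
#' to be useful search models.
#'
#' @param hits hit tibble with columns `id`, `score`
#' @param cutoff minimum retained score (default 20)
#' @return filtered tibble sorted by descending score
#' @export
filter_hits <- function(hits, cutoff = 20) {
  tb <- as_tibble(hits)
  tb <- tb[tb$score >= cutoff, , drop = FALSE]
  tb[order(-tb$score), , drop = FALSE]
}

#' Cluster hits into domains by alignment midpoint and extent
#'
#' A simple seeded grouping of sequence matches into "domains": the
#' highest-scoring unassigned hit seeds a new numbered cluster and every
#' unassigned hit whose midpoint lies within `mid_tol` residues of the
#' seed's midpoint *and* whose extent lies within `ext_tol` residues of the
#' seed's extent joins it; this repeats until every hit is assigned.
#' Tolerances are measured to the seed, not chained, so the partition is
#' deterministic. Score ties are broken by identifier.
#'
#' @param hits tibble with columns `id`, `score`, `midpoint`, `extent`
#' @param mid_tol midpoint tolerance in residues (default 10)
#' @param ext_tol extent tolerance in residues (default 25)
#' @return the input tibble with a `domain` column (cluster number, 1-based
#'   in creation order) and a `seed` logical column
#' @export
cluster_domains <- function(hits, mid_tol = 10, ext_tol = 25) {
  tb <- as_tibble(hits)
  if (nrow(tb) == 0) return(dplyr::mutate(tb, domain = integer(), seed = logical()))
  if (any(is.na(tb$midpoint)) || any(is.na(tb$extent))) {
    abort("every hit needs a midpoint and extent before clustering")
  }
  domain <- rep(NA_integer_, nrow(tb))
  seed <- rep(FALSE, nrow(tb))
  ord <- order(-tb$score, tb$id)
  next_cluster <- 1L
  for (k in ord) {
    if (!is.na(domain[k])) next
    domain[k] <- next_cluster
    seed[k] <- TRUE
    open <- is.na(domain)
    close_enough <- abs(tb$midpoint - tb$midpoint[k]) <= mid_tol &
      abs(tb$extent - tb$extent[k]) <= ext_tol
    domain[open & close_enough] <- next_cluster
    next_cluster <- next_cluster + 1L
  }
  tb$domain <- domain
  tb$seed <- seed
  tb
}
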