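#' Global sequence identity under an end-gap-free affine alignment
#'
#' Aligns two sequences with a Needleman-Wunsch/Gotoh dynamic programme
#' (match +1, mismatch 0, gap open -10, gap extend -0.5 per gap position,
#' terminal gaps free) and reports the fraction of identical aligned
#' residue pairs over the length of the shorter sequence. This denominator
#' makes a fragment that matches part of a full-length chain score as
#' highly identical, which is the semantics redundancy clustering needs.
#'
#' @param a,b amino-acid sequences (one-letter strings)
#' @return identity fraction in \[0, 1\]
#' @export
sequence_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) abort("sequences must be non-empty")
  aln <- align_overlap(a, b)
  aln$n_identical / min(nchar(a), nchar(b))
}

# End-gap-free (overlap) Gotoh alignment. Returns the optimal score and the
# number of identical residue pairs on one optimal path (diagonal-preferred
# traceback).
align_overlap <- function(a, b, match = 1, mismatch = 0,
                          gap_open = 10, gap_ext = 0.5) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  open1 <- gap_open + gap_ext  # cost of the first position of a gap run
  NEG <- -1e18
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)  # gap in a (consumes b)
  F_ <- matrix(NEG, m + 1, n + 1) # gap in b (consumes a)
  for (i in seq_len(m)) {
    Hi1 <- H[i, ]
    Hi <- H[i + 1, ]
    Ei <- E[i + 1, ]
    for (j in seq_len(n)) {
      e <- max(Hi[j] - open1, Ei[j] - gap_ext)
      f <- max(Hi1[j + 1] - open1, F_[i, j + 1] - gap_ext)
      s <- Hi1[j] + if (av[i] == bv[j]) match else mismatch
      Ei[j + 1] <- e
      F_[i + 1, j + 1] <- f
      Hi[j + 1] <- max(s, e, f)
    }
    H[i + 1, ] <- Hi
    E[i + 1, ] <- Ei
  }
  # free trailing gaps: best score on the last row or column
  best <- max(H[m + 1, ], H[, n + 1])
  # endpoint preference: (m, n), then last row (largest j), then last column
  if (H[m + 1, n + 1] >= best) {
    ei <- m; ej <- n
  } else if (max(H[m + 1, ]) >= best) {
    ei <- m; ej <- max(which(H[m + 1, ] >= best)) - 1L
  } else {
    ei <- max(which(H[, n + 1] >= best)) - 1L; ej <- n
  }
  n_id <- 0L
  i <- ei; j <- ej
  tol <- 1e-9
  state <- "H"
  while (i > 0 && j > 0) {
    if (state == "H") {
      s <- H[i, j] + if (av[i] == bv[j]) match else mismatch
      if (abs(H[i + 1, j + 1] - s) < tol) {
        if (av[i] == bv[j]) n_id <- n_id + 1L
        i <- i - 1L; j <- j - 1L
      } else if (abs(H[i + 1, j + 1] - E[i + 1, j + 1]) < tol) {
        state <- "E"
      } else {
        state <- "F"
      }
    } else if (state == "E") {
      from_h <- abs(E[i + 1, j + 1] - (H[i + 1, j] - open1)) < tol
      j <- j - 1L
      if (from_h) state <- "H"
    } else {
      from_h <- abs(F_[i + 1, j + 1] - (H[i, j + 1] - open1)) < tol
      i <- i - 1L
      if (from_h) state <- "H"
    }
  }
  list(score = best, n_identical = n_id)
}

#' Extract the pairwise target/hit alignment from a multiple alignment
#'
#' Takes the target and hit rows of a multiple sequence alignment, removes
#' columns that are gapped in both rows, and derives the identity over
#' match columns plus the residue-position mapping between the two
#' sequences.
#'
#' @param msa alignment tibble from [read_stockholm()] (columns `id`,
#'   `aligned`)
#' @param target_id,hit_id row identifiers, both present in `msa`
#' @return a `pairwise_aln` object: gapped `target_row`/`hit_row`,
#'   `identity` (identical / match columns), and `mapping`, a tibble of
#'   `target_pos`/`hit_pos` for every column where both rows have a residue
#' @export
extract_pairwise <- function(msa, target_id, hit_id) {
  for (id in c(target_id, hit_id)) {
    if (!id %in% msa$id) abort(sprintf("id '%s' not present in alignment", id))
  }
  t_row <- strsplit(msa$aligned[match(target_id, msa$id)], "")[[1]]
  h_row <- strsplit(msa$aligned[match(hit_id, msa$id)], "")[[1]]
  keep <- !(t_row == "-" & h_row == "-")
  t_row <- t_row[keep]; h_row <- h_row[keep]
  t_pos <- cumsum(t_row != "-")
  h_pos <- cumsum(h_row != "-")
  is_match <- t_row != "-" & h_row != "-"
  mapping <- tibble(target_pos = t_pos[is_match], hit_pos = h_pos[is_match],
                    target_resid1 = t_row[is_match], hit_resid1 = h_row[is_match])
  identity <- if (nrow(mapping) == 0) 0 else {
    mean(mapping$target_resid1 == mapping$hit_resid1)
  }
  structure(list(target_id = target_id, hit_id = hit_id,
                 target_row = paste(t_row, collapse = ""),
                 hit_row = paste(h_row, collapse = ""),
                 identity = identity, mapping = mapping),
            class = "pairwise_aln")
}

#' @export
print.pairwise_aln <- function(x, ...) {
  cat(sprintf("<pairwise_aln %s ~ %s>  %d match columns, identity %.3f\n",
              x$target_id, x$hit_id, nrow(x$mapping), x$identity))
  invisible(x)
}

#' @export
tidy.pairwise_aln <- function(x, ...) x$mapping

#' Midpoint and extent of a hit in target numbering
#'
#' The extent is the number of target residues between the first and last
#' aligned positions inclusive; the midpoint is their mean, rounded half-up
#' to an integer residue index.
#'
#' @param aln a `pairwise_aln` from [extract_pairwise()]
#' @return named list with `midpoint` and `extent` (integers)
#' @export
hit_span <- function(aln) {
  if (nrow(aln$mapping) == 0) abort("alignment has no match columns")
  first <- min(aln$mapping$target_pos)
  last <- max(aln$mapping$target_pos)
  list(midpoint = as.integer(floor((first + last) / 2 + 0.5)),
       extent = as.integer(last - first + 1L))
}
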