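# Independent oracles: each re-derives a quantity by a different route from
# the implementation it checks.

# Horn's quaternion characteristic-polynomial method for the minimal
# superposition r.m.s.d. (independent of the SVD route in kabsch()).
quaternion_rmsd <- function(fixed, moving) {
  X <- sweep(as.matrix(fixed), 2, colMeans(fixed))
  Y <- sweep(as.matrix(moving), 2, colMeans(moving))
  S <- t(Y) %*% X
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[3, 1] + S[1, 3]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  e2 <- (sum(X^2) + sum(Y^2) - 2 * lambda) / nrow(X)
  sqrt(max(e2, 0))
}

# identity / alignment-score oracle via Biostrings (independent NW engine
# with the same scoring scheme: match 1, mismatch 0, open 10, extend 0.5,
# free end gaps)
biostrings_overlap <- function(a, b) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]
  mat <- matrix(0, length(aas), length(aas), dimnames = list(aas, aas))
  diag(mat) <- 1
  pa <- Biostrings::pairwiseAlignment(a, b, type = "overlap",
                                      substitutionMatrix = mat,
                                      gapOpening = 10, gapExtension = 0.5)
  list(score = Biostrings::score(pa),
       identity = Biostrings::nmatch(pa) / min(nchar(a), nchar(b)))
}

# brute-force redundancy oracle: full identity matrix, transitive closure,
# then the same representative-preference rule
redundancy_oracle <- function(recs, level) {
  n <- nrow(recs)
  if (level == 100 || n <= 1) return(recs$id)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        adj[i, j] <- sequence_identity(recs$sequence[i], recs$sequence[j]) >
          level / 100
      }
    }
  }
  reach <- adj | diag(TRUE, n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- apply(reach, 1, function(r) min(which(r)))
  res <- if ("resolution" %in% names(recs)) recs$resolution else rep(NA_real_, n)
  rv <- if ("r_value" %in% names(recs)) recs$r_value else rep(NA_real_, n)
  res[is.na(res)] <- Inf
  rv[is.na(rv)] <- Inf
  reps <- vapply(unique(comp), function(cm) {
    mem <- which(comp == cm)
    mem[order(res[mem], rv[mem], recs$id[mem])][1]
  }, integer(1))
  recs$id[sort(reps)]
}

# exhaustive seeded-clustering oracle: literal restatement of the rule with
# explicit set bookkeeping
cluster_oracle <- function(hits, mid_tol = 10, ext_tol = 25) {
  remaining <- seq_len(nrow(hits))
  domain <- rep(NA_integer_, nrow(hits))
  cl <- 0L
  while (length(remaining) > 0) {
    cl <- cl + 1L
    sc <- hits$score[remaining]
    best <- remaining[order(-sc, hits$id[remaining])][1]
    members <- remaining[abs(hits$midpoint[remaining] - hits$midpoint[best]) <= mid_tol &
                           abs(hits$extent[remaining] - hits$extent[best]) <= ext_tol]
    domain[members] <- cl
    remaining <- setdiff(remaining, members)
  }
  domain
}

# brute-force pairwise mapping oracle: walk MSA columns explicitly
mapping_oracle <- function(msa, target_id, hit_id) {
  t_row <- strsplit(msa$aligned[match(target_id, msa$id)], "")[[1]]
  h_row <- strsplit(msa$aligned[match(hit_id, msa$id)], "")[[1]]
  tp <- 0; hp <- 0
  out <- list()
  for (k in seq_along(t_row)) {
    if (t_row[k] != "-") tp <- tp + 1
    if (h_row[k] != "-") hp <- hp + 1
    if (t_row[k] != "-" && h_row[k] != "-") {
      out[[length(out) + 1]] <- c(tp, hp)
    }
  }
  do.call(rbind, out)
}
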