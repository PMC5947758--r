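#' Generate a synthetic target fold and sequence
#'
#' Builds a deterministic, self-avoiding protein-like chain for testing the
#' preparation pipeline without downloads: alternating idealized helical
#' segments (2.3 Angstrom radius, 1.5 Angstrom rise, 100 degrees per
#' residue) and smooth connecting turns, laid out as a serpentine bundle.
#' CA positions are placed by marching along the smooth path at a chord
#' length of 3.8 Angstrom, so consecutive CA-CA distances are exact;
#' backbone atoms (N, C, O), C-beta and a single gamma atom are added from
#' an idealized local frame. The sequence is drawn uniformly from the 20
#' standard residues. Geometry is idealized, not energy-minimised: it
#' provides plausible spacing and self-avoidance, nothing more.
#'
#' @param n_residues chain length (>= 10)
#' @param seed RNG seed; the same (n_residues, seed) always produces the
#'   same structure and sequence
#' @return list with `model` (an [mr_structure], chain `"A"`, residues
#'   numbered from 1) and `sequence` (a one-row sequence tibble)
#' @export
make_target <- function(n_residues, seed = 1) {
  if (n_residues < 10) abort("need at least 10 residues")
  withr_seed(seed, {
    seq1 <- paste(sample(setdiff(names(AA_THREE), "X"), n_residues,
                         replace = TRUE), collapse = "")
    path <- serpentine_path(n_residues)
    ca <- chord_march(path, n_residues, step = 3.8)
    atoms <- backbone_from_ca(ca, strsplit(seq1, "")[[1]])
    list(model = mr_structure(atoms, id = "target"),
         sequence = tibble(id = "target", sequence = seq1,
                           resolution = NA_real_, r_value = NA_real_))
  })
}

# run code under a locally-seeded RNG without disturbing the global stream
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# dense polyline through alternating helices and Hermite turns
serpentine_path <- function(n_residues, helix_len = 12, turn_span = 8) {
  # enough path for n_residues CAs at 3.8 A chords
  n_helices <- ceiling(n_residues / helix_len) + 1
  pts <- list()
  z_dir <- 1
  height <- helix_len * 1.5
  for (h in seq_len(n_helices)) {
    x0 <- 11 * (h - 1)
    t <- seq(0, helix_len, by = 0.02)
    z <- if (z_dir > 0) 1.5 * t else height - 1.5 * t
    theta <- (100 * pi / 180) * t
    helix <- cbind(x0 + 2.3 * cos(theta), 2.3 * sin(theta), z)
    pts[[length(pts) + 1]] <- helix
    if (h < n_helices) {
      # Hermite connector over the top (or bottom) to the next helix
      p0 <- helix[nrow(helix), ]
      t_next <- seq(0, helix_len, by = 0.02)
      z_next_dir <- -z_dir
      z1 <- if (z_next_dir > 0) 1.5 * t_next else height - 1.5 * t_next
      theta1 <- (100 * pi / 180) * t_next
      p1 <- c(11 * h + 2.3 * cos(theta1[1]), 2.3 * sin(theta1[1]), z1[1])
      bulge <- if (z_dir > 0) 6 else -6
      s <- seq(0.02, 0.98, by = 0.005)
      m0 <- c(0, 0, bulge); m1 <- c(0, 0, -bulge)
      herm <- sapply(s, function(u) {
        h00 <- 2 * u^3 - 3 * u^2 + 1; h10 <- u^3 - 2 * u^2 + u
        h01 <- -2 * u^3 + 3 * u^2; h11 <- u^3 - u^2
        h00 * p0 + h10 * m0 + h01 * p1 + h11 * m1
      })
      pts[[length(pts) + 1]] <- t(herm)
    }
    z_dir <- -z_dir
  }
  do.call(rbind, pts)
}

# place n points along a dense polyline at an exact chord distance
chord_march <- function(path, n, step = 3.8) {
  out <- matrix(NA_real_, n, 3)
  out[1, ] <- path[1, ]
  idx <- 1L
  for (i in 2:n) {
    cur <- out[i - 1, ]
    j <- idx
    repeat {
      j <- j + 1L
      if (j > nrow(path)) abort("path exhausted while placing CA atoms")
      if (sqrt(sum((path[j, ] - cur)^2)) >= step) break
    }
    # interpolate between path[j-1] and path[j] to land exactly at `step`
    a <- path[j - 1, ]; b <- path[j, ]
    lo <- 0; hi <- 1
    for (k in 1:40) {
      mid <- (lo + hi) / 2
      p <- a + mid * (b - a)
      if (sqrt(sum((p - cur)^2)) < step) lo <- mid else hi <- mid
    }
    out[i, ] <- a + hi * (b - a)
    idx <- j - 1L
  }
  out
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-9) c(1, 0, 0) else v / n
}

# idealized backbone + CB + gamma atom around each CA from a local frame
backbone_from_ca <- function(ca, seq_chars) {
  n <- nrow(ca)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    prev <- if (i > 1) ca[i - 1, ] else ca[i, ] - (ca[i + 1, ] - ca[i, ])
    nxt <- if (i < n) ca[i + 1, ] else ca[i, ] + (ca[i, ] - ca[i - 1, ])
    t_vec <- unit(nxt - prev)
    curv <- unit((nxt - ca[i, ]) + (prev - ca[i, ]))
    if (abs(sum(t_vec * curv)) > 0.99) curv <- unit(c(t_vec[2], -t_vec[1], 0))
    n_vec <- unit(pracma_cross(t_vec, curv))
    resid <- one_to_three(seq_chars[i])
    pos <- list(
      N = ca[i, ] + 1.46 * unit(-t_vec + 0.4 * curv),
      CA = ca[i, ],
      C = ca[i, ] + 1.52 * unit(t_vec + 0.4 * curv),
      O = ca[i, ] + 1.52 * unit(t_vec + 0.4 * curv) + 1.23 * unit(n_vec + 0.3 * curv)
    )
    if (resid != "GLY") pos$CB <- ca[i, ] + 1.53 * unit(-curv + 0.5 * n_vec)
    if (!resid %in% c("GLY", "ALA")) {
      gname <- gamma_atom_for(resid)
      pos[[gname]] <- pos$CB + 1.52 * unit(-curv - 0.3 * t_vec)
    }
    nm <- names(pos)
    xyz <- do.call(rbind, pos)
    rows[[i]] <- tibble(chain = "A", resno = i, ins = "", resid = resid,
                        atom = nm, element = substr(gsub("[0-9]", "", nm), 1, 1),
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        occ = 1, b = 20)
  }
  dplyr::bind_rows(rows)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Generate a homologue family with controlled identity and noise tiers
#'
#' Emulates the statistical structure ensembling assumes: a conserved core
#' plus variable loops. Each member takes the target coordinates, displaces
#' every residue rigidly by an isotropic Gaussian offset whose standard
#' deviation is `core_sd` in core regions and `loop_sd` inside one
#' contiguous loop block covering `loop_fraction` of the chain, and
#' (optionally) applies a random rigid motion. Member sequences are the
#' target sequence mutated at enough positions to land on the requested
#' identity fraction; structure residue types follow the mutated sequence.
#' Each member carries plausible synthetic entry metadata (resolution,
#' R value).
#'
#' @param target result of [make_target()]
#' @param n_members number of homologues
#' @param identity target sequence identity fraction in (0, 1]
#' @param core_sd,loop_sd per-axis coordinate noise (Angstrom)
#' @param loop_fraction fraction of positions in the variable block
#' @param rigid_motion apply a random rotation + translation per member
#' @param seed RNG seed
#' @return list with `members` (named list of [mr_structure]), `sequences`
#'   (tibble), and `sd_map` (tibble `resno`, `sd`, `tier`) recording the
#'   injected noise for parameter-recovery tests
#' @export
make_family <- function(target, n_members = 10, identity = 0.3,
                        core_sd = 0.2, loop_sd = 2.0, loop_fraction = 0.25,
                        rigid_motion = TRUE, seed = 1) {
  if (identity <= 0 || identity > 1) abort("identity must lie in (0, 1]")
  if (core_sd < 0 || loop_sd < 0) abort("noise sds must be non-negative")
  if (loop_fraction < 0 || loop_fraction >= 1) abort("loop_fraction must lie in [0, 1)")
  tb <- as_tibble(target$model)
  n <- max(tb$resno)
  withr_seed(seed, {
    loop_len <- round(loop_fraction * n)
    loop_start <- if (loop_len > 0) sample(seq_len(n - loop_len + 1), 1) else 1L
    loop_pos <- if (loop_len > 0) seq(loop_start, loop_start + loop_len - 1) else integer(0)
    sd_map <- tibble(resno = seq_len(n),
                     sd = ifelse(seq_len(n) %in% loop_pos, loop_sd, core_sd),
                     tier = ifelse(seq_len(n) %in% loop_pos, "loop", "core"))
    target_chars <- strsplit(target$sequence$sequence, "")[[1]]
    n_mut <- round((1 - identity) * n)
    members <- list()
    seqs <- list()
    for (m in seq_len(n_members)) {
      id <- sprintf("hom%02d_A", m)
      mut_pos <- if (n_mut > 0) sample(seq_len(n), n_mut) else integer(0)
      chars <- target_chars
      for (p in mut_pos) {
        chars[p] <- sample(setdiff(setdiff(names(AA_THREE), "X"), chars[p]), 1)
      }
      atoms <- tb
      # per-residue rigid displacement, tiered by region
      disp <- matrix(rnorm(3 * n), n, 3) * sd_map$sd
      k <- match(atoms$resno, seq_len(n))
      atoms$x <- atoms$x + disp[k, 1]
      atoms$y <- atoms$y + disp[k, 2]
      atoms$z <- atoms$z + disp[k, 3]
      atoms <- retype_residues(atoms, chars)
      model <- mr_structure(atoms, id = id,
                            resolution = round(runif(1, 1.2, 3.0), 2),
                            r_value = round(runif(1, 0.15, 0.25), 3))
      if (rigid_motion) {
        model <- transform_structure(model, random_rigid_motion())
      }
      members[[id]] <- model
      seqs[[id]] <- tibble(id = id, sequence = paste(chars, collapse = ""),
                           resolution = attr(model, "resolution"),
                           r_value = attr(model, "r_value"))
    }
    list(members = members, sequences = dplyr::bind_rows(seqs), sd_map = sd_map)
  })
}

random_rigid_motion <- function(max_shift = 20) {
  M <- matrix(rnorm(9), 3, 3)
  qr_d <- qr(M)
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(rotation = R, translation = runif(3, -max_shift, max_shift))
}

# rename residues to a mutated sequence, adjusting CB/gamma atom inventory
retype_residues <- function(atoms, chars) {
  out <- split(atoms, atoms$resno)
  out <- purrr::map(out, function(res) {
    i <- res$resno[1]
    new_resid <- one_to_three(chars[i])
    if (new_resid == res$resid[1]) return(res)
    keep <- res[res$atom %in% c("N", "CA", "C", "O"), , drop = FALSE]
    cb <- res[res$atom == "CB", , drop = FALSE]
    gm <- res[!res$atom %in% c("N", "CA", "C", "O", "CB"), , drop = FALSE]
    if (new_resid != "GLY" && nrow(cb) == 1) keep <- dplyr::bind_rows(keep, cb)
    if (!new_resid %in% c("GLY", "ALA") && nrow(gm) >= 1) {
      g <- gm[1, , drop = FALSE]
      g$atom <- gamma_atom_for(new_resid)
      g$element <- substr(g$atom, 1, 1)
      keep <- dplyr::bind_rows(keep, g)
    }
    keep$resid <- new_resid
    keep
  })
  dplyr::bind_rows(out)
}

#' Generate a multi-domain hit table and Stockholm alignment
#'
#' Emulates the output of a profile-HMM search whose matches group into
#' domains: for each requested cluster, hits are generated whose aligned
#' span jitters tightly around the cluster midpoint/extent (within +/- 5
#' and +/- 12 residues, i.e. inside the default clustering tolerances) and
#' whose scores are drawn from the given range. The multiple alignment has
#' the full ungapped target row and one gapped row per hit; hit residues
#' are the target subsequence mutated to roughly the requested identity.
#'
#' @param target result of [make_target()]
#' @param clusters tibble with columns `midpoint`, `extent`, `n_hits`,
#'   `score_min`, `score_max`
#' @param identity approximate hit-to-target identity within the span
#' @param seed RNG seed
#' @return list with `hit_table` (text), `stockholm` (text) and `truth`
#'   (tibble `id`, `cluster`, `midpoint`, `extent`, `score`)
#' @export
make_hits <- function(target, clusters, identity = 0.6, seed = 1) {
  n <- nchar(target$sequence$sequence)
  target_chars <- strsplit(target$sequence$sequence, "")[[1]]
  withr_seed(seed, {
    rows <- list()
    truth <- list()
    for (ci in seq_len(nrow(clusters))) {
      cl <- clusters[ci, ]
      for (j in seq_len(cl$n_hits)) {
        mid <- cl$midpoint + sample(-5:5, 1)
        ext <- cl$extent + sample(-12:12, 1)
        first <- mid - floor((ext - 1) / 2)
        last <- first + ext - 1
        if (first < 1 || last > n) {
          abort(sprintf("cluster %d span [%d, %d] falls outside the target (1-%d)",
                        ci, first, last, n))
        }
        id <- sprintf("c%dh%02d_A", ci, j)
        span_chars <- target_chars[first:last]
        n_mut <- round((1 - identity) * length(span_chars))
        if (n_mut > 0) {
          mp <- sample(seq_along(span_chars), n_mut)
          for (p in mp) {
            span_chars[p] <- sample(setdiff(setdiff(names(AA_THREE), "X"),
                                            span_chars[p]), 1)
          }
        }
        row <- rep("-", n)
        row[first:last] <- span_chars
        score <- round(runif(1, cl$score_min, cl$score_max), 1)
        rows[[id]] <- paste(row, collapse = "")
        truth[[id]] <- tibble(id = id, cluster = ci,
                              midpoint = floor((first + last) / 2 + 0.5),
                              extent = as.integer(last - first + 1),
                              score = score)
      }
    }
    truth <- dplyr::bind_rows(truth)
    truth <- truth[order(-truth$score, truth$id), , drop = FALSE]
    msa <- tibble(id = c("target", truth$id),
                  aligned = c(target$sequence$sequence,
                              unlist(rows[truth$id], use.names = FALSE)))
    list(
      hit_table = paste(c("# hit  score",
                          sprintf("%-12s %6.1f", truth$id, truth$score), ""),
                        collapse = "\n"),
      stockholm = write_stockholm(msa),
      truth = truth
    )
  })
}

#' Write a Stockholm 1.0 alignment
#'
#' @param msa tibble with columns `id`, `aligned`
#' @param path optional file path
#' @return Stockholm text as one string
#' @export
write_stockholm <- function(msa, path = NULL) {
  wid <- max(nchar(msa$id))
  out <- c("# STOCKHOLM 1.0",
           sprintf("%-*s  %s", wid, msa$id, msa$aligned),
           "//")
  txt <- paste(c(out, ""), collapse = "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(txt))
  }
  txt
}
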