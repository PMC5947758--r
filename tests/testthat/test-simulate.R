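test_that("target generation is deterministic and geometrically sane", {
  t1 <- make_target(50, seed = 1)
  t2 <- make_target(50, seed = 1)
  expect_identical(as.data.frame(t1$model), as.data.frame(t2$model))
  expect_identical(t1$sequence$sequence, t2$sequence$sequence)
  expect_false(identical(t1$sequence$sequence,
                         make_target(50, seed = 2)$sequence$sequence))
  expect_error(make_target(5), "at least 10")
})

test_that("CA geometry respects chain spacing and self-avoidance", {
  for (seed in c(1, 7)) {
    ca <- as.matrix(ca_coords(make_target(150, seed = seed)$model)[, c("x", "y", "z")])
    consec <- sqrt(rowSums(diff(ca)^2))
    expect_true(all(abs(consec - 3.8) <= 0.1))
    # brute-force: no nonconsecutive pair closer than 3.0 A
    D <- as.matrix(dist(ca))
    D[abs(row(D) - col(D)) <= 1] <- Inf
    expect_gte(min(D), 3.0)
  }
})

test_that("zero noise and no motion reproduce the target exactly", {
  tgt <- make_target(40, seed = 4)
  fam <- make_family(tgt, n_members = 3, identity = 1.0, core_sd = 0,
                     loop_sd = 0, loop_fraction = 0.2, rigid_motion = FALSE,
                     seed = 4)
  for (m in fam$members) {
    expect_equal(as.matrix(m[, c("x", "y", "z")]),
                 as.matrix(tgt$model[, c("x", "y", "z")]), tolerance = 1e-12)
    expect_equal(nrow(m), nrow(tgt$model))
  }
})

test_that("requested sequence identity is achieved within 2%", {
  tgt <- make_target(200, seed = 5)
  for (id_frac in c(0.3, 0.6, 0.9)) {
    fam <- make_family(tgt, n_members = 3, identity = id_frac, seed = 5)
    for (s in fam$sequences$sequence) {
      achieved <- mean(strsplit(s, "")[[1]] ==
                         strsplit(tgt$sequence$sequence, "")[[1]])
      expect_equal(achieved, id_frac, tolerance = 0.02)
    }
  }
})

test_that("family generation returns the injected noise map", {
  tgt <- make_target(100, seed = 6)
  fam <- make_family(tgt, n_members = 4, core_sd = 0.1, loop_sd = 1.5,
                     loop_fraction = 0.3, seed = 6)
  expect_equal(nrow(fam$sd_map), 100)
  expect_equal(sort(unique(fam$sd_map$sd)), c(0.1, 1.5))
  expect_equal(sum(fam$sd_map$tier == "loop"), 30)
  # the loop block is contiguous
  loops <- fam$sd_map$resno[fam$sd_map$tier == "loop"]
  expect_equal(loops, seq(min(loops), max(loops)))
})

test_that("structure residue types track the mutated member sequences", {
  tgt <- make_target(60, seed = 8)
  fam <- make_family(tgt, n_members = 2, identity = 0.5, seed = 8)
  for (id in names(fam$members)) {
    m <- fam$members[[id]]
    chain_seq <- paste(mrprep:::three_to_one(m$resid[m$atom == "CA"]),
                       collapse = "")
    expect_equal(chain_seq, fam$sequences$sequence[fam$sequences$id == id])
  }
})

test_that("engineered hit groups are recovered by domain clustering", {
  tgt <- make_target(400, seed = 10)
  spec4 <- tibble::tibble(midpoint = c(60, 150, 250, 340),
                          extent = c(70, 60, 80, 70),
                          n_hits = c(4, 3, 5, 3),
                          score_min = c(40, 35, 30, 25),
                          score_max = c(60, 55, 50, 45))
  h <- make_hits(tgt, spec4, seed = 10)
  hits <- read_hit_table(h$hit_table)
  msa <- read_stockholm(h$stockholm)
  spans <- purrr::map(hits$id, ~ hit_span(extract_pairwise(msa, "target", .x)))
  hits$midpoint <- purrr::map_int(spans, "midpoint")
  hits$extent <- purrr::map_int(spans, "extent")
  out <- cluster_domains(hits)
  expect_equal(length(unique(out$domain)), 4)
  # recovered partition equals the construction truth
  truth <- h$truth$cluster[match(out$id, h$truth$id)]
  expect_equal(length(unique(paste(out$domain, truth))), 4)
  # single group gives a single cluster
  h1 <- make_hits(tgt, spec4[1, ], seed = 3)
  hits1 <- read_hit_table(h1$hit_table)
  hits1$midpoint <- h1$truth$midpoint[match(hits1$id, h1$truth$id)]
  hits1$extent <- h1$truth$extent[match(hits1$id, h1$truth$id)]
  expect_equal(unique(cluster_domains(hits1)$domain), 1L)
})

test_that("hit generation respects the score cutoff downstream and bounds", {
  tgt <- make_target(100, seed = 12)
  lo <- tibble::tibble(midpoint = 50, extent = 60, n_hits = 6,
                       score_min = 10, score_max = 30)
  h <- make_hits(tgt, lo, seed = 12)
  hits <- read_hit_table(h$hit_table)
  kept <- filter_hits(hits, 20)
  expect_true(all(kept$score >= 20))
  expect_true(nrow(kept) < nrow(hits))
  bad <- tibble::tibble(midpoint = 95, extent = 60, n_hits = 2,
                        score_min = 30, score_max = 40)
  expect_error(make_hits(tgt, bad, seed = 1), "outside the target")
})

test_that("fixture generation is byte-identical across runs", {
  tgt <- make_target(150, seed = 20)
  spec <- tibble::tibble(midpoint = 75, extent = 80, n_hits = 4,
                         score_min = 25, score_max = 50)
  h1 <- make_hits(tgt, spec, seed = 20)
  h2 <- make_hits(tgt, spec, seed = 20)
  expect_identical(h1$hit_table, h2$hit_table)
  expect_identical(h1$stockholm, h2$stockholm)
  f1 <- make_family(tgt, n_members = 3, seed = 21)
  f2 <- make_family(tgt, n_members = 3, seed = 21)
  expect_identical(purrr::map(f1$members, as.data.frame),
                   purrr::map(f2$members, as.data.frame))
})
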