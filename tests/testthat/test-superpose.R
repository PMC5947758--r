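test_that("kabsch recovers rigid motions exactly", {
  set.seed(2)
  X <- rand_coords(12)
  same <- kabsch(X, X)
  expect_equal(same$rotation, diag(3), tolerance = 1e-9)
  expect_equal(same$translation, rep(0, 3), tolerance = 1e-9)
  expect_equal(same$rmsd, 0, tolerance = 1e-9)
  R <- rotation_about_z(90)
  Y <- X %*% t(R)
  Y <- sweep(Y, 2, c(5, 0, 0), `+`)
  fit <- kabsch(X, Y)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  back <- Y %*% t(fit$rotation)
  back <- sweep(back, 2, fit$translation, `+`)
  expect_equal(back, X, tolerance = 1e-9)
})

test_that("kabsch rejects degenerate input", {
  X <- rand_coords(5)
  expect_error(kabsch(X, X[1:4, ]), "differ in size")
  expect_error(kabsch(X[1:2, ], X[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch(rand_coords(5), line), "collinear")
})

test_that("kabsch agrees with the quaternion oracle to 1e-9 A", {
  set.seed(11)
  for (k in 1:20) {
    X <- rand_coords(10)
    Y <- X + matrix(rnorm(30, sd = 0.7), 10, 3)
    Y <- Y %*% t(random_rotation())
    expect_equal(kabsch(X, Y)$rmsd, quaternion_rmsd(X, Y), tolerance = 1e-9)
  }
})

test_that("superposition rmsd is symmetric and rigid-motion invariant", {
  set.seed(5)
  X <- rand_coords(15)
  Y <- X + matrix(rnorm(45, sd = 0.5), 15, 3)
  r1 <- kabsch(X, Y)$rmsd
  expect_equal(kabsch(Y, X)$rmsd, r1, tolerance = 1e-9)
  moved <- sweep(Y %*% t(random_rotation()), 2, c(9, -3, 2), `+`)
  expect_equal(kabsch(X, moved)$rmsd, r1, tolerance = 1e-9)
})

test_that("core positions are the intersection of member CA coverage", {
  cov <- list(a = 1:100, b = 5:100, c = 1:95)
  members <- purrr::imap(cov, function(rng, nm) {
    tgt <- make_target(110, seed = 1)$model
    rewrap(tgt[tgt$resno %in% rng, ], tgt)
  })
  core <- core_positions(members)
  expect_equal(core, 5:95)
  expect_equal(core_positions(members["a"]), 1:100)
  # random coverage against a brute-force intersection
  set.seed(8)
  for (k in 1:10) {
    sets <- lapply(1:3, function(i) sort(sample(1:110, sample(60:100, 1))))
    mems <- lapply(sets, function(s) {
      tgt <- make_target(110, seed = 1)$model
      rewrap(tgt[tgt$resno %in% s, ], tgt)
    })
    expect_equal(core_positions(mems), sort(Reduce(intersect, sets)))
  }
})

test_that("identical copies under random rigid motions collapse to zero spread", {
  set.seed(4)
  tgt <- make_target(60, seed = 12)$model
  members <- lapply(1:3, function(i) {
    transform_structure(tgt, list(rotation = random_rotation(),
                                  translation = runif(3, -15, 15)))
  })
  names(members) <- paste0("copy", 1:3)
  se <- superpose_to_centroid(members)
  expect_lt(max(se$member_rmsd$rmsd), 1e-6)
  expect_lt(max(se$variance$variance), 1e-12)
})

test_that("mean member rmsd matches the closed-form noise expectation", {
  # isotropic Gaussian CA noise sd sigma per axis, n members: the rms about
  # the sample mean has expectation sigma*sqrt(3)*sqrt(1 - 1/n)
  tgt <- make_target(200, seed = 20)
  fam <- make_family(tgt, n_members = 10, identity = 1.0, core_sd = 0.5,
                     loop_sd = 0.5, loop_fraction = 0, rigid_motion = TRUE,
                     seed = 20)
  se <- superpose_to_centroid(fam$members)
  expected <- 0.5 * sqrt(3) * sqrt(1 - 1 / 10)
  expect_equal(mean(se$member_rmsd$rmsd), expected, tolerance = 0.1)
})

test_that("member order only changes the frame, not the spreads", {
  tgt <- make_target(80, seed = 30)
  fam <- make_family(tgt, n_members = 4, identity = 0.9, seed = 30)
  se1 <- superpose_to_centroid(fam$members)
  se2 <- superpose_to_centroid(rev(fam$members))
  r1 <- se1$member_rmsd$rmsd[order(se1$member_rmsd$member)]
  r2 <- se2$member_rmsd$rmsd[order(se2$member_rmsd$member)]
  expect_equal(r1, r2, tolerance = 1e-6)
})

test_that("variance decomposition is conserved", {
  tgt <- make_target(100, seed = 40)
  fam <- make_family(tgt, n_members = 6, identity = 0.8, seed = 40)
  se <- superpose_to_centroid(fam$members)
  lhs <- sum(se$variance$variance) * length(fam$members)
  rhs <- sum(se$member_rmsd$rmsd^2) * length(se$core)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("variance ranking separates injected noise tiers", {
  tgt <- make_target(200, seed = 11)
  fam <- make_family(tgt, n_members = 10, identity = 0.9, core_sd = 0.2,
                     loop_sd = 2.0, loop_fraction = 0.25, seed = 11)
  se <- superpose_to_centroid(fam$members)
  v <- se$variance$variance[match(fam$sd_map$resno, se$variance$resno)]
  k <- sum(fam$sd_map$tier == "loop")
  top <- fam$sd_map$resno[order(-v)][seq_len(k)]
  agreement <- mean(fam$sd_map$tier[match(top, fam$sd_map$resno)] == "loop")
  expect_gte(agreement, 0.95)
})

test_that("pairwise rmsd is zero for rigid copies and tracks noise", {
  tgt <- make_target(60, seed = 50)$model
  expect_equal(pairwise_rmsd(tgt, tgt), 0, tolerance = 1e-9)
  moved <- transform_structure(tgt, list(rotation = rotation_about_z(120),
                                         translation = c(3, 1, -9)))
  expect_equal(pairwise_rmsd(tgt, moved), 0, tolerance = 1e-9)
  # Monte-Carlo oracle for the expected rmsd between two noisy copies
  set.seed(60)
  sigma <- 0.4
  n_pos <- 60
  base <- as.matrix(ca_coords(tgt)[, c("x", "y", "z")])
  mc <- replicate(200, {
    quaternion_rmsd(base + matrix(rnorm(3 * n_pos, sd = sigma), n_pos, 3),
                    base + matrix(rnorm(3 * n_pos, sd = sigma), n_pos, 3))
  })
  measured <- replicate(20, NA_real_)
  for (i in 1:20) {
    f <- make_family(make_target(60, seed = 50), n_members = 2, identity = 1.0,
                     core_sd = sigma, loop_sd = sigma, loop_fraction = 0,
                     seed = 61 + i)
    measured[i] <- pairwise_rmsd(f$members[[1]], f$members[[2]])
  }
  expect_equal(mean(measured), mean(mc), tolerance = 0.05)
})
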