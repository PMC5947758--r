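test_that("database preprocessing strips His tags and short sequences", {
  body40 <- strrep("MKVLITGHAA", 4)
  recs <- tibble::tibble(
    id = c("tagged", "short", "plain", "ctag"),
    sequence = c(paste0("HHHHHH", body40), "MKVLITGH",
                 strrep("MKVLITGHAA", 10), paste0(body40, "HHHH")))
  out <- preprocess_sequence_db(recs)
  expect_equal(out$id, c("tagged", "plain", "ctag"))
  expect_equal(out$sequence[out$id == "tagged"], body40)
  expect_equal(out$sequence[out$id == "ctag"], body40)
  expect_equal(out$sequence[out$id == "plain"], strrep("MKVLITGHAA", 10))
  # three consecutive H are not treated as a tag
  keep3 <- tibble::tibble(id = "x", sequence = paste0("HHH", body40))
  expect_equal(preprocess_sequence_db(keep3)$sequence, paste0("HHH", body40))
})

test_that("redundancy level 100 is a no-op and preference follows metadata", {
  seqs <- tibble::tibble(
    id = c("b", "a"),
    sequence = rep(strrep("MKVLITGHAA", 5), 2),
    resolution = c(1.5, 2.0), r_value = c(0.2, 0.18))
  expect_identical(reduce_redundancy(seqs, 100), seqs)
  out <- reduce_redundancy(seqs, 95)
  expect_equal(nrow(out), 1)
  expect_equal(out$id, "b")  # 1.5 A beats 2.0 A regardless of R value
  # equal resolution: lower R value wins
  seqs2 <- dplyr::mutate(seqs, resolution = 1.5)
  expect_equal(reduce_redundancy(seqs2, 95)$id, "a")
  expect_error(reduce_redundancy(seqs, 80), "one of")
})

test_that("single-linkage collapse matches pairwise-identity expectations", {
  base <- strrep("ACDEFGHIKLMNPQRSTVWY", 3)  # 60 residues
  mutate_at <- function(s, pos) {
    v <- strsplit(s, "")[[1]]
    v[pos] <- ifelse(v[pos] == "A", "G", "A")
    paste(v, collapse = "")
  }
  near <- tibble::tibble(
    id = c("s1", "s2", "s3"),
    sequence = c(base, mutate_at(base, 1:2), mutate_at(base, 3:4)),
    resolution = c(2.0, 1.4, 2.6), r_value = c(0.2, 0.2, 0.2))
  # pairwise ~96.7% identical: one cluster at 95 and at 50
  expect_equal(nrow(reduce_redundancy(near, 95)), 1)
  expect_equal(reduce_redundancy(near, 95)$id, "s2")
  expect_equal(nrow(reduce_redundancy(near, 50)), 1)
  far <- tibble::tibble(
    id = c("f1", "f2", "f3"),
    sequence = c(base, mutate_at(base, 1:24), mutate_at(base, 25:48)),
    resolution = rep(2, 3), r_value = rep(0.2, 3))
  # pairwise 60% identical: all retained at 95
  expect_equal(nrow(reduce_redundancy(far, 95)), 3)
})

test_that("redundancy reduction matches the transitive-closure oracle", {
  set.seed(13)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  parents <- replicate(3, paste(sample(aas, 50, TRUE), collapse = ""))
  recs <- list()
  for (i in 1:12) {
    p <- strsplit(parents[(i %% 3) + 1], "")[[1]]
    nmut <- sample(0:6, 1)
    if (nmut > 0) for (q in sample(50, nmut)) p[q] <- sample(aas, 1)
    recs[[i]] <- tibble::tibble(
      id = sprintf("r%02d", i), sequence = paste(p, collapse = ""),
      resolution = round(runif(1, 1, 3), 2), r_value = round(runif(1, 0.15, 0.3), 3))
  }
  recs <- dplyr::bind_rows(recs)
  for (level in c(95, 90, 70, 50)) {
    expect_equal(reduce_redundancy(recs, level)$id,
                 redundancy_oracle(recs, level),
                 info = paste("level", level))
  }
})

test_that("output size never grows as the redundancy level drops", {
  set.seed(17)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  base <- paste(sample(aas, 40, TRUE), collapse = "")
  recs <- dplyr::bind_rows(lapply(1:8, function(i) {
    v <- strsplit(base, "")[[1]]
    for (q in sample(40, sample(0:20, 1))) v[q] <- sample(aas, 1)
    tibble::tibble(id = sprintf("m%d", i), sequence = paste(v, collapse = ""),
                   resolution = 2, r_value = 0.2)
  }))
  sizes <- vapply(c(100, 95, 90, 70, 50),
                  function(l) nrow(reduce_redundancy(recs, l)), integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("hit filtering is inclusive at the cutoff, ordered, and idempotent", {
  hits <- tibble::tibble(id = c("a", "b", "c", "d"),
                         score = c(19.99, 20.0, 53.9, 43.9))
  out <- filter_hits(hits, cutoff = 20)
  expect_equal(out$id, c("c", "d", "b"))
  expect_identical(filter_hits(out, 20), out)
  expect_equal(nrow(filter_hits(hits[0, ], 20)), 0)
  # the printed ten-hit example set all clears the default cutoff
  table3 <- read_hit_table(system.file("extdata", "example_hits.txt",
                                       package = "mrprep"))
  expect_equal(nrow(filter_hits(table3)), 10)
})

test_that("domain clustering groups by seed-relative tolerances", {
  one <- tibble::tibble(id = c("a", "b", "c"), score = c(30, 20, 25),
                        midpoint = c(100, 105, 108), extent = c(200, 210, 190))
  out <- cluster_domains(one)
  expect_equal(unique(out$domain), 1L)
  expect_true(out$seed[out$id == "a"])
  two <- tibble::tibble(id = c("a", "b", "c", "d"), score = c(50, 45, 40, 35),
                        midpoint = c(100, 102, 300, 305),
                        extent = c(150, 140, 90, 100))
  out2 <- cluster_domains(two)
  expect_equal(out2$domain, c(1L, 1L, 2L, 2L))
})

test_that("clustering matches the exhaustive oracle on 50 seeded hits", {
  set.seed(7)
  hits <- tibble::tibble(
    id = sprintf("h%02d", 1:50),
    score = round(runif(50, 15, 60), 1),
    midpoint = sample(c(100, 150, 300), 50, TRUE) + sample(-15:15, 50, TRUE),
    extent = sample(c(80, 200), 50, TRUE) + sample(-30:30, 50, TRUE))
  out <- cluster_domains(hits)
  expect_equal(out$domain, cluster_oracle(hits))
  # every hit in exactly one cluster; seeds are their clusters' top scorers
  expect_false(any(is.na(out$domain)))
  for (d in unique(out$domain)) {
    members <- out[out$domain == d, ]
    expect_equal(members$id[members$seed],
                 members$id[order(-members$score, members$id)][1])
  }
})
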