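test_that("TN93 distance matches a hand evaluation of the closed form", {
  # 100 bp, 5 A->G transitions, no other changes; frequencies from the
  # pooled pair: gA = 55/200, gG = 45/200, gC = gT = 50/200
  a <- c(rep("A", 30), rep("G", 20), rep("C", 25), rep("T", 25))
  b <- a; b[1:5] <- "G"
  gA <- 55 / 200; gG <- 45 / 200; gR <- gA + gG
  k1 <- 2 * gA * gG / gR
  w1 <- 1 - 0.05 / k1
  expect_equal(tn93_distance(a, b, gamma_shape = NULL), -k1 * log(w1),
               tolerance = 1e-12)
  expect_equal(tn93_distance(a, b, gamma_shape = 0.3),
               k1 * 0.3 * (w1^(-1 / 0.3) - 1), tolerance = 1e-12)
  expect_equal(tn93_distance(a, a), 0)
})

test_that("TN93 agrees with an independent library implementation", {
  skip_if_not_installed("ape")
  set.seed(42)
  for (rep in 1:8) {
    base <- sample(c("a", "c", "g", "t"), 300, replace = TRUE)
    mut <- base
    mut[sample(300, 40)] <- sample(c("a", "c", "g", "t"), 40,
                                   replace = TRUE)
    x <- rbind(base, mut)
    plain <- ape::dist.dna(ape::as.DNAbin(x), model = "TN93")
    gam <- ape::dist.dna(ape::as.DNAbin(x), model = "TN93", gamma = 0.3)
    expect_equal(tn93_distance(toupper(x[1, ]), toupper(x[2, ]),
                               gamma_shape = NULL),
                 as.numeric(plain), tolerance = 1e-9)
    expect_equal(tn93_distance(toupper(x[1, ]), toupper(x[2, ]),
                               gamma_shape = 0.3),
                 as.numeric(gam), tolerance = 1e-9)
    # gamma correction can only increase a distance
    expect_gte(tn93_distance(toupper(x[1, ]), toupper(x[2, ]), 0.3),
               tn93_distance(toupper(x[1, ]), toupper(x[2, ]), NULL))
  }
})

test_that("TN93 raises typed errors on saturation and empty overlap", {
  expect_error(tn93_distance(rep("A", 50), rep("G", 50)),
               class = "mtexpand_saturated")
  expect_error(tn93_distance(rep("-", 10), rep("A", 10)),
               class = "mtexpand_degenerate")
})

test_that("distance matrices are symmetric with zero diagonal", {
  # simulated alignment with its invariant background, the realistic input
  m <- demography("constant", theta = 4, n = 8, L = 400, seed = 17)
  aln <- simulate_coalescent(m)
  d <- tn93_matrix(aln)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  # complete deletion makes the result independent of column order
  sc <- mtexpand:::site_cols(aln)
  perm <- mt_alignment(as.matrix(as.data.frame(aln[, sample(sc)])),
                       aln$sample_id, aln$locality)
  expect_equal(sort(d[upper.tri(d)]),
               sort(tn93_matrix(perm)[upper.tri(d)]))
})

test_that("group means average between-group pairs only", {
  background <- paste(rep("ACGT", 30), collapse = "")
  seq_y <- sub("^ACGT", "ACTT", background)
  aln <- make_aln(c(background, background, seq_y, seq_y),
                  localities = c("x", "x", "y", "y"))
  res <- group_mean_distance(aln, c("g1", "g1", "g2", "g2"),
                             bootstrap_reps = 50, seed = 3)
  expect_equal(nrow(res), 1)
  expect_equal(res$n_pairs, 4)
  expect_gt(res$mean_distance, 0)
  expect_gt(res$se, 0)
  same <- group_mean_distance(make_aln(c("ACGT", "ACGT", "ACGT"),
                                       localities = c("x", "x", "y")),
                              c("g1", "g1", "g2"), bootstrap_reps = 20)
  expect_equal(same$mean_distance, 0)
  expect_equal(same$se, 0)
  expect_error(group_mean_distance(aln, c("g1", "g1", NA, "g2")),
               "group label")
})

test_that("group means track a known simulated divergence", {
  # two island blocks separated by fixed differences: the TN93 mean between
  # groups should sit near the per-pair distance of the founders
  set.seed(8)
  base <- sample(c("A", "C", "G", "T"), 500, replace = TRUE)
  shift <- base
  shift[sample(500, 25)] <- sample(c("A", "C", "G", "T"), 25,
                                   replace = TRUE)
  jitter1 <- function(s) {
    i <- sample(500, 2); s[i] <- sample(c("A", "C", "G", "T"), 2,
                                        replace = TRUE); s
  }
  m <- rbind(base, jitter1(base), shift, jitter1(shift))
  aln <- mt_alignment(m, paste0("s", 1:4), c("p", "p", "q", "q"))
  res <- group_mean_distance(aln, c("A", "A", "B", "B"),
                             bootstrap_reps = 200, seed = 4)
  founder <- tn93_distance(base, shift)
  expect_lt(abs(res$mean_distance - founder), 3 * res$se + 0.01)
})
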