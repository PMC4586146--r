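test_that("mismatch histograms count every pair exactly once", {
  ident <- mismatch_histogram(make_aln(rep("ACGT", 5)))
  expect_equal(ident$differences, 0)
  expect_equal(ident$count, 10)
  # Israel + Europe pooled: the 2 x 247 cross pairs sit at 3 differences,
  # all 30 382 within-group pairs at 0
  h <- mismatch_histogram(abroad_aln)
  expect_equal(h$count[h$differences == 0], 30382)
  expect_equal(h$count[h$differences == 3], 494)
  expect_equal(sum(h$count), choose(249, 2))
  expect_equal(sum(h$frequency), 1)
  # exhaustive pair-loop oracle on a small random alignment
  set.seed(21)
  seqs <- replicate(8, paste(sample(c("A", "G"), 10, replace = TRUE),
                             collapse = ""))
  aln <- make_aln(seqs)
  hh <- mismatch_histogram(aln)
  m <- mtexpand:::state_matrix(aln)
  d <- c()
  for (i in 1:7) for (j in (i + 1):8) d <- c(d, sum(m[i, ] != m[j, ]))
  expect_equal(hh$count, tabulate(d + 1, max(d) + 1))
  # the Indian sample is right-skewed unimodal: modal class above zero
  hi <- mismatch_histogram(india_aln)
  expect_gt(hi$differences[which.max(hi$count)], 0)
})

test_that("the sudden-expansion fit recovers parameters from its own curve", {
  f <- expected_mismatch(0:30, tau = 5, theta0 = 0.5)
  h <- tibble::tibble(differences = 0:30,
                      count = round(f / sum(f) * 1e6),
                      frequency = f / sum(f))
  attr(h, "n_pairs") <- 1e6
  class(h) <- c("mt_mismatch", class(h))
  fit <- fit_sudden_expansion(h)
  expect_lt(abs(fit$tau - 5), 0.5)
  expect_lt(abs(fit$theta0 - 0.5), 0.3)
  # degenerate single-class histogram is a typed error
  expect_error(fit_sudden_expansion(mismatch_histogram(
    make_aln(rep("AC", 4)))), class = "mtexpand_degenerate")
})

test_that("the expansion curve is a proper distribution", {
  for (tau in c(0, 1, 5.5)) {
    f <- expected_mismatch(0:400, tau, theta0 = 0.7, theta1 = 99999)
    expect_true(all(f >= 0))
    expect_equal(sum(f), 1, tolerance = 1e-6)
  }
  # tau = 0 collapses to the theta0 equilibrium geometric
  expect_equal(expected_mismatch(0:10, 0, 2, 99999),
               2^(0:10) / 3^(1:11), tolerance = 1e-4)
})

test_that("raggedness follows Harpending's sum of squared steps", {
  expect_equal(raggedness(c(0.5, 0.5)), 0.25)
  # flat distributions are smooth: r shrinks with the number of classes
  expect_lt(raggedness(rep(1 / 20, 20)), raggedness(rep(1 / 5, 5)))
  r_india <- raggedness(mismatch_histogram(
    haplotype_alignment(cr_tbl, localities = india_localities)))
  expect_gt(r_india, 0.02)
  expect_lt(r_india, 0.08)
})

test_that("expansion dating reproduces the published arithmetic exactly", {
  expect_equal(expansion_time(5.414)$t_years, 37083)
  expect_equal(expansion_time(3.000)$t_years, 20548)
  expect_equal(expansion_time(0)$t_years, 0)
  # linear in tau, inverse in mu
  expect_equal(expansion_time(10, mu = 7.3e-5)$t_years,
               as.integer(ceiling(10 / (2 * 7.3e-5))))
  expect_equal(expansion_time(5, mu = 2e-5)$t_years,
               expansion_time(5, mu = 1e-5)$t_years / 2)
  expect_error(expansion_time(5, mu = 0), "positive")
  # per-bp mode multiplies the rate by the locus length
  expect_equal(expansion_time(5, mu = 1e-7, per_bp = TRUE, L = 100)$t_years,
               expansion_time(5, mu = 1e-5)$t_years)
  ci <- expansion_time(5.414, tau_ci = c(2.4, 10.4))
  expect_lte(ci$ci_low, ci$t_years)
  expect_gte(ci$ci_high, ci$t_years)
})

test_that("bootstrap tau intervals nest by level and reject tiny B", {
  ha <- haplotype_alignment(cr_tbl, localities = india_localities)
  expect_error(tau_bootstrap_ci(ha, B = 0), "at least 100")
  ci90 <- tau_bootstrap_ci(ha, B = 120, level = 0.90, seed = 7)
  ci80 <- tau_bootstrap_ci(ha, B = 120, level = 0.80, seed = 7)
  expect_gte(ci80$tau_low, ci90$tau_low)
  expect_lte(ci80$tau_high, ci90$tau_high)
  expect_lte(ci90$tau_low, ci90$tau_high)
})

test_that("bootstrap intervals cover the generating tau", {
  # reduced-scale coverage experiment: 8 datasets from the expansion model,
  # 90% parametric bootstrap interval should cover tau = 5 almost always
  set.seed(31)
  cover <- replicate(8, {
    m <- demography("sudden_expansion", theta0 = 0.5, theta1 = 99999,
                    tau = 5, n = 30, L = 1000)
    a <- simulate_coalescent(m, seed = sample.int(2^31 - 1, 1))
    ci <- tau_bootstrap_ci(a, B = 100, level = 0.90,
                           seed = sample.int(2^31 - 1, 1))
    ci$tau_low <= 5 && 5 <= ci$tau_high
  })
  expect_gte(mean(cover), 0.7)
})

test_that("finer fitting grids never worsen the fit", {
  h <- mismatch_histogram(india_aln)
  ssd_coarse <- fit_sudden_expansion(h, grid_n = 8)$ssd
  ssd_fine <- fit_sudden_expansion(h, grid_n = 30)$ssd
  expect_lte(ssd_fine, ssd_coarse + 1e-10)
})
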