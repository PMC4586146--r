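#' Tajima's D constants
#'
#' The normalizing constants a1, a2, b1, b2, c1, c2, e1, e2 of Tajima
#' (1989) for a sample of n sequences.
#'
#' @param n Sample size (>= 4).
#' @return A named list of the eight constants.
#' @export
tajima_constants <- function(n) {
  if (n < 4) rlang::abort("Tajima's D requires n >= 4.")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' Standardized difference between the pairwise-difference estimator of
#' theta (k) and the segregating-sites estimator (S / a1):
#' `D = (k - S/a1) / sqrt(e1 S + e2 S (S - 1))`. Negative values indicate
#' an excess of rare variants, the signature of demographic expansion (or
#' directional selection); positive values an excess of intermediate
#' frequencies.
#'
#' @param S Number of segregating sites (>= 1; `S = 0` leaves D undefined
#'   and raises an error of class `mtexpand_undefined`).
#' @param k Mean pairwise differences.
#' @param n Sample size (>= 4).
#' @return The D statistic (finite number).
#' @export
tajimas_d <- function(S, k, n) {
  if (S < 1) {
    rlang::abort("Tajima's D is undefined when S = 0.",
                 class = "mtexpand_undefined")
  }
  cst <- tajima_constants(n)
  (k - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
}

## log of unsigned Stirling numbers of the first kind |s(n, j)|, j = 1..n,
## via the recursion |s(n,j)| = |s(n-1,j-1)| + (n-1) |s(n-1,j)| carried in
## log space with log-sum-exp. O(n^2); n is capped to keep the quadratic
## table affordable.
log_stirling1 <- function(n) {
  if (n > 10000) rlang::abort("n too large for the Stirling table (max 10000).")
  cur <- 0 # log|s(1,1)| = 0
  if (n == 1) return(cur)
  for (m in 2:n) {
    prev <- cur
    cur <- numeric(m)
    lm <- log(m - 1)
    # j = 1: |s(m,1)| = (m-1)!
    cur[1] <- lm + prev[1]
    if (m > 2) {
      j <- 2:(m - 1)
      a <- prev[j - 1]
      b <- lm + prev[j]
      hi <- pmax(a, b)
      cur[j] <- hi + log1p(exp(pmin(a, b) - hi))
    }
    cur[m] <- 0 # |s(m,m)| = 1
  }
  cur
}

#' Ewens sampling distribution of the number of alleles
#'
#' Probabilities `P(K = j) = |s(n, j)| theta^j / theta_(n)` for the number
#' of distinct alleles K in a neutral sample of size n at scaled mutation
#' rate theta, where `theta_(n)` is the rising factorial. Computed in log
#' space so that it is stable for large n.
#'
#' @param n Sample size.
#' @param theta Scaled mutation rate (> 0).
#' @param log Return log-probabilities?
#' @return Numeric vector of length n (`j = 1..n`), summing to 1.
#' @export
ewens_k_probs <- function(n, theta, log = FALSE) {
  if (theta <= 0) rlang::abort("`theta` must be positive.")
  lognum <- log_stirling1(n) + seq_len(n) * base::log(theta)
  logden <- sum(base::log(theta + 0:(n - 1)))
  lp <- lognum - logden
  if (log) lp else exp(lp)
}

#' Fu's Fs
#'
#' Log-odds of observing at least as many distinct haplotypes as seen,
#' under the Ewens sampling distribution with theta estimated by the mean
#' pairwise differences k: `Fs = ln(S' / (1 - S'))` with
#' `S' = P(K >= n_alleles | theta = k)`. Large negative values indicate an
#' excess of haplotypes relative to neutral-equilibrium expectation, the
#' signature of recent demographic expansion.
#'
#' @param k Mean pairwise differences (> 0; `k = 0` leaves theta degenerate
#'   and raises an error of class `mtexpand_undefined`).
#' @param n Sample size (>= 2).
#' @param n_alleles Observed number of distinct haplotypes (2..n;
#'   `n_alleles = 1` makes `S' = 1` and Fs infinite, raised as a typed
#'   error).
#' @return The Fs statistic.
#' @export
fus_fs <- function(k, n, n_alleles) {
  if (k <= 0) {
    rlang::abort("Fu's Fs is undefined when k = 0 (theta-hat degenerate).",
                 class = "mtexpand_undefined")
  }
  if (n_alleles < 1 || n_alleles > n) {
    rlang::abort("`n_alleles` must lie in 1..n.")
  }
  if (n_alleles == 1) {
    rlang::abort("Fu's Fs is infinite for n_alleles = 1 (S' = 1).",
                 class = "mtexpand_undefined")
  }
  lp <- ewens_k_probs(n, k, log = TRUE)
  ge <- lp[n_alleles:n]
  hi <- max(ge)
  logS <- min(hi + base::log(sum(exp(ge - hi))), 0)
  # Fs = log(S') - log(1 - S'), entirely in log space so that very small
  # tail probabilities give large negative but finite statistics
  log1mS <- if (logS < -1e-12) base::log1p(-exp(logS)) else -Inf
  fs <- logS - log1mS
  if (!is.finite(fs)) {
    rlang::abort("Fu's Fs is infinite (S' collapsed to 0 or 1).",
                 class = "mtexpand_undefined")
  }
  fs
}

## summary statistics of an alignment used by the neutrality tests
neutrality_observed <- function(aln, gap_policy) {
  m <- state_matrix(aln)
  if (gap_policy == "complete_deletion") {
    m2 <- apply_complete_deletion(m)
    aln2 <- mt_alignment(m2, aln$sample_id, aln$locality,
                         sites = aln_sites(aln)[match(colnames(m2),
                                                      colnames(m))],
                         L = attr(aln, "L"))
  } else {
    aln2 <- aln
  }
  S <- segregating_sites(aln, gap_policy)
  k <- mean_pairwise_differences(aln, gap_policy)
  n_alleles <- nrow(collapse_haplotypes(aln2))
  list(n = nrow(aln), S = S, k = k, n_alleles = n_alleles)
}

#' Neutrality tests with coalescent-simulation p-values
#'
#' Computes Tajima's D and Fu's Fs for a sample and attaches p-values from
#' constant-size coalescent simulations run at `theta = k` (the observed
#' mean pairwise differences) with the same sample size. Following the
#' convention of the programs that popularized these tests, both p-values
#' are lower-tail: the fraction of simulated statistics less than or equal
#' to the observed one, i.e. the probability of a value at least as
#' expansion-like as observed.
#'
#' @param aln An `mt_aln` tibble of individuals.
#' @param gap_policy Gap policy used consistently for S, k and the
#'   haplotype count; defaults to `"complete_deletion"` (sites containing
#'   gaps or missing data are excluded wholesale, the convention of the
#'   programs these tests originate from).
#' @param n_sims Number of coalescent replicates (>= 100).
#' @param seed Integer seed; the run is reproducible.
#' @return A one-row tibble of class `mt_neutrality` with columns `D`,
#'   `p_D`, `Fs`, `p_Fs`, `n`, `S`, `k`, `n_alleles`, `n_sims`, `seed`.
#' @export
neutrality_test <- function(aln, gap_policy = c("complete_deletion",
                                                "gap_as_state",
                                                "gap_as_missing"),
                            n_sims = 1000, seed = 42) {
  gap_policy <- match.arg(gap_policy)
  if (n_sims < 100) rlang::abort("`n_sims` must be at least 100.")
  obs <- neutrality_observed(aln, gap_policy)
  D <- tajimas_d(obs$S, obs$k, obs$n)
  Fs <- fus_fs(obs$k, obs$n, obs$n_alleles)
  sims <- with_preserved_seed(seed, {
    replicate(n_sims, {
      s <- sim_sample_summary(obs$n, theta = obs$k)
      c(
        D = if (s$S >= 1) tajimas_d(s$S, s$k, obs$n) else NA_real_,
        Fs = if (s$k > 0 && s$n_alleles > 1) {
          tryCatch(fus_fs(s$k, obs$n, s$n_alleles),
                   mtexpand_undefined = function(e) NA_real_)
        } else NA_real_
      )
    })
  })
  p_D <- mean(sims["D", ] <= D, na.rm = TRUE)
  p_Fs <- mean(sims["Fs", ] <= Fs, na.rm = TRUE)
  out <- tibble::tibble(D = D, p_D = p_D, Fs = Fs, p_Fs = p_Fs,
                        n = obs$n, S = obs$S, k = obs$k,
                        n_alleles = obs$n_alleles,
                        n_sims = n_sims, seed = seed)
  class(out) <- c("mt_neutrality", class(out))
  out
}

## run code with a fixed seed without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, code) {
  force(seed) # must resolve before the RNG state is captured
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
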