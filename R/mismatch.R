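#' Mismatch distribution of pairwise differences
#'
#' Exhaustively counts the number of differing sites for every pair of
#' sequences and tabulates the distribution over difference classes
#' `0..d_max`. By default columns containing gaps or missing data are
#' excluded wholesale (complete deletion), the convention of the classical
#' sequence-polymorphism software; pass `"gap_as_state"` to count a
#' segregating indel as a difference instead. To obtain the distribution
#' among distinct haplotypes rather than individuals - the form in which
#' such distributions are usually published for mtDNA - pass the output of
#' [haplotype_alignment()].
#'
#' @param aln An `mt_aln` tibble (n >= 2).
#' @inheritParams segregating_sites
#' @return A tibble of class `mt_mismatch` with columns `differences`,
#'   `count` and `frequency` (summing to `choose(n, 2)` and 1); the number
#'   of pairs is attached as attribute `n_pairs`.
#' @export
mismatch_histogram <- function(aln, gap_policy = c("complete_deletion",
                                                   "gap_as_state",
                                                   "gap_as_missing")) {
  gap_policy <- match.arg(gap_policy)
  m <- state_matrix(aln)
  if (nrow(m) < 2) rlang::abort("Mismatch distribution needs n >= 2.")
  d <- pairwise_differences(m, gap_policy)
  dmax <- max(d)
  counts <- tabulate(d + 1L, nbins = dmax + 1L)
  out <- tibble::tibble(differences = 0:dmax, count = counts,
                        frequency = counts / length(d))
  attr(out, "n_pairs") <- length(d)
  class(out) <- c("mt_mismatch", class(out))
  out
}

## equilibrium (geometric) mismatch distribution, log-space for stability
feq_geometric <- function(i, th) {
  if (th == 0) return(as.numeric(i == 0))
  exp(i * log(th) - (i + 1) * log1p(th))
}

#' Expected mismatch distribution under sudden expansion
#'
#' The sudden-expansion (stepwise growth) model of Rogers & Harpending: a
#' population at equilibrium with `theta0` grows instantaneously to
#' `theta1` at mutational time `tau` before the present. The expected
#' frequency of pairs differing at `i` sites is
#' `F(i) = Feq(i, theta1) + exp(-tau (theta1 + 1) / theta1) *
#'   sum_{j<=i} tau^j / j! * (Feq(i-j, theta0) - Feq(i-j, theta1))`
#' where `Feq(i, theta) = theta^i / (theta + 1)^(i+1)` is the equilibrium
#' (geometric) mismatch distribution.
#'
#' @param i Vector of difference classes (non-negative integers).
#' @param tau Expansion time in mutational units.
#' @param theta0,theta1 Pre-/post-expansion scaled mutation rates.
#' @return Expected relative frequencies, same length as `i`.
#' @export
expected_mismatch <- function(i, tau, theta0, theta1 = 99999) {
  if (any(i < 0) || any(i != round(i))) {
    rlang::abort("`i` must be non-negative integer difference classes.")
  }
  M <- max(i)
  idx <- 0:M
  f1 <- feq_geometric(idx, theta1)
  dlt <- feq_geometric(idx, theta0) - f1
  tau_pow <- if (tau == 0) c(1, rep(0, M)) else {
    exp(idx * log(tau) - lgamma(idx + 1))
  }
  conv <- vapply(idx, function(ii)
    sum(tau_pow[1:(ii + 1)] * dlt[(ii + 1):1]), numeric(1))
  out <- f1 + exp(-tau * (theta1 + 1) / theta1) * conv
  pmax(out[i + 1], 0) # clip floating-point cancellation noise
}

#' Fit the sudden-expansion model to a mismatch distribution
#'
#' Least-squares fit of the expected sudden-expansion mismatch curve to the
#' observed relative frequencies. `theta1` is fixed at a large ceiling by
#' default (the convention of the classical mismatch software; freeing all
#' three parameters on shallow data is ill-conditioned) and can be freed
#' with `free_theta1 = TRUE`. The optimizer is a coarse grid over
#' `tau in [0, 2 d_max]` and `theta0 in [0, mean(d)]` followed by local
#' refinement with `optim(L-BFGS-B)`. Observed classes are zero-padded to
#' twice the largest observed difference so the fit also penalizes model
#' mass beyond the data's support.
#'
#' @param hist An `mt_mismatch` tibble (needs >= 2 non-empty classes).
#' @param theta1 Fixed post-expansion theta.
#' @param free_theta1 Also optimize theta1?
#' @param grid_n Grid resolution per parameter.
#' @return An object of class `mt_expansion_fit`: a list with `tau`,
#'   `theta0`, `theta1`, `ssd`, `raggedness` and the histogram.
#' @export
fit_sudden_expansion <- function(hist, theta1 = 99999, free_theta1 = FALSE,
                                 grid_n = 25) {
  stopifnot(inherits(hist, "mt_mismatch"))
  if (sum(hist$count > 0) < 2) {
    rlang::abort("Degenerate mismatch histogram: a single occupied class.",
                 class = "mtexpand_degenerate")
  }
  dmax <- max(hist$differences)
  support <- 0:(2 * dmax)
  obs <- numeric(length(support))
  obs[hist$differences + 1] <- hist$frequency
  kbar <- sum(hist$differences * hist$frequency)
  ssd_of <- function(tau, th0, th1) {
    sum((obs - expected_mismatch(support, tau, th0, th1))^2)
  }
  taus <- seq(0, 2 * dmax, length.out = grid_n)
  th0s <- seq(0, max(kbar, 0.1), length.out = grid_n)
  # vectorized grid scan: for each tau, the expansion curve for every th0
  # is one lower-triangular Toeplitz product with the Poisson(tau) weights
  M <- length(support) - 1
  f1 <- feq_geometric(support, theta1)
  dlt <- vapply(th0s, function(t0) feq_geometric(support, t0) - f1,
                numeric(M + 1))
  ij <- outer(support, support, "-") # row i, col j -> i - j
  best <- list(ssd = Inf, tau = taus[1], th0 = th0s[1])
  for (tau in taus) {
    p <- if (tau == 0) c(1, rep(0, M)) else {
      exp(support * log(tau) - lgamma(support + 1))
    }
    Tm <- matrix(0, M + 1, M + 1)
    Tm[ij >= 0] <- p[ij[ij >= 0] + 1]
    Fm <- f1 + exp(-tau * (theta1 + 1) / theta1) * (Tm %*% dlt)
    ss <- colSums((Fm - obs)^2)
    if (min(ss) < best$ssd) {
      best <- list(ssd = min(ss), tau = tau, th0 = th0s[which.min(ss)])
    }
  }
  if (free_theta1) {
    par0 <- c(best$tau, best$th0, theta1)
    opt <- stats::optim(par0, function(p) ssd_of(p[1], p[2], p[3]),
                        method = "L-BFGS-B",
                        lower = c(0, 0, 1e-3),
                        upper = c(4 * dmax, 10 * max(kbar, 1), 1e6))
    tau <- opt$par[1]; th0 <- opt$par[2]; th1 <- opt$par[3]
    ssd <- opt$value
  } else {
    opt <- stats::optim(c(best$tau, best$th0),
                        function(p) ssd_of(p[1], p[2], theta1),
                        method = "L-BFGS-B", lower = c(0, 0),
                        upper = c(4 * dmax, 10 * max(kbar, 1)))
    tau <- opt$par[1]; th0 <- opt$par[2]; th1 <- theta1
    ssd <- opt$value
  }
  structure(list(tau = tau, theta0 = th0, theta1 = th1, ssd = ssd,
                 raggedness = raggedness(hist), histogram = hist,
                 n_pairs = attr(hist, "n_pairs")),
            class = "mt_expansion_fit")
}

#' @export
print.mt_expansion_fit <- function(x, ...) {
  cat("Sudden-expansion mismatch fit\n")
  cat(sprintf("  tau = %.3f, theta0 = %.3f, theta1 = %g\n",
              x$tau, x$theta0, x$theta1))
  cat(sprintf("  SSD = %.5f, raggedness r = %.4f\n", x$ssd, x$raggedness))
  invisible(x)
}

#' Harpending's raggedness index
#'
#' `r = sum_{i=1}^{d+1} (x_i - x_{i-1})^2` over the relative frequencies
#' `x_0..x_d` of the mismatch classes, with `x_{d+1} = 0` appended (d is
#' the largest observed difference). Smooth unimodal distributions - the
#' expansion signature - give small r; ragged multimodal ones give large r.
#'
#' @param hist An `mt_mismatch` tibble, or a numeric vector of relative
#'   frequencies for classes `0..d`.
#' @return The raggedness index (>= 0).
#' @export
raggedness <- function(hist) {
  x <- if (inherits(hist, "data.frame")) {
    f <- numeric(max(hist$differences) + 1)
    f[hist$differences + 1] <- hist$frequency
    f
  } else as.numeric(hist)
  if (length(x) < 2) {
    rlang::abort("Raggedness needs at least two mismatch classes.")
  }
  sum(diff(c(x, 0))^2)
}

#' Expansion time from tau
#'
#' Inverts `tau = 2 mu t`: `t = tau / (2 mu)` generations, times the
#' generation time in years. Following the convention of the source
#' analyses this treats `mu` as a whole-locus per-generation rate (i.e. tau
#' is not divided by sequence length); pass `per_bp = TRUE` with a length
#' `L` to use `u = mu * L` instead. Times are rounded up to the next whole
#' year.
#'
#' @param tau Expansion time in mutational units (>= 0), possibly a vector.
#' @param mu Mutation rate per generation (default 7.3e-5).
#' @param gen_years Generation time in years (default 1).
#' @param tau_ci Optional length-2 vector of tau confidence bounds, mapped
#'   through the same transform.
#' @param per_bp Treat `mu` as a per-bp rate and multiply by `L`?
#' @param L Locus length, required when `per_bp = TRUE`.
#' @return A one-row tibble with `t_years` (and `ci_low`, `ci_high` when
#'   `tau_ci` is given).
#' @export
expansion_time <- function(tau, mu = 7.3e-5, gen_years = 1, tau_ci = NULL,
                           per_bp = FALSE, L = NULL) {
  if (mu <= 0) rlang::abort("`mu` must be positive.")
  if (any(tau < 0)) rlang::abort("`tau` must be non-negative.")
  u <- if (per_bp) {
    if (is.null(L)) rlang::abort("`per_bp = TRUE` requires `L`.")
    mu * L
  } else mu
  yrs <- function(tt) as.integer(ceiling(tt / (2 * u) * gen_years - 1e-9))
  out <- tibble::tibble(t_years = yrs(tau))
  if (!is.null(tau_ci)) {
    ci <- sort(yrs(tau_ci))
    out$ci_low <- ci[1]
    out$ci_high <- ci[2]
  }
  out
}

#' Parametric bootstrap confidence interval for tau
#'
#' Fits the sudden-expansion model to the sample, then simulates `B`
#' coalescent datasets from the fitted model (same sample size), refits tau
#' to each, and returns the percentile interval at the requested level.
#'
#' @param aln An `mt_aln` tibble of individuals.
#' @param B Number of bootstrap replicates (>= 100).
#' @param level Confidence level (default 0.90).
#' @param seed Integer seed.
#' @param gap_policy Gap policy for the observed histogram.
#' @param theta1 Fixed post-expansion theta for fitting and simulation.
#' @return A one-row tibble with `tau`, `tau_low`, `tau_high`, `level` and
#'   `B`; the bootstrap tau draws are attached as attribute `taus`.
#' @export
tau_bootstrap_ci <- function(aln, B = 1000, level = 0.90, seed = 42,
                             gap_policy = "complete_deletion",
                             theta1 = 99999) {
  if (B < 100) rlang::abort("`B` must be at least 100.")
  fit <- fit_sudden_expansion(mismatch_histogram(aln, gap_policy),
                              theta1 = theta1)
  n <- nrow(aln)
  L <- max(aln_length(aln), 10 * max(fit$histogram$differences), 1000)
  model <- demography("sudden_expansion",
                      theta0 = max(fit$theta0, 1e-6),
                      theta1 = theta1,
                      tau = fit$tau, n = n, L = L)
  taus <- with_preserved_seed(seed, {
    vapply(seq_len(B), function(b) {
      s <- tryCatch({
        sim <- simulate_coalescent(model, seed = sample.int(2^31 - 1, 1))
        fit_sudden_expansion(mismatch_histogram(sim, gap_policy),
                             theta1 = theta1)$tau
      }, error = function(e) NA_real_)
      s
    }, numeric(1))
  })
  fail <- mean(is.na(taus))
  if (fail > 0.10) {
    rlang::abort(paste0("Expansion refit failed in ",
                        round(100 * fail), "% of bootstrap replicates."))
  }
  qs <- stats::quantile(taus, c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, names = FALSE)
  out <- tibble::tibble(tau = fit$tau, tau_low = qs[1], tau_high = qs[2],
                        level = level, B = B)
  attr(out, "taus") <- taus
  out
}
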