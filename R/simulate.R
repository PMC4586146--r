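#' Specify a demographic model for coalescent simulation
#'
#' Two demographies are supported: a constant-size population with scaled
#' mutation rate `theta = 2 N u` (u = per-locus per-generation mutation
#' rate, N = female effective size for mtDNA), and a sudden (stepwise)
#' expansion in which the population grew instantaneously from `theta0` to
#' `theta1` at mutational time `tau = 2 u t` before the present. Time is
#' measured throughout in mutational units, so a `tau` supplied here is
#' directly comparable to the `tau` recovered by
#' [fit_sudden_expansion()].
#'
#' @param kind `"constant"` or `"sudden_expansion"`.
#' @param theta Scaled mutation rate (constant model).
#' @param theta0,theta1 Pre- and post-expansion theta
#'   (`theta1 > theta0 >= 0`).
#' @param tau Expansion time in mutational units (>= 0).
#' @param n Sample size (>= 2).
#' @param L Locus length in bp onto which mutations are placed.
#' @param seed Default seed used by [simulate_coalescent()].
#' @return A list of class `mt_demography`.
#' @export
demography <- function(kind = c("constant", "sudden_expansion"),
                       theta = NULL, theta0 = NULL, theta1 = NULL,
                       tau = NULL, n = 20, L = 440, seed = 42) {
  kind <- match.arg(kind)
  if (n < 2) rlang::abort("`n` must be at least 2.")
  if (kind == "constant") {
    if (is.null(theta) || theta < 0) {
      rlang::abort("Constant model needs `theta` >= 0.")
    }
  } else {
    if (is.null(theta0) || is.null(theta1) || is.null(tau) ||
        theta0 < 0 || tau < 0 || theta1 <= theta0) {
      rlang::abort("Expansion model needs theta1 > theta0 >= 0 and tau >= 0.")
    }
  }
  structure(list(kind = kind, theta = theta, theta0 = theta0,
                 theta1 = theta1, tau = tau, n = as.integer(n),
                 L = as.integer(L), seed = as.integer(seed)),
            class = "mt_demography")
}

## Simulate one coalescent genealogy and drop mutations on it.
##
## Time runs from the present backwards in mutational units; a branch of
## length ell receives Poisson(ell / 2) mutations, so that for a constant
## population E[k] = theta and E[S] = theta * a1(n). The coalescence rate
## for j lineages is choose(j, 2) / theta(t), piecewise constant for the
## sudden-expansion model (theta1 up to tau, theta0 beyond). Returns one
## row per mutation: the set of descendant leaves.
sim_genealogy_mutations <- function(n, theta1, theta0 = NULL, tau = Inf) {
  if (theta1 <= 0 && is.null(theta0)) {
    return(list(mut_leafsets = list(), height = 0))
  }
  groups <- as.list(seq_len(n)) # leaf sets of active lineages
  birth <- numeric(n)           # time each active lineage started
  t <- 0
  muts <- list()
  eps <- 1e-12
  while (length(groups) > 1) {
    j <- length(groups)
    th <- if (t < tau) theta1 else theta0
    rate <- if (th <= eps) Inf else choose(j, 2) / th
    w <- if (is.finite(rate)) stats::rexp(1, rate) else 0
    if (t < tau && t + w >= tau) {
      # crossed the epoch boundary: advance and redraw (memoryless)
      t <- tau
      next
    }
    t <- t + w
    pair <- sample.int(j, 2)
    for (idx in pair) {
      len <- t - birth[idx]
      nm <- stats::rpois(1, len / 2)
      if (nm > 0) {
        muts <- c(muts, rep(list(groups[[idx]]), nm))
      }
    }
    merged <- c(groups[[pair[1]]], groups[[pair[2]]])
    groups[[pair[1]]] <- merged
    birth[pair[1]] <- t
    groups <- groups[-pair[2]]
    birth <- birth[-pair[2]]
  }
  list(mut_leafsets = muts, height = t)
}

## Fast path: summary statistics of one simulated sample, no sequences.
sim_sample_summary <- function(n, theta, theta0 = NULL, tau = Inf) {
  g <- sim_genealogy_mutations(n, theta, theta0, tau)
  muts <- g$mut_leafsets
  S <- length(muts)
  if (S == 0) {
    return(list(S = 0L, k = 0, n_alleles = 1L, height = g$height))
  }
  d <- vapply(muts, length, integer(1))
  k <- sum(d * (n - d)) / choose(n, 2)
  sig <- rep("", n)
  for (i in seq_along(muts)) {
    sig[muts[[i]]] <- paste0(sig[muts[[i]]], i, ".")
  }
  list(S = as.integer(S), k = k, n_alleles = length(unique(sig)),
       height = g$height)
}

#' Simulate haploid samples under a neutral coalescent
#'
#' Draws a genealogy under the chosen demography, places Poisson mutations
#' on its branches, and scatters them over distinct positions of an L-bp
#' locus (infinite-sites model: no recurrent mutation, every mutation hits
#' a fresh site). With `finite_sites = TRUE` positions are drawn with
#' replacement and repeat hits overwrite, a deliberately rougher model for
#' robustness checks. Ancestral and derived states are random nucleotides.
#'
#' @param model An [demography()] object.
#' @param seed Integer seed; identical seeds give identical alignments.
#' @param finite_sites Allow recurrent mutation at a site?
#' @return An `mt_aln` tibble with samples `sim1..simN` carrying a `truth`
#'   attribute (the model, the realized tree height and S).
#' @export
simulate_coalescent <- function(model, seed = model$seed,
                                finite_sites = FALSE) {
  stopifnot(inherits(model, "mt_demography"))
  with_preserved_seed(seed, {
    g <- if (model$kind == "constant") {
      sim_genealogy_mutations(model$n, model$theta)
    } else {
      sim_genealogy_mutations(model$n, model$theta1, model$theta0,
                              model$tau)
    }
    muts <- g$mut_leafsets
    S <- length(muts)
    if (!finite_sites && S > model$L) {
      rlang::abort(paste0("Simulated ", S, " mutations but locus has only ",
                          model$L, " bp; increase `L`."))
    }
    nuc <- c("A", "C", "G", "T")
    anc <- sample(nuc, model$L, replace = TRUE)
    m <- matrix(rep(anc, each = model$n), nrow = model$n)
    pos <- if (finite_sites) {
      sample.int(model$L, S, replace = TRUE)
    } else {
      if (S > 0) sample.int(model$L, S) else integer(0)
    }
    for (i in seq_len(S)) {
      derived <- sample(setdiff(nuc, m[muts[[i]][1], pos[i]]), 1)
      m[muts[[i]], pos[i]] <- derived
    }
    aln <- mt_alignment(m, paste0("sim", seq_len(model$n)),
                        localities = "sim", L = model$L)
    attr(aln, "truth") <- list(model = unclass(model), seed = seed,
                               tree_height = g$height, S = S)
    aln
  })
}
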