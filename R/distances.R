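#' Tamura-Nei (TN93) distance between two sequences
#'
#' Closed-form TN93 distance, which allows different rates for the two
#' transition types (A<->G within purines, C<->T within pyrimidines) and
#' unequal base frequencies:
#' `d = -k1 log(w1) - k2 log(w2) - k3 log(w3)` with
#' `w1 = 1 - P1/k1 - Q/(2 gR)`, `w2 = 1 - P2/k2 - Q/(2 gY)`,
#' `w3 = 1 - Q/(2 gR gY)`, where `P1`, `P2`, `Q` are the observed
#' proportions of purine transitions, pyrimidine transitions and
#' transversions, `gR`/`gY` the purine/pyrimidine frequencies, and
#' `k1 = 2 gA gG / gR`, `k2 = 2 gC gT / gY`,
#' `k3 = 2 (gR gY - gA gG gY / gR - gC gT gR / gY)`.
#' With gamma-distributed rate heterogeneity of shape `a`, each `-log(w)`
#' is replaced by `a (w^(-1/a) - 1)`; the gamma-corrected distance is never
#' smaller than the uncorrected one. Base frequencies are estimated from
#' the two sequences pooled. Columns containing gaps or missing data are
#' removed before comparison (complete deletion).
#'
#' @param seq_a,seq_b Character vectors of single-character states (or
#'   single strings), equal length.
#' @param gamma_shape Gamma shape parameter, `> 0`, or `NULL`/`Inf` for no
#'   rate heterogeneity.
#' @return The distance (substitutions per site, >= 0).
#' @export
tn93_distance <- function(seq_a, seq_b, gamma_shape = 0.3) {
  if (length(seq_a) == 1 && nchar(seq_a[1]) > 1) {
    seq_a <- strsplit(seq_a, "")[[1]]
  }
  if (length(seq_b) == 1 && nchar(seq_b[1]) > 1) {
    seq_b <- strsplit(seq_b, "")[[1]]
  }
  if (length(seq_a) != length(seq_b)) {
    rlang::abort("Sequences must have equal length.")
  }
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  ok <- seq_a %in% c("A", "C", "G", "T") & seq_b %in% c("A", "C", "G", "T")
  a <- seq_a[ok]; b <- seq_b[ok]
  nsites <- length(a)
  if (nsites == 0) {
    rlang::abort("No comparable sites after complete deletion.",
                 class = "mtexpand_degenerate")
  }
  freq <- (table(factor(a, levels = c("A", "C", "G", "T"))) +
             table(factor(b, levels = c("A", "C", "G", "T")))) / (2 * nsites)
  gA <- freq[["A"]]; gC <- freq[["C"]]; gG <- freq[["G"]]; gT <- freq[["T"]]
  gR <- gA + gG; gY <- gC + gT
  pur <- c("A", "G")
  P1 <- mean((a %in% pur) & (b %in% pur) & a != b)   # A<->G
  P2 <- mean(!(a %in% pur) & !(b %in% pur) & a != b) # C<->T
  Q <- mean((a %in% pur) != (b %in% pur))            # transversions
  if (P1 + P2 + Q == 0) return(0)
  k1 <- if (gR > 0) 2 * gA * gG / gR else 0
  k2 <- if (gY > 0) 2 * gC * gT / gY else 0
  k3 <- 2 * (gR * gY -
               (if (gR > 0) gA * gG * gY / gR else 0) -
               (if (gY > 0) gC * gT * gR / gY else 0))
  w1 <- if (k1 > 0) 1 - P1 / k1 - Q / (2 * gR) else 1
  w2 <- if (k2 > 0) 1 - P2 / k2 - Q / (2 * gY) else 1
  w3 <- if (gR * gY > 0) 1 - Q / (2 * gR * gY) else 1
  if ((k1 == 0 && P1 > 0) || (k2 == 0 && P2 > 0) ||
      (gR * gY == 0 && Q > 0)) {
    rlang::abort("TN93 distance saturated (a substitution class has no
                  compatible base frequencies).",
                 class = "mtexpand_saturated")
  }
  if (min(w1, w2, w3) <= 0) {
    rlang::abort("TN93 distance saturated (log/power argument <= 0).",
                 class = "mtexpand_saturated")
  }
  corr <- if (is.null(gamma_shape) || !is.finite(gamma_shape)) {
    function(w) -log(w)
  } else {
    if (gamma_shape <= 0) rlang::abort("`gamma_shape` must be positive.")
    function(w) gamma_shape * (w^(-1 / gamma_shape) - 1)
  }
  d <- k1 * corr(w1) + k2 * corr(w2) + k3 * corr(w3)
  max(d, 0)
}

#' Pairwise TN93 distance matrix
#'
#' @param aln An `mt_aln` or `mt_haps` tibble. Columns containing `-`/`?`
#'   anywhere in the alignment are removed first (complete deletion), so
#'   every pair is compared over the same sites.
#' @inheritParams tn93_distance
#' @return A symmetric matrix with zero diagonal.
#' @export
tn93_matrix <- function(aln, gamma_shape = 0.3) {
  m <- apply_complete_deletion(state_matrix(aln))
  if (ncol(m) == 0) {
    rlang::abort("No comparable sites after complete deletion.",
                 class = "mtexpand_degenerate")
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- tn93_distance(m[i, ], m[j, ], gamma_shape)
    }
  }
  d
}

#' Mean between-group TN93 distances with bootstrap standard errors
#'
#' Averages the TN93(+gamma) distance over all between-group sequence
#' pairs, for every pair of groups. Standard errors come from a bootstrap
#' over alignment sites (columns resampled with replacement, seeded), the
#' convention of the standard distance software.
#'
#' @param aln An `mt_aln` tibble.
#' @param groups Group label per sequence: either a character vector of
#'   length `nrow(aln)`, or a data frame with columns `locality` and
#'   `group`/`region` mapped through the alignment's localities.
#' @inheritParams tn93_distance
#' @param bootstrap_reps Site-bootstrap replicates for the SE (0 skips).
#' @param seed Integer seed for the bootstrap.
#' @return A tibble with one row per unordered group pair: `group_a`,
#'   `group_b`, `mean_distance`, `se`, `n_pairs`.
#' @export
group_mean_distance <- function(aln, groups, gamma_shape = 0.3,
                                bootstrap_reps = 1000, seed = 42) {
  if (is.data.frame(groups)) {
    gcol <- intersect(c("group", "region"), names(groups))[1]
    glab <- groups[[gcol]][match(aln$locality, groups$locality)]
  } else {
    glab <- as.character(groups)
  }
  if (length(glab) != nrow(aln) || anyNA(glab)) {
    rlang::abort("Every sequence needs a group label.")
  }
  lv <- unique(glab)
  if (any(table(glab) < 1)) rlang::abort("Empty group.")
  m <- apply_complete_deletion(state_matrix(aln))
  if (ncol(m) == 0) {
    rlang::abort("No comparable sites after complete deletion.",
                 class = "mtexpand_degenerate")
  }
  mean_for <- function(mat, ga, gb) {
    ia <- which(glab == ga); ib <- which(glab == gb)
    pairs <- expand.grid(i = ia, j = ib)
    if (ga == gb) pairs <- pairs[pairs$i < pairs$j, , drop = FALSE]
    if (!nrow(pairs)) return(NA_real_)
    mean(mapply(function(i, j) tn93_distance(mat[i, ], mat[j, ],
                                             gamma_shape),
                pairs$i, pairs$j))
  }
  combos <- utils::combn(lv, 2, simplify = FALSE)
  rows <- purrr::map_dfr(combos, function(gp) {
    obs <- mean_for(m, gp[1], gp[2])
    se <- NA_real_
    if (bootstrap_reps > 0) {
      reps <- with_preserved_seed(seed, {
        vapply(seq_len(bootstrap_reps), function(b) {
          cols <- sample.int(ncol(m), replace = TRUE)
          tryCatch(mean_for(m[, cols, drop = FALSE], gp[1], gp[2]),
                   error = function(e) NA_real_)
        }, numeric(1))
      })
      se <- stats::sd(reps, na.rm = TRUE)
    }
    tibble::tibble(group_a = gp[1], group_b = gp[2],
                   mean_distance = obs, se = se,
                   n_pairs = sum(glab == gp[1]) * sum(glab == gp[2]))
  })
  rows
}
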