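## Gap handling. The three classical population-genetics programs used for
## mtDNA summary statistics disagree on what to do with alignment gaps, so
## every statistic takes an explicit policy:
##   gap_as_state      '-' is a fifth character state
##   gap_as_missing    '-' and '?' are ignored when assessing a column /
##                     pairwise-deleted when comparing two sequences
##   complete_deletion columns containing any '-' or '?' are dropped first
GAP_POLICIES <- c("gap_as_state", "gap_as_missing", "complete_deletion")

apply_complete_deletion <- function(m) {
  keep <- apply(m, 2, function(col) all(col != "-" & col != "?"))
  m[, keep, drop = FALSE]
}

#' Number of segregating (polymorphic) sites
#'
#' @param aln An `mt_aln` or `mt_haps` tibble (for a haplotype table each
#'   distinct haplotype counts once; counts are irrelevant for S).
#' @param gap_policy One of `"gap_as_state"` (a column is polymorphic if it
#'   holds two distinct states including `-`), `"gap_as_missing"` (gaps and
#'   missing data are ignored when testing variability) or
#'   `"complete_deletion"` (columns containing any `-`/`?` are removed
#'   first).
#' @return Integer count of polymorphic columns.
#' @export
segregating_sites <- function(aln, gap_policy = GAP_POLICIES) {
  gap_policy <- match.arg(gap_policy)
  m <- state_matrix(aln)
  if (nrow(m) < 2) rlang::abort("Need at least 2 sequences to count S.")
  if (gap_policy == "complete_deletion") m <- apply_complete_deletion(m)
  poly <- apply(m, 2, function(col) {
    states <- unique(col)
    states <- setdiff(states, "?")
    if (gap_policy == "gap_as_missing") states <- setdiff(states, "-")
    length(states) >= 2
  })
  sum(poly)
}

#' Haplotype (gene) diversity
#'
#' The unbiased estimator `h = n (1 - sum p_i^2) / (n - 1)`: the probability
#' that two randomly sampled individuals carry different haplotypes. The
#' sampling standard deviation follows the classical variance formula for
#' heterozygosity (Nei 1987, eq. 8.12).
#'
#' @param counts Haplotype frequency counts (or an `mt_haps` tibble, whose
#'   total counts are used).
#' @return A one-row tibble with `h`, `sd_h`, `n` and `n_hap`.
#' @examples
#' haplotype_diversity(c(247, 2)) # h = 0.0160 +/- 0.0111
#' @export
haplotype_diversity <- function(counts) {
  if (inherits(counts, "mt_haps")) counts <- hap_counts(counts)
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) rlang::abort("Haplotype diversity needs n >= 2.")
  p <- counts / n
  sum2 <- sum(p^2)
  h <- n * (1 - sum2) / (n - 1)
  v <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(p^3) - sum2^2) + sum2 - sum2^2)
  tibble::tibble(h = h, sd_h = sqrt(max(v, 0)),
                 n = n, n_hap = length(counts))
}

## Pairwise difference counts for all C(n,2) pairs, as a vector (one entry
## per pair). gap_as_missing performs pairwise deletion: a site where either
## sequence has '-'/'?' is skipped for that pair. gap_as_state compares '-'
## like any other state but always skips '?'.
pairwise_differences <- function(m, gap_policy) {
  n <- nrow(m)
  if (gap_policy == "complete_deletion") {
    m <- apply_complete_deletion(m)
    gap_policy <- "gap_as_state"
  }
  diff <- matrix(0L, n, n)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (all(col == col[1])) next # invariant columns contribute nothing
    miss <- col == "?"
    if (gap_policy == "gap_as_missing") miss <- miss | col == "-"
    ne <- outer(col, col, "!=")
    ne[miss, ] <- FALSE
    ne[, miss] <- FALSE
    diff <- diff + ne
  }
  diff[upper.tri(diff)]
}

#' Mean number of pairwise differences (k)
#'
#' Average Hamming distance over all sequence pairs. Under
#' `"gap_as_missing"` sites are pairwise-deleted (a site is skipped for a
#' pair if either member has `-` or `?` there).
#'
#' @param aln An `mt_aln` tibble (use [expand_table()] to weight haplotypes
#'   by their counts).
#' @inheritParams segregating_sites
#' @return Mean pairwise differences, a number >= 0.
#' @export
mean_pairwise_differences <- function(aln,
                                      gap_policy = c("gap_as_missing",
                                                     "gap_as_state",
                                                     "complete_deletion")) {
  gap_policy <- match.arg(gap_policy)
  m <- state_matrix(aln)
  if (nrow(m) < 2) rlang::abort("Need at least 2 sequences for k.")
  mean(pairwise_differences(m, gap_policy))
}

#' Nucleotide diversity per site
#'
#' `pi = k / L`, the average proportion of sites at which two sequences
#' differ. Because published haplotype tables hold only the variable
#' columns, the effective sequence length `L` must be supplied (it defaults
#' to the table's declared locus length). The standard deviation uses the
#' classical approximation of Nei (1987, eq. 10.7) combining sampling and
#' stochastic variance.
#'
#' @inheritParams mean_pairwise_differences
#' @param L Effective sequence length in bp.
#' @return A one-row tibble with `pi`, `sd_pi`, `k` and `L`.
#' @export
nucleotide_diversity <- function(aln, L = aln_length(aln),
                                 gap_policy = c("gap_as_missing",
                                                "gap_as_state",
                                                "complete_deletion")) {
  gap_policy <- match.arg(gap_policy)
  if (is.null(L) || L <= 0) rlang::abort("`L` must be a positive length.")
  k <- mean_pairwise_differences(aln, gap_policy)
  n <- nrow(aln)
  pi <- k / L
  v <- (n + 1) * pi / (3 * (n - 1) * L) +
    2 * (n^2 + n + 3) * pi^2 / (9 * n * (n - 1))
  tibble::tibble(pi = pi, sd_pi = sqrt(max(v, 0)), k = k, L = as.integer(L))
}

#' Molecular diversity summary for one sample
#'
#' One row of the classical mtDNA diversity table: sample size, segregating
#' sites, haplotype count, haplotype diversity, nucleotide diversity and
#' mean pairwise differences. Gap policies default to the per-statistic
#' conventions of the programs traditionally used for such tables: S counts
#' gaps as a fifth state, while k and pi use pairwise deletion.
#'
#' @param aln An `mt_aln` tibble of individuals.
#' @param L Effective sequence length for pi.
#' @param s_policy,k_policy Gap policies for S and for k/pi.
#' @return A one-row tibble (`n`, `S`, `n_hap`, `h`, `sd_h`, `pi`, `sd_pi`,
#'   `k`, `L`).
#' @export
diversity_stats <- function(aln, L = aln_length(aln),
                            s_policy = "gap_as_state",
                            k_policy = "gap_as_missing") {
  haps <- collapse_haplotypes(aln)
  hd <- haplotype_diversity(hap_counts(haps))
  nd <- nucleotide_diversity(aln, L = L, gap_policy = k_policy)
  tibble::tibble(
    n = nrow(aln),
    S = segregating_sites(aln, s_policy),
    n_hap = nrow(haps),
    h = hd$h, sd_h = hd$sd_h,
    pi = nd$pi, sd_pi = nd$sd_pi,
    k = nd$k, L = nd$L
  )
}
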