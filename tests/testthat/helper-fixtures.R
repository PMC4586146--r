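# shared fixtures and oracles

cr_tbl <- jackal_cr_haplotypes()
cytb_tbl <- jackal_cytb_haplotypes()
regions <- jackal_regions()
india_localities <- regions$locality[regions$region == "India"]
abroad_localities <- regions$locality[regions$region != "India"]

india_aln <- expand_table(cr_tbl, localities = india_localities)
abroad_aln <- expand_table(cr_tbl, localities = abroad_localities)

# small deterministic alignment builder
make_aln <- function(seqs, localities = "loc", ids = NULL, sites = NULL,
                     L = NULL) {
  m <- do.call(rbind, strsplit(seqs, ""))
  if (is.null(ids)) ids <- paste0("s", seq_along(seqs))
  mt_alignment(m, ids, localities, sites = sites, L = L)
}

# random haplotype table over a binary-ish alphabet (distinct rows)
random_hap_table <- function(n_hap, n_sites, n_loc = 2,
                             alphabet = c("A", "C")) {
  repeat {
    m <- matrix(sample(alphabet, n_hap * n_sites, replace = TRUE),
                nrow = n_hap)
    if (!anyDuplicated(apply(m, 1, paste, collapse = ""))) break
  }
  counts <- matrix(sample(0:4, n_hap * n_loc, replace = TRUE),
                   nrow = n_hap,
                   dimnames = list(NULL, paste0("L", seq_len(n_loc))))
  counts[rowSums(counts) == 0, 1] <- 1L
  mt_haplotypes(m, paste0("h", seq_len(n_hap)), counts)
}

# brute-force mean pairwise differences by explicit double loop
brute_force_k <- function(aln, gap_policy = "gap_as_missing") {
  m <- mtexpand:::state_matrix(aln)
  if (gap_policy == "complete_deletion") {
    keep <- apply(m, 2, function(col) all(col != "-" & col != "?"))
    m <- m[, keep, drop = FALSE]
    gap_policy <- "gap_as_state"
  }
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      for (s in seq_len(ncol(m))) {
        a <- m[i, s]; b <- m[j, s]
        miss <- if (gap_policy == "gap_as_missing") c("-", "?") else "?"
        if (a %in% miss || b %in% miss) next
        if (a != b) tot <- tot + 1
      }
    }
  }
  tot / choose(n, 2)
}

# independent all-MST oracle: an edge of weight w belongs to some minimum
# spanning tree iff contracting it changes the MST weight by exactly -w
# (igraph computes the MST weights)
msn_oracle <- function(d) {
  n <- nrow(d)
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  base <- sum(igraph::E(igraph::mst(g))$weight)
  ut <- which(upper.tri(d), arr.ind = TRUE)
  keep <- logical(nrow(ut))
  for (r in seq_len(nrow(ut))) {
    i <- ut[r, 1]; j <- ut[r, 2]
    gc <- igraph::contract(g, ifelse(seq_len(n) == j, i,
                                     seq_len(n)))
    gc <- igraph::simplify(gc, edge.attr.comb = list(weight = "min"))
    contracted <- sum(igraph::E(igraph::mst(gc))$weight)
    keep[r] <- isTRUE(all.equal(contracted + d[i, j], base))
  }
  ed <- data.frame(i = ut[keep, 1], j = ut[keep, 2])
  ed[order(ed$i, ed$j), ]
}
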