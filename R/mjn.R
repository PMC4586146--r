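## ---- median-joining haplotype networks -----------------------------------
##
## Bandelt-style construction: (1) weighted Hamming distances between all
## node states; (2) epsilon-relaxed minimum spanning network (with eps = 0,
## the union of all minimum spanning trees); (3) candidate median vectors
## from triplets with at least two links, added when their connection cost
## is minimal; (4) iterate to a fixpoint; (5) prune median vectors of
## degree < 2. All ties are broken lexicographically so the output is
## deterministic.

weighted_hamming <- function(m, w) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (j in seq_len(ncol(m))) {
    ne <- outer(m[, j], m[, j], "!=")
    d <- d + w[j] * ne
  }
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

## union-find over admitted edges below a weight threshold
components_below <- function(n, edges, threshold) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(edges)) {
    keep <- edges$w < threshold - 1e-9
    for (r in which(keep)) {
      a <- find(edges$i[r]); b <- find(edges$j[r])
      if (a != b) parent[a] <- b
    }
  }
  vapply(seq_len(n), find, integer(1))
}

## epsilon-relaxed minimum spanning network over a distance matrix.
## An edge (u, v, w) is admitted when u and v are not connected by admitted
## edges of weight < w - eps; with eps = 0 this is the union of all minimum
## spanning trees (Kruskal with equality grouping).
msn_edges <- function(d, eps = 0) {
  n <- nrow(d)
  ut <- which(upper.tri(d), arr.ind = TRUE)
  cand <- data.frame(i = ut[, 1], j = ut[, 2], w = d[ut])
  cand <- cand[order(cand$w, cand$i, cand$j), , drop = FALSE]
  admitted <- cand[0, ]
  for (w in unique(cand$w)) {
    comp <- components_below(n, admitted, w - eps)
    rows <- cand[cand$w == w, , drop = FALSE]
    take <- comp[rows$i] != comp[rows$j]
    admitted <- rbind(admitted, rows[take, , drop = FALSE])
  }
  admitted
}

## columnwise majority of three state vectors; three-way ties resolve to
## the lexicographically smallest of the three states
triplet_median <- function(a, b, c) {
  vapply(seq_along(a), function(j) {
    s <- c(a[j], b[j], c[j])
    tab <- sort(table(s), decreasing = TRUE)
    if (tab[1] >= 2) names(tab)[1] else sort(s)[1]
  }, character(1))
}

#' Build a median-joining haplotype network
#'
#' Connects the haplotypes of a table through an epsilon-relaxed minimum
#' spanning network and augments it with median (Steiner) vectors: for
#' every triplet of nodes with at least two links, the columnwise majority
#' consensus is a candidate intermediate; all candidates achieving the
#' minimal connection cost (sum of distances to the triplet, within
#' `epsilon`) are added, and the network is rebuilt until no new median
#' arises. Median vectors that end up with fewer than two links are pruned.
#' With `epsilon = 0` and no admissible medians the result is exactly the
#' minimum spanning network. Tie-breaking is lexicographic throughout, so
#' the output is deterministic.
#'
#' Indel-containing columns should be removed beforehand (see
#' [drop_indel_sites()]); the construction treats every residual character,
#' including `-`/`?`, as an ordinary state.
#'
#' @param tbl An `mt_haps` tibble with >= 2 distinct haplotypes.
#' @param epsilon Relaxation parameter (default 0, which minimizes
#'   alternative connections).
#' @param weights Per-site weight vector (default: equal weight 1 for all
#'   variable sites).
#' @param prune Remove median vectors of degree < 2 (default TRUE)?
#' @param max_iter Safety cap on median-addition sweeps.
#' @return An object of class `mt_haplonet`: a list with `nodes` (tibble:
#'   `node_id`, `type` sampled/median, `frequency`, list-column
#'   `localities`), `edges` (tibble: `from`, `to`, `weight`, `n_mutations`,
#'   list-column `sites`), `epsilon` and `weights`.
#' @export
build_mjn <- function(tbl, epsilon = 0, weights = NULL, prune = TRUE,
                      max_iter = 25) {
  stopifnot(inherits(tbl, "mt_haps"))
  sm <- state_matrix(tbl)
  if (nrow(sm) < 2) rlang::abort("Need at least two haplotypes.")
  key <- apply(sm, 1, paste, collapse = "")
  if (anyDuplicated(key)) {
    rlang::abort("Duplicate haplotype states; collapse before networking.")
  }
  sites <- aln_sites(tbl)
  if (is.null(weights)) weights <- rep(1, ncol(sm))
  if (length(weights) != ncol(sm)) {
    rlang::abort("`weights` must have one entry per site column.")
  }

  nodes <- sm
  sampled <- rep(TRUE, nrow(sm))
  n_median <- 0L
  for (iter in seq_len(max_iter)) {
    d <- weighted_hamming(nodes, weights)
    ed <- msn_edges(d, epsilon)
    # collect triplets with >= 2 links via shared endpoints
    adj <- lapply(seq_len(nrow(nodes)), function(u) {
      sort(unique(c(ed$j[ed$i == u], ed$i[ed$j == u])))
    })
    seen <- character(0)
    cand_states <- list()
    cand_cost <- numeric(0)
    existing <- apply(nodes, 1, paste, collapse = "")
    for (u in seq_len(nrow(nodes))) {
      nb <- adj[[u]]
      if (length(nb) < 2) next
      for (vi in seq_len(length(nb) - 1)) {
        for (wi in (vi + 1):length(nb)) {
          v <- nb[vi]; w <- nb[wi]
          med <- triplet_median(nodes[u, ], nodes[v, ], nodes[w, ])
          mk <- paste(med, collapse = "")
          if (mk %in% existing || mk %in% seen) next
          cost <- sum(weights * (med != nodes[u, ])) +
            sum(weights * (med != nodes[v, ])) +
            sum(weights * (med != nodes[w, ]))
          seen <- c(seen, mk)
          cand_states <- c(cand_states, list(med))
          cand_cost <- c(cand_cost, cost)
        }
      }
    }
    if (!length(cand_cost)) break
    lambda <- min(cand_cost)
    take <- which(cand_cost <= lambda + epsilon)
    take <- take[order(vapply(cand_states[take], paste, character(1),
                              collapse = ""))]
    for (t in take) {
      n_median <- n_median + 1L
      nodes <- rbind(nodes, cand_states[[t]])
      rownames(nodes)[nrow(nodes)] <- paste0("mv", n_median)
      sampled <- c(sampled, FALSE)
    }
  }

  # final network, pruning obsolete medians (degree < 2) to a fixpoint
  repeat {
    d <- weighted_hamming(nodes, weights)
    ed <- msn_edges(d, epsilon)
    deg <- tabulate(c(ed$i, ed$j), nbins = nrow(nodes))
    drop <- which(!sampled & deg < 2)
    if (!prune || !length(drop)) break
    nodes <- nodes[-drop, , drop = FALSE]
    sampled <- sampled[-drop]
  }

  freq <- hap_counts(tbl)[rownames(nodes)[sampled]]
  cm <- hap_count_matrix(tbl)
  node_tbl <- tibble::tibble(
    node_id = rownames(nodes),
    type = ifelse(sampled, "sampled", "median"),
    frequency = ifelse(sampled, freq[rownames(nodes)], 0L),
    localities = purrr::map(rownames(nodes), function(id) {
      if (id %in% rownames(cm)) {
        v <- cm[id, ]
        v[v > 0]
      } else integer(0)
    })
  )
  edge_tbl <- tibble::tibble(
    from = rownames(nodes)[ed$i],
    to = rownames(nodes)[ed$j],
    weight = ed$w,
    n_mutations = mapply(function(i, j) sum(nodes[i, ] != nodes[j, ]),
                         ed$i, ed$j),
    sites = purrr::map2(ed$i, ed$j,
                        function(i, j) sites[nodes[i, ] != nodes[j, ]])
  )
  structure(list(nodes = node_tbl, edges = edge_tbl,
                 states = nodes, epsilon = epsilon, weights = weights),
            class = "mt_haplonet")
}

#' @export
print.mt_haplonet <- function(x, ...) {
  cat("Median-joining haplotype network\n")
  cat(sprintf("  %d sampled haplotypes, %d median vectors, %d edges\n",
              sum(x$nodes$type == "sampled"),
              sum(x$nodes$type == "median"), nrow(x$edges)))
  invisible(x)
}

#' Topology summary of a haplotype network
#'
#' Degrees are counted over all incident edges, including links to median
#' vectors. Sampled haplotypes of degree 1 are peripheral (derived tips);
#' high-degree interior haplotypes are candidate ancestral types.
#'
#' @param net An `mt_haplonet`.
#' @return A tibble over sampled nodes: `node_id`, `degree`, `frequency`,
#'   `peripheral`, `rank` (1 = most interior, ties share the minimum rank).
#' @export
network_stats <- function(net) {
  ids <- net$nodes$node_id
  deg <- stats::setNames(integer(length(ids)), ids)
  for (v in c(net$edges$from, net$edges$to)) deg[v] <- deg[v] + 1L
  out <- tibble::tibble(
    node_id = ids,
    type = net$nodes$type,
    degree = as.integer(deg[ids]),
    frequency = net$nodes$frequency
  )
  out <- out[out$type == "sampled", c("node_id", "degree", "frequency")]
  out$peripheral <- out$degree == 1L
  out$rank <- rank(-out$degree, ties.method = "min")
  out[order(out$rank, out$node_id), ]
}

#' Convert a haplotype network to igraph
#'
#' @param net An `mt_haplonet`.
#' @return An undirected `igraph` graph with node attributes `type` and
#'   `frequency` and edge attribute `n_mutations`.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("from", "to", "n_mutations")],
    directed = FALSE,
    vertices = data.frame(name = net$nodes$node_id,
                          type = net$nodes$type,
                          frequency = net$nodes$frequency)
  )
  g
}

#' Export a haplotype network
#'
#' `write_network_edges()` writes a TSV edge list (`node_a`, `node_b`,
#' `n_mutations`, comma-separated `sites`); `write_network_graphml()`
#' writes GraphML for external viewers.
#'
#' @param net An `mt_haplonet`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network_edges <- function(net, path) {
  df <- tibble::tibble(
    node_a = net$edges$from,
    node_b = net$edges$to,
    n_mutations = net$edges$n_mutations,
    sites = vapply(net$edges$sites, paste, character(1), collapse = ",")
  )
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_network_edges
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
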