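test_that("two haplotypes one step apart give a single bare edge", {
  tbl <- mt_haplotypes(rbind(c("A", "A"), c("A", "C")), c("h1", "h2"),
                       matrix(c(1L, 1L), 2, 1,
                              dimnames = list(NULL, "X")))
  net <- build_mjn(tbl)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$n_mutations, 1)
  expect_equal(sum(net$nodes$type == "median"), 0)
})

test_that("a star triplet is resolved through one median vector", {
  # three haplotypes each one mutation from an unsampled centre AAA;
  # exhaustive Steiner reasoning: total length 3 via the centre vs 4 via
  # any tree on the sampled nodes alone
  tbl <- mt_haplotypes(rbind(c("C", "A", "A"), c("A", "C", "A"),
                             c("A", "A", "C")),
                       c("h1", "h2", "h3"),
                       matrix(1L, 3, 1, dimnames = list(NULL, "X")))
  net <- build_mjn(tbl)
  med <- net$nodes$node_id[net$nodes$type == "median"]
  expect_length(med, 1)
  st <- network_stats(net)
  expect_true(all(st$degree == 1))
  expect_equal(nrow(net$edges), 3)
  expect_true(all(net$edges$n_mutations == 1))
  # the median is the consensus AAA
  expect_equal(unname(net$states[med, ]), c("A", "A", "A"))
})

test_that("the jackal CR network reproduces the published topology", {
  net <- build_mjn(drop_indel_sites(cr_tbl))
  st <- network_stats(net)
  expect_equal(sum(st$peripheral), 11)
  expect_equal(max(st$degree), 6)
  expect_equal(st$node_id[which.max(st$degree)], "Ind11")
  # the four secondary hubs
  four <- st$node_id[st$degree == 4]
  expect_setequal(four, c("Ind1", "Ind7", "Ind8", "Ind15"))
  # the European haplotype hangs one mutation off an Indian haplotype,
  # the Israeli two mutations away (via a median vector)
  eur_edge <- net$edges[net$edges$from == "Eur" | net$edges$to == "Eur", ]
  expect_equal(eur_edge$n_mutations, 1)
  isr_edge <- net$edges[net$edges$from == "Isr" | net$edges$to == "Isr", ]
  expect_equal(isr_edge$n_mutations, 1)
  other <- setdiff(c(isr_edge$from, isr_edge$to), "Isr")
  expect_equal(net$nodes$type[net$nodes$node_id == other], "median")
  # connected, and medians never dangle
  expect_true(igraph::is_connected(as_igraph(net)))
  deg <- igraph::degree(as_igraph(net))
  expect_true(all(deg[net$nodes$node_id[net$nodes$type == "median"]] >= 2))
})

test_that("duplicate haplotype states are rejected", {
  tbl <- mt_haplotypes(rbind(c("A", "A"), c("A", "C")), c("h1", "h2"),
                       matrix(1L, 2, 1, dimnames = list(NULL, "X")))
  tbl2 <- tbl
  tbl2[2, c("s1", "s2")] <- list("A", "A")
  expect_error(build_mjn(tbl2), "[Dd]uplicate")
})

test_that("the network always contains a minimum spanning network", {
  # independent all-MST oracle via igraph edge contraction
  set.seed(77)
  for (rep in 1:8) {
    tbl <- random_hap_table(sample(4:7, 1), sample(4:7, 1))
    net <- build_mjn(tbl, prune = TRUE)
    d <- mtexpand:::weighted_hamming(mtexpand:::state_matrix(tbl),
                                     rep(1, length(aln_sites(tbl))))
    oracle <- msn_oracle(d)
    ids <- tbl$haplotype_id
    got <- net$edges
    if (sum(net$nodes$type == "median") == 0) {
      # no admissible medians: the network IS the minimum spanning network
      got_pairs <- sort(paste(pmin(got$from, got$to),
                              pmax(got$from, got$to)))
      want_pairs <- sort(paste(pmin(ids[oracle$i], ids[oracle$j]),
                               pmax(ids[oracle$i], ids[oracle$j])))
      expect_equal(got_pairs, want_pairs)
    }
    # and medians can only shorten the total network length
    msn_total <- sum(d[as.matrix(oracle)])
    expect_lte(sum(net$edges$weight), msn_total + 1e-9)
  }
})

test_that("path-shaped data yields the path with no medians", {
  tbl <- mt_haplotypes(rbind(c("A", "A", "A"), c("C", "A", "A"),
                             c("C", "C", "A"), c("C", "C", "C")),
                       paste0("h", 1:4),
                       matrix(1L, 4, 1, dimnames = list(NULL, "X")))
  net <- build_mjn(tbl)
  expect_equal(sum(net$nodes$type == "median"), 0)
  st <- network_stats(net)
  expect_equal(sort(st$degree), c(1, 1, 2, 2))
})

test_that("relaxing epsilon only adds connections on a fixed node set", {
  d <- mtexpand:::weighted_hamming(
    mtexpand:::state_matrix(drop_indel_sites(cr_tbl)), rep(1, 22))
  e0 <- mtexpand:::msn_edges(d, 0)
  e1 <- mtexpand:::msn_edges(d, 1)
  p0 <- paste(e0$i, e0$j)
  p1 <- paste(e1$i, e1$j)
  expect_true(all(p0 %in% p1))
  expect_gt(length(p1), length(p0))
})

test_that("network exports and tidiers expose the same structure", {
  net <- build_mjn(drop_indel_sites(cytb_tbl))
  g <- glance(net)
  expect_equal(g$n_sampled, 9)
  td <- tidy(net)
  expect_equal(nrow(td), g$n_edges)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_network_edges(net, tmp)
  back <- readr::read_tsv(tmp, show_col_types = FALSE)
  expect_equal(nrow(back), g$n_edges)
  tmp2 <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, tmp2)
  g2 <- igraph::read_graph(tmp2, format = "graphml")
  expect_equal(igraph::gorder(g2), nrow(net$nodes))
})
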