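test_that("reading an aligned FASTA preserves states and order", {
  tmp <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">r1", "ACGTACGTAC", ">r2", "ACGTACGTAC"), tmp)
  aln <- read_alignment(tmp)
  expect_s3_class(aln, "mt_aln")
  expect_equal(aln$sample_id, c("r1", "r2"))
  expect_equal(segregating_sites(aln, "gap_as_state"), 0)

  writeLines(c(">a", "ACGT?N-A", ">b", "ACGTTTTA"), tmp)
  expect_warning(aln2 <- read_alignment(tmp), "mapped to '\\?'")
  m <- mtexpand:::state_matrix(aln2)
  expect_equal(unname(m[1, 5:7]), c("?", "?", "-"))

  writeLines(c(">a", "ACGTT", ">b", "ACG"), tmp)
  expect_error(read_alignment(tmp), "Ragged alignment: record 'b'")
  writeLines(character(0), tmp)
  expect_error(read_alignment(tmp))
})

test_that("the CR fixture expands, writes and re-reads faithfully", {
  full <- expand_table(cr_tbl)
  expect_equal(nrow(full), 301)
  tmp <- withr::local_tempfile(fileext = ".fa")
  write_alignment(full, tmp)
  back <- read_alignment(tmp, sites = aln_sites(cr_tbl))
  expect_identical(unname(mtexpand:::state_matrix(back)),
                   unname(mtexpand:::state_matrix(full)))
  # every printed column is variable once gaps count as a state
  expect_equal(segregating_sites(back, "gap_as_state"), 27)
})

test_that("site classification isolates the five indel columns", {
  cls <- classify_sites(cr_tbl)
  expect_equal(cls$site[cls$indel],
               c(15465, 15466, 15518, 15528, 15529))
  expect_equal(sum(cls$class == "substitution_variable"), 22)
  # invariant under row permutation
  perm <- cr_tbl[sample(nrow(cr_tbl)), ]
  class(perm) <- class(cr_tbl)
  expect_equal(classify_sites(perm), cls)
  # monomorphic alignment: all invariant
  mono <- make_aln(c("AAAA", "AAAA", "AAAA"))
  expect_true(all(classify_sites(mono)$class == "invariant"))
})

test_that("collapsing recovers the published haplotype counts", {
  haps <- collapse_haplotypes(expand_table(cr_tbl))
  expect_equal(nrow(haps), 18)
  cm <- mtexpand:::hap_count_matrix(haps)
  indian <- rowSums(cm[, india_localities, drop = FALSE]) > 0
  expect_equal(sum(indian), 16)
  expect_equal(sum(cm), 301)

  cb <- collapse_haplotypes(expand_table(cytb_tbl))
  expect_equal(nrow(cb), 9)
  expect_equal(sum(mtexpand:::hap_count_matrix(cb)), 40)

  ident <- make_aln(rep("ACGT", 7))
  one <- collapse_haplotypes(ident)
  expect_equal(nrow(one), 1)
  expect_equal(unname(hap_counts(one)), 7)
})

test_that("ignore_missing collapsing merges through wildcards", {
  aln <- make_aln(c("AC", "A?", "?C", "GG"))
  strict <- collapse_haplotypes(aln, "strict")
  loose <- collapse_haplotypes(aln, "ignore_missing")
  expect_equal(nrow(strict), 4)
  expect_equal(nrow(loose), 2)
  expect_equal(unname(hap_counts(loose)), c(3, 1))
  # representative has wildcards filled in
  expect_equal(unname(mtexpand:::state_matrix(loose)[1, ]), c("A", "C"))
})

test_that("expansion respects locality filters and counts", {
  expect_equal(nrow(india_aln), 52)
  expect_equal(nrow(abroad_aln), 249)
  expect_error(expand_table(cr_tbl, localities = "Atlantis"),
               "Unknown localit")
  single <- mt_haplotypes(matrix("A", 1, 1), "h1",
                          matrix(1L, 1, 1, dimnames = list(NULL, "X")))
  expect_equal(nrow(expand_table(single)), 1)
})

test_that("collapse is the left inverse of expand on random tables", {
  set.seed(101)
  for (rep in 1:10) {
    tbl <- random_hap_table(sample(2:6, 1), sample(3:8, 1))
    back <- collapse_haplotypes(expand_table(tbl),
                                ids = tbl$haplotype_id)
    expect_equal(mtexpand:::state_matrix(back),
                 mtexpand:::state_matrix(tbl))
    cm_b <- mtexpand:::hap_count_matrix(back)
    cm_t <- mtexpand:::hap_count_matrix(tbl)
    expect_equal(cm_b[, colnames(cm_t)], cm_t)
    # counts conserved
    expect_equal(sum(cm_b), nrow(expand_table(tbl)))
  }
})

test_that("haplotype-table TSV round-trips and rejects malformed input", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_haplotype_table(cr_tbl, tmp)
  back <- read_haplotype_table(tmp)
  expect_equal(back, cr_tbl)
  expect_equal(aln_length(back), 440)

  lines <- readLines(tmp)
  dup <- c(lines, lines[3])
  writeLines(dup, tmp)
  expect_error(read_haplotype_table(tmp), "duplicate haplotype id 'Ind1'")

  bad <- lines
  bad[3] <- sub("\t2\t", "\tx\t", bad[3])
  writeLines(bad, tmp)
  expect_error(read_haplotype_table(tmp), "counts must be integers")

  writeLines(c("#L=10", "wrong\theader"), tmp)
  expect_error(read_haplotype_table(tmp), "haplotype_id")
})

test_that("haplotype_alignment returns each haplotype once", {
  ha <- haplotype_alignment(cr_tbl)
  expect_equal(nrow(ha), 18)
  hi <- haplotype_alignment(cr_tbl, localities = india_localities)
  expect_equal(nrow(hi), 16)
  expect_setequal(hi$sample_id, paste0("Ind", 1:16))
})
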