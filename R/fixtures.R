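#' Golden jackal haplotype fixtures
#'
#' The package ships the published golden jackal mtDNA haplotype tables as
#' plain-text fixtures: 18 control-region (CR) haplotypes scored at 27
#' variable sites (positions 15,465-15,751 on the Canis lupus reference
#' mitogenome NC_009686; amplified fragment ~440 bp) with per-locality
#' counts totalling 301 individuals, and 9 cytochrome-b haplotypes at 9
#' variable sites (positions 14,279-14,669; 412 bp fragment) totalling 40
#' individuals. These are the inputs for the worked examples and for the
#' desk-scale reproduction of the published diversity and expansion
#' statistics.
#'
#' The printed CR locality counts sum to 52 Indian individuals, whereas the
#' published summary statistics report n = 51 for India (one individual was
#' evidently excluded from analysis, but which one is not recoverable).
#' `as_analyzed = TRUE` therefore removes one copy of the modal Indian
#' haplotype (Ind5, Gujarat) so that group sizes match the published
#' analysis; the default reports the counts exactly as printed.
#'
#' @param as_analyzed Logical; see Details.
#' @return An `mt_haps` tibble.
#' @export
jackal_cr_haplotypes <- function(as_analyzed = FALSE) {
  tbl <- read_haplotype_table(
    system.file("extdata", "jackal_cr.tsv", package = "mtexpand",
                mustWork = TRUE))
  if (as_analyzed) {
    tbl$n_GJ[tbl$haplotype_id == "Ind5"] <-
      tbl$n_GJ[tbl$haplotype_id == "Ind5"] - 1L
  }
  tbl
}

#' @rdname jackal_cr_haplotypes
#' @export
jackal_cytb_haplotypes <- function() {
  read_haplotype_table(
    system.file("extdata", "jackal_cytb.tsv", package = "mtexpand",
                mustWork = TRUE))
}

#' Locality-to-region lookup for the jackal fixtures
#'
#' Maps each sampled locality to the regional groups used in the published
#' summary tables: `India` (Gujarat, Uttar Pradesh, Rajasthan, Uttarakhand,
#' Haryana, Karnataka, Madhya Pradesh, Central India), `Israel`, and
#' `Europe` (Bulgaria, Serbia, Croatia, Italy, Austria).
#'
#' @return A tibble with columns `locality` and `region`.
#' @export
jackal_regions <- function() {
  india <- c("GJ", "UP", "RJ", "UA", "HR", "KR", "MP", "Central India")
  europe <- c("Bulgaria", "Serbia", "Croatia", "Italy", "Austria")
  tibble::tibble(
    locality = c(india, "Israel", europe),
    region = c(rep("India", length(india)), "Israel",
               rep("Europe", length(europe)))
  )
}

#' Pool haplotype-table counts into regional groups
#'
#' Collapses the locality count columns of a haplotype table according to a
#' locality-to-group mapping and drops haplotypes absent from the retained
#' groups.
#'
#' @param tbl An `mt_haps` tibble.
#' @param groups Data frame with columns `locality` and `region` (or
#'   `group`), e.g. [jackal_regions()].
#' @param keep Optional character vector of groups to retain.
#' @return An `mt_haps` tibble whose count columns are the groups.
#' @export
pool_localities <- function(tbl, groups, keep = NULL) {
  gcol <- if ("region" %in% names(groups)) "region" else "group"
  cm <- hap_count_matrix(tbl)
  miss <- setdiff(colnames(cm), groups$locality)
  if (length(miss)) {
    rlang::abort(paste0("No group assigned for localit",
                        if (length(miss) > 1) "ies: " else "y: ",
                        paste(miss, collapse = ", ")))
  }
  grp <- groups[[gcol]][match(colnames(cm), groups$locality)]
  pooled <- t(rowsum(t(cm), grp))
  if (!is.null(keep)) {
    unknown <- setdiff(keep, colnames(pooled))
    if (length(unknown)) {
      rlang::abort(paste0("Unknown group: ", paste(unknown, collapse = ", ")))
    }
    pooled <- pooled[, keep, drop = FALSE]
  }
  present <- rowSums(pooled) > 0
  mt_haplotypes(state_matrix(tbl)[present, , drop = FALSE],
                tbl$haplotype_id[present],
                pooled[present, , drop = FALSE],
                sites = aln_sites(tbl), L = attr(tbl, "L"))
}
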