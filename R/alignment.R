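#' @keywords internal
"_PACKAGE"

## Allowed per-site states. '-' is an alignment gap (an indel state observed
## in the sample); '?' is missing data and is never treated as a state.
ALN_ALPHABET <- c("A", "C", "G", "T", "-", "?")

#' Construct an aligned-sequence table
#'
#' An alignment is stored as a tibble with one row per individual: a
#' `sample_id` column, a `locality` column, and one single-character column
#' per alignment site named `s<position>` (positions are 1-based coordinates
#' on a reference mitogenome, e.g. `s15465`). Because published haplotype
#' tables print only the variable columns, the tibble usually holds just
#' those, and the total locus length used for per-site statistics (such as
#' nucleotide diversity) travels separately in the `L` attribute.
#'
#' @param states Character matrix (individuals x sites) over the alphabet
#'   `A C G T - ?`, where `-` is an alignment gap and `?` missing data.
#' @param sample_ids Unique sample identifiers, one per row.
#' @param localities Locality label per sample (recycled if length 1).
#' @param sites Integer vector of strictly increasing 1-based reference
#'   coordinates, one per column. Defaults to `1:ncol(states)`.
#' @param L Declared total alignment length in bp (>= number of columns).
#'   Stored as an attribute; defaults to `max(sites)` span when omitted.
#' @return A tibble of class `mt_aln`.
#' @export
mt_alignment <- function(states, sample_ids, localities = NA_character_,
                         sites = NULL, L = NULL) {
  states <- as.matrix(states)
  if (is.null(sites)) sites <- seq_len(ncol(states))
  sites <- as.integer(sites)
  n <- nrow(states)
  sample_ids <- as.character(sample_ids)
  localities <- rep_len(as.character(localities), n)
  if (length(sample_ids) != n) {
    rlang::abort("`sample_ids` must have one entry per alignment row.")
  }
  if (anyDuplicated(sample_ids)) {
    dup <- sample_ids[duplicated(sample_ids)][1]
    rlang::abort(paste0("Duplicate sample id: '", dup, "'."))
  }
  if (length(sites) != ncol(states)) {
    rlang::abort("`sites` must have one coordinate per alignment column.")
  }
  if (is.unsorted(sites, strictly = TRUE)) {
    rlang::abort("`sites` must be strictly increasing.")
  }
  bad <- setdiff(unique(as.vector(states)), ALN_ALPHABET)
  if (length(bad)) {
    rlang::abort(paste0("Alignment states outside {A,C,G,T,-,?}: ",
                        paste(bad, collapse = ", ")))
  }
  if (is.null(L)) L <- length(sites)
  colnames(states) <- paste0("s", sites)
  out <- tibble::tibble(sample_id = sample_ids, locality = localities)
  out <- dplyr::bind_cols(out, tibble::as_tibble(states))
  attr(out, "L") <- as.integer(L)
  class(out) <- c("mt_aln", class(out))
  out
}

site_cols <- function(x) grep("^s[0-9]+$", names(x), value = TRUE)

#' Site coordinates of an alignment or haplotype table
#' @param x An `mt_aln` or `mt_haps` tibble.
#' @return Integer vector of 1-based reference positions.
#' @export
aln_sites <- function(x) as.integer(sub("^s", "", site_cols(x)))

#' Declared total locus length of an alignment or haplotype table
#' @inheritParams aln_sites
#' @return Integer length in bp, or the number of stored columns if no
#'   length was declared.
#' @export
aln_length <- function(x) {
  L <- attr(x, "L")
  if (is.null(L)) length(site_cols(x)) else as.integer(L)
}

## character matrix of per-site states, rownames = sample/haplotype ids
state_matrix <- function(x) {
  sc <- site_cols(x)
  m <- as.matrix(as.data.frame(x[, sc, drop = FALSE]))
  id_col <- if ("sample_id" %in% names(x)) "sample_id" else "haplotype_id"
  rownames(m) <- x[[id_col]]
  m
}

#' Read an aligned FASTA file
#'
#' Records must all have the same length (the file is an alignment, not raw
#' reads). IUPAC ambiguity codes and `N` are mapped to the missing-data
#' character `?` with a warning; `-` is kept as a gap state. Sample order
#' follows file order.
#'
#' @param path Path to a FASTA file.
#' @param locality_map Optional data frame with columns `sample_id` and
#'   `locality`, or a named character vector, assigning a locality label to
#'   each record. Unmapped records get `NA`.
#' @param sites Optional reference coordinates for the columns.
#' @param L Optional declared locus length (defaults to record length).
#' @return An [mt_alignment()] tibble.
#' @export
read_alignment <- function(path, locality_map = NULL, sites = NULL, L = NULL) {
  recs <- as.character(ape::read.FASTA(path))
  if (length(recs) == 0) rlang::abort(paste0("No FASTA records in ", path))
  lens <- lengths(recs)
  if (length(unique(lens)) > 1) {
    bad <- which(lens != lens[1])[1]
    rlang::abort(paste0("Ragged alignment: record '", names(recs)[bad],
                        "' has length ", lens[bad], ", expected ", lens[1],
                        "."))
  }
  m <- toupper(do.call(rbind, recs))
  amb <- !(m %in% ALN_ALPHABET)
  if (any(amb)) {
    warning(sum(amb), " ambiguous/unknown base(s) mapped to '?'",
            call. = FALSE)
    m[amb] <- "?"
  }
  ids <- names(recs)
  loc <- rep(NA_character_, length(ids))
  if (!is.null(locality_map)) {
    if (is.data.frame(locality_map)) {
      loc <- locality_map$locality[match(ids, locality_map$sample_id)]
    } else {
      loc <- unname(locality_map[ids])
    }
  }
  if (is.null(L)) L <- ncol(m)
  mt_alignment(m, ids, loc, sites = sites, L = L)
}

#' Write an alignment to FASTA
#'
#' @param aln An `mt_aln` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  m <- state_matrix(aln)
  dna <- ape::as.DNAbin(tolower(m))
  ape::write.FASTA(dna, path)
  invisible(path)
}

#' Classify alignment columns
#'
#' Each stored column is classified as `invariant`, `substitution_variable`
#' (at least two distinct non-gap, non-missing states) or `indel_containing`
#' (at least one sampled gap state `-`; this takes precedence in `class`,
#' since downstream analyses that cannot model indels drop such columns
#' wholesale). Missing data `?` never makes a column variable on its own.
#' The classification depends only on the set of states per column, so it is
#' invariant under row permutation.
#'
#' @param aln An `mt_aln` or `mt_haps` tibble.
#' @return A tibble with columns `site`, `n_states` (distinct non-gap,
#'   non-missing states), `variable`, `indel` and `class`.
#' @export
classify_sites <- function(aln) {
  m <- state_matrix(aln)
  per_col <- apply(m, 2, function(col) {
    nuc <- setdiff(unique(col), c("-", "?"))
    c(n_states = length(nuc), indel = as.integer(any(col == "-")))
  })
  n_states <- per_col["n_states", ]
  indel <- per_col["indel", ] == 1
  variable <- n_states >= 2
  tibble::tibble(
    site = aln_sites(aln),
    n_states = as.integer(n_states),
    variable = variable,
    indel = indel,
    class = dplyr::case_when(
      indel ~ "indel_containing",
      variable ~ "substitution_variable",
      TRUE ~ "invariant"
    )
  )
}

#' Drop indel-containing columns
#'
#' Removes every column in which any sampled state is a gap, the usual
#' pre-processing step before network construction or model-based distances
#' when alignment blocks containing indels are excluded from analysis.
#'
#' @param x An `mt_aln` or `mt_haps` tibble.
#' @return The same type of tibble without indel-containing site columns;
#'   the declared length attribute is preserved.
#' @export
drop_indel_sites <- function(x) {
  cls <- classify_sites(x)
  drop <- paste0("s", cls$site[cls$indel])
  out <- x[, setdiff(names(x), drop), drop = FALSE]
  attr(out, "L") <- attr(x, "L")
  class(out) <- class(x)
  out
}
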