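#' Construct a haplotype-by-variable-site table
#'
#' The in-memory form of a published haplotype table: one row per distinct
#' haplotype with its per-site states and per-locality counts. Stored as a
#' tibble with `haplotype_id`, one `s<position>` column per site, and one
#' `n_<locality>` count column per locality.
#'
#' @param states Character matrix (haplotypes x sites).
#' @param haplotype_ids Unique haplotype identifiers.
#' @param counts Non-negative integer matrix (haplotypes x localities) with
#'   locality names as column names.
#' @param sites,L As in [mt_alignment()].
#' @return A tibble of class `mt_haps`.
#' @export
mt_haplotypes <- function(states, haplotype_ids, counts, sites = NULL,
                          L = NULL) {
  states <- as.matrix(states)
  counts <- as.matrix(counts)
  if (is.null(sites)) sites <- seq_len(ncol(states))
  sites <- as.integer(sites)
  if (anyDuplicated(haplotype_ids)) {
    dup <- haplotype_ids[duplicated(haplotype_ids)][1]
    rlang::abort(paste0("Duplicate haplotype id: '", dup, "'."))
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    rlang::abort("Haplotype counts must be non-negative integers.")
  }
  if (any(rowSums(counts) < 1)) {
    bad <- haplotype_ids[rowSums(counts) < 1][1]
    rlang::abort(paste0("Haplotype '", bad, "' has total count 0."))
  }
  key <- apply(states, 1, paste, collapse = "")
  if (anyDuplicated(key)) {
    rlang::abort("Two haplotype rows have identical states; collapse first.")
  }
  if (is.null(L)) L <- length(sites)
  colnames(states) <- paste0("s", sites)
  out <- tibble::tibble(haplotype_id = as.character(haplotype_ids))
  out <- dplyr::bind_cols(out, tibble::as_tibble(states))
  cnt <- tibble::as_tibble(counts)
  names(cnt) <- paste0("n_", colnames(counts))
  out <- dplyr::bind_cols(out, cnt)
  attr(out, "L") <- as.integer(L)
  class(out) <- c("mt_haps", class(out))
  out
}

count_cols <- function(tbl) grep("^n_", names(tbl), value = TRUE)

#' Localities recorded in a haplotype table
#' @param tbl An `mt_haps` tibble.
#' @return Character vector of locality names.
#' @export
hap_localities <- function(tbl) sub("^n_", "", count_cols(tbl))

hap_count_matrix <- function(tbl) {
  cc <- count_cols(tbl)
  m <- as.matrix(as.data.frame(tbl[, cc, drop = FALSE]))
  storage.mode(m) <- "integer"
  rownames(m) <- tbl$haplotype_id
  colnames(m) <- sub("^n_", "", cc)
  m
}

#' Total count per haplotype
#' @param tbl An `mt_haps` tibble.
#' @return Named integer vector.
#' @export
hap_counts <- function(tbl) rowSums(hap_count_matrix(tbl))

#' Collapse aligned sequences into haplotypes
#'
#' Groups identical rows of an alignment into distinct haplotypes and
#' aggregates their counts per locality. Under `missing_policy = "strict"`
#' any character difference (including gaps and missing data) distinguishes
#' haplotypes. Under `"ignore_missing"`, `?` matches any state and rows are
#' merged greedily in input order into the first compatible haplotype; the
#' retained states are the first row's, with `?` filled in from later
#' members where they are observed.
#'
#' @param aln An `mt_aln` tibble.
#' @param missing_policy `"strict"` or `"ignore_missing"`.
#' @param ids Optional explicit haplotype ids (one per resulting haplotype,
#'   in first-occurrence order). By default ids are zero-padded serials
#'   `H01, H02, ...` in first-seen order, which makes the collapse
#'   deterministic.
#' @param id_prefix Prefix for automatic ids.
#' @return An `mt_haps` tibble.
#' @export
collapse_haplotypes <- function(aln,
                                missing_policy = c("strict", "ignore_missing"),
                                ids = NULL, id_prefix = "H") {
  missing_policy <- match.arg(missing_policy)
  m <- state_matrix(aln)
  if (nrow(m) == 0) rlang::abort("Cannot collapse an empty alignment.")
  n <- nrow(m)
  group <- integer(n)
  reps <- list() # representative state vectors per haplotype class
  for (i in seq_len(n)) {
    row <- m[i, ]
    hit <- 0L
    for (g in seq_along(reps)) {
      r <- reps[[g]]
      same <- if (missing_policy == "strict") {
        all(r == row)
      } else {
        all(r == row | r == "?" | row == "?")
      }
      if (same) { hit <- g; break }
    }
    if (hit == 0L) {
      reps[[length(reps) + 1L]] <- row
      group[i] <- length(reps)
    } else {
      if (missing_policy == "ignore_missing") {
        fill <- reps[[hit]] == "?" & row != "?"
        if (any(fill)) reps[[hit]][fill] <- row[fill]
      }
      group[i] <- hit
    }
  }
  locs <- aln$locality
  locs[is.na(locs)] <- "unknown"
  loc_levels <- unique(locs)
  counts <- matrix(0L, nrow = length(reps), ncol = length(loc_levels),
                   dimnames = list(NULL, loc_levels))
  for (i in seq_len(n)) {
    counts[group[i], locs[i]] <- counts[group[i], locs[i]] + 1L
  }
  if (is.null(ids)) {
    ids <- sprintf("%s%0*d", id_prefix,
                   max(2L, nchar(length(reps))), seq_along(reps))
  }
  if (length(ids) != length(reps)) {
    rlang::abort("`ids` must supply one id per distinct haplotype.")
  }
  mt_haplotypes(do.call(rbind, reps), ids, counts,
                sites = aln_sites(aln), L = attr(aln, "L"))
}

#' Expand a haplotype table into a per-individual alignment
#'
#' The inverse of the publication format: each haplotype row is replicated
#' once per counted individual. `collapse_haplotypes(expand_table(tbl))`
#' recovers `tbl` up to haplotype ids.
#'
#' @param tbl An `mt_haps` tibble.
#' @param localities Optional character vector restricting the expansion to
#'   these localities. Unknown names are an error.
#' @return An `mt_aln` tibble with sample ids `<haplotype>.<locality>.<i>`.
#' @export
expand_table <- function(tbl, localities = NULL) {
  cm <- hap_count_matrix(tbl)
  if (!is.null(localities)) {
    unknown <- setdiff(localities, colnames(cm))
    if (length(unknown)) {
      rlang::abort(paste0("Unknown localit",
                          if (length(unknown) > 1) "ies: " else "y: ",
                          paste(unknown, collapse = ", ")))
    }
    cm <- cm[, localities, drop = FALSE]
  }
  sm <- state_matrix(tbl)
  rows <- list(); ids <- character(); locs <- character()
  for (h in seq_len(nrow(cm))) {
    for (l in colnames(cm)) {
      k <- cm[h, l]
      if (k > 0) {
        rows <- c(rows, rep(list(sm[h, ]), k))
        ids <- c(ids, paste(rownames(cm)[h], gsub("\\s+", "", l),
                            seq_len(k), sep = "."))
        locs <- c(locs, rep(l, k))
      }
    }
  }
  if (!length(rows)) rlang::abort("No individuals left after filtering.")
  mt_alignment(do.call(rbind, rows), ids, locs,
               sites = aln_sites(tbl), L = attr(tbl, "L"))
}

#' One-sequence-per-haplotype alignment
#'
#' Returns an alignment containing each distinct haplotype exactly once,
#' regardless of its frequency. This is the input for analyses that are
#' published at the haplotype level, such as mismatch distributions "among
#' haplotypes" and haplotype networks.
#'
#' @param tbl An `mt_haps` tibble.
#' @param localities Optional locality filter, as in [expand_table()]
#'   (haplotypes absent from the retained localities are dropped).
#' @return An `mt_aln` tibble with one row per haplotype; the locality
#'   column holds the locality with the largest count for that haplotype.
#' @export
haplotype_alignment <- function(tbl, localities = NULL) {
  cm <- hap_count_matrix(tbl)
  if (!is.null(localities)) {
    unknown <- setdiff(localities, colnames(cm))
    if (length(unknown)) {
      rlang::abort(paste0("Unknown locality: ",
                          paste(unknown, collapse = ", ")))
    }
    cm <- cm[, localities, drop = FALSE]
  }
  keep <- rowSums(cm) > 0
  if (!any(keep)) rlang::abort("No haplotypes left after filtering.")
  main_loc <- colnames(cm)[apply(cm[keep, , drop = FALSE], 1, which.max)]
  mt_alignment(state_matrix(tbl)[keep, , drop = FALSE],
               tbl$haplotype_id[keep], main_loc,
               sites = aln_sites(tbl), L = attr(tbl, "L"))
}

#' Write / read a haplotype table as TSV
#'
#' The dialect mirrors the in-memory layout: a header row
#' `haplotype_id <tab> site:15465 ... <tab> count:GJ ...`, single-character
#' states, integer counts, UTF-8, LF line endings. `read_haplotype_table()`
#' and `write_haplotype_table()` round-trip losslessly (the declared locus
#' length is carried in a `#L=` comment line).
#'
#' @param tbl An `mt_haps` tibble.
#' @param path File path.
#' @return `write_haplotype_table()` returns `path` invisibly;
#'   `read_haplotype_table()` returns an `mt_haps` tibble.
#' @export
write_haplotype_table <- function(tbl, path) {
  sm <- state_matrix(tbl)
  cm <- hap_count_matrix(tbl)
  hdr <- c("haplotype_id", paste0("site:", aln_sites(tbl)),
           paste0("count:", colnames(cm)))
  rows <- vapply(seq_len(nrow(tbl)), function(i)
    paste(c(tbl$haplotype_id[i], sm[i, ], cm[i, ]), collapse = "\t"),
    character(1))
  con <- file(path, open = "wb") # force LF endings
  on.exit(close(con))
  writeLines(c(paste0("#L=", aln_length(tbl)),
               paste(hdr, collapse = "\t"), rows), con, sep = "\n",
             useBytes = TRUE)
  invisible(path)
}

#' @rdname write_haplotype_table
#' @export
read_haplotype_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  L <- NULL
  if (length(lines) && startsWith(lines[1], "#L=")) {
    L <- as.integer(sub("^#L=", "", lines[1]))
    lines <- lines[-1]
  }
  hdr_line <- 1L + (if (is.null(L)) 0L else 1L)
  if (!length(lines)) rlang::abort("Empty haplotype table file.")
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (hdr[1] != "haplotype_id") {
    rlang::abort(paste0("Malformed header (line ", hdr_line,
                        "): first field must be 'haplotype_id'."))
  }
  is_site <- startsWith(hdr, "site:")
  is_count <- startsWith(hdr, "count:")
  if (!any(is_site) || !any(is_count) ||
      any(!is_site & !is_count & hdr != "haplotype_id")) {
    rlang::abort(paste0("Malformed header (line ", hdr_line,
                        "): fields must be site:<pos> or count:<locality>."))
  }
  sites <- as.integer(sub("^site:", "", hdr[is_site]))
  localities <- sub("^count:", "", hdr[is_count])
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (!length(body)) rlang::abort("Haplotype table has no data rows.")
  fields <- strsplit(body, "\t", fixed = TRUE)
  ids <- character(length(body))
  states <- matrix("", length(body), sum(is_site))
  counts <- matrix(0L, length(body), sum(is_count),
                   dimnames = list(NULL, localities))
  for (i in seq_along(fields)) {
    ln <- hdr_line + i
    f <- fields[[i]]
    if (length(f) != length(hdr)) {
      rlang::abort(paste0("Line ", ln, ": expected ", length(hdr),
                          " fields, found ", length(f), "."))
    }
    ids[i] <- f[1]
    st <- f[is_site]
    if (any(nchar(st) != 1)) {
      rlang::abort(paste0("Line ", ln, ": states must be single characters."))
    }
    states[i, ] <- st
    cn <- suppressWarnings(as.numeric(f[is_count]))
    if (any(!nzchar(f[is_count])) || any(is.na(cn)) || any(cn != round(cn))) {
      rlang::abort(paste0("Line ", ln, ": counts must be integers."))
    }
    counts[i, ] <- as.integer(cn)
  }
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    ln <- hdr_line + which(ids == dup)[2]
    rlang::abort(paste0("Line ", ln, ": duplicate haplotype id '", dup, "'."))
  }
  mt_haplotypes(states, ids, counts, sites = sites, L = L)
}
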