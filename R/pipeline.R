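#' Configure a full phylogeography run
#'
#' Bundles every knob of the analysis chain (collapse -> diversity ->
#' neutrality -> mismatch/dating -> network) into one validated object.
#' Defaults are pinned to the conventions of the worked jackal analysis:
#' mutation rate `mu = 7.3e-5` per generation, generation time 1 year,
#' epsilon = 0 and equal site weights for the network, 1000 simulation and
#' bootstrap replicates, gap policies per stage as in [diversity_stats()]
#' and [neutrality_test()].
#'
#' @param table An `mt_haps` tibble (or path to a haplotype-table TSV).
#' @param groups Data frame with columns `locality` and `region`/`group`
#'   defining the populations analyzed; every locality in `table` must be
#'   covered.
#' @param L Effective sequence length for nucleotide diversity.
#' @param mu,gen_years Expansion-dating parameters.
#' @param n_sims Coalescent replicates for neutrality p-values.
#' @param boot_reps Bootstrap replicates for the tau confidence interval.
#' @param ci_level Level of the tau/date confidence interval.
#' @param s_policy,k_policy,neutrality_policy,mismatch_policy Per-stage gap
#'   policies.
#' @param mismatch_level `"haplotype"` (the published convention: pairwise
#'   differences among distinct haplotypes) or `"individual"` for the
#'   frequency-weighted distribution.
#' @param seed Integer master seed.
#' @param out_dir Optional directory for TSV/JSON/GraphML outputs.
#' @return A list of class `mt_config`.
#' @export
run_config <- function(table, groups, L = NULL,
                       mu = 7.3e-5, gen_years = 1,
                       n_sims = 1000, boot_reps = 1000, ci_level = 0.90,
                       s_policy = "gap_as_state",
                       k_policy = "gap_as_missing",
                       neutrality_policy = "complete_deletion",
                       mismatch_policy = "complete_deletion",
                       mismatch_level = c("haplotype", "individual"),
                       seed = 42, out_dir = NULL) {
  mismatch_level <- match.arg(mismatch_level)
  if (is.character(table)) table <- read_haplotype_table(table)
  stopifnot(inherits(table, "mt_haps"))
  if (mu <= 0) rlang::abort("`mu` must be positive.")
  gcol <- intersect(c("region", "group"), names(groups))[1]
  if (is.na(gcol)) rlang::abort("`groups` needs a region/group column.")
  miss <- setdiff(hap_localities(table), groups$locality)
  if (length(miss)) {
    rlang::abort(paste0("Unassigned locality: ",
                        paste(miss, collapse = ", ")))
  }
  if (is.null(L)) L <- aln_length(table)
  structure(list(table = table, groups = groups, group_col = gcol, L = L,
                 mu = mu, gen_years = gen_years, n_sims = n_sims,
                 boot_reps = boot_reps, ci_level = ci_level,
                 s_policy = s_policy, k_policy = k_policy,
                 neutrality_policy = neutrality_policy,
                 mismatch_policy = mismatch_policy,
                 mismatch_level = mismatch_level,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "mt_config")
}

#' Run the full phylogeography pipeline
#'
#' For every group (and the pooled total) this computes the molecular
#' diversity summary, the neutrality tests with simulation p-values, the
#' mismatch-distribution expansion fit with bootstrap-dated expansion time,
#' and builds the median-joining network over all haplotypes with
#' indel-containing columns removed. Every number in the report equals the
#' output of the corresponding single-stage function; there are no
#' pipeline-only code paths. With `out_dir` set, the report is also written
#' as `diversity.tsv`, `expansion.tsv`, `network_edges.tsv`,
#' `network.graphml` and `report.json`.
#'
#' @param config An [run_config()] object.
#' @return A list of class `mt_report` with tibbles `diversity` and
#'   `expansion`, the `network`, its `network_stats`, and a `log` of the
#'   settings used.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "mt_config"))
  tbl <- config$table
  groups <- config$groups
  gcol <- config$group_col
  group_names <- unique(groups[[gcol]])

  div_rows <- list(); exp_rows <- list()
  for (g in group_names) {
    locs <- groups$locality[groups[[gcol]] == g]
    locs <- intersect(locs, hap_localities(tbl))
    sub <- tryCatch(expand_table(tbl, localities = locs),
                    error = function(e) {
                      rlang::abort(paste0("Group '", g, "' is empty."),
                                   parent = e)
                    })
    if (nrow(sub) < 2) rlang::abort(paste0("Group '", g, "' has n < 2."))
    dv <- diversity_stats(sub, L = config$L, s_policy = config$s_policy,
                          k_policy = config$k_policy)
    div_rows[[g]] <- dplyr::bind_cols(tibble::tibble(group = g), dv)

    nt <- tryCatch(
      neutrality_test(sub, gap_policy = config$neutrality_policy,
                      n_sims = config$n_sims, seed = config$seed),
      error = function(e) {
        tibble::tibble(D = NA_real_, p_D = NA_real_, Fs = NA_real_,
                       p_Fs = NA_real_)
      })
    exp_row <- tibble::tibble(group = g, D = nt$D, p_D = nt$p_D,
                              Fs = nt$Fs, p_Fs = nt$p_Fs)
    mm_aln <- if (config$mismatch_level == "haplotype") {
      haplotype_alignment(tbl, localities = locs)
    } else sub
    fitres <- tryCatch({
      ci <- tau_bootstrap_ci(mm_aln, B = config$boot_reps,
                             level = config$ci_level, seed = config$seed,
                             gap_policy = config$mismatch_policy)
      hist <- mismatch_histogram(mm_aln, config$mismatch_policy)
      fit <- fit_sudden_expansion(hist)
      et <- expansion_time(fit$tau, mu = config$mu,
                           gen_years = config$gen_years,
                           tau_ci = c(ci$tau_low, ci$tau_high))
      tibble::tibble(raggedness = fit$raggedness, tau = fit$tau,
                     ssd = fit$ssd, t_years = et$t_years,
                     t_low = et$ci_low, t_high = et$ci_high)
    }, error = function(e) {
      tibble::tibble(raggedness = NA_real_, tau = NA_real_, ssd = NA_real_,
                     t_years = NA_integer_, t_low = NA_integer_,
                     t_high = NA_integer_)
    })
    exp_rows[[g]] <- dplyr::bind_cols(exp_row, fitres)
  }
  diversity <- dplyr::bind_rows(div_rows)
  expansion <- dplyr::bind_rows(exp_rows)

  net_tbl <- drop_indel_sites(tbl)
  net <- build_mjn(net_tbl, epsilon = 0)
  stats <- network_stats(net)

  log <- list(
    package_version = as.character(utils::packageVersion("mtexpand")),
    seed = config$seed, L = config$L, mu = config$mu,
    gen_years = config$gen_years, n_sims = config$n_sims,
    boot_reps = config$boot_reps, ci_level = config$ci_level,
    policies = list(S = config$s_policy, k = config$k_policy,
                    neutrality = config$neutrality_policy,
                    mismatch = config$mismatch_policy),
    epsilon = 0, weights = "equal"
  )
  report <- structure(list(diversity = diversity, expansion = expansion,
                           network = net, network_stats = stats, log = log),
                      class = "mt_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(diversity, file.path(config$out_dir, "diversity.tsv"))
    readr::write_tsv(expansion, file.path(config$out_dir, "expansion.tsv"))
    write_network_edges(net, file.path(config$out_dir, "network_edges.tsv"))
    write_network_graphml(net, file.path(config$out_dir, "network.graphml"))
    jsonlite::write_json(
      list(diversity = diversity, expansion = expansion,
           network_stats = stats, log = log),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.mt_report <- function(x, ...) {
  cat("mtexpand pipeline report\n\nMolecular diversity:\n")
  print(x$diversity)
  cat("\nExpansion statistics:\n")
  print(x$expansion)
  cat("\n")
  print(x$network)
  invisible(x)
}
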