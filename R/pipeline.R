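# End-to-end orchestration: consensus scan -> per-cohort statistics ->
# meta-ranking (-> synergy when dose files are given), with
# deterministic seeding and reproducibility headers on every output.

#' Build and validate a pipeline run configuration
#'
#' @param cohort_dirs Named character vector: cohort name -> directory
#'   holding the files written by [write_cohort()].
#' @param utr_fasta Path to the multi-FASTA of 3'-UTRs (record id =
#'   gene id).
#' @param mirna Mature miRNA sequence (literal, 5'->3') or path to a
#'   single-record FASTA.
#' @param out_dir Output directory.
#' @param min_votes,fdr_max,expected_fold_sign,expected_r_sign,min_matched
#'   Filter thresholds; see [prioritize_targets()] and
#'   [cohort_gene_stats()].
#' @param n_perm,exhaustive_limit Permutation-test settings.
#' @param seed Root seed; per-cohort seeds are derived as
#'   `seed + cohort index - 1`.
#' @param dose_single1,dose_single2,dose_combo Optional dose-response
#'   TSV paths for the synergy stage (two single drugs + combination).
#' @return List of class `run_config`.
#' @export
run_config <- function(cohort_dirs, utr_fasta, mirna, out_dir,
                       min_votes = 5L, fdr_max = 0.1,
                       expected_fold_sign = -1, expected_r_sign = -1,
                       min_matched = 5L, n_perm = 10000L,
                       exhaustive_limit = 20000L, seed = 1L,
                       dose_single1 = NULL, dose_single2 = NULL,
                       dose_combo = NULL) {
  if (is.null(names(cohort_dirs)) || any(names(cohort_dirs) == "")) {
    stop("cohort_dirs must be named by cohort", call. = FALSE)
  }
  if (length(cohort_dirs) < 1L) stop("need >= 1 cohort", call. = FALSE)
  for (nm in names(cohort_dirs)) {
    f <- file.path(cohort_dirs[[nm]], paste0(nm, "_mrna.tsv"))
    if (!file.exists(f)) {
      stop("validation error: missing cohort file ", f, call. = FALSE)
    }
  }
  if (!file.exists(utr_fasta)) {
    stop("validation error: missing UTR FASTA ", utr_fasta, call. = FALSE)
  }
  if (file.exists(mirna)) {
    mirna <- as.character(Biostrings::readDNAStringSet(mirna)[[1L]])
  }
  mirna <- .norm_seq(mirna, "miRNA sequence")
  for (f in c(dose_single1, dose_single2, dose_combo)) {
    if (!file.exists(f)) {
      stop("validation error: missing dose-response file ", f,
           call. = FALSE)
    }
  }
  structure(list(cohort_dirs = cohort_dirs, utr_fasta = utr_fasta,
                 mirna = mirna, out_dir = out_dir, min_votes = min_votes,
                 fdr_max = fdr_max,
                 expected_fold_sign = expected_fold_sign,
                 expected_r_sign = expected_r_sign,
                 min_matched = min_matched, n_perm = as.integer(n_perm),
                 exhaustive_limit = as.integer(exhaustive_limit),
                 seed = as.integer(seed), dose_single1 = dose_single1,
                 dose_single2 = dose_single2, dose_combo = dose_combo),
            class = "run_config")
}

#' Run the full target-prioritization pipeline
#'
#' Stages: seed-consensus scan of the UTR FASTA, per-cohort statistics
#' (permutation test, BH FDR, log2 fold, matched-sample Pearson),
#' Fisher/Stouffer meta-ranking, and -- when dose-response files are
#' configured -- median-effect fits and the combination-index curve.
#' All outputs go under `config$out_dir` with a header recording the
#' seed and config hash; two runs with equal configs are byte-identical.
#' On any stage error the partial outputs are removed.
#'
#' @param config A [run_config()] object.
#' @return List with `ranked` (the [prioritize_targets()] table),
#'   `stats` (stacked per-cohort statistics), `consensus`, optional
#'   `synergy`, and `paths` of the written artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  note <- function(p) { written <<- c(written, p); p }
  # out_dir is excluded: it does not affect the analysis, and two runs
  # of the same analysis must produce byte-identical tables
  hash <- .config_hash(unclass(config)[setdiff(names(unclass(config)),
                                               "out_dir")])
  tryCatch({
    message("[1/3] seed-consensus scan: ", config$utr_fasta)
    utrs <- Biostrings::readDNAStringSet(config$utr_fasta)
    consensus <- consensus_table(utrs, config$mirna)
    write_seed_sites(note(file.path(config$out_dir, "seed_sites.tsv")),
                     utrs, config$mirna)

    message("[2/3] per-cohort statistics (", length(config$cohort_dirs),
            " cohorts)")
    stats_list <- lapply(seq_along(config$cohort_dirs), function(i) {
      nm <- names(config$cohort_dirs)[i]
      ch <- read_cohort(config$cohort_dirs[[i]], nm)
      st <- cohort_gene_stats(ch, n_perm = config$n_perm,
                              seed = config$seed + i - 1L,
                              exhaustive_limit = config$exhaustive_limit,
                              min_matched = config$min_matched)
      out <- st
      names(out) <- c("gene_id", "cohort", "p_value_TN", "FDR",
                      "log2fold_TN", "r_pearson", "p_value_pearson",
                      "n_matched")
      p <- note(file.path(config$out_dir, paste0("stats_", nm, ".tsv")))
      con <- file(p, "wt"); on.exit(close(con), add = TRUE)
      writeLines(c(paste0("# seed=", config$seed),
                   paste0("# config_hash=", hash)), con)
      utils::write.table(format(out, digits = 7, trim = TRUE), con,
                         sep = "\t", quote = FALSE, row.names = FALSE)
      st
    })
    stats <- do.call(rbind, stats_list)

    message("[3/3] meta-ranking")
    ranked <- prioritize_targets(stats, consensus,
                                 min_votes = config$min_votes,
                                 fdr_max = config$fdr_max,
                                 expected_fold_sign = config$expected_fold_sign,
                                 expected_r_sign = config$expected_r_sign)
    write_ranked_table(note(file.path(config$out_dir, "ranked_targets.tsv")),
                       ranked, seed = config$seed, config_hash = hash)
    jsonlite::write_json(
      list(seed = config$seed, config_hash = hash,
           n_genes_scanned = nrow(consensus),
           n_genes_ranked = sum(!is.na(ranked$rank)),
           excluded = attr(ranked, "excluded")),
      note(file.path(config$out_dir, "run_report.json")),
      auto_unbox = TRUE, pretty = TRUE)

    synergy <- NULL
    if (!is.null(config$dose_combo)) {
      message("[synergy] median-effect fits and CI curve")
      f1 <- fit_median_effect(read_dose_response(config$dose_single1))
      f2 <- fit_median_effect(read_dose_response(config$dose_single2))
      cic <- ci_curve(f1, f2, read_dose_response(config$dose_combo))
      p <- note(file.path(config$out_dir, "ci_curve.tsv"))
      con2 <- file(p, "wt"); on.exit(close(con2), add = TRUE)
      writeLines(c(paste0("# seed=", config$seed),
                   paste0("# config_hash=", hash)), con2)
      utils::write.table(format(cic, digits = 7, trim = TRUE), con2,
                         sep = "\t", quote = FALSE, row.names = FALSE)
      synergy <- list(fit1 = f1, fit2 = f2, ci = cic)
    }
    list(ranked = ranked, stats = stats, consensus = consensus,
         synergy = synergy, seed = config$seed, config_hash = hash,
         paths = written)
  }, error = function(e) {
    unlink(written)
    stop("pipeline aborted: ", conditionMessage(e), call. = FALSE)
  })
}
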