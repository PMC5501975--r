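# Evidence combination across cohorts (Fisher, Stouffer), filters and
# the ranked target table.

#' Fisher's method for combining p-values
#'
#' `X^2 = -2 * sum(log(p_i))` referred to the upper tail of the
#' chi-square distribution with `2k` degrees of freedom. The result is
#' clipped to the numerical floor (1e-300) rather than reported as 0.
#'
#' @param p_values Numeric vector, k >= 1 values in (0, 1].
#' @return Combined p-value.
#' @examples
#' fisher_combine(c(0.01, 0.02))  # ~1.90e-3
#' @export
fisher_combine <- function(p_values) {
  .check_prob(p_values, open_left = TRUE, open_right = FALSE)
  x2 <- -2 * sum(log(p_values))
  .floor_p(stats::pchisq(x2, df = 2 * length(p_values), lower.tail = FALSE))
}

#' Stouffer's method for combining one-sided p-values
#'
#' `z_i = qnorm(1 - p_i)`; `Z = sum(w_i z_i) / sqrt(sum(w_i^2))`; the
#' combined value is `1 - pnorm(Z)`, floored at the numerical minimum
#' (never reported as 0). Inputs must lie strictly inside (0, 1); callers
#' holding boundary values must pre-floor/ceiling them.
#'
#' @param p_values Numeric vector, k >= 1 one-sided values in (0, 1).
#' @param weights Optional positive weights (default equal).
#' @return Combined one-sided p-value.
#' @examples
#' stouffer_combine(c(0.05, 0.05))  # ~0.0100
#' @export
stouffer_combine <- function(p_values, weights = NULL) {
  if (length(p_values) == 0L) stop("at least one p-value required",
                                   call. = FALSE)
  if (anyNA(p_values) || any(p_values <= 0 | p_values >= 1)) {
    stop("Stouffer inputs must lie strictly in (0, 1); ",
         "pre-floor/ceiling boundary values before combining",
         call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, length(p_values))
  .check_positive(weights, "weights")
  if (length(weights) != length(p_values)) {
    stop("weights must match p_values in length", call. = FALSE)
  }
  z <- stats::qnorm(1 - p_values)
  Z <- sum(weights * z) / sqrt(sum(weights^2))
  .floor_p(stats::pnorm(Z, lower.tail = FALSE))
}

#' Convert a two-sided p-value to a directional one-sided p-value
#'
#' `p/2` when the observed effect sign matches the expected sign,
#' `1 - p/2` otherwise; a zero effect returns 0.5. The result is clipped
#' inside (1e-300, 1 - 1e-16) so it is always a valid Stouffer input.
#'
#' @param p_two_sided Two-sided p-value in (0, 1].
#' @param effect_sign Sign of the observed effect (-1, 0, +1).
#' @param expected_sign Expected direction (-1 or +1).
#' @return One-sided p-value.
#' @export
to_one_sided <- function(p_two_sided, effect_sign, expected_sign) {
  .check_prob(p_two_sided, open_left = TRUE, open_right = FALSE)
  if (!expected_sign %in% c(-1, 1)) {
    stop("expected_sign must be -1 or +1", call. = FALSE)
  }
  if (effect_sign == 0) return(0.5)
  p <- if (sign(effect_sign) == expected_sign) p_two_sided / 2 else
    1 - p_two_sided / 2
  min(max(p, .P_FLOOR), 1 - 1e-16)
}

#' Prioritize and rank candidate miRNA targets across cohorts
#'
#' Applies the three published filters -- predictor consensus
#' (`votes >= min_votes`), common deregulation (in every cohort
#' `fdr <= fdr_max` with the expected fold sign) and anticorrelation
#' (expected correlation sign in every cohort where a correlation is
#' available) -- and combines the one-sided correlation p-values of the
#' cohorts with available correlations by Fisher's and Stouffer's
#' methods. Genes passing all filters receive ranks 1..k ordered by the
#' combined p-value (Fisher by default, Stouffer as tie-break, then gene
#' id); all other genes are retained unranked. A combined
#' tumor-vs-normal p-value (`combined_p_tn_fisher`) is reported as a
#' supplementary column but does not drive the rank.
#'
#' @param stats Data frame stacking [cohort_gene_stats()] rows for every
#'   cohort (columns `gene_id`, `cohort`, `p_tn`, `fdr`, `log2fold`,
#'   `r`, `p_r`, `n_matched`).
#' @param consensus Data frame with `gene_id` and `votes` (see
#'   [consensus_table()]).
#' @param min_votes Consensus vote threshold (default 5 of 6).
#' @param fdr_max FDR ceiling for the deregulation filter.
#' @param expected_fold_sign,expected_r_sign Expected direction of the
#'   tumor/normal fold and of the correlation (-1 for a repressive
#'   oncomiR).
#' @param sort_key `"fisher"` (default) or `"stouffer"` as primary sort.
#' @return Data frame of class `ranked_targets`, one row per gene with
#'   vote and per-cohort statistics columns (named
#'   `<cohort>_p_value_TN`, `<cohort>_FDR`, `<cohort>_log2fold_TN`,
#'   `<cohort>_r_pearson`, `<cohort>_p_value_pearson`), combined
#'   p-values, filter flags and `rank` (NA when unranked). Genes missing
#'   a cohort or lacking any correlation evidence are listed in
#'   `attr(x, "excluded")` with reasons; genes passing every filter but
#'   lacking correlation evidence are flagged `no_correlation` and left
#'   unranked, not dropped.
#' @export
prioritize_targets <- function(stats, consensus, min_votes = 5L,
                               fdr_max = 0.1, expected_fold_sign = -1,
                               expected_r_sign = -1,
                               sort_key = c("fisher", "stouffer")) {
  sort_key <- match.arg(sort_key)
  need <- c("gene_id", "cohort", "p_tn", "fdr", "log2fold", "r", "p_r")
  if (!all(need %in% names(stats))) {
    stop("stats must carry columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  cohorts <- unique(stats$cohort)
  genes <- unique(stats$gene_id)
  if (length(genes) == 0L) {
    out <- data.frame(gene_id = character(), n_softw_pred = integer(),
                      combined_p_fisher = numeric(),
                      combined_p_stouffer = numeric(),
                      combined_p_tn_fisher = numeric(),
                      passes_votes = logical(),
                      passes_deregulation = logical(),
                      passes_anticorrelation = logical(),
                      no_correlation = logical(), rank = integer())
    attr(out, "excluded") <- list()
    class(out) <- c("ranked_targets", class(out))
    return(out)
  }
  # genes must have stats in every cohort
  tab <- table(stats$gene_id)
  incomplete <- names(tab)[tab < length(cohorts)]
  excluded <- lapply(incomplete, function(g) {
    list(gene_id = g, reason = "missing in at least one cohort")
  })
  genes <- setdiff(genes, incomplete)
  vote_map <- structure(consensus$votes, names = consensus$gene_id)

  rows <- lapply(genes, function(g) {
    s <- stats[stats$gene_id == g, , drop = FALSE]
    s <- s[match(cohorts, s$cohort), , drop = FALSE]
    votes <- unname(vote_map[g])
    if (length(votes) != 1L || is.na(votes)) votes <- 0L
    has_cor <- !is.na(s$r)
    passes_votes <- votes >= min_votes
    passes_dereg <- all(s$fdr <= fdr_max) &&
      all(sign(s$log2fold) == expected_fold_sign)
    passes_anti <- any(has_cor) &&
      all(sign(s$r[has_cor]) == expected_r_sign)
    if (any(has_cor)) {
      one_sided <- mapply(to_one_sided, s$p_r[has_cor],
                          sign(s$r[has_cor]),
                          MoreArgs = list(expected_sign = expected_r_sign))
      p_fisher <- fisher_combine(pmin(pmax(one_sided, .P_FLOOR), 1))
      p_stouffer <- stouffer_combine(one_sided)
    } else {
      p_fisher <- NA_real_
      p_stouffer <- NA_real_
    }
    p_tn_fisher <- fisher_combine(s$p_tn)
    per_cohort <- unlist(lapply(seq_along(cohorts), function(i) {
      v <- c(s$p_tn[i], s$fdr[i], s$log2fold[i], s$r[i], s$p_r[i])
      names(v) <- paste0(cohorts[i], c("_p_value_TN", "_FDR",
                                       "_log2fold_TN", "_r_pearson",
                                       "_p_value_pearson"))
      v
    }))
    c(list(gene_id = g, n_softw_pred = as.integer(votes)),
      as.list(per_cohort),
      list(combined_p_fisher = p_fisher, combined_p_stouffer = p_stouffer,
           combined_p_tn_fisher = p_tn_fisher,
           passes_votes = passes_votes,
           passes_deregulation = passes_dereg,
           passes_anticorrelation = passes_anti,
           no_correlation = !any(has_cor)))
  })
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  pass_all <- out$passes_votes & out$passes_deregulation &
    out$passes_anticorrelation
  rankable <- pass_all & !out$no_correlation
  key1 <- if (sort_key == "fisher") out$combined_p_fisher else
    out$combined_p_stouffer
  key2 <- if (sort_key == "fisher") out$combined_p_stouffer else
    out$combined_p_fisher
  ord <- order(!rankable, key1, key2, out$gene_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- NA_integer_
  out$rank[seq_len(sum(rankable))] <- seq_len(sum(rankable))
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  class(out) <- c("ranked_targets", class(out))
  out
}
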