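# Synthetic-data generators: expression cohorts with planted miRNA
# targets and decoys, 3'-UTR/promoter sequences with planted seed
# sites, and median-effect dose-response series (single drugs and
# Loewe-additive combinations). Every generator is a pure function of
# (config, seed).

#' Configuration for one simulated cohort
#'
#' Expression is generated directly on the log2 scale. The query miRNA
#' is Normal(`mirna_baseline` + `mirna_tumor_shift` * is_tumor,
#' `noise_sd`). Planted targets follow
#' `gene_baseline + target_slope * miRNA + noise`, so they are both
#' tumor-downregulated (for an oncomiR shift > 0 and slope < 0) and
#' anticorrelated with the miRNA. Decoy classes exercise the composite
#' filter: `frac_decoy_down` of the non-targets get the same tumor
#' down-shift but no miRNA coupling; `frac_decoy_corr` are coupled to
#' the miRNA's fluctuations but carry no net tumor shift. Remaining
#' background genes are independent noise.
#'
#' @param n_genes Number of genes (positive).
#' @param n_planted_targets Number of true targets (<= `n_genes`).
#' @param n_tumor,n_normal Sample counts per class (>= 2).
#' @param n_matched Number of samples carrying both miRNA and mRNA
#'   assays (<= tumor count for `matched_mode = "tumor"`).
#' @param mirna_tumor_shift Tumor shift of the miRNA, log2 units (> 0
#'   for an oncomiR).
#' @param target_slope Expected log2-mRNA change per unit log2-miRNA
#'   (< 0 for repression).
#' @param noise_sd Gaussian noise s.d., log2 units (> 0).
#' @param frac_decoy_down,frac_decoy_corr Fractions in \[0, 1\] of
#'   non-target genes assigned to the two decoy classes.
#' @param seed RNG seed (integer).
#' @param mirna_baseline,gene_baseline Baseline log2 expression levels.
#' @param matched_mode `"tumor"`: matched samples are a flagged subset
#'   of tumor samples (correlation within tumors); `"pooled"`: drawn
#'   from tumors and normals alternately.
#' @param name Cohort name.
#' @return List of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_genes = 500L, n_planted_targets = 5L,
                              n_tumor = 30L, n_normal = 30L,
                              n_matched = 20L, mirna_tumor_shift = 2,
                              target_slope = -1, noise_sd = 1,
                              frac_decoy_down = 0.05,
                              frac_decoy_corr = 0.05, seed = 1L,
                              mirna_baseline = 5, gene_baseline = 8,
                              matched_mode = c("tumor", "pooled"),
                              name = "cohort") {
  matched_mode <- match.arg(matched_mode)
  if (n_genes < 1L) stop("n_genes must be positive", call. = FALSE)
  if (n_planted_targets < 0L || n_planted_targets > n_genes) {
    stop("invalid config: n_planted_targets must lie in [0, n_genes]",
         call. = FALSE)
  }
  if (n_tumor < 2L || n_normal < 2L) {
    stop("need >= 2 tumor and >= 2 normal samples", call. = FALSE)
  }
  cap <- if (matched_mode == "tumor") n_tumor else 2L * min(n_tumor, n_normal)
  if (n_matched < 0L || n_matched > cap) {
    stop("invalid config: n_matched exceeds available samples",
         call. = FALSE)
  }
  .check_positive(noise_sd, "noise_sd")
  .check_fraction(frac_decoy_down, "frac_decoy_down")
  .check_fraction(frac_decoy_corr, "frac_decoy_corr")
  structure(list(n_genes = as.integer(n_genes),
                 n_planted_targets = as.integer(n_planted_targets),
                 n_tumor = as.integer(n_tumor),
                 n_normal = as.integer(n_normal),
                 n_matched = as.integer(n_matched),
                 mirna_tumor_shift = mirna_tumor_shift,
                 target_slope = target_slope, noise_sd = noise_sd,
                 frac_decoy_down = frac_decoy_down,
                 frac_decoy_corr = frac_decoy_corr,
                 seed = as.integer(seed),
                 mirna_baseline = mirna_baseline,
                 gene_baseline = gene_baseline,
                 matched_mode = matched_mode, name = name),
            class = "cohort_sim_config")
}

# Draw disjoint planted/decoy gene classes from a config's seed.
.draw_truth <- function(cfg, gene_ids) {
  .with_seed(cfg$seed + 1000L, {
    n <- length(gene_ids)
    planted <- sample(gene_ids, cfg$n_planted_targets)
    rest <- setdiff(gene_ids, planted)
    n_down <- round(cfg$frac_decoy_down * length(rest))
    n_corr <- round(cfg$frac_decoy_corr * length(rest))
    decoys <- sample(rest, min(length(rest), n_down + n_corr))
    list(planted_target_ids = sort(planted),
         decoy_down_ids = sort(decoys[seq_len(n_down)]),
         decoy_corr_ids = sort(decoys[n_down + seq_len(n_corr)]))
  })
}

#' Simulate expression cohorts with known ground truth
#'
#' @param configs List of [cohort_sim_config()] objects (>= 1).
#' @param shared_truth When TRUE (default) all cohorts share gene ids
#'   and the same planted/decoy gene classes (drawn from the first
#'   config's seed); all configs must then agree on `n_genes`.
#' @return List with `cohorts` (a list of [cohort()] objects) and
#'   `truth` (class `sim_truth`: `planted_target_ids`,
#'   `decoy_down_ids`, `decoy_corr_ids` -- pairwise disjoint -- plus
#'   per-gene `slope` and `shift`).
#' @export
simulate_cohorts <- function(configs, shared_truth = TRUE) {
  if (inherits(configs, "cohort_sim_config")) configs <- list(configs)
  if (length(configs) < 1L) stop("need >= 1 config", call. = FALSE)
  lapply(configs, function(cfg) {
    if (!inherits(cfg, "cohort_sim_config")) {
      stop("configs must be cohort_sim_config objects", call. = FALSE)
    }
  })
  if (shared_truth &&
      length(unique(vapply(configs, `[[`, integer(1L), "n_genes"))) != 1L) {
    stop("shared_truth requires all configs to agree on n_genes",
         call. = FALSE)
  }
  gene_ids <- sprintf("g%05d", seq_len(configs[[1L]]$n_genes))
  truth0 <- if (shared_truth) .draw_truth(configs[[1L]], gene_ids) else NULL

  cohorts <- lapply(configs, function(cfg) {
    ids <- if (shared_truth) gene_ids else
      sprintf("g%05d", seq_len(cfg$n_genes))
    tr <- if (shared_truth) truth0 else .draw_truth(cfg, ids)
    .with_seed(cfg$seed, {
      samples <- c(sprintf("%s_T%03d", cfg$name, seq_len(cfg$n_tumor)),
                   sprintf("%s_N%03d", cfg$name, seq_len(cfg$n_normal)))
      is_tumor <- rep(c(TRUE, FALSE), c(cfg$n_tumor, cfg$n_normal))
      n <- length(samples)
      mirna <- stats::rnorm(n, cfg$mirna_baseline +
                              cfg$mirna_tumor_shift * is_tumor,
                            cfg$noise_sd)
      names(mirna) <- samples
      X <- matrix(stats::rnorm(length(ids) * n, 0, cfg$noise_sd),
                  nrow = length(ids), ncol = n,
                  dimnames = list(ids, samples))
      X <- X + cfg$gene_baseline
      pl <- ids %in% tr$planted_target_ids
      dd <- ids %in% tr$decoy_down_ids
      dc <- ids %in% tr$decoy_corr_ids
      if (any(pl)) {
        X[pl, ] <- X[pl, , drop = FALSE] +
          matrix(cfg$target_slope * mirna, nrow = sum(pl), ncol = n,
                 byrow = TRUE)
      }
      if (any(dd)) {
        X[dd, ] <- X[dd, , drop = FALSE] +
          matrix(cfg$target_slope * cfg$mirna_tumor_shift * is_tumor,
                 nrow = sum(dd), ncol = n, byrow = TRUE)
      }
      if (any(dc)) {
        detrended <- mirna - cfg$mirna_tumor_shift * is_tumor
        X[dc, ] <- X[dc, , drop = FALSE] +
          matrix(cfg$target_slope * detrended, nrow = sum(dc), ncol = n,
                 byrow = TRUE)
      }
      matched <- if (cfg$matched_mode == "tumor") {
        samples[is_tumor][seq_len(cfg$n_matched)]
      } else {
        # alternate tumor/normal so a pooled matched set spans both classes
        k <- min(cfg$n_tumor, cfg$n_normal)
        pool <- as.vector(rbind(samples[is_tumor][seq_len(k)],
                                samples[!is_tumor][seq_len(k)]))
        pool[seq_len(cfg$n_matched)]
      }
      sample_class <- ifelse(is_tumor, "tumor", "normal")
      names(sample_class) <- samples
      cohort(cfg$name, X, sample_class, mirna = mirna, matched = matched)
    })
  })
  tr <- if (shared_truth) truth0 else .draw_truth(configs[[1L]], gene_ids)
  slope <- structure(rep(0, length(gene_ids)), names = gene_ids)
  slope[tr$planted_target_ids] <- configs[[1L]]$target_slope
  slope[tr$decoy_corr_ids] <- configs[[1L]]$target_slope
  shift <- structure(rep(0, length(gene_ids)), names = gene_ids)
  shift[tr$planted_target_ids] <-
    configs[[1L]]$target_slope * configs[[1L]]$mirna_tumor_shift
  shift[tr$decoy_down_ids] <-
    configs[[1L]]$target_slope * configs[[1L]]$mirna_tumor_shift
  truth <- structure(c(tr, list(slope = slope, shift = shift)),
                     class = "sim_truth")
  list(cohorts = cohorts, truth = truth)
}

#' Simulate 3'-UTR sequences with planted seed sites
#'
#' Background composition follows `gc_fraction`; for genes with a
#' non-empty site plan, sites are planted at random non-overlapping
#' positions and the whole sequence is rejection-sampled until planting
#' created no additional unplanned site of an equal-or-higher
#' stringency type than the least stringent planted type (sites fully
#' contained in a planted interval, such as the 7mers inside an 8mer,
#' are expected and allowed). Genes with an empty plan are plain random
#' sequences.
#'
#' @param gene_ids Character vector of sequence names.
#' @param mirna_sequence Mature miRNA, 5'->3'.
#' @param site_plan Named list mapping gene id -> character vector of
#'   site types to plant (see [mir_site_types()]); genes absent from the
#'   plan get no planted site.
#' @param length UTR length in nt (>= longest planted site + 2).
#' @param gc_fraction Background GC content in \[0, 1\].
#' @param seed RNG seed.
#' @return List with `utrs` (a `Biostrings::DNAStringSet`) and `truth`
#'   (data frame `gene_id`, `site_type`, `start`, `end` of every planted
#'   site).
#' @export
simulate_utrs <- function(gene_ids, mirna_sequence, site_plan = list(),
                          length = 200L, gc_fraction = 0.5, seed = 1L) {
  .check_fraction(gc_fraction, "gc_fraction")
  stopifnot(length(gene_ids) >= 1L)
  bad_types <- setdiff(unlist(site_plan), .SITE_TYPES)
  if (length(bad_types)) {
    stop("unsupported site type(s): ", paste(bad_types, collapse = ", "),
         call. = FALSE)
  }
  pats <- .seed_patterns(mirna_sequence)
  max_len <- if (length(site_plan)) {
    max(.SITE_LEN[unlist(site_plan)])
  } else {
    0L
  }
  if (length < max_len + 2L) {
    stop("invalid config: UTR length must be >= longest site + 2",
         call. = FALSE)
  }
  probs <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
             G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  .with_seed(seed, {
    seqs <- character(length(gene_ids))
    truth <- list()
    for (i in seq_along(gene_ids)) {
      g <- gene_ids[i]
      plan <- site_plan[[g]]
      if (is.null(plan) || length(plan) == 0L) {
        seqs[i] <- paste(sample(names(probs), length, replace = TRUE,
                                prob = probs), collapse = "")
        next
      }
      # forbid unplanned sites at least as stringent as the weakest
      # planted type
      cutoff <- max(match(plan, .SITE_TYPES))
      forbidden <- .SITE_TYPES[seq_len(cutoff)]
      for (attempt in seq_len(1000L)) {
        chars <- sample(names(probs), length, replace = TRUE, prob = probs)
        placed <- data.frame(gene_id = character(), site_type = character(),
                             start = integer(), end = integer(),
                             stringsAsFactors = FALSE)
        ok_place <- TRUE
        for (ty in plan) {
          w <- .SITE_LEN[[ty]]
          avail <- setdiff(seq_len(length - w + 1L),
                           unlist(lapply(seq_len(nrow(placed)), function(k) {
                             (placed$start[k] - w + 1L):placed$end[k]
                           })))
          avail <- avail[avail >= 1L]
          if (!length(avail)) { ok_place <- FALSE; break }
          st <- if (length(avail) == 1L) avail else sample(avail, 1L)
          chars[st:(st + w - 1L)] <- strsplit(pats[[ty]], "")[[1L]]
          placed <- rbind(placed, data.frame(gene_id = g, site_type = ty,
                                             start = st, end = st + w - 1L,
                                             stringsAsFactors = FALSE))
        }
        if (!ok_place) next
        s <- paste(chars, collapse = "")
        found <- find_seed_sites(s, mirna_sequence, site_types = forbidden)
        stray <- !vapply(seq_len(nrow(found)), function(k) {
          any(found$start[k] >= placed$start & found$end[k] <= placed$end)
        }, logical(1L))
        if (!any(stray)) {
          seqs[i] <- s
          truth[[g]] <- placed
          break
        }
      }
      if (seqs[i] == "") {
        stop("could not place sites for gene ", g,
             " without stray matches; increase UTR length", call. = FALSE)
      }
    }
    utrs <- Biostrings::DNAStringSet(seqs)
    names(utrs) <- gene_ids
    truth_df <- if (length(truth)) do.call(rbind, truth) else
      data.frame(gene_id = character(), site_type = character(),
                 start = integer(), end = integer(),
                 stringsAsFactors = FALSE)
    rownames(truth_df) <- NULL
    list(utrs = utrs, truth = truth_df)
  })
}

#' Simulate a median-effect dose-response series
#'
#' `fa(D) = D^m / (D^m + Dm^m)`, with Gaussian noise of s.d. `noise_sd`
#' added on the logit scale and the result clipped to the open interval
#' (0, 1).
#'
#' @param m Sigmoidicity coefficient (> 0).
#' @param Dm Median-effect dose (> 0).
#' @param doses Positive dose vector.
#' @param noise_sd Logit-scale noise s.d. (>= 0).
#' @param seed RNG seed (required when `noise_sd > 0`).
#' @return Data frame with columns `dose`, `fa`.
#' @export
simulate_dose_response <- function(m, Dm, doses, noise_sd = 0, seed = 1L) {
  if (length(m) != 1L || is.na(m) || m <= 0 ||
      length(Dm) != 1L || is.na(Dm) || Dm <= 0) {
    stop("invalid config: m and Dm must be positive", call. = FALSE)
  }
  .check_positive(doses, "doses")
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  lg <- m * log(doses / Dm)  # logit of fa under the median-effect model
  if (noise_sd > 0) {
    lg <- .with_seed(seed, lg + stats::rnorm(length(lg), 0, noise_sd))
  }
  fa <- stats::plogis(lg)
  eps <- 1e-12
  fa <- pmin(pmax(fa, eps), 1 - eps)
  data.frame(dose = doses, fa = fa)
}

#' Simulate a Loewe-additive drug combination
#'
#' For each target fraction affected `fa` in `fa_grid`, component doses
#' `(d1, d2)` with `d2/d1 = ratio` are chosen on the Loewe-additivity
#' line `d1/Dx1(fa) + d2/Dx2(fa) = 1`, so the noiseless combination
#' index is exactly 1 at every point. Observed `fa` is the target plus
#' logit-scale noise.
#'
#' @param fit1_params,fit2_params Lists with elements `m` and `Dm` for
#'   the two single drugs.
#' @param fa_grid Target fractions affected, strictly in (0, 1),
#'   non-empty.
#' @param ratio Dose ratio `d2/d1` (> 0).
#' @param noise_sd Logit-scale noise s.d. (>= 0).
#' @param seed RNG seed.
#' @return Data frame with columns `dose1`, `dose2`, `fa`.
#' @export
simulate_additive_combination <- function(fit1_params, fit2_params, fa_grid,
                                          ratio, noise_sd = 0, seed = 1L) {
  if (length(fa_grid) == 0L) {
    stop("invalid config: fa_grid must be non-empty", call. = FALSE)
  }
  if (anyNA(fa_grid) || any(fa_grid <= 0 | fa_grid >= 1)) {
    stop("fa_grid values must lie strictly in (0, 1)", call. = FALSE)
  }
  .check_positive(ratio, "ratio")
  dx1 <- dose_for_effect(fit1_params, fa_grid)
  dx2 <- dose_for_effect(fit2_params, fa_grid)
  d1 <- 1 / (1 / dx1 + ratio / dx2)
  d2 <- ratio * d1
  lg <- stats::qlogis(fa_grid)
  if (noise_sd > 0) {
    lg <- .with_seed(seed, lg + stats::rnorm(length(lg), 0, noise_sd))
  }
  eps <- 1e-12
  fa <- pmin(pmax(stats::plogis(lg), eps), 1 - eps)
  data.frame(dose1 = d1, dose2 = d2, fa = fa)
}
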