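# Independent brute-force oracles. These deliberately avoid the
# package's code paths: patterns are built character by character from
# a local complement table, windows are tested one by one, and the
# enumeration/step-up definitions are spelled out directly.

MIR21 <- "UAGCUUAUCAGACUGAUGUUGA"

oracle_complement <- c(A = "T", C = "G", G = "C", T = "A", U = "A")

oracle_revcomp <- function(x) {
  chars <- strsplit(toupper(chartr("u", "t", x)), "")[[1L]]
  paste(rev(unname(oracle_complement[chars])), collapse = "")
}

# site-type definitions, independently restated
oracle_site_defs <- function(mirna) {
  m <- toupper(chartr("Uu", "TT", mirna))
  sub2_8 <- substr(m, 2, 8); sub2_7 <- substr(m, 2, 7); sub3_8 <- substr(m, 3, 8)
  list(
    "8mer"        = paste0(oracle_revcomp(sub2_8), "A"),
    "7mer-m8"     = oracle_revcomp(sub2_8),
    "7mer-A1"     = paste0(oracle_revcomp(sub2_7), "A"),
    "6mer"        = oracle_revcomp(sub2_7),
    "offset-6mer" = oracle_revcomp(sub3_8),
    "6mer-A1"     = paste0(oracle_revcomp(sub2_7), "A")
  )
}

# every window of every site type, tested one window at a time
oracle_find_sites <- function(utr, mirna) {
  utr <- toupper(chartr("Uu", "TT", utr))
  defs <- oracle_site_defs(mirna)
  rows <- list()
  for (ty in names(defs)) {
    pat <- defs[[ty]]
    w <- nchar(pat)
    if (w > nchar(utr)) next
    for (st in seq_len(nchar(utr) - w + 1L)) {
      if (substr(utr, st, st + w - 1L) == pat) {
        rows[[length(rows) + 1L]] <- data.frame(site_type = ty, start = st,
                                                end = st + w - 1L)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(site_type = character(), start = integer(),
                      end = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$site_type), , drop = FALSE]
}

# exhaustive two-sided permutation p by direct enumeration of label
# assignments (difference of means statistic)
oracle_perm_p <- function(tumor, normal) {
  pool <- c(tumor, normal)
  n1 <- length(tumor)
  obs <- mean(tumor) - mean(normal)
  combos <- combn(length(pool), n1)
  diffs <- apply(combos, 2L, function(ix) {
    mean(pool[ix]) - mean(pool[-ix])
  })
  mean(abs(diffs) >= abs(obs) - 1e-12)
}

# BH step-up from its definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  sorted <- p[o]
  for (i in seq_len(n)) {
    q[i] <- min(1, min(sorted[i:n] * n / (i:n)))
  }
  out <- numeric(n)
  out[o] <- q
  out
}

# per-window log2-odds PWM scoring, one window and one position at a time
oracle_pwm_scan <- function(sequence, atg, M, bg, thr) {
  seq_chars <- strsplit(toupper(sequence), "")[[1L]]
  w <- ncol(M)
  L <- log2(M / bg)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  hits <- list()
  upstream_len <- atg - 1L
  if (upstream_len < w) {
    return(data.frame(upstream_edge = integer(), downstream_edge = integer(),
                      strand = character(), score = numeric()))
  }
  for (st in seq_len(upstream_len - w + 1L)) {
    win <- seq_chars[st:(st + w - 1L)]
    if (any(!win %in% names(comp))) next
    sc_p <- 0; sc_m <- 0
    rc <- rev(unname(comp[win]))
    for (j in seq_len(w)) {
      sc_p <- sc_p + L[win[j], j]
      sc_m <- sc_m + L[rc[j], j]
    }
    if (sc_p >= thr - 1e-12) {
      hits[[length(hits) + 1L]] <- data.frame(
        upstream_edge = st - atg, downstream_edge = st + w - 1L - atg,
        strand = "+", score = sc_p)
    }
    if (sc_m >= thr - 1e-12) {
      hits[[length(hits) + 1L]] <- data.frame(
        upstream_edge = st - atg, downstream_edge = st + w - 1L - atg,
        strand = "-", score = sc_m)
    }
  }
  if (!length(hits)) {
    return(data.frame(upstream_edge = integer(), downstream_edge = integer(),
                      strand = character(), score = numeric()))
  }
  out <- do.call(rbind, hits)
  out[order(out$upstream_edge, out$strand), , drop = FALSE]
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# area under the ROC curve for scores where smaller = more target-like
auroc_from_scores <- function(score, is_positive) {
  r <- rank(score, ties.method = "average")
  n_pos <- sum(is_positive)
  n_neg <- sum(!is_positive)
  # probability a positive scores lower than a negative
  (sum(r[!is_positive]) - n_neg * (n_neg + 1) / 2) / (n_pos * n_neg)
}

# the spec'd three-cohort synthetic study conditions
study_configs <- function(seed) {
  lapply(1:3, function(i) {
    cohort_sim_config(n_genes = 500L, n_planted_targets = 5L,
                      n_tumor = 30L, n_normal = 30L, n_matched = 20L,
                      mirna_tumor_shift = 2, target_slope = -1,
                      noise_sd = 1, seed = seed + i - 1L,
                      name = paste0("cohort", i))
  })
}
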