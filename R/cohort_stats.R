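# Per-cohort statistics: permutation tumor-vs-normal test, BH FDR,
# log2 fold change, and miRNA-mRNA Pearson anticorrelation on matched
# samples.

#' Construct a cohort object
#'
#' A cohort bundles the query-miRNA expression vector, the gene x sample
#' log2 mRNA matrix, tumor/normal sample labels and the matched-sample
#' subset (samples carrying both assays) on which miRNA-mRNA
#' correlations are computed.
#'
#' @param name Cohort name.
#' @param mrna Numeric matrix, genes x samples, log2 expression; row
#'   names are gene ids, column names sample ids.
#' @param sample_class Named character vector over the mRNA samples with
#'   values `"tumor"` or `"normal"`.
#' @param mirna Named numeric vector of log2 miRNA expression (may be
#'   `NULL` for cohorts without a miRNA assay).
#' @param matched Character vector of sample ids carrying both assays
#'   (subset of both `names(mirna)` and `colnames(mrna)`).
#' @return List of class `cohort`.
#' @export
cohort <- function(name, mrna, sample_class, mirna = NULL,
                   matched = character()) {
  if (!is.matrix(mrna) || !is.numeric(mrna)) {
    stop("mrna must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(mrna)) || is.null(colnames(mrna))) {
    stop("mrna must carry gene ids (rownames) and sample ids (colnames)",
         call. = FALSE)
  }
  sample_class <- sample_class[colnames(mrna)]
  if (anyNA(sample_class) || !all(sample_class %in% c("tumor", "normal"))) {
    stop("every mRNA sample needs a class in {tumor, normal}", call. = FALSE)
  }
  if (sum(sample_class == "tumor") < 2L || sum(sample_class == "normal") < 2L) {
    stop("cohort '", name, "' needs >= 2 tumor and >= 2 normal samples",
         call. = FALSE)
  }
  matched <- as.character(matched)
  if (length(matched)) {
    if (is.null(mirna)) {
      stop("matched samples declared but no miRNA vector given", call. = FALSE)
    }
    missing_m <- setdiff(matched, intersect(names(mirna), colnames(mrna)))
    if (length(missing_m)) {
      stop("matched sample(s) absent from an assay: ",
           paste(missing_m, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(name = name, mrna = mrna, mirna = mirna,
                 sample_class = sample_class, matched = matched),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort '%s'> %d genes, %d tumor / %d normal samples, %d matched\n",
              x$name, nrow(x$mrna), sum(x$sample_class == "tumor"),
              sum(x$sample_class == "normal"), length(x$matched)))
  invisible(x)
}

# Permutation assignment generator shared by the single-gene test and
# the genewise cohort path, so both give identical p-values for equal
# seeds. Returns the tumor-column index matrix (n1 x K) and whether the
# enumeration is exhaustive.
.perm_assignments <- function(n, n1, n_perm, exhaustive_limit, seed) {
  k_total <- choose(n, n1)
  if (k_total <= exhaustive_limit) {
    list(idx = utils::combn(n, n1), exhaustive = TRUE)
  } else {
    idx <- .with_seed(seed, {
      vapply(seq_len(n_perm), function(i) sample.int(n, n1), integer(n1))
    })
    list(idx = matrix(idx, nrow = n1), exhaustive = FALSE)
  }
}

# Difference-of-means permutation test for a gene matrix: X is genes x
# samples, columns ordered tumor first. In the Monte-Carlo branch,
# assignments are drawn independently per block of `block_size` genes
# (seed advanced per block) so cross-gene dependence through a shared
# resample set stays negligible; the exhaustive branch enumerates the
# full assignment space once, which is deterministic and shared safely.
.perm_de_matrix <- function(X, n1, n2, n_perm, seed, exhaustive_limit,
                            block_size = 100L) {
  n <- n1 + n2
  obs <- rowMeans(X[, seq_len(n1), drop = FALSE]) -
    rowMeans(X[, n1 + seq_len(n2), drop = FALSE])
  exhaustive <- choose(n, n1) <= exhaustive_limit
  blocks <- if (exhaustive) list(seq_len(nrow(X))) else
    split(seq_len(nrow(X)), (seq_len(nrow(X)) - 1L) %/% block_size)
  p <- numeric(nrow(X))
  K <- NA_integer_
  for (bi in seq_along(blocks)) {
    rows <- blocks[[bi]]
    asg <- .perm_assignments(n, n1, n_perm, exhaustive_limit,
                             seed + bi - 1L)
    K <- ncol(asg$idx)
    W <- matrix(-1 / n2, nrow = n, ncol = K)
    W[as.vector(asg$idx) + rep((seq_len(K) - 1L) * n, each = n1)] <- 1 / n1
    perm <- X[rows, , drop = FALSE] %*% W
    b <- rowSums(abs(perm) >= abs(obs[rows]) - 1e-12)
    p[rows] <- if (asg$exhaustive) b / K else (b + 1) / (K + 1)
  }
  list(p = p, log2fold = as.vector(obs), exhaustive = exhaustive,
       n_assignments = K)
}

#' Permutation test for a tumor-vs-normal difference
#'
#' Two-sided permutation test with statistic `mean(tumor) - mean(normal)`.
#' When the number of distinct label assignments `choose(n, n_tumor)` is
#' at most `exhaustive_limit`, all assignments are enumerated and the
#' p-value is the exact tail fraction; otherwise `n_perm` seeded
#' resamples are drawn and the add-one estimate `p = (b + 1) / (B + 1)`
#' is used, so p is never 0. Constant pooled data yields p = 1.
#'
#' @param tumor_values,normal_values Numeric vectors, >= 2 finite values
#'   each.
#' @param n_perm Monte-Carlo resamples when enumeration is infeasible.
#' @param seed RNG seed for the resampling branch.
#' @param exhaustive_limit Enumerate exhaustively when the assignment
#'   count does not exceed this.
#' @return List with `p_tn`, `log2fold`, `exhaustive`, `n_assignments`.
#' @examples
#' permutation_de_test(c(3, 4), c(1, 2))  # exact p = 1/3
#' @export
permutation_de_test <- function(tumor_values, normal_values, n_perm = 10000L,
                                seed = 1L, exhaustive_limit = 20000L) {
  if (length(tumor_values) < 2L || length(normal_values) < 2L) {
    stop("insufficient data: need >= 2 values per group", call. = FALSE)
  }
  if (!all(is.finite(c(tumor_values, normal_values)))) {
    stop("group values must be finite", call. = FALSE)
  }
  X <- matrix(c(tumor_values, normal_values), nrow = 1L)
  res <- .perm_de_matrix(X, length(tumor_values), length(normal_values),
                         n_perm, seed, exhaustive_limit)
  list(p_tn = res$p, log2fold = res$log2fold, exhaustive = res$exhaustive,
       n_assignments = res$n_assignments)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment `q(i) = min_{j >= i} min(1, p(j) * n / j)` over the
#' sorted p-values, mapped back to input order (delegates to
#' [stats::p.adjust()] after validating the input range).
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted values in input order.
#' @export
bh_fdr <- function(p_values) {
  .check_prob(p_values, open_left = TRUE, open_right = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Pearson anticorrelation between miRNA and mRNA across matched samples
#'
#' Two-sided p-value from the t transform
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` with `n - 2` degrees of
#' freedom. With fewer than `min_matched` complete pairs the result is
#' absent (`NA` fields); a perfect correlation reports the numerical
#' p-value floor rather than 0.
#'
#' @param mirna_values,mrna_values Paired numeric vectors.
#' @param min_matched Minimum complete pairs for a defined result.
#' @return List with `r`, `p_r`, `n_matched`.
#' @export
mirna_mrna_correlation <- function(mirna_values, mrna_values,
                                   min_matched = 5L) {
  if (length(mirna_values) != length(mrna_values)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  ok <- is.finite(mirna_values) & is.finite(mrna_values)
  x <- mirna_values[ok]
  y <- mrna_values[ok]
  n <- length(x)
  if (n < min_matched) {
    return(list(r = NA_real_, p_r = NA_real_, n_matched = n))
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("undefined correlation: zero variance in a paired vector",
         call. = FALSE)
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1 - 1e-15) {
    p <- .P_FLOOR
  } else {
    tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- .floor_p(2 * stats::pt(-abs(tval), df = n - 2))
  }
  list(r = r, p_r = p, n_matched = n)
}

#' Per-gene statistics for one cohort
#'
#' Runs the permutation tumor-vs-normal test for every requested gene
#' (exhaustive enumeration is shared by all genes; Monte-Carlo
#' assignments are drawn independently per block of 100 genes so
#' genewise p-values carry no common resampling error), adjusts
#' the p-values with [bh_fdr()] across the requested set, and computes
#' the miRNA-mRNA Pearson correlation on the matched-sample subset.
#' Correlation fields are absent when fewer than `min_matched` matched
#' samples exist. Genes with missing values are dropped with a warning.
#'
#' @param cohort A [cohort()] object.
#' @param gene_ids Genes to analyse (default: all rows).
#' @param n_perm,seed,exhaustive_limit Passed to the permutation test.
#' @param min_matched Minimum matched samples for a correlation.
#' @return Data frame with one row per gene: `gene_id`, `cohort`,
#'   `p_tn`, `fdr`, `log2fold`, `r`, `p_r`, `n_matched`.
#' @export
cohort_gene_stats <- function(cohort, gene_ids = rownames(cohort$mrna),
                              n_perm = 10000L, seed = 1L,
                              exhaustive_limit = 20000L, min_matched = 5L) {
  stopifnot(inherits(cohort, "cohort"))
  absent <- setdiff(gene_ids, rownames(cohort$mrna))
  if (length(absent)) {
    stop("cohort '", cohort$name, "': gene(s) not in matrix: ",
         paste(utils::head(absent, 5L), collapse = ", "), call. = FALSE)
  }
  X <- cohort$mrna[gene_ids, , drop = FALSE]
  bad <- rownames(X)[!apply(is.finite(X), 1L, all)]
  if (length(bad)) {
    warning("cohort '", cohort$name, "': dropping ", length(bad),
            " gene(s) with missing values", call. = FALSE)
    X <- X[setdiff(rownames(X), bad), , drop = FALSE]
  }
  tum <- names(cohort$sample_class)[cohort$sample_class == "tumor"]
  nor <- names(cohort$sample_class)[cohort$sample_class == "normal"]
  Xo <- X[, c(tum, nor), drop = FALSE]
  de <- .perm_de_matrix(Xo, length(tum), length(nor), n_perm, seed,
                        exhaustive_limit)
  fdr <- bh_fdr(de$p)

  r <- rep(NA_real_, nrow(X))
  p_r <- rep(NA_real_, nrow(X))
  m_ids <- cohort$matched
  nm <- length(m_ids)
  if (nm >= min_matched) {
    y <- cohort$mirna[m_ids]
    Xm <- X[, m_ids, drop = FALSE]
    sds <- apply(Xm, 1L, stats::sd)
    if (stats::var(y) == 0) {
      warning("cohort '", cohort$name,
              "': miRNA constant on matched samples; correlations undefined",
              call. = FALSE)
    } else {
      usable <- sds > 0
      if (any(!usable)) {
        warning("cohort '", cohort$name, "': ", sum(!usable),
                " gene(s) constant on matched samples; correlation left absent",
                call. = FALSE)
      }
      if (any(usable)) {
        rr <- as.vector(stats::cor(t(Xm[usable, , drop = FALSE]), y))
        tval <- rr * sqrt(nm - 2) / sqrt(pmax(1 - rr^2, 1e-300))
        pp <- .floor_p(2 * stats::pt(-abs(tval), df = nm - 2))
        pp[abs(rr) >= 1 - 1e-15] <- .P_FLOOR
        r[usable] <- rr
        p_r[usable] <- pp
      }
    }
  }
  data.frame(gene_id = rownames(X), cohort = cohort$name, p_tn = de$p,
             fdr = fdr, log2fold = de$log2fold, r = r, p_r = p_r,
             n_matched = nm, stringsAsFactors = FALSE)
}
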