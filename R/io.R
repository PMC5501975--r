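# TSV/FASTA/JSON dialects shared by the generators and the pipeline.
# Expression tables: tab-separated, first column gene_id, header row of
# sample ids, UTF-8, decimal point; scientific notation accepted on
# read. Lines starting with '#' are header comments.

#' Read a gene x sample expression table
#'
#' @param path TSV path: first column gene ids, header row sample ids.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#")
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty input file: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(parts)
  if (any(widths != widths[1L])) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf("ragged row in %s at line %d (%d fields, expected %d)",
                 path, line_no[bad], widths[bad], widths[1L]),
         call. = FALSE)
  }
  header <- parts[[1L]]
  samples <- header[-1L]
  if (length(samples) == 0L) stop("no sample columns in ", path,
                                  call. = FALSE)
  dup_s <- duplicated(samples)
  if (any(dup_s)) {
    stop(sprintf("duplicate sample id '%s' in %s header",
                 samples[which(dup_s)[1L]], path), call. = FALSE)
  }
  if (length(parts) == 1L) stop("no data rows in ", path, call. = FALSE)
  body <- parts[-1L]
  genes <- vapply(body, `[[`, character(1L), 1L)
  dup_g <- duplicated(genes)
  if (any(dup_g)) {
    stop(sprintf("duplicate gene id '%s' in %s at line %d",
                 genes[which(dup_g)[1L]], path,
                 line_no[-1L][which(dup_g)[1L]]), call. = FALSE)
  }
  vals <- suppressWarnings(
    vapply(body, function(p) as.numeric(p[-1L]), numeric(length(samples)))
  )
  M <- matrix(vals, nrow = length(genes), ncol = length(samples),
              byrow = TRUE, dimnames = list(genes, samples))
  if (anyNA(M) ) {
    bad_row <- which(apply(is.na(M), 1L, any))[1L]
    stop(sprintf("non-numeric value in %s at line %d", path,
                 line_no[-1L][bad_row]), call. = FALSE)
  }
  M
}

#' Write a gene x sample expression table
#'
#' @param path Output TSV path.
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param comments Optional character vector written as leading
#'   `#`-prefixed header lines.
#' @return Invisibly, `path`.
#' @export
write_expression_table <- function(path, mat, comments = NULL) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  writeLines(paste(c("gene_id", colnames(mat)), collapse = "\t"), con)
  body <- apply(mat, 1L, function(v) {
    paste(formatC(v, digits = 6, format = "g"), collapse = "\t")
  })
  writeLines(paste(rownames(mat), body, sep = "\t"), con)
  invisible(path)
}

#' Read a sample-class table
#'
#' TSV with columns `sample_id`, `class` (tumor/normal) and optionally
#' `matched` (0/1).
#'
#' @param path TSV path.
#' @return Data frame with `sample_id`, `class`, `matched` (logical).
#' @export
read_sample_classes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "class") %in% names(df))) {
    stop("sample-class file needs columns sample_id and class",
         call. = FALSE)
  }
  if (!all(df$class %in% c("tumor", "normal"))) {
    stop("sample class values must be 'tumor' or 'normal'", call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample id in ", path, call. = FALSE)
  }
  df$matched <- if ("matched" %in% names(df)) df$matched == 1 else FALSE
  df[, c("sample_id", "class", "matched")]
}

#' Write a cohort to disk
#'
#' Emits `<name>_mrna.tsv` (genes x samples), `<name>_mirna.tsv`
#' (single-row table for the query miRNA, when present) and
#' `<name>_samples.tsv` (`sample_id`, `class`, `matched`).
#'
#' @param cohort A [cohort()] object.
#' @param dir Output directory (created if needed).
#' @param comments Optional header comments for the expression tables.
#' @return Invisibly, a named list of the written paths.
#' @export
write_cohort <- function(cohort, dir, comments = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(dir, cohort$name)
  paths <- list(mrna = paste0(base, "_mrna.tsv"),
                samples = paste0(base, "_samples.tsv"))
  write_expression_table(paths$mrna, cohort$mrna, comments)
  if (!is.null(cohort$mirna)) {
    paths$mirna <- paste0(base, "_mirna.tsv")
    m <- matrix(cohort$mirna, nrow = 1L,
                dimnames = list("miRNA", names(cohort$mirna)))
    write_expression_table(paths$mirna, m, comments)
  }
  df <- data.frame(sample_id = names(cohort$sample_class),
                   class = unname(cohort$sample_class),
                   matched = as.integer(names(cohort$sample_class) %in%
                                          cohort$matched))
  utils::write.table(df, paths$samples, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read a cohort from the files written by [write_cohort()]
#'
#' @param dir Directory holding the cohort files.
#' @param name Cohort name (file prefix).
#' @return A [cohort()] object.
#' @export
read_cohort <- function(dir, name) {
  base <- file.path(dir, name)
  mrna <- read_expression_table(paste0(base, "_mrna.tsv"))
  cls <- read_sample_classes(paste0(base, "_samples.tsv"))
  sample_class <- structure(cls$class, names = cls$sample_id)
  mirna_path <- paste0(base, "_mirna.tsv")
  mirna <- NULL
  if (file.exists(mirna_path)) {
    m <- read_expression_table(mirna_path)
    mirna <- m[1L, ]
  }
  cohort(name, mrna, sample_class, mirna = mirna,
         matched = cls$sample_id[cls$matched])
}

#' Read a dose-response TSV
#'
#' Single drug: columns `dose`, `fa`. Combination: `dose1`, `dose2`,
#' `fa`.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_dose_response <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  ok_single <- all(c("dose", "fa") %in% names(df))
  ok_combo <- all(c("dose1", "dose2", "fa") %in% names(df))
  if (!ok_single && !ok_combo) {
    stop("dose-response file needs columns (dose, fa) or (dose1, dose2, fa)",
         call. = FALSE)
  }
  df
}

# Key numeric columns written with a round-tripping decimal repr.
.RANKED_KEY_COLS <- c("combined_p_fisher", "combined_p_stouffer",
                      "combined_p_tn_fisher")

#' Write the ranked target table
#'
#' TSV mirroring the published table's header (`gene_id`,
#' `n_softw_pred`, per-cohort `p_value_TN` / `FDR` / `log2fold_TN` /
#' `r_pearson` / `p_value_pearson`, `combined_p_fisher`,
#' `combined_p_stouffer`) plus filter flags and `rank`. The combined
#' p-value columns use a full-precision decimal representation so
#' `read_ranked_table(write_ranked_table(x))` round-trips exactly; other
#' numeric columns carry 6 significant digits. Leading `#` comments
#' record the seed and config hash.
#'
#' @param path Output TSV path.
#' @param ranked A [prioritize_targets()] result.
#' @param seed Seed recorded in the header.
#' @param config_hash Configuration fingerprint recorded in the header.
#' @return Invisibly, `path`.
#' @export
write_ranked_table <- function(path, ranked, seed = NA, config_hash = "") {
  df <- as.data.frame(ranked)
  for (cl in names(df)) {
    if (cl %in% .RANKED_KEY_COLS) {
      df[[cl]] <- sprintf("%.17g", df[[cl]])
    } else if (is.numeric(df[[cl]]) && !is.integer(df[[cl]])) {
      df[[cl]] <- formatC(df[[cl]], digits = 6, format = "g")
    }
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(paste0("# seed=", seed),
               paste0("# config_hash=", config_hash)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ranked target table written by [write_ranked_table()]
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_ranked_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
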