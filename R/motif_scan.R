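# Log-odds PWM scanning of promoter sequences with ATG-relative
# coordinates (negative positions upstream of the translational start).

.BASES <- c("A", "C", "G", "T")

.IUPAC <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))

#' Build a position weight matrix
#'
#' @param matrix 4 x L numeric matrix of per-position base
#'   probabilities, rows named A, C, G, T; each column must sum to 1.
#' @param name Motif name.
#' @param background Background base distribution (default uniform).
#' @return Object of class `pwm`.
#' @export
pwm <- function(matrix, name = "motif",
                background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (!is.matrix(matrix) || nrow(matrix) != 4L) {
    stop("matrix must be 4 x L with rows A, C, G, T", call. = FALSE)
  }
  if (is.null(rownames(matrix))) rownames(matrix) <- .BASES
  matrix <- matrix[.BASES, , drop = FALSE]
  if (ncol(matrix) < 4L) stop("motif length must be >= 4", call. = FALSE)
  if (any(abs(colSums(matrix) - 1) > 1e-9)) {
    stop("each PWM position must sum to 1", call. = FALSE)
  }
  background <- background[.BASES]
  if (anyNA(background) || abs(sum(background) - 1) > 1e-9) {
    stop("background must be a distribution over A, C, G, T",
         call. = FALSE)
  }
  structure(list(name = name, matrix = matrix, background = background),
            class = "pwm")
}

#' Expand a consensus string (IUPAC codes allowed) into a PWM
#'
#' Each position assigns probability `strong` split over the bases the
#' IUPAC code allows and `1 - strong` split over the remaining bases.
#' The default E2F-like consensus is `TTTSSCGC`.
#'
#' @param consensus Consensus string (IUPAC nucleotide codes).
#' @param name Motif name.
#' @param strong Total probability on the consensus base(s) at each
#'   position (default 0.95).
#' @param background Background base distribution.
#' @return A [pwm()] object.
#' @export
pwm_from_consensus <- function(consensus = "TTTSSCGC", name = consensus,
                               strong = 0.95,
                               background = c(A = 0.25, C = 0.25,
                                              G = 0.25, T = 0.25)) {
  chars <- strsplit(toupper(consensus), "", fixed = TRUE)[[1L]]
  bad <- setdiff(chars, names(.IUPAC))
  if (length(bad)) stop("invalid IUPAC code(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  M <- vapply(chars, function(ch) {
    allowed <- .IUPAC[[ch]]
    p <- rep((1 - strong) / (4L - length(allowed)), 4L)
    names(p) <- .BASES
    if (length(allowed) == 4L) p[] <- 0.25 else p[allowed] <-
        strong / length(allowed)
    p
  }, numeric(4L))
  pwm(M, name = name, background = background)
}

#' Read a JASPAR-style plain-text PWM
#'
#' Accepts the JASPAR matrix format: a `>name` header followed by four
#' lines `A [ 1 2 ... ]` (brackets optional). Counts are converted to
#' probabilities with an additive pseudocount.
#'
#' @param path Path to the matrix file.
#' @param pseudocount Added to every count before normalization.
#' @param background Background base distribution.
#' @return A [pwm()] object.
#' @export
read_pwm_jaspar <- function(path, pseudocount = 0.5,
                            background = c(A = 0.25, C = 0.25, G = 0.25,
                                           T = 0.25)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  name <- "motif"
  if (startsWith(lines[1L], ">")) {
    name <- trimws(sub("^>", "", lines[1L]))
    lines <- lines[-1L]
  }
  if (length(lines) < 4L) stop("malformed JASPAR matrix: need 4 base rows",
                               call. = FALSE)
  counts <- lapply(lines[1:4], function(l) {
    l <- gsub("[][]", " ", l)
    toks <- strsplit(trimws(l), "\\s+")[[1L]]
    list(base = toupper(toks[1L]), counts = as.numeric(toks[-1L]))
  })
  bases <- vapply(counts, `[[`, character(1L), "base")
  if (!setequal(bases, .BASES)) {
    stop("malformed JASPAR matrix: rows must be A, C, G, T", call. = FALSE)
  }
  C <- do.call(rbind, lapply(counts, `[[`, "counts"))
  rownames(C) <- bases
  C <- C[.BASES, , drop = FALSE] + pseudocount
  pwm(sweep(C, 2L, colSums(C), "/"), name = name, background = background)
}

# Log2-odds window scores over one strand; NA where a window spans an N.
.pwm_window_scores <- function(codes, L, w) {
  n_win <- length(codes) - w + 1L
  if (n_win < 1L) return(numeric())
  sc <- numeric(n_win)
  for (j in seq_len(w)) {
    sc <- sc + L[cbind(codes[seq_len(n_win) + j - 1L], j)]
  }
  sc
}

#' Scan a promoter sequence with a PWM
#'
#' Scores every window on both strands against the log2-odds matrix
#' `log2(p / background)` and reports windows at or above the threshold
#' that lie entirely upstream (5') of the ATG, in ATG-relative
#' coordinates: the base immediately 5' of the A of ATG is position -1.
#' Windows containing `N` are skipped. Hits are sorted most-upstream
#' first.
#'
#' @param sequence Promoter sequence over A/C/G/T/N (case-insensitive).
#' @param atg_position 1-based index of the A of the ATG start codon.
#' @param pwm A [pwm()] object.
#' @param threshold Score threshold: log2-odds units
#'   (`threshold_type = "logodds"`) or fraction of the maximum
#'   attainable score in \[0, 1\] (`threshold_type = "fraction"`, the
#'   default).
#' @param threshold_type `"fraction"` or `"logodds"`.
#' @param both_strands Scan the minus strand too (default TRUE).
#' @return Data frame with columns `upstream_edge`, `downstream_edge`
#'   (negative, ATG-relative, closed interval), `strand`, `score`.
#' @export
scan_pwm <- function(sequence, atg_position, pwm, threshold = 0.8,
                     threshold_type = c("fraction", "logodds"),
                     both_strands = TRUE) {
  threshold_type <- match.arg(threshold_type)
  stopifnot(inherits(pwm, "pwm"))
  s <- .norm_seq(sequence, "promoter sequence", allow_n = TRUE)
  n <- nchar(s)
  if (length(atg_position) != 1L || is.na(atg_position) ||
      atg_position < 1L || atg_position > n) {
    stop("atg_position out of range [1, ", n, "]", call. = FALSE)
  }
  upstream <- substr(s, 1L, atg_position - 1L)
  w <- ncol(pwm$matrix)
  if (nchar(upstream) < w) {
    return(data.frame(upstream_edge = integer(), downstream_edge = integer(),
                      strand = character(), score = numeric()))
  }
  L <- log2(pwm$matrix / pwm$background)
  chars <- strsplit(upstream, "", fixed = TRUE)[[1L]]
  codes <- match(chars, .BASES)  # N -> NA, poisons any window it touches
  plus <- .pwm_window_scores(codes, L, w)
  max_score <- sum(apply(L, 2L, max))
  thr <- if (threshold_type == "fraction") {
    .check_fraction(threshold, "threshold")
    threshold * max_score
  } else {
    threshold
  }
  hit_p <- which(!is.na(plus) & plus >= thr - 1e-12)
  res <- data.frame(start = hit_p, strand = rep("+", length(hit_p)),
                    score = plus[hit_p], stringsAsFactors = FALSE)
  if (both_strands) {
    # minus strand: score the reverse complement of each window, i.e.
    # the reverse-complemented log-odds matrix on the plus sequence
    Lrc <- L[4:1, w:1, drop = FALSE]
    rownames(Lrc) <- .BASES
    minus <- .pwm_window_scores(codes, Lrc, w)
    hit <- which(!is.na(minus) & minus >= thr - 1e-12)
    if (length(hit)) {
      res <- rbind(res, data.frame(start = hit, strand = "-",
                                   score = minus[hit],
                                   stringsAsFactors = FALSE))
    }
  }
  out <- data.frame(upstream_edge = res$start - atg_position,
                    downstream_edge = res$start + w - 1L - atg_position,
                    strand = res$strand, score = res$score,
                    stringsAsFactors = FALSE)
  out <- out[order(out$upstream_edge, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a promoter FASTA and write hits as TSV
#'
#' @param fasta_path Promoter FASTA; the ATG position of each record is
#'   given in `atg_positions` (named by record id).
#' @param atg_positions Named integer vector of 1-based ATG positions.
#' @param pwm A [pwm()] object.
#' @param out_path Optional TSV output path.
#' @inheritParams scan_pwm
#' @return Data frame of hits with a leading `seq_id` column.
#' @export
scan_promoters <- function(fasta_path, atg_positions, pwm, threshold = 0.8,
                           threshold_type = c("fraction", "logodds"),
                           out_path = NULL) {
  threshold_type <- match.arg(threshold_type)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- names(seqs)
  missing_atg <- setdiff(ids, names(atg_positions))
  if (length(missing_atg)) {
    stop("no ATG position for record(s): ",
         paste(missing_atg, collapse = ", "), call. = FALSE)
  }
  hits <- lapply(ids, function(id) {
    h <- scan_pwm(as.character(seqs[[id]]), atg_positions[[id]], pwm,
                  threshold = threshold, threshold_type = threshold_type)
    if (nrow(h)) cbind(seq_id = id, h) else NULL
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(seq_id = character(), upstream_edge = integer(),
                      downstream_edge = integer(), strand = character(),
                      score = numeric())
  }
  if (!is.null(out_path)) {
    utils::write.table(out, out_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}
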