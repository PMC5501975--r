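# Canonical miRNA seed-match site detection in 3'-UTRs, and the
# six-mode stringency consensus that stands in for a panel of target
# prediction programs.

# Stringency-ordered vocabulary; lengths are the site footprint on the
# UTR (A1-anchored types include the adenine opposite miRNA position 1).
.SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer", "offset-6mer",
                 "6mer-A1")
.SITE_LEN <- c("8mer" = 8L, "7mer-m8" = 7L, "7mer-A1" = 7L, "6mer" = 6L,
               "offset-6mer" = 6L, "6mer-A1" = 7L)
.SITE_MIRNA_POS <- list("8mer" = c(2L, 8L), "7mer-m8" = c(2L, 8L),
                        "7mer-A1" = c(2L, 7L), "6mer" = c(2L, 7L),
                        "offset-6mer" = c(3L, 8L), "6mer-A1" = c(2L, 7L))

#' Supported seed-match site types
#'
#' Returns the canonical site-type vocabulary in decreasing stringency
#' order: `8mer` (reverse complement of miRNA positions 2-8 followed by
#' an A opposite position 1), `7mer-m8` (match to positions 2-8),
#' `7mer-A1` (match to positions 2-7 plus the A1 anchor), `6mer`
#' (positions 2-7), `offset-6mer` (positions 3-8) and `6mer-A1` (the
#' A1-anchored hexamer match, footprint identical to `7mer-A1`).
#'
#' @return Character vector of site-type names.
#' @export
mir_site_types <- function() .SITE_TYPES

# Target-site pattern (UTR strand, 5'->3') for each site type given a
# mature miRNA sequence.
.seed_patterns <- function(mirna) {
  m <- .norm_seq(mirna, "miRNA sequence")
  if (nchar(m) < 8L) stop("miRNA sequence must be at least 8 nt",
                          call. = FALSE)
  s28 <- substr(m, 2L, 8L)
  s27 <- substr(m, 2L, 7L)
  s38 <- substr(m, 3L, 8L)
  c("8mer"        = paste0(.revcomp(s28), "A"),
    "7mer-m8"     = .revcomp(s28),
    "7mer-A1"     = paste0(.revcomp(s27), "A"),
    "6mer"        = .revcomp(s27),
    "offset-6mer" = .revcomp(s38),
    "6mer-A1"     = paste0(.revcomp(s27), "A"))
}

#' Find miRNA seed-match sites in a 3'-UTR sequence
#'
#' Reports every occurrence of every requested canonical site type.
#' Overlapping occurrences of different types (e.g. the 7mers contained
#' in an 8mer) are all reported. Coordinates are 1-based inclusive on
#' the UTR in 5'->3' orientation; `U` and `T` are equivalent.
#'
#' @param utr_sequence UTR sequence (character scalar over A/C/G/T/U,
#'   case-insensitive).
#' @param mirna_sequence Mature miRNA sequence, 5'->3', length >= 8.
#' @param site_types Site types to search for; see [mir_site_types()].
#' @return A data frame with columns `gene_id` (NA, filled by callers
#'   that scan FASTA sets), `site_type`, `start`, `end`,
#'   `mirna_from`, `mirna_to` (matched miRNA seed positions), sorted by
#'   `start` then decreasing stringency.
#' @examples
#' find_seed_sites("CCCCATAAGCTACCCC", "UAGCUUAUCAGACUGAUGUUGA")
#' @export
find_seed_sites <- function(utr_sequence, mirna_sequence,
                            site_types = mir_site_types()) {
  utr <- .norm_seq(utr_sequence, "UTR sequence")
  site_types <- match.arg(site_types, .SITE_TYPES, several.ok = TRUE)
  pats <- .seed_patterns(mirna_sequence)
  subject <- Biostrings::DNAString(utr)
  out <- lapply(site_types, function(ty) {
    if (nchar(pats[[ty]]) > nchar(utr)) return(NULL)
    st <- Biostrings::start(Biostrings::matchPattern(pats[[ty]], subject))
    if (length(st) == 0L) return(NULL)
    data.frame(gene_id = NA_character_, site_type = ty, start = st,
               end = st + .SITE_LEN[[ty]] - 1L,
               mirna_from = .SITE_MIRNA_POS[[ty]][1L],
               mirna_to = .SITE_MIRNA_POS[[ty]][2L],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, list(.empty_sites())))
  res[order(res$start, match(res$site_type, .SITE_TYPES)), , drop = FALSE]
}

.empty_sites <- function() {
  data.frame(gene_id = character(), site_type = character(),
             start = integer(), end = integer(), mirna_from = integer(),
             mirna_to = integer(), stringsAsFactors = FALSE)
}

# Hexamer windows matching miRNA positions 2-7 with at most one G:U
# wobble (miRNA G : target T, or miRNA U : target G), rest Watson-Crick.
.find_wobble_6mer <- function(utr, mirna) {
  m <- strsplit(substr(mirna, 2L, 7L), "", fixed = TRUE)[[1L]]
  u <- strsplit(utr, "", fixed = TRUE)[[1L]]
  L <- length(u)
  if (L < 6L) return(integer())
  wc <- c(A = "T", C = "G", G = "C", T = "A")
  n_win <- L - 5L
  ok <- matrix(FALSE, n_win, 6L)
  wob <- matrix(FALSE, n_win, 6L)
  # target window position j (5'->3') pairs with miRNA seed position 7 - j + 1
  for (j in seq_len(6L)) {
    mb <- m[7L - j]        # miRNA base paired to window offset j
    tb <- u[seq_len(n_win) + j - 1L]
    ok[, j] <- tb == wc[[mb]]
    wob[, j] <- (mb == "G" & tb == "T") | (mb == "T" & tb == "G")
  }
  n_ok <- rowSums(ok)
  n_wob <- rowSums(wob & !ok)
  which(n_ok + n_wob == 6L & n_wob <= 1L)
}

#' Consensus prediction vote for one UTR
#'
#' Emulates a six-program target-prediction consensus with six seed
#' stringency modes, most to least stringent: (1) 8mer only;
#' (2) >= 7mer-m8; (3) >= 7mer-A1; (4) >= 6mer; (5) >= offset-6mer;
#' (6) >= 6mer allowing one G:U wobble in the seed match. Each mode is
#' cumulative over the stringency order, so a site of a stricter type
#' also fires every mode whose threshold it exceeds; the vote is the
#' number of modes detecting at least one site (0-6).
#'
#' @inheritParams find_seed_sites
#' @param gene_id Optional identifier carried into the result.
#' @return List of class `consensus_prediction` with `gene_id`, `votes`
#'   and `sites_by_mode` (per-mode site data frames).
#' @export
consensus_votes <- function(utr_sequence, mirna_sequence, gene_id = NA_character_) {
  utr <- .norm_seq(utr_sequence, "UTR sequence")
  sites <- find_seed_sites(utr, mirna_sequence)
  has <- vapply(.SITE_TYPES, function(ty) any(sites$site_type == ty),
                logical(1L))
  # cumulative: mode k fires if any site of stringency rank <= k exists
  mode_fires <- logical(6L)
  mode_fires[1L] <- has[["8mer"]]
  mode_fires[2L] <- mode_fires[1L] || has[["7mer-m8"]]
  mode_fires[3L] <- mode_fires[2L] || has[["7mer-A1"]]
  mode_fires[4L] <- mode_fires[3L] || has[["6mer"]]
  mode_fires[5L] <- mode_fires[4L] || has[["offset-6mer"]]
  wobble <- .find_wobble_6mer(utr, .norm_seq(mirna_sequence, "miRNA sequence"))
  mode_fires[6L] <- mode_fires[5L] || length(wobble) > 0L
  cum_types <- list("8mer",
                    c("8mer", "7mer-m8"),
                    c("8mer", "7mer-m8", "7mer-A1"),
                    c("8mer", "7mer-m8", "7mer-A1", "6mer"),
                    c("8mer", "7mer-m8", "7mer-A1", "6mer", "offset-6mer"))
  sites_by_mode <- lapply(seq_len(5L), function(k) {
    sites[sites$site_type %in% cum_types[[k]], , drop = FALSE]
  })
  wob_df <- if (length(wobble)) {
    data.frame(gene_id = gene_id, site_type = "6mer-GU", start = wobble,
               end = wobble + 5L, mirna_from = 2L, mirna_to = 7L,
               stringsAsFactors = FALSE)
  } else {
    .empty_sites()
  }
  sites_by_mode[[6L]] <- rbind(sites_by_mode[[5L]], wob_df)
  names(sites_by_mode) <- paste0("mode", 1:6)
  structure(list(gene_id = gene_id, votes = sum(mode_fires),
                 sites_by_mode = sites_by_mode),
            class = "consensus_prediction")
}

#' Consensus votes for a set of UTRs
#'
#' @param utrs Named character vector of UTR sequences or a
#'   `Biostrings::DNAStringSet` (names are gene ids).
#' @param mirna_sequence Mature miRNA sequence, 5'->3'.
#' @return Data frame with columns `gene_id` and `votes`.
#' @export
consensus_table <- function(utrs, mirna_sequence) {
  if (methods::is(utrs, "DNAStringSet")) utrs <- as.character(utrs)
  if (is.null(names(utrs)) || anyNA(names(utrs)) || any(names(utrs) == "")) {
    stop("UTR set must be named by gene id", call. = FALSE)
  }
  votes <- vapply(seq_along(utrs), function(i) {
    consensus_votes(utrs[[i]], mirna_sequence, gene_id = names(utrs)[i])$votes
  }, integer(1L))
  data.frame(gene_id = names(utrs), votes = votes, stringsAsFactors = FALSE)
}

#' Write seed sites of a UTR set to TSV
#'
#' One row per site: `gene_id`, `votes`, `site_type`, `start`, `end`.
#'
#' @param path Output file path.
#' @inheritParams consensus_table
#' @return Invisibly, the written data frame.
#' @export
write_seed_sites <- function(path, utrs, mirna_sequence) {
  if (methods::is(utrs, "DNAStringSet")) utrs <- as.character(utrs)
  tabs <- lapply(names(utrs), function(g) {
    cv <- consensus_votes(utrs[[g]], mirna_sequence, gene_id = g)
    s <- find_seed_sites(utrs[[g]], mirna_sequence)
    if (nrow(s)) {
      s$gene_id <- g
      cbind(s[, "gene_id", drop = FALSE], votes = cv$votes,
            s[, c("site_type", "start", "end")])
    } else {
      NULL
    }
  })
  out <- do.call(rbind, tabs)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), votes = integer(),
                      site_type = character(), start = integer(),
                      end = integer())
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
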