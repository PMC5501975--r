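# Internal helpers shared across modules.

# Smallest p-value ever reported; combined p-values that underflow are
# clipped here rather than printed as 0.
.P_FLOOR <- 1e-300

.floor_p <- function(p) pmax(p, .P_FLOOR)

.check_prob <- function(p, open_left = TRUE, open_right = FALSE,
                        what = "p-value") {
  if (length(p) == 0L) stop("at least one ", what, " required", call. = FALSE)
  if (anyNA(p) || !is.numeric(p)) {
    stop(what, "s must be numeric and non-missing", call. = FALSE)
  }
  lo_bad <- if (open_left) p <= 0 else p < 0
  hi_bad <- if (open_right) p >= 1 else p > 1
  if (any(lo_bad | hi_bad)) {
    rng <- sprintf("%s0, 1%s", if (open_left) "(" else "[",
                   if (open_right) ")" else "]")
    stop(what, " outside ", rng, ": ", p[which(lo_bad | hi_bad)[1L]],
         call. = FALSE)
  }
  invisible(p)
}

.check_positive <- function(x, what) {
  if (length(x) == 0L || anyNA(x) || !is.numeric(x) || any(x <= 0)) {
    stop(what, " must be positive", call. = FALSE)
  }
  invisible(x)
}

.check_fraction <- function(x, what) {
  if (length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(what, " must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

# Normalize a nucleotide string: uppercase, RNA U -> DNA T, validate the
# alphabet and name the first offending position on failure.
.norm_seq <- function(x, what = "sequence", allow_n = FALSE) {
  if (length(x) != 1L || !is.character(x) || is.na(x) || nchar(x) == 0L) {
    stop(what, " must be a single non-empty string", call. = FALSE)
  }
  s <- chartr("u", "t", toupper(x))
  s <- chartr("U", "T", s)
  alphabet <- if (allow_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% alphabet)
  if (length(bad)) {
    stop(sprintf("%s has invalid symbol '%s' at position %d",
                 what, chars[bad[1L]], bad[1L]), call. = FALSE)
  }
  s
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Seed-scoped RNG: generators are pure functions of (config, seed) and do
# not disturb the caller's RNG state.
.with_seed <- function(seed, code) {
  if (is.null(seed)) stop("a seed is required for reproducibility",
                          call. = FALSE)
  withr::with_seed(as.integer(seed), code)
}

# Small rolling polynomial hash over the JSON form of a config; used to
# fingerprint run configurations in output headers.
.config_hash <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
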