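# Shared low-level helpers: residue tables, sequence checks, interval maths.

AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_ALPHABET <- c(AA_STANDARD, "X")

# Kyte-Doolittle hydropathy; X (unknown) scores 0 and never matches motif
# character classes.
KD_HYDROPATHY <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2,
  X =  0.0
)

HYDROPHOBIC_CORE <- c("L", "I", "V", "F", "M")   # LRR core positions
POLAR_CORE <- c("N", "T", "S", "C")              # LRR asparagine position

check_sequence <- function(sequence, id = "<sequence>") {
  if (length(sequence) != 1L || !is.character(sequence))
    stop("sequence must be a single character string (protein ", id, ")")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (length(chars) < 1L) stop("empty sequence for protein ", id)
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0L)
    stop("invalid residue(s) ", paste(bad, collapse = ", "),
         " in protein ", id, " (uppercase 20-letter alphabet plus X expected)")
  invisible(chars)
}

seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

hydropathy_of <- function(chars) unname(KD_HYDROPATHY[chars])

# Hydropathy values are 0.1-granular, so achievable window means are spaced
# ~0.005 apart; comparing against thresholds with this slack makes the >=
# decision exact regardless of floating-point summation order.
HYDROPATHY_EPS <- 1e-9

# Sliding-window means of length w over x; result[i] is mean(x[i:(i+w-1)]).
window_means <- function(x, w) {
  n <- length(x)
  if (n < w) return(numeric(0))
  cs <- cumsum(c(0, x))
  (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
}

# Merge overlapping (not merely adjacent) 1-based inclusive intervals.
merge_intervals <- function(starts, ends) {
  if (length(starts) == 0L) return(data.frame(start = integer(0), end = integer(0)))
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out_s <- integer(0); out_e <- integer(0)
  for (k in seq_along(starts)[-1]) {
    if (starts[k] <= me) {
      me <- max(me, ends[k])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[k]; me <- ends[k]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

empty_domain_calls <- function() {
  data.frame(kind = character(0), start = integer(0), end = integer(0),
             score = numeric(0), source = character(0),
             stringsAsFactors = FALSE)
}

domain_call <- function(kind, start, end, score = NA_real_, source = "builtin") {
  data.frame(kind = kind, start = as.integer(start), end = as.integer(end),
             score = as.numeric(score), source = source,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
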