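#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft rnorm runif quantile sd var approx mvfft cor setNames pnorm qt
#' @importFrom utils write.csv read.csv head tail packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Next 5-smooth integer >= n
#'
#' FFT lengths whose prime factors are all in {2, 3, 5} keep the mixed-radix
#' transform fast; padding to such a length bounds the cost of every
#' frequency-domain filtering step.
#'
#' @param n positive integer.
#' @return smallest integer `>= n` with no prime factor larger than 5.
#' @keywords internal
.nfl_cache <- new.env(parent = emptyenv())

next_fast_len <- function(n) {
  n <- as.integer(n)
  if (n <= 6L) return(max(n, 1L))
  key <- as.character(n)
  hit <- .nfl_cache[[key]]
  if (!is.null(hit)) return(hit)
  factor_counts <- function(m) {
    k <- c(0L, 0L, 0L)
    ps <- c(2L, 3L, 5L)
    for (i in 1:3) while (m %% ps[i] == 0L) { m <- m %/% ps[i]; k[i] <- k[i] + 1L }
    if (m == 1L) k else NULL
  }
  # among 5-smooth lengths within 6% of n, prefer short factorizations and
  # penalize runs of factor 2 (R's mixed-radix FFT is slowest on those)
  best <- NA_integer_; best_score <- Inf
  for (m in n:as.integer(ceiling(1.06 * n))) {
    k <- factor_counts(m)
    if (is.null(k)) next
    score <- 1.3 * k[1] + k[2] + k[3]
    if (score < best_score) { best <- m; best_score <- score }
  }
  if (is.na(best)) {
    best <- n
    while (is.null(factor_counts(best))) best <- best + 1L
  }
  .nfl_cache[[key]] <- best
  best
}

# Deterministic 32-bit substream seed derived from a master seed and a
# sequence of tags (strings/numbers).  Keeps all randomness traceable to one
# master seed while decoupling the streams of different channels / stages.
substream_seed <- function(master, ...) {
  tags <- paste(c(master, ...), collapse = "/")
  bytes <- utf8ToInt(tags)
  h <- as.double(master %% 2147483647L)
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}
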