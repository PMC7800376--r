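# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derived integer seed for an independent substream; stays below 2^31.
substream_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + as.double(offset) * 7919) %% 2147483629)
}

# Linear interpolation over NA runs; endpoints extended with nearest value.
interp_na <- function(x) {
  n <- length(x)
  ok <- which(!is.na(x))
  if (length(ok) == 0L || length(ok) == n) return(x)
  stats::approx(ok, x[ok], xout = seq_len(n), method = "linear", rule = 2)$y
}

# Running median of 3 that only replaces values deviating from the local
# median by more than `tol` (tol = 0 reproduces a full 3-point median filter).
# NA neighbours are ignored; NA centres stay NA. Endpoints are left unchanged.
despike_median3 <- function(x, tol = 0) {
  n <- length(x)
  if (n < 3L) return(x)
  a <- c(NA_real_, x[-n])
  b <- c(x[-1L], NA_real_)
  m3 <- function(p, q, r) {
    lo <- pmin(p, q, r, na.rm = TRUE)
    hi <- pmax(p, q, r, na.rm = TRUE)
    s <- rowSums(cbind(p, q, r), na.rm = TRUE)
    cnt <- rowSums(!is.na(cbind(p, q, r)))
    ifelse(cnt == 3L, s - lo - hi, (lo + hi) / 2)
  }
  med <- suppressWarnings(m3(a, x, b))
  out <- x
  repl <- !is.na(x) & !is.na(med) & abs(x - med) > tol
  repl[c(1L, n)] <- FALSE
  out[repl] <- med[repl]
  out
}

# Boolean median filter (debounce) with odd window `w`; ends padded by
# extension. Equivalent to "majority vote in a centred window".
median_debounce <- function(x, w) {
  stopifnot(w >= 1, w %% 2 == 1)
  if (w == 1L || length(x) < w) return(x)
  n <- length(x)
  half <- (w - 1L) %/% 2L
  xx <- c(rep(x[1L], half), as.integer(x), rep(x[n], half))
  cs <- cumsum(xx)
  tot <- cs[seq_len(n) + 2L * half] - c(0, cs)[seq_len(n)]
  tot > half
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

logistic <- function(x) 1 / (1 + exp(-x))
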