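## Internal helpers shared across modules.

## One percentile definition package-wide: linear interpolation between order
## statistics (stats::quantile type 7).
pctl <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))

## Derive a stream of child seeds (< 2^31) from a master seed, so that
## per-neuron / per-stage randomness is reproducible yet decoupled.
childSeeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

## Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
## caller's stream afterwards. `seed = NULL` leaves the stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed %% .Machine$integer.max)
  expr
}

## Rolling mean of a 0/1 (or numeric) vector over full windows of length w.
## Returns a vector aligned to window centers (index start + floor(w/2)),
## NA elsewhere; partial edge windows are dropped, not padded.
rollMeanCentered <- function(x, w, na.rm = FALSE) {
  n <- length(x)
  out <- rep(NA_real_, n)
  if (n < w) return(out)
  if (na.rm) {
    v <- ifelse(is.na(x), 0, x)
    k <- as.numeric(!is.na(x))
    cs <- c(0, cumsum(v))
    ck <- c(0, cumsum(k))
    sums <- cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]
    cnts <- ck[(w + 1):(n + 1)] - ck[1:(n - w + 1)]
    m <- ifelse(cnts > 0, sums / cnts, NA_real_)
  } else {
    cs <- c(0, cumsum(x))
    m <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
  }
  centers <- seq_len(n - w + 1L) + floor(w / 2)
  out[centers] <- m
  out
}

## Last index (on `t`) before/at `tMax` at which band 1 and band 2 become and
## remain disjoint through tMax. Bands are lists with $lo and $hi vectors on
## the common axis `t`. Disjoint = lo1 > hi2 or lo2 > hi1. Requires the
## separation to be sustained (all subsequent evaluable points disjoint).
bandSeparationPoint <- function(t, band1, band2, tMax = 0) {
  stopifnot(length(t) == length(band1$lo), length(t) == length(band2$lo))
  use <- t <= tMax
  t <- t[use]
  lo1 <- band1$lo[use]; hi1 <- band1$hi[use]
  lo2 <- band2$lo[use]; hi2 <- band2$hi[use]
  ok <- !(is.na(lo1) | is.na(hi1) | is.na(lo2) | is.na(hi2))
  disjoint <- ok & (lo1 > hi2 | lo2 > hi1)
  if (!any(disjoint)) return(NA_integer_)
  evaluable <- which(ok)
  ## sustained: from candidate onward, every evaluable point is disjoint
  rev_ok <- rev(cumprod(rev(ifelse(ok, disjoint, TRUE))))
  cand <- which(disjoint & rev_ok == 1)
  if (!length(cand)) return(NA_integer_)
  t[min(cand)]
}

## Trapezoidal integral of y over x.
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

`%||%` <- function(a, b) if (is.null(a)) b else a
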