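# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Cumulative sum restarted at each new group; `group` must be contiguous.
grouped_cumsum <- function(x, group) {
  cs <- cumsum(x)
  starts <- which(!duplicated(group))
  offset <- rep.int(c(0, cs[starts[-1L] - 1L]), tabulate(match(group, group[starts])))
  cs - offset
}

# Normal(1, cv) truncated to (lo, hi); deterministic draw count irrelevant,
# rejection keeps the distribution honest.
rtrunc_mult <- function(n, cv, lo = 0.05, hi = 2) {
  if (cv <= 0) return(rep(1, n))
  out <- rnorm(n, 1, cv)
  bad <- which(out <= lo | out >= hi)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), 1, cv)
    bad <- bad[out[bad] <= lo | out[bad] >= hi]
  }
  out
}

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Depth-bin midpoint labels like "0-10" for breaks 0,10,...
bin_labels <- function(breaks) {
  paste0(breaks[-length(breaks)], "-", breaks[-1L])
}

# Length of each segment falling in each depth slab [lo, hi); segments given
# as z0, z1 (any order), len. Returns matrix [segment x bin].
slab_lengths <- function(z0, z1, len, breaks) {
  nb <- length(breaks) - 1L
  zlo <- pmin(z0, z1); zhi <- pmax(z0, z1)
  dz <- zhi - zlo
  out <- matrix(0, length(len), nb)
  flat <- dz <= .Machine$double.eps * pmax(zhi, 1)
  for (b in seq_len(nb)) {
    lo <- breaks[b]; hi <- breaks[b + 1L]
    frac <- pmax(0, pmin(zhi, hi) - pmax(zlo, lo)) / ifelse(flat, 1, dz)
    frac[flat] <- as.numeric(zlo[flat] >= lo & zlo[flat] < hi)
    out[, b] <- len * frac
  }
  out
}
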