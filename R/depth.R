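#' Rooting-depth quantile (D50, D80, D90, D95)
#'
#' The soil depth above which `p` percent of the profile's root length lies,
#' computed from cumulative root length over the depth bins with linear
#' interpolation inside the bin containing the threshold (mass is treated as
#' uniform within a bin).  Invariant to rescaling the profile by a positive
#' constant.
#'
#' @param profile An `rc_profile`, `rc_core`, or a plain non-negative numeric
#'   vector of per-bin root length / RLD.
#' @param p Percentile in (0, 100); conventionally 50, 80, 90 or 95.
#' @param depth_bins Breakpoints when `profile` is a bare numeric vector.
#' @return Depth in cm (scalar).
#' @examples
#' depth_quantile(rep(1, 6), 50)   # uniform profile -> 30
#' @export
depth_quantile <- function(profile, p, depth_bins = seq(0, 60, 10)) {
  stop_if(!is.numeric(p) || length(p) != 1 || p <= 0 || p >= 100,
          "p must be a single value in (0, 100)")
  if (inherits(profile, "rc_core")) {
    v <- profile$root_length_by_bin; depth_bins <- profile$depth_bins
  } else if (inherits(profile, "rc_profile")) {
    v <- profile$rld_by_bin; depth_bins <- profile$depth_bins
  } else {
    v <- as.numeric(profile)
  }
  stop_if(length(v) != length(depth_bins) - 1L, "bin count mismatch")
  stop_if(any(v < 0), "profile must be non-negative")
  tot <- sum(v)
  stop_if(tot <= 0, "depth quantile undefined for an all-zero profile")
  cum <- cumsum(v) / tot
  target <- p / 100
  b <- which(cum >= target - 1e-12)[1L]
  below <- if (b == 1L) 0 else cum[b - 1L]
  frac_bin <- v[b] / tot
  lo <- depth_bins[b]; hi <- depth_bins[b + 1L]
  if (frac_bin <= 0) return(lo)
  lo + (target - below) / frac_bin * (hi - lo)
}

#' Manhattan distance between two RLD profiles
#'
#' Sum over depth bins of absolute RLD differences — the scalar used to rank
#' how closely a core-based estimate reproduces a reference profile.
#'
#' @param a,b `rc_profile`/`rc_core`/`rc_estimate` objects or numeric vectors
#'   with identical depth bins.
#' @return Distance in cm cm^-3.
#' @export
manhattan_distance <- function(a, b) {
  va <- profile_values(a); vb <- profile_values(b)
  if (!is.null(attr(va, "bins")) && !is.null(attr(vb, "bins")))
    stop_if(!isTRUE(all.equal(attr(va, "bins"), attr(vb, "bins"))),
            "depth bin mismatch")
  stop_if(length(va) != length(vb), "profiles have different bin counts")
  sum(abs(va - vb))
}

profile_values <- function(x) {
  if (inherits(x, "rc_estimate")) x <- x$profile
  if (inherits(x, "rc_profile"))
    structure(x$rld_by_bin, bins = x$depth_bins)
  else if (inherits(x, "rc_core"))
    structure(x$rld_by_bin, bins = x$depth_bins)
  else as.numeric(x)
}

#' Depth metrics for a set of cores combined by depth
#'
#' Sums root length of the contributing cores bin-by-bin before taking the
#' quantile, the protocol for multi-location depth metrics.
#'
#' @param cores List of `rc_core` with identical bins.
#' @param p Percentile in (0, 100).
#' @return Depth in cm.
#' @export
combined_depth_quantile <- function(cores, p) {
  stop_if(length(cores) == 0, "need at least one core")
  rl <- Reduce(`+`, lapply(cores, `[[`, "root_length_by_bin"))
  depth_quantile(rl, p, cores[[1]]$depth_bins)
}
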