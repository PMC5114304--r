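#' Multi-echo gradient-echo series
#'
#' Container for per-vertex multi-echo magnitudes at fixed echo times.
#'
#' @param signal Numeric matrix, vertices x echoes (arbitrary units).
#' @param echo_times Echo times in seconds, strictly increasing, one per
#'   signal column.
#' @return An `echo_series` object.
#' @export
echo_series <- function(signal, echo_times) {
  signal <- as.matrix(signal)
  if (length(echo_times) != ncol(signal)) {
    stop("one echo time per signal column required", call. = FALSE)
  }
  if (any(echo_times <= 0) || any(diff(echo_times) <= 0)) {
    stop("echo times must be positive and strictly increasing",
         call. = FALSE)
  }
  structure(list(signal = signal, echo_times = as.numeric(echo_times)),
            class = "echo_series")
}

#' Mono-exponential T2* fit
#'
#' Fits S(TE) = S0 exp(-TE / T2*) per vertex by least squares on the
#' log-signal: the slope of log S against TE is -1/T2* and the intercept is
#' log S0. Vertices with any non-positive echo signal are marked unfittable
#' (`NA` in both output maps) rather than fitted. A non-negative slope (no
#' measurable decay) yields the `+Inf` T2* marker.
#'
#' @param echoes An [echo_series()].
#' @param weighted If `TRUE`, weight the log-linear regression by the
#'   squared signal magnitude (first-order variance stabilization of the log
#'   transform); default unweighted ordinary least squares, which is exact
#'   in the noiseless limit.
#' @return List with `s0` (a.u.), `t2s` (seconds) and the logical
#'   `unfittable` mask.
#' @examples
#' te <- c(2.53, 7.03, 12.55, 20.35) / 1000
#' sig <- matrix(100 * exp(-te / 0.05), nrow = 1)
#' fit_t2star(echo_series(sig, te))$t2s  # 0.05
#' @export
fit_t2star <- function(echoes, weighted = FALSE) {
  stopifnot(inherits(echoes, "echo_series"))
  sig <- echoes$signal
  te <- echoes$echo_times
  if (length(te) < 2L) stop("at least 2 echoes required", call. = FALSE)
  ok <- rowSums(sig <= 0 | !is.finite(sig)) == 0L
  n <- nrow(sig)
  s0 <- rep(NA_real_, n)
  t2s <- rep(NA_real_, n)
  if (any(ok)) {
    y <- log(sig[ok, , drop = FALSE])
    if (weighted) {
      w <- sig[ok, , drop = FALSE]^2
      sw <- rowSums(w)
      tbar <- (w %*% te) / sw
      ybar <- rowSums(w * y) / sw
      tc <- outer(as.vector(tbar), te, function(a, b) b - a)
      slope <- rowSums(w * tc * (y - as.vector(ybar))) / rowSums(w * tc^2)
      intercept <- as.vector(ybar) - slope * as.vector(tbar)
    } else {
      tc <- te - mean(te)
      slope <- (y %*% tc) / sum(tc^2)
      intercept <- rowMeans(y) - slope * mean(te)
    }
    s0[ok] <- exp(intercept)
    t2s[ok] <- ifelse(slope < 0, -1 / slope, Inf)
  }
  list(s0 = s0, t2s = t2s, unfittable = !ok)
}

#' T2*-weighted map from echo extremes
#'
#' The T2*-weighted image is the last-echo magnitude divided by the
#' first-echo magnitude, which cancels the receive-coil sensitivity while
#' keeping T2* decay contrast. Noiseless series give
#' exp(-(TE_last - TE_first)/T2*) exactly.
#'
#' @param echoes An [echo_series()].
#' @return Dimensionless per-vertex numeric vector; `NA` where the
#'   first-echo signal is not strictly positive.
#' @export
t2star_weighted <- function(echoes) {
  stopifnot(inherits(echoes, "echo_series"))
  sig <- echoes$signal
  first <- sig[, 1L]
  last <- sig[, ncol(sig)]
  out <- ifelse(is.finite(first) & first > 0, last / first, NA_real_)
  as.numeric(out)
}

#' Reciprocal of a relaxation map
#'
#' Elementwise 1/x with unit relabeling between times and rates
#' (T1 s -> R1 s^-1, T2* s -> R2* s^-1). Non-positive or missing inputs
#' propagate as unfittable (`NA`).
#'
#' @param values Per-vertex numeric vector.
#' @return Per-vertex reciprocal.
#' @export
reciprocal_map <- function(values) {
  ifelse(is.finite(values) & values > 0, 1 / values,
         ifelse(is.infinite(values) & values > 0, 0, NA_real_))
}

#' Ratio maps between longitudinal and transversal parameters
#'
#' Computes the two myelin-contrast-enhancing ratios: weighted
#' T1w / T2*w (a.u.) and quantitative R1 / T2* (s^-2). Unfittable (`NA`)
#' vertices in either parent and non-positive denominators propagate as
#' `NA`.
#'
#' @param t1w T1-weighted map (a.u.).
#' @param t2sw T2*-weighted map (dimensionless).
#' @param r1 Quantitative R1 map (s^-1).
#' @param t2s Quantitative T2* map (s).
#' @return List with `t1w_t2sw` and `r1_t2s` per-vertex vectors.
#' @export
ratio_maps <- function(t1w, t2sw, r1, t2s) {
  safe_div <- function(num, den) {
    ifelse(is.finite(num) & is.finite(den) & den > 0, num / den, NA_real_)
  }
  list(t1w_t2sw = safe_div(t1w, t2sw), r1_t2s = safe_div(r1, t2s))
}

#' Susceptibility-artifact exclusion mask
#'
#' Vertices whose across-subject average T2* falls below the exclusion
#' threshold (default 0.024 s) are dominated by static-field inhomogeneity
#' (air-tissue interfaces, large veins) and are excluded from all
#' statistics; unfittable vertices are excluded too.
#'
#' @param t2s_avg Across-subject average T2* per vertex (seconds).
#' @param threshold Exclusion threshold in seconds.
#' @return Logical vector, `TRUE` = excluded.
#' @export
exclusion_mask <- function(t2s_avg, threshold = 0.024) {
  is.na(t2s_avg) | t2s_avg < threshold
}
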