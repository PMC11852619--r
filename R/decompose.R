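#' @name ssa
#' @title Singular spectrum analysis trend decomposition
#'
#' @description
#' Singular spectrum analysis (SSA) embeds a series `x[1..N]` into a Hankel
#' trajectory matrix `X[i, j] = x[i + j - 1]` of size `L x K`
#' (`K = N - L + 1`), takes its singular value decomposition
#' `X = sum_i sigma_i u_i v_i'`, and reconstructs each rank-1 term back into
#' a series by averaging along the anti-diagonals. Summing every elementary
#' component recovers the input exactly, so any grouping of components
#' gives an additive decomposition `A = L + S + R` into a long-term trend
#' `L`, oscillatory components `S`, and a remainder `R`.
NULL

# Anti-diagonal (Hankel) averaging of sigma * u v': outer(u, v) summed along
# anti-diagonals is the polynomial convolution of u and v; dividing by the
# number of entries per anti-diagonal gives the averaged series.
diag_average <- function(u, v, sigma) {
  Lw <- length(u); K <- length(v)
  conv <- convolve(u, rev(v), type = "open")
  counts <- pmin(seq_len(Lw + K - 1L), Lw, K,
                 rev(seq_len(Lw + K - 1L)))
  sigma * conv / counts
}

#' Elementary SSA decomposition
#'
#' @param series a [uniform_series()] of length `N >= 4`.
#' @param window_len embedding window length `L` in samples,
#'   `2 <= L <= N / 2`.
#' @return An object of class `ssa_components`: list with `components`
#'   (an `N x L` matrix, one elementary reconstructed series per column,
#'   ordered by decreasing singular value), `eigenvalues` (squared singular
#'   values, descending), `window_len`, `rate`, `t0` and the original
#'   `values`.
#' @examples
#' s <- uniform_series(sin(2 * pi * (0:199) / 20), rate = 10)
#' d <- ssa_decompose(s, window_len = 40)
#' sum(d$eigenvalues[1:2]) / sum(d$eigenvalues)  # ~1: a sinusoid is rank 2
#' @export
ssa_decompose <- function(series, window_len) {
  x <- series$values
  N <- length(x)
  window_len <- as.integer(window_len)
  if (N < 4L) stop("ssa_decompose needs at least 4 samples")
  if (is.na(window_len) || window_len < 2L || window_len > N / 2)
    stop("`window_len` must satisfy 2 <= window_len <= length/2 (length ",
         N, ", got ", window_len, ")")
  K <- N - window_len + 1L
  X <- matrix(0, window_len, K)
  for (i in seq_len(window_len)) X[i, ] <- x[i:(i + K - 1L)]
  sv <- svd(X)
  comps <- matrix(0, N, window_len)
  for (i in seq_len(window_len)) {
    comps[, i] <- diag_average(sv$u[, i], sv$v[, i], sv$d[i])
  }
  structure(
    list(components = comps, eigenvalues = sv$d^2, window_len = window_len,
         rate = series$rate, t0 = series$t0, values = x),
    class = "ssa_components"
  )
}

#' @export
print.ssa_components <- function(x, ...) {
  ev <- x$eigenvalues / sum(x$eigenvalues)
  cat(sprintf(
    "<ssa_components> %d components (window %d); top energy fractions: %s\n",
    ncol(x$components), x$window_len,
    paste(sprintf("%.3f", utils::head(ev, 4)), collapse = ", ")))
  invisible(x)
}

# Dominant frequency (Hz) of one component: location of the largest
# non-negative-frequency FFT amplitude, DC included.
dominant_freq <- function(values, rate) {
  n <- length(values)
  a <- Mod(stats::fft(values))[seq_len(floor(n / 2) + 1L)]
  (which.max(a) - 1L) * rate / n
}

#' Group elementary SSA components into trend, oscillation, remainder
#'
#' Components whose dominant FFT frequency lies below `trend_cutoff` join
#' the long-term trend `L`; of the rest, components holding at least
#' `energy_floor` of the total squared singular value join the oscillatory
#' part `S`; everything else is remainder `R`. The grouping is automatic so
#' results are reproducible (no interactive pairing).
#'
#' @param decomp an `ssa_components` object from [ssa_decompose()].
#' @param trend_cutoff trend/oscillation frequency boundary in Hz.
#' @param energy_floor minimum energy fraction for an oscillatory component.
#' @return An object of class `ssa_result`: list with series `L`, `S`, `R`
#'   (each a [uniform_series()]), `eigenvalues`, `window_len`, and
#'   `grouping` (factor over components with levels L/S/R).
#' @export
group_components <- function(decomp, trend_cutoff = 0.1, energy_floor = 0.05) {
  stopifnot(inherits(decomp, "ssa_components"))
  nc <- ncol(decomp$components)
  if (nc == 0L) stop("no components to group")
  domf <- apply(decomp$components, 2L, dominant_freq, rate = decomp$rate)
  efrac <- decomp$eigenvalues / sum(decomp$eigenvalues)
  grp <- ifelse(domf < trend_cutoff, "L",
                ifelse(efrac >= energy_floor, "S", "R"))
  sum_group <- function(g) {
    idx <- which(grp == g)
    v <- if (length(idx)) rowSums(decomp$components[, idx, drop = FALSE])
         else rep(0, length(decomp$values))
    uniform_series(v, decomp$rate, decomp$t0)
  }
  structure(
    list(L = sum_group("L"), S = sum_group("S"), R = sum_group("R"),
         eigenvalues = decomp$eigenvalues, window_len = decomp$window_len,
         grouping = factor(grp, levels = c("L", "S", "R")),
         input = uniform_series(decomp$values, decomp$rate, decomp$t0)),
    class = "ssa_result"
  )
}

#' @export
print.ssa_result <- function(x, ...) {
  cat(sprintf(
    "<ssa_result> A = L + S + R over %d samples; components L:%d S:%d R:%d\n",
    length(x$input$values), sum(x$grouping == "L"), sum(x$grouping == "S"),
    sum(x$grouping == "R")))
  invisible(x)
}

#' Long-term trend of a series via SSA
#'
#' Convenience composition of [ssa_decompose()] and [group_components()]
#' returning only the trend `L`. Used on the squared band-passed envelope
#' to produce the magnitude trendline of the struggle phase.
#'
#' @param series a [uniform_series()].
#' @param window_len embedding window in samples; default
#'   `round(rate * 20)` capped at `length / 2`, so the trend spans several
#'   IBM periods.
#' @param trend_cutoff,energy_floor see [group_components()].
#' @return The trend as a [uniform_series()].
#' @export
trend_of <- function(series,
                     window_len = min(round(series$rate * 20),
                                      floor(length(series$values) / 2)),
                     trend_cutoff = 0.1, energy_floor = 0.05) {
  group_components(ssa_decompose(series, window_len),
                   trend_cutoff = trend_cutoff,
                   energy_floor = energy_floor)$L
}
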