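# Periodized discrete wavelet transform with the Daubechies-2 (4-tap)
# basis. Small and self-contained: the motion-correction stage only needs
# analysis, per-level detail thresholding, and exact reconstruction.

DB2_H <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
DB2_G <- rev(DB2_H) * c(1, -1, 1, -1)  # quadrature mirror

# one analysis step: x (even length) -> list(approx, detail), periodized
dwt_step <- function(x) {
  n <- length(x)
  idx <- outer(seq(1, n, by = 2), 0:3, `+`)
  idx <- (idx - 1L) %% n + 1L
  xm <- matrix(x[idx], ncol = 4)
  list(approx = as.vector(xm %*% DB2_H), detail = as.vector(xm %*% DB2_G))
}

idwt_step <- function(approx, detail) {
  n2 <- 2L * length(approx)
  y <- numeric(n2)
  pos <- seq(1, n2, by = 2)
  for (k in 0:3) {
    tgt <- (pos + k - 1L) %% n2 + 1L
    contrib <- approx * DB2_H[k + 1L] + detail * DB2_G[k + 1L]
    y[tgt] <- y[tgt] + contrib
  }
  y
}

# full pyramid to `levels` levels; x length must be divisible by 2^levels
dwt_db2 <- function(x, levels) {
  out <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- dwt_step(a)
    out[[j]] <- s$detail
    a <- s$approx
  }
  list(details = out, approx = a)
}

idwt_db2 <- function(decomp) {
  a <- decomp$approx
  for (j in rev(seq_along(decomp$details)))
    a <- idwt_step(a, decomp$details[[j]])
  a
}

#' Wavelet-based motion-artifact correction
#'
#' Decomposes each channel x wavelength series with a multi-level
#' Daubechies-2 discrete wavelet transform and zeroes, per decomposition
#' level, every detail coefficient falling outside
#' `[Q1 - iqr_k * IQR, Q3 + iqr_k * IQR]` of that level's coefficient
#' distribution, then reconstructs. Motion artifacts (spikes, abrupt
#' shifts) concentrate in outlying detail coefficients and are removed;
#' the smooth hemodynamic content, carried by the approximation and the
#' bulk of the details, passes through.
#'
#' @param od optical-density vector, matrix (time x channel) or array
#'   (time x channel x wavelength).
#' @param iqr_k outlier half-width in IQR units (default 0.1, an
#'   aggressive setting appropriate for slow event-related designs);
#'   `Inf` leaves the series untouched up to reconstruction round-off.
#' @param levels number of decomposition levels.
#' @return Object of the same shape as `od`.
#' @export
wavelet_motion_correct <- function(od, iqr_k = 0.1, levels = 5) {
  apply_columns(od, function(x) wavelet_correct_vec(x, iqr_k, levels))
}

wavelet_correct_vec <- function(x, iqr_k, levels) {
  n <- length(x)
  block <- 2L^levels
  if (n < 2L * block) {
    warning("series too short for ", levels,
            "-level wavelet decomposition; passed through")
    return(x)
  }
  # remove the endpoint-to-endpoint trend and mirror the whole series
  # before the periodized transform: the extended signal is continuous at
  # both junctions, so the boundary contributes no spurious outlier
  # coefficients (which IQR thresholding would otherwise zero, distorting
  # the edges)
  line <- x[1L] + (x[n] - x[1L]) * (seq_len(n) - 1) / (n - 1)
  xp <- c(x - line, rev(x - line))
  pad <- (block - length(xp) %% block) %% block
  if (pad > 0) xp <- c(xp, xp[length(xp) - seq_len(pad) + 1L])
  dec <- dwt_db2(xp, levels)
  if (is.finite(iqr_k)) {
    dec$details <- lapply(dec$details, function(d) {
      q <- quantile(d, c(0.25, 0.75), names = FALSE, type = 7)
      iqr <- q[2] - q[1]
      d[d < q[1] - iqr_k * iqr | d > q[2] + iqr_k * iqr] <- 0
      d
    })
  }
  idwt_db2(dec)[seq_len(n)] + line
}

# apply a vector function over the time dimension of vec/matrix/array input
apply_columns <- function(x, f) {
  if (is.null(dim(x))) return(f(x))
  d <- dim(x)
  if (length(d) == 2L) {
    out <- x
    for (j in seq_len(d[2])) out[, j] <- f(x[, j])
    return(out)
  }
  out <- x
  for (j in seq_len(d[2])) for (w in seq_len(d[3])) out[, j, w] <- f(x[, j, w])
  out
}
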