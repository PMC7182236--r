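# Spherical-spline interpolation of scalp potentials (Perrin et al. 1989
# style): g(x) = 1/(4*pi) * sum_l (2l+1) / (l(l+1))^m * P_l(x), solved
# with a small stiffness term on the diagonal and the usual zero-sum
# constraint on the spline coefficients.

# P_1..P_lmax evaluated at each x, by the Bonnet recurrence.
legendre_table <- function(x, lmax) {
  out <- matrix(0, length(x), lmax)
  pm1 <- rep(1, length(x))  # P_0
  p <- x                    # P_1
  out[, 1] <- p
  if (lmax > 1) for (l in 2:lmax) {
    pn <- ((2 * l - 1) * x * p - (l - 1) * pm1) / l
    out[, l] <- pn
    pm1 <- p; p <- pn
  }
  out
}

spline_g <- function(x, m = 4, lmax = 50) {
  l <- seq_len(lmax)
  w <- (2 * l + 1) / (l * (l + 1))^m
  as.vector(legendre_table(as.vector(x), lmax) %*% w) / (4 * pi)
}

# Linear operator mapping potentials at `good` electrodes to estimates at
# `bad` electrodes (both index into the montage).
spline_operator <- function(montage, good, bad, m = 4, lambda = 1e-5,
                            lmax = 50) {
  cs <- montage_cosines(montage)
  ng <- length(good)
  G <- matrix(spline_g(cs[good, good, drop = FALSE], m, lmax), ng, ng)
  A <- rbind(cbind(G + diag(lambda, ng), 1), c(rep(1, ng), 0))
  Gb <- matrix(spline_g(cs[bad, good, drop = FALSE], m, lmax),
               length(bad), ng)
  sol <- solve(A)[, seq_len(ng), drop = FALSE]  # maps z -> (c, d)
  cbind(Gb, 1) %*% sol
}

#' Interpolate channels by spherical splines
#'
#' Replaces the listed scalp channels, in every epoch, with
#' spherical-spline estimates (order `m = 4`, stiffness
#' `lambda = 1e-5`) from the remaining scalp channels.
#'
#' @param epochs An [epoch_set()].
#' @param channels Character vector of channels to interpolate (may be
#'   empty, in which case the input is returned unchanged).
#' @param m Spline order.
#' @param lambda Stiffness added to the spline system's diagonal.
#' @return The epoch set with the channels replaced.
#' @export
interpolate_channels <- function(epochs, channels, m = 4, lambda = 1e-5) {
  if (length(channels) == 0) return(epochs)
  scalp <- which(epochs$montage$type == "scalp")
  bad <- match(channels, epochs$montage$channel)
  if (anyNA(bad)) abort("Unknown channel(s) to interpolate.")
  if (any(!bad %in% scalp)) abort("Only scalp channels can be interpolated.")
  good <- setdiff(scalp, bad)
  if (length(good) < 0.75 * length(scalp)) {
    abort("Too few intact channels for spline interpolation (< 3/4 of montage).",
          class = "fpvs_interpolation_error")
  }
  op <- spline_operator(epochs$montage, good, bad, m, lambda)
  d <- dim(epochs$data)
  for (i in seq_len(d[1])) {
    epochs$data[i, bad, ] <- op %*% epochs$data[i, good, ]
  }
  epochs
}
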