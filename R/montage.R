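#' Synthetic 64 + 4 channel EEG montage
#'
#' Builds an electrode layout emulating a 64-channel scalp cap at 256 Hz
#' recordings plus four periocular EOG electrodes. Scalp electrodes are
#' placed on a unit-sphere head model by a Fibonacci lattice over a
#' spherical cap, with the vertex electrode labelled `Cz`; the geometry is
#' synthetic (no digitised cap positions are shipped) and is used only
#' where inter-electrode angles matter: spherical-spline interpolation and
#' topography displays.
#'
#' @param n_scalp Number of scalp electrodes (default 64).
#' @param n_eog Number of EOG electrodes (default 4).
#' @param max_polar Maximum polar angle of the scalp cap in degrees,
#'   measured from the vertex (default 100, extending slightly below the
#'   equator as physical caps do).
#' @return A tibble with one row per channel: `channel`, `type`
#'   (`"scalp"` or `"eog"`), and unit-sphere coordinates `x`, `y`, `z`
#'   (x right, y anterior, z superior).
#' @examples
#' m <- synthetic_montage()
#' table(m$type)
#' @export
synthetic_montage <- function(n_scalp = 64, n_eog = 4, max_polar = 100) {
  stopifnot(n_scalp >= 8, n_eog >= 0)
  k <- seq_len(n_scalp) - 1
  # Fibonacci lattice on the cap: uniform in cos(polar) down to max_polar
  golden <- pi * (3 - sqrt(5))
  zmin <- cos(max_polar * pi / 180)
  z <- 1 - k / (n_scalp - 1) * (1 - zmin)
  r <- sqrt(pmax(0, 1 - z^2))
  az <- k * golden
  scalp <- tibble(
    channel = c("Cz", sprintf("E%02d", 2:n_scalp)),
    type = "scalp",
    x = r * cos(az), y = r * sin(az), z = z
  )
  if (n_eog > 0) {
    # periocular positions, anterior-inferior; not part of the scalp cap
    ang <- seq(-0.5, 0.5, length.out = n_eog)
    eog <- tibble(
      channel = sprintf("EXG%d", seq_len(n_eog)),
      type = "eog",
      x = sin(ang), y = cos(ang) * 0.95, z = -0.3
    )
    eog <- dplyr::mutate(eog, norm = sqrt(.data$x^2 + .data$y^2 + .data$z^2),
                         x = .data$x / .data$norm, y = .data$y / .data$norm,
                         z = .data$z / .data$norm)
    eog$norm <- NULL
    scalp <- dplyr::bind_rows(scalp, eog)
  }
  scalp
}

scalp_channels <- function(montage) montage$channel[montage$type == "scalp"]
eog_channels <- function(montage) montage$channel[montage$type == "eog"]

# Cosine of the angle between every pair of electrodes.
montage_cosines <- function(montage) {
  p <- as.matrix(montage[, c("x", "y", "z")])
  p <- p / sqrt(rowSums(p^2))
  cs <- tcrossprod(p)
  pmin(pmax(cs, -1), 1)
}
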