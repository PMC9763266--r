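#' Linear channel-to-energy axis
#'
#' A photon-counting detector bins photons into energy channels. After
#' calibration against fluorescence peaks of known energy, the mapping from
#' channel index to photon energy is linear: `E(ch) = offset + gain * (ch - 1)`
#' with `ch` the 1-based channel index, so `offset` is the energy of the
#' centre of the first channel and `gain` is the channel width in keV.
#'
#' @param n_channels Number of energy channels (integer, at least 2).
#' @param gain Channel width in keV per channel (must be positive).
#' @param offset Energy of the first channel centre, keV.
#'
#' @return An object of class `energy_axis`.
#' @examples
#' ax <- energy_axis(200, gain = 0.25, offset = 5)
#' channel_to_energy(ax, 113)
#' @export
energy_axis <- function(n_channels, gain, offset) {
  n_channels <- as.integer(n_channels)
  stopifnot(is.finite(gain), is.finite(offset))
  if (n_channels < 2L) stop("an energy axis needs at least 2 channels")
  if (gain <= 0) stop("`gain` must be positive (energies strictly increasing)")
  structure(
    list(n_channels = n_channels, gain = as.numeric(gain),
         offset = as.numeric(offset)),
    class = "energy_axis"
  )
}

#' @export
print.energy_axis <- function(x, ...) {
  cat(sprintf(
    "<energy_axis> %d channels, %.6g keV/channel, %.6g-%.6g keV\n",
    x$n_channels, x$gain, x$offset, x$offset + x$gain * (x$n_channels - 1)
  ))
  invisible(x)
}

#' Convert channel indices to energies and back
#'
#' `channel_to_energy()` returns the channel-centre energy of 1-based channel
#' indices; `energy_to_channel()` rounds to the nearest channel centre and is
#' the left inverse of `channel_to_energy()` on channel centres.
#' `axis_energies()` returns all channel-centre energies.
#'
#' @param axis An [energy_axis()].
#' @param ch Integer channel index (1-based), vectorised.
#' @param energy_kev Photon energy in keV, vectorised.
#' @return Energies in keV, or integer channel indices.
#' @export
channel_to_energy <- function(axis, ch) {
  stopifnot(inherits(axis, "energy_axis"))
  ch <- as.integer(ch)
  if (any(ch < 1L | ch > axis$n_channels)) {
    stop(sprintf("channel index out of range [1, %d]", axis$n_channels))
  }
  axis$offset + axis$gain * (ch - 1L)
}

#' @rdname channel_to_energy
#' @export
energy_to_channel <- function(axis, energy_kev) {
  stopifnot(inherits(axis, "energy_axis"))
  ch <- as.integer(round((energy_kev - axis$offset) / axis$gain)) + 1L
  pmin(pmax(ch, 1L), axis$n_channels)
}

#' @rdname channel_to_energy
#' @export
axis_energies <- function(axis) {
  stopifnot(inherits(axis, "energy_axis"))
  axis$offset + axis$gain * (seq_len(axis$n_channels) - 1L)
}

# first channel whose centre energy is >= energy_kev (edge channel convention)
first_channel_at_or_above <- function(axis, energy_kev) {
  e <- axis_energies(axis)
  k <- which(e >= energy_kev)[1]
  if (is.na(k)) stop(sprintf("energy %.3f keV beyond axis range", energy_kev))
  k
}
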