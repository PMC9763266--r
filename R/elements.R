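#' Contrast-agent element table
#'
#' Heavy elements used as contrast stains are identified by the energy of
#' their K absorption edge: iodine 33.17 keV, barium 37.44 keV, tungsten
#' 69.53 keV and calcium 4.04 keV. The packaged table also carries the two
#' parameters of the attenuation model used by the simulator and the
#' analytic ground truth: a power-law amplitude `A` (cm^2/g keV^3) and the
#' edge jump ratio `r` (post-edge over pre-edge mass attenuation at the
#' edge). `A` and `r` are anchored to tabulated mass-attenuation magnitudes
#' but are parameters of a simplified two-branch power law, not a copy of
#' the full attenuation tables.
#'
#' @param file Optional path to a user CSV with the same schema
#'   (`symbol, k_edge_kev, A, r`; `#` comment lines allowed). Defaults to
#'   the packaged table.
#' @return A tibble with columns `symbol`, `k_edge_kev`, `A`, `r`.
#' @examples
#' element_table()
#' @export
element_table <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "elements.csv", package = "kedge")
  }
  if (!file.exists(file)) stop("element table file not found: ", file)
  df <- utils::read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("symbol", "k_edge_kev", "A", "r")
  if (!all(need %in% names(df))) {
    stop("element table must have columns: ", paste(need, collapse = ", "))
  }
  tb <- tibble::as_tibble(df[need])
  if (any(tb$k_edge_kev <= 0) || any(tb$A <= 0) || any(tb$r <= 1)) {
    stop("element table invariants violated: need k_edge_kev > 0, A > 0, r > 1")
  }
  tb
}

#' Look up one element record
#'
#' @param symbol Element symbol, e.g. `"I"`, `"Ba"`, `"W"`, `"Ca"`.
#' @param table An [element_table()] tibble.
#' @return A one-row list with fields `symbol`, `k_edge_kev`, `A`, `r`.
#' @export
element_record <- function(symbol, table = element_table()) {
  i <- match(symbol, table$symbol)
  if (is.na(i)) {
    stop(sprintf("element '%s' not in table (have: %s)", symbol,
                 paste(table$symbol, collapse = ", ")))
  }
  as.list(table[i, ])
}

#' Linear attenuation of a dissolved contrast element
#'
#' Two-branch power-law model of a contrast solute's linear attenuation:
#' below the K-edge `mu = c * A * E^-3 * 1e-4` mm^-1 and at or above the
#' edge the same expression multiplied by the jump ratio `r`, so the
#' attenuation jumps discontinuously upward at `E = E_K` and is exactly
#' proportional to concentration. The factor `1e-4` converts
#' (cm^2/g) * (mg/ml) into mm^-1.
#'
#' @param elem An [element_record()].
#' @param energy_kev Photon energies in keV (vectorised, all > 0).
#' @param concentration_mg_ml Solute concentration in mg/ml (>= 0).
#' @return Linear attenuation in mm^-1, same length as `energy_kev`.
#' @examples
#' iodine <- element_record("I")
#' elemental_mu(iodine, c(33.0, 33.25), 50)
#' @export
elemental_mu <- function(elem, energy_kev, concentration_mg_ml) {
  if (any(energy_kev <= 0)) stop("photon energy must be positive")
  if (concentration_mg_ml < 0) stop("concentration must be >= 0")
  jump <- ifelse(energy_kev >= elem$k_edge_kev, elem$r, 1)
  concentration_mg_ml * elem$A * energy_kev^-3 * jump * 1e-4
}

#' Analytic K-edge step height of a solute
#'
#' Closed-form ground truth for the attenuation step at the K-edge:
#' `delta_mu0 = c * A * E_K^-3 * (r - 1) * 1e-4` mm^-1. The edge-height
#' estimator must recover this exactly in the noiseless limit.
#'
#' @inheritParams elemental_mu
#' @return Step height in mm^-1.
#' @export
elemental_edge_step <- function(elem, concentration_mg_ml) {
  concentration_mg_ml * elem$A * elem$k_edge_kev^-3 * (elem$r - 1) * 1e-4
}
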