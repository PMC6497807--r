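#' Conductance map for crossbar export
#'
#' @param g_min,g_max device conductance bounds (same arbitrary units, e.g.
#'   microsiemens), `g_max > g_min > 0`.
#' @param scheme `"single"` — one device per synapse, weight linearly mapped
#'   onto `[g_min, g_max]`; `"differential"` — two devices per synapse with
#'   `G = G+ - G-`.
#' @return a list of class `conductance_map`.
#' @export
conductance_map <- function(g_min, g_max, scheme = c("single", "differential")) {
  if (!(g_max > g_min && g_min > 0)) stop("need g_max > g_min > 0")
  structure(list(g_min = g_min, g_max = g_max, scheme = match.arg(scheme)),
            class = "conductance_map")
}

#' Map trained weights to device conductances
#'
#' Single-device scheme: the affine map
#' `G = W (g_max - g_min) / 2 + (g_max + g_min) / 2`, sending -1 to `g_min`,
#' 0 to the midpoint and +1 to `g_max`. Differential scheme: each weight is
#' split over two devices with `G+ - G- = W (g_max - g_min)`, using
#' `G+ = g_min + max(W, 0) (g_max - g_min)` and
#' `G- = g_min - min(W, 0) (g_max - g_min)`, so both devices stay inside
#' `[g_min, g_max]` and at most one per synapse leaves its floor.
#'
#' @param W weight matrix with values in \[-1, 1\].
#' @param map a [conductance_map].
#' @return single scheme: a conductance matrix; differential scheme: a list
#'   `list(g_plus, g_minus)`.
#' @export
weights_to_conductance <- function(W, map) {
  if (any(W < -1 | W > 1)) stop("weights must lie in [-1, 1]")
  span <- map$g_max - map$g_min
  if (map$scheme == "single") {
    W * span / 2 + (map$g_max + map$g_min) / 2
  } else {
    list(g_plus = map$g_min + pmax(W, 0) * span,
         g_minus = map$g_min - pmin(W, 0) * span)
  }
}

#' Invert a conductance export back to weights
#'
#' Exact inverse of [weights_to_conductance] (to floating-point precision).
#'
#' @param G a conductance matrix (single scheme) or `list(g_plus, g_minus)`.
#' @param map the [conductance_map] used for export.
#' @return the weight matrix.
#' @export
conductance_to_weights <- function(G, map) {
  span <- map$g_max - map$g_min
  if (map$scheme == "single") {
    (2 * G - (map$g_max + map$g_min)) / span
  } else {
    (G$g_plus - G$g_minus) / span
  }
}

#' Export a trained network as a crossbar conductance CSV with JSON sidecar
#'
#' @param state a trained `snn_network`.
#' @param map a [conductance_map].
#' @param path CSV output path (differential scheme writes `<path>` for G+
#'   and a second file suffixed `_gminus.csv`); a JSON sidecar
#'   `<path>.json` records the scheme, bounds and prune mask.
#' @return `invisible(path)`.
#' @export
export_crossbar <- function(state, map, path) {
  G <- weights_to_conductance(state$W, map)
  if (map$scheme == "single") {
    utils::write.table(G, path, sep = ",", row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.table(G$g_plus, path, sep = ",", row.names = FALSE, col.names = FALSE)
    utils::write.table(G$g_minus, sub("\\.csv$", "_gminus.csv", path),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  sidecar <- list(scheme = map$scheme, g_min = map$g_min, g_max = map$g_max,
                  m = nrow(state$W), n = ncol(state$W),
                  frozen = which(state$prune_mask) - 1L)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
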