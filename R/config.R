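#' Default analysis configuration
#'
#' Returns the full set of tunable parameters used by [extract_features()]
#' and [run_pipeline()]: analysis frequency bands, FIR and median filter
#' orders, matched-filter template shape, surface thresholds, entropy
#' parameters, multiscale depth, connectivity estimator settings, and
#' cross-validation settings. Any element can be overridden by passing a
#' named list of replacements.
#'
#' @param ... named overrides, e.g. `default_config(tau_max = 5)` or
#'   `default_config(entropy = list(c = 5))` (partial lists are merged).
#' @return A nested named list.
#' @export
#' @examples
#' cfg <- default_config(tau_max = 5)
#' cfg$tau_max
default_config <- function(...) {
  cfg <- list(
    fs = 240,                      # Hz
    duration = 42,                 # s, paper-faithful recording length
    min_duration = 42,             # s, recordings below this are excluded
    bands = list(low = c(0.08, 5), high = c(5, 25), wide = c(0.08, 25)),
    fir_order = 200,
    median_order = 200,
    blink = list(threshold_mad = 5, max_blink = 0.5, flank_s = 0.05,
                 return_frac = 0.1),
    template = list(hold_s = 1.5, rise_s = 0.05, min_separation = 1.3,
                    select = "temporal", n_extrema = 4),
    threshold = 0.35,              # surface thresholds at +/- this value
    entropy = list(m = 2, c = 6, d = 1, r = 0.2, fuzzy_power = 2, kmax = 10),
    tau_max = 10,
    connectivity = list(n_bins = 10, seg_s = 4, overlap = 0.5,
                        max_order = 20),
    cv = list(k_folds = 10, variance_target = 0.95, cost = 1),
    channel_mode = "mean"          # average left/right features ("mean"|"left"|"right")
  )
  modifyList(cfg, list(...))
}
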