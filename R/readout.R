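#' MGMT observation-model parameters
#'
#' The observable resistance channel is bulk MGMT expression reported as a
#' fold-change over the untreated (pure sensitive) baseline, as in qPCR.
#' A resistant cell expresses `alpha` times the sensitive per-cell level;
#' a transient-state (persister) cell expresses `c_tr` times that level
#' (default 0: single-cell data place MGMT onset in the emerging resistant
#' cells, not in the persister pool).
#'
#' @param alpha per-cell MGMT expression of a resistant cell relative to a
#'   sensitive cell; unitless, >= 1.
#' @param c_tr relative per-cell MGMT expression of a transient-state cell;
#'   unitless in `[0, alpha]`.
#' @param normalize_to_baseline logical; kept for interface completeness,
#'   the readout is always expressed relative to the sensitive baseline.
#' @param mode `"average"` (default): population-average per-cell
#'   expression, the bulk-qPCR analogue. `"total"`: total expression of the
#'   population divided by the baseline total of `baseline_n` sensitive
#'   cells (average times population size).
#' @param baseline_n baseline population size, required for `mode = "total"`.
#' @return an object of class `readout_params`.
#' @export
readout_params <- function(alpha = 20, c_tr = 0, normalize_to_baseline = TRUE,
                           mode = c("average", "total"), baseline_n = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(alpha) || alpha < 1) stop("alpha must be >= 1", call. = FALSE)
  if (!is.numeric(c_tr) || c_tr < 0 || c_tr > alpha) {
    stop("c_tr must lie in [0, alpha]", call. = FALSE)
  }
  if (mode == "total" && (is.null(baseline_n) || baseline_n <= 0)) {
    stop("mode = 'total' requires a positive baseline_n", call. = FALSE)
  }
  structure(list(alpha = as.numeric(alpha), c_tr = as.numeric(c_tr),
                 normalize_to_baseline = isTRUE(normalize_to_baseline),
                 mode = mode, baseline_n = baseline_n),
            class = "readout_params")
}

#' Bulk MGMT fold-change of a mixed population
#'
#' Population-average per-cell MGMT expression relative to a pure sensitive
#' population: `(S + c_tr * TR + alpha * R) / (S + TR + R)`. Equals 1 for a
#' pure sensitive population and `alpha` for a pure resistant one, and is
#' monotone non-decreasing in the resistant fraction. With
#' `mode = "total"` the numerator is instead divided by `baseline_n`.
#'
#' @param S,TR,R compartment sizes (cells, >= 0); vectors are recycled to a
#'   common length.
#' @param params a [readout_params()] object.
#' @return unitless fold-change vector.
#' @examples
#' mgmt_readout(50, 0, 50, readout_params(alpha = 21))  # (1 + 21) / 2 = 11
#' @export
mgmt_readout <- function(S, TR, R, params = readout_params()) {
  stopifnot(inherits(params, "readout_params"))
  n <- max(length(S), length(TR), length(R))
  S <- rep_len(as.numeric(S), n); TR <- rep_len(as.numeric(TR), n)
  R <- rep_len(as.numeric(R), n)
  if (any(S < 0 | TR < 0 | R < 0)) {
    stop("compartment sizes must be non-negative", call. = FALSE)
  }
  total <- S + TR + R
  if (any(total <= 0)) {
    stop("mgmt_readout undefined for an empty population", call. = FALSE)
  }
  expr <- S + params$c_tr * TR + params$alpha * R
  if (params$mode == "average") expr / total else expr / params$baseline_n
}
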