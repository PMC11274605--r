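#' Default PISA temperature gradient
#'
#' The eight-point heat-treatment gradient used to generate the pooled
#' solubility-integral (PISA) sample. Aliquots are heated for 3 minutes at
#' each temperature and equal volumes of the soluble fractions are combined
#' into a single pooled sample, so the measured PISA abundance is the
#' unweighted mean of the per-temperature soluble abundances.
#'
#' @param temperatures Numeric vector of temperatures in degrees Celsius,
#'   strictly increasing. Defaults to the standard eight-point gradient.
#' @return A numeric vector of class `"pisa_gradient"`.
#' @examples
#' pisa_gradient()
#' pisa_gradient(seq(40, 60, by = 5))
#' @export
pisa_gradient <- function(temperatures = c(39.4, 43.8, 47.1, 51, 53.4,
                                           55.4, 57.9, 61.4)) {
  if (length(temperatures) == 0) {
    stop("temperature gradient is empty", call. = FALSE)
  }
  if (!is.numeric(temperatures) || anyNA(temperatures)) {
    stop("temperatures must be numeric and non-missing", call. = FALSE)
  }
  if (any(diff(temperatures) <= 0)) {
    stop("temperatures must be strictly increasing", call. = FALSE)
  }
  structure(as.numeric(temperatures), class = "pisa_gradient")
}

#' Two-state melting parameters for a proteoform
#'
#' Describes a proteoform's melting behaviour as a two-state sigmoid: the
#' soluble fraction at temperature `t` is
#' `plateau + (1 - plateau) / (1 + exp(slope * (t - tm_eff)))`, where
#' `tm_eff = tm + delta_tm` under treatment. `delta_tm > 0` means the
#' treatment stabilizes the proteoform (melts at higher temperature).
#'
#' @param tm Melting midpoint in degrees Celsius.
#' @param slope Steepness of the melting transition (1/degree C), positive.
#' @param plateau Residual soluble fraction at high temperature, in `[0, 1)`.
#' @param delta_tm Treatment-induced midpoint shift in degrees Celsius
#'   (may be negative).
#' @return A list of class `"melt_params"`.
#' @examples
#' melt_params(tm = 50, delta_tm = 3)
#' @export
melt_params <- function(tm, slope = 0.3, plateau = 0.02, delta_tm = 0) {
  stopifnot(is.numeric(tm), length(tm) == 1L, is.finite(tm))
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope) ||
      slope <= 0) {
    stop("slope must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(plateau) || length(plateau) != 1L || plateau < 0 ||
      plateau >= 1) {
    stop("plateau must lie in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(delta_tm) || length(delta_tm) != 1L || !is.finite(delta_tm)) {
    stop("delta_tm must be a single finite number", call. = FALSE)
  }
  structure(list(tm = tm, slope = slope, plateau = plateau,
                 delta_tm = delta_tm),
            class = "melt_params")
}

#' Soluble fraction of a proteoform at a given temperature
#'
#' Evaluates the two-state sigmoid melting curve. The fraction decreases
#' monotonically with temperature from 1 (fully soluble) towards the
#' residual `plateau`; at the effective midpoint the non-plateau population
#' is half melted.
#'
#' @param t Temperature(s) in degrees Celsius (vectorized).
#' @param params A [melt_params()] object.
#' @param treated Logical; if `TRUE` the midpoint is shifted by
#'   `params$delta_tm`.
#' @return Soluble fraction(s) in `[plateau, 1]`.
#' @examples
#' soluble_fraction(50, melt_params(tm = 50, plateau = 0))  # 0.5
#' @export
soluble_fraction <- function(t, params, treated = FALSE) {
  if (!inherits(params, "melt_params")) {
    params <- do.call(melt_params, as.list(params))
  }
  tm_eff <- params$tm + if (isTRUE(treated)) params$delta_tm else 0
  params$plateau + (1 - params$plateau) /
    (1 + exp(params$slope * (t - tm_eff)))
}

#' Pooled solubility-integral (PISA) abundance
#'
#' The PISA readout for a proteoform: equal volumes of the soluble fraction
#' at each gradient temperature are pooled into one sample, so the pooled
#' abundance is the unheated abundance times the unweighted mean of the
#' soluble fractions over the gradient. It is linear in `a`, bounded by
#' `plateau * a` and `a`, and strictly increasing in the effective midpoint.
#'
#' @param a Unheated (global) abundance, non-negative. Vectorized.
#' @param params A [melt_params()] object.
#' @param gradient A [pisa_gradient()] (default: the standard 8 temperatures).
#' @param treated Logical; apply the treatment midpoint shift.
#' @return Pooled soluble abundance, same length as `a`.
#' @examples
#' pisa_value(100, melt_params(tm = 50))
#' @export
pisa_value <- function(a, params, gradient = pisa_gradient(),
                       treated = FALSE) {
  if (!inherits(gradient, "pisa_gradient")) gradient <- pisa_gradient(gradient)
  if (any(a < 0)) stop("abundance must be non-negative", call. = FALSE)
  a * mean(soluble_fraction(gradient, params, treated = treated))
}
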