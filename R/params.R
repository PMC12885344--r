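#' Model parameters for the dynamic confidence drift-diffusion model
#'
#' Bundles the eight free parameters of the model together with the fixed
#' accumulation noise. Pre-decisional evidence accumulates from `start`
#' towards absorbing bounds at 0 and `bound` with drift `stimulus * drift`
#' and noise `sigma` (fixed at 1 by convention, since it trades off with the
#' drift and bound). After the bound is hit, evidence keeps accumulating at
#' the post-decisional drift `v_ratio * stimulus * drift + choice * v_bias`
#' for the duration of the confidence response time, and the final evidence
#' is mapped to a confidence report in (0, 1) by a logistic transform with
#' additive criterion shift `a_bias` and multiplicative slope `m_bias`.
#'
#' @param drift Pre-decisional drift-rate magnitude (evidence units / s)
#'   towards the correct bound.
#' @param bound Upper decision bound (evidence units); the lower bound is 0.
#' @param start Starting point of accumulation, strictly between 0 and
#'   `bound`. Defaults to the unbiased midpoint `bound / 2`.
#' @param ndt Nondecision time (s), added to the first-passage time.
#' @param v_ratio Post- over pre-decisional drift ratio (dimensionless); a
#'   dynamic measure of metacognitive efficiency, typically in (0, 1).
#' @param v_bias Decision-contingent additive bias of the post-decisional
#'   drift (evidence units / s); negative values accumulate evidence against
#'   the decision just made (accumulative distortion).
#' @param a_bias Additive shift of the confidence criterion (evidence
#'   units); positive values produce underconfidence.
#' @param m_bias Multiplicative slope of the logistic evidence-to-confidence
#'   mapping; must be positive.
#' @param sigma Accumulation noise (evidence units / sqrt(s)), fixed at 1
#'   unless explicitly overridden for testing.
#'
#' @return An object of class `model_params` (a named list).
#' @examples
#' p <- model_params(drift = 1, bound = 2, v_ratio = 0.8, v_bias = -0.3)
#' p
#' @export
model_params <- function(drift = 1, bound = 2, start = bound / 2, ndt = 0.3,
                         v_ratio = 0.8, v_bias = 0, a_bias = 0, m_bias = 1,
                         sigma = 1) {
  p <- structure(list(drift = drift, bound = bound, start = start, ndt = ndt,
                      v_ratio = v_ratio, v_bias = v_bias, a_bias = a_bias,
                      m_bias = m_bias, sigma = sigma),
                 class = "model_params")
  validate_model_params(p)
  p
}

#' Validate a `model_params` object
#'
#' @param p A `model_params` object (or named list with the same fields).
#' @return `p` invisibly; throws an informative error on any violated
#'   invariant (non-finite values, `bound <= 0`, `start` outside
#'   `(0, bound)`, negative `ndt`, non-positive `m_bias` or `sigma`).
#' @export
validate_model_params <- function(p) {
  need <- c("drift", "bound", "start", "ndt", "v_ratio", "v_bias",
            "a_bias", "m_bias", "sigma")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("missing model parameters: ", paste(miss, collapse = ", "))
  vals <- unlist(p[need], use.names = TRUE)
  if (!is.numeric(vals) || any(!is.finite(vals)))
    stop("model parameters must all be finite numbers")
  if (p$bound <= 0) stop("bound must be positive")
  if (p$start <= 0 || p$start >= p$bound)
    stop("start must lie strictly between 0 and bound")
  if (p$ndt < 0) stop("nondecision time must be non-negative")
  if (p$m_bias <= 0) stop("m_bias must be positive")
  if (p$sigma <= 0) stop("sigma must be positive")
  invisible(p)
}

# Fixed layout used by the compiled simulator.
par_vector <- function(p) {
  validate_model_params(p)
  c(p$drift, p$bound, p$start, p$ndt, p$v_ratio, p$v_bias, p$a_bias,
    p$m_bias, p$sigma)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Dynamic confidence DDM parameters\n")
  cat(sprintf("  pre-decision : drift=%.4g bound=%.4g start=%.4g ndt=%.4g s\n",
              x$drift, x$bound, x$start, x$ndt))
  cat(sprintf("  post-decision: v_ratio=%.4g v_bias=%.4g\n", x$v_ratio, x$v_bias))
  cat(sprintf("  confidence   : a_bias=%.4g m_bias=%.4g  (sigma=%.4g)\n",
              x$a_bias, x$m_bias, x$sigma))
  invisible(x)
}
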