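#' Controller gains and learning parameters
#'
#' One adaptive fuzzy controller drives each muscle.  Its critics are
#' `re = h1 e + h2 edot + h3 int(e)` (weighted kinematic error composite,
#' error in mm) and `r_alpha = |alpha|` (activation penalty), combined in the
#' cost `E = 1/2 ke re^2 + 1/2 kalpha alpha^2`.  The consequent weights are
#' updated every control step by steepest descent,
#' `dw_i = eta (ke h1 re j - kalpha r_alpha) dalpha/dw_i`.
#'
#' @param h1,h2,h3 Error, error-rate and error-integral coefficients.
#' @param kalpha Activation-penalty weight.
#' @param ke Kinematic-error weights per level L1..L5 (top first).  The
#'   decreasing profile prioritises the upper levels.
#' @param eta Learning rate per control step.  Not reported for the original
#'   controller; the default is tuned once so that tracking stays within the
#'   2 mm learning bound and converges in roughly 20 s (see the vignette).
#' @param windup_mm_s Anti-windup clamp on the error integral (mm s).
#' @return A list of class `controller_gains`.
#' @export
controller_gains <- function(h1 = 2, h2 = 2, h3 = 2, kalpha = 0.2,
                             ke = c(15, 7, 2.5, 1, 0.1), eta = 1e-4,
                             windup_mm_s = 50) {
  stopifnot(h1 >= 0, h2 >= 0, h3 >= 0, kalpha >= 0, all(ke >= 0), eta > 0,
            windup_mm_s > 0)
  structure(
    list(h1 = h1, h2 = h2, h3 = h3, kalpha = kalpha, ke = ke, eta = eta,
         windup_mm_s = windup_mm_s),
    class = "controller_gains"
  )
}

#' Fuzzy network architecture
#'
#' Zero-order Takagi-Sugeno network: a `n x n` grid of Gaussian memberships
#' over the normalized `(e, edot)` plane (inputs clipped to `[-1, 1]` after
#' normalization, so the family always covers the domain), one scalar
#' consequent weight per rule, output the normalized weighted sum clipped to
#' `[0, 1]`.  The weight sensitivity needed by the steepest-descent update is
#' `dalpha/dw_i = mu_i / sum(mu)`.
#'
#' @param n Rules per axis.
#' @param sigma Gaussian width (in normalized units); defaults to the grid
#'   spacing.
#' @param norm_e_mm,norm_edot_mm_s Normalization constants for the error and
#'   error-rate inputs.
#' @return A list of class `fuzzy_network`.
#' @export
fuzzy_network <- function(n = 7L, sigma = NULL, norm_e_mm = 2,
                          norm_edot_mm_s = 20) {
  n <- as.integer(n)
  stopifnot(n >= 2L, norm_e_mm > 0, norm_edot_mm_s > 0)
  centers <- seq(-1, 1, length.out = n)
  if (is.null(sigma)) sigma <- centers[2] - centers[1]
  structure(
    list(n = n, centers = centers, sigma = sigma, norm_e_mm = norm_e_mm,
         norm_edot_mm_s = norm_edot_mm_s),
    class = "fuzzy_network"
  )
}

#' Evaluate a fuzzy controller unit
#'
#' Returns the activation together with the normalized firing strengths
#' `mu_i / sum(mu)` (the exact weight gradient of the unclipped output).
#'
#' @param weights Consequent weight vector (`n^2` rules).
#' @param e_mm Position error (target - actual lateral coordinate), mm.
#' @param edot_mm_s Error rate, mm/s.
#' @param net A [fuzzy_network()].
#' @return List with `alpha` (clipped), `alpha_raw` and `mu_norm`.
#' @export
#' @examples
#' net <- fuzzy_network()
#' fuzzy_activation(rep(0.3, 49), e_mm = 0.5, edot_mm_s = -1, net = net)$alpha
fuzzy_activation <- function(weights, e_mm, edot_mm_s, net = fuzzy_network()) {
  stopifnot(length(weights) == net$n^2)
  out <- cpp_fuzzy_eval(weights, e_mm, edot_mm_s, net$centers, net$sigma,
                        net$norm_e_mm, net$norm_edot_mm_s)
  out$mu_norm <- as.numeric(out$mu_norm)
  out
}

#' Critic signals of one controller
#'
#' Computes `e`, `edot`, the rectangle-rule error integral and the composite
#' critic `re = h1 e + h2 edot + h3 int(e)`; the target posture is
#' stationary, so `edot = -Zdot`.
#'
#' @param target_z_mm,actual_z_mm Target and actual lateral coordinate (mm).
#' @param actual_zdot_mm_s Actual lateral velocity (mm/s).
#' @param int_e_mm_s Error integral carried from the previous step (mm s).
#' @param dt Control step (s).
#' @param gains A [controller_gains()].
#' @return List with `e`, `edot`, `int_e` (updated, anti-windup clamped) and
#'   `re`.
#' @export
compute_error_signals <- function(target_z_mm, actual_z_mm, actual_zdot_mm_s,
                                  int_e_mm_s = 0, dt = 1e-3,
                                  gains = controller_gains()) {
  stopifnot(dt > 0)
  e <- target_z_mm - actual_z_mm
  edot <- -actual_zdot_mm_s
  int_e <- max(-gains$windup_mm_s,
               min(gains$windup_mm_s, int_e_mm_s + e * dt))
  re <- gains$h1 * e + gains$h2 * edot + gains$h3 * int_e
  list(e = e, edot = edot, int_e = int_e, re = re)
}

#' Steepest-descent weight update of one controller
#'
#' `w_i <- w_i + eta (ke h1 re j - kalpha |alpha|) mu_i / sum(mu)`, applied
#' every control step; weights are not clamped (activation clipping handles
#' the output range).
#'
#' @param weights Current weight vector.
#' @param mu_norm Normalized firing strengths from [fuzzy_activation()].
#' @param re Composite error critic.
#' @param alpha Current activation (its magnitude is the second critic).
#' @param jsign Jacobian sign of the muscle.
#' @param ke Error weight of the muscle's level.
#' @param gains A [controller_gains()].
#' @return Updated weight vector.
#' @export
update_weights <- function(weights, mu_norm, re, alpha, jsign, ke,
                           gains = controller_gains()) {
  weights + gains$eta * (ke * gains$h1 * re * jsign -
                           gains$kalpha * abs(alpha)) * mu_norm
}
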