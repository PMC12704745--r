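#' Wiener first-passage-time density
#'
#' Density of the first-passage time at the named boundary of a Wiener
#' diffusion with diffusion scale 1, boundaries 0 and `a`, relative start
#' point `w` and drift `v`, shifted by the nondecision time `t0` (the density
#' is 0 for `t <= t0`). Evaluated with the small-time and large-time series
#' expansions, switching automatically to whichever needs fewer terms for a
#' truncation error below `err`.
#'
#' @param t evaluation times in seconds (vectorised).
#' @param boundary `"upper"` or `"lower"`.
#' @param v drift rate; positive drifts toward the upper boundary.
#' @param a boundary separation (> 0).
#' @param w relative start point in (0, 1).
#' @param t0 nondecision time (s).
#' @param err series truncation error bound.
#' @return nonnegative density values.
#' @export
wiener_fpt_density <- function(t, boundary = c("upper", "lower"),
                               v, a, w = 0.5, t0 = 0, err = 1e-7) {
  boundary <- match.arg(boundary)
  if (a <= 0 || w <= 0 || w >= 1 || t0 < 0) {
    abort("require a > 0, 0 < w < 1, t0 >= 0.", class = "metaown_config_error")
  }
  .dwiener_cpp(as.numeric(t), a, v, w, t0, boundary == "upper", err)
}

#' Probability of absorption at the upper boundary
#'
#' Closed form for the Wiener diffusion with scale 1:
#' \deqn{P(upper) = \frac{1 - e^{-2 v a w}}{1 - e^{-2 v a}},}
#' with the zero-drift limit `P(upper) = w` handled analytically.
#'
#' @inheritParams wiener_fpt_density
#' @return probability in `[0, 1]`.
#' @export
choice_probability <- function(v, a, w = 0.5) {
  if (a <= 0 || w <= 0 || w >= 1) {
    abort("require a > 0 and 0 < w < 1.", class = "metaown_config_error")
  }
  if (abs(v) < 1e-9) return(w)
  # mirror negative drift onto the stable positive-drift expression
  if (v < 0) return(1 - choice_probability(-v, a, 1 - w))
  expm1(-2 * v * a * w) / expm1(-2 * v * a)
}
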