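#' Direct component of a cluster
#'
#' The direct component (DC) is a piecewise-Gaussian temporal activation
#' profile derived straight from a cluster's pooled (onset, offset) phase
#' statistics, in contrast to activation waveforms obtained by matrix
#' decomposition. The profile peaks at the mid-phase
#' `Z = (X + Y) / 2` with rising-side width `sigma1 = (Z - X)/3 + sX` and
#' falling-side width `sigma2 = (Y - Z)/3 + sY`; activation is assumed to span
#' `(X - 3 sX, Y + 3 sY)`, reported as metadata (tails are not truncated).
#'
#' @param pooled list with elements `X`, `sX`, `Y`, `sY` (a cluster's pooled
#'   stats) — `Y > X` required.
#' @param cluster_id integer id carried along for labelling.
#' @param amplitude unitless peak scale (default 1).
#' @return object of class `direct_component` with elements `cluster_id`, `Z`,
#'   `sigma1`, `sigma2`, `support`, `amplitude`.
#' @examples
#' dc <- direct_component(list(X = 0.1, Y = 0.3, sX = 0.03, sY = 0.03))
#' dc$Z       # 0.2
#' dc$sigma1  # 0.0633...
#' @export
direct_component <- function(pooled, cluster_id = NA_integer_, amplitude = 1) {
  X <- pooled$X; Y <- pooled$Y
  sX <- pooled$sX; sY <- pooled$sY
  if (Y <= X) stop("invalid cluster: pooled offset must exceed pooled onset")
  if (amplitude < 0) stop("amplitude must be non-negative")
  Z <- (X + Y) / 2
  structure(
    list(
      cluster_id = cluster_id,
      Z = Z,
      sigma1 = (Z - X) / 3 + sX,
      sigma2 = (Y - Z) / 3 + sY,
      support = c(X - 3 * sX, Y + 3 * sY),
      amplitude = amplitude
    ),
    class = "direct_component"
  )
}

#' Evaluate a direct component at given phases
#'
#' `amplitude * exp(-(t - Z)^2 / (2 sigma^2))` with `sigma = sigma1` on the
#' rising side (`t < Z`) and `sigma2` on the falling side; continuous at `Z`
#' where it equals `amplitude`. `mode = "literal"` divides by `2 sigma`
#' instead of `2 sigma^2` (the non-squared denominator); the squared form is
#' the default since it makes the basis function a proper Gaussian in phase
#' units.
#'
#' @param dc a [direct_component()].
#' @param t phase(s) at which to evaluate.
#' @param mode `"squared"` (default) or `"literal"`.
#' @return activation values in `[0, amplitude]`.
#' @export
evaluate_dc <- function(dc, t, mode = c("squared", "literal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dc, "direct_component"))
  s <- ifelse(t < dc$Z, dc$sigma1, dc$sigma2)
  denom <- if (mode == "squared") 2 * s^2 else 2 * s
  dc$amplitude * exp(-(t - dc$Z)^2 / denom)
}

#' @export
print.direct_component <- function(x, ...) {
  cat(sprintf(
    "direct_component #%s: Z=%.4f sigma1=%.4f sigma2=%.4f amp=%.3f support=(%.4f, %.4f)\n",
    x$cluster_id, x$Z, x$sigma1, x$sigma2, x$amplitude, x$support[1], x$support[2]))
  invisible(x)
}

#' Correlated bivariate-normal cluster ellipse
#'
#' In standardized coordinates `u = (x - X)/sX`, `v = (y - Y)/sY` the 1-SD
#' contour of the correlated bivariate normal is
#' `u^2 + v^2 - 2 u v rho = 1 - rho^2`. For `rho = 0` this is the axis-aligned
#' 1-SD ellipse; non-zero `rho` skews it while keeping it inscribed in the
#' +/-1 SD rectangle.
#'
#' @param center numeric length-2, cluster centroid `(X, Y)`.
#' @param axes_sd numeric length-2, `(sX, sY)`, both > 0.
#' @param rho correlation, `|rho| < 1`.
#' @return object of class `cluster_ellipse`.
#' @export
cluster_ellipse <- function(center, axes_sd, rho = 0) {
  if (abs(rho) >= 1) stop("degenerate ellipse: |rho| must be < 1")
  if (any(axes_sd <= 0)) stop("axes_sd must be positive")
  structure(list(center = as.numeric(center), axes_sd = as.numeric(axes_sd),
                 rho = rho),
            class = "cluster_ellipse")
}

#' Points on the cluster ellipse boundary
#'
#' Uses the exact parameterization `u = cos(theta)`,
#' `v = rho cos(theta) + sqrt(1 - rho^2) sin(theta)`, which satisfies the
#' boundary equation identically, then maps back to phase coordinates.
#'
#' @param e a [cluster_ellipse()].
#' @param m number of points (>= 8), uniform in the angle parameter.
#' @return data.frame with columns `x`, `y`.
#' @export
ellipse_points <- function(e, m = 200) {
  stopifnot(inherits(e, "cluster_ellipse"))
  if (m < 8) stop("m must be at least 8")
  theta <- seq(0, 2 * pi, length.out = m + 1L)[-(m + 1L)]
  u <- cos(theta)
  v <- e$rho * cos(theta) + sqrt(1 - e$rho^2) * sin(theta)
  data.frame(x = e$center[1L] + e$axes_sd[1L] * u,
             y = e$center[2L] + e$axes_sd[2L] * v)
}

#' Tangency points of the ellipse with the +/-1 SD rectangle
#'
#' The boundary touches the encompassing +/-1 SD rectangle exactly at the
#' standardized points `(u, v) = (+/-1, +/-rho)` and `(+/-rho, +/-1)` with
#' matching signs; these are returned in phase coordinates.
#'
#' @param e a [cluster_ellipse()].
#' @return data.frame with columns `u`, `v`, `x`, `y` (four rows).
#' @export
ellipse_tangency <- function(e) {
  stopifnot(inherits(e, "cluster_ellipse"))
  uv <- rbind(
    c(1, e$rho), c(-1, -e$rho),
    c(e$rho, 1), c(-e$rho, -1)
  )
  data.frame(
    u = uv[, 1L], v = uv[, 2L],
    x = e$center[1L] + e$axes_sd[1L] * uv[, 1L],
    y = e$center[2L] + e$axes_sd[2L] * uv[, 2L]
  )
}

#' Analytic area of the cluster ellipse
#'
#' `pi * sX * sY * sqrt(1 - rho^2)` in squared phase units.
#'
#' @param e a [cluster_ellipse()].
#' @return area.
#' @export
ellipse_area <- function(e) {
  stopifnot(inherits(e, "cluster_ellipse"))
  pi * e$axes_sd[1L] * e$axes_sd[2L] * sqrt(1 - e$rho^2)
}

#' Direct components for every cluster of a solution
#'
#' @param solution a `cluster_solution`.
#' @return list of [direct_component()] objects, one per cluster.
#' @export
solution_dcs <- function(solution) {
  stopifnot(inherits(solution, "cluster_solution"))
  lapply(solution$clusters, function(cl) {
    direct_component(cl$pooled, cluster_id = cl$id)
  })
}

#' Sampled direct-component profiles of a solution
#'
#' Evaluates every cluster's DC on a uniform grid (default 1000 points over
#' phases -0.5 to 1.5, covering pre-reference activity and the full cycle).
#'
#' @param solution a `cluster_solution`.
#' @param grid phases at which to evaluate.
#' @param mode exponent convention, see [evaluate_dc()].
#' @param prefix column-name prefix (e.g. a condition name).
#' @return data.frame with `phase` plus one column per cluster.
#' @export
dc_profiles <- function(solution, grid = seq(-0.5, 1.5, length.out = 1000),
                        mode = "squared", prefix = "u") {
  dcs <- solution_dcs(solution)
  out <- data.frame(phase = grid)
  for (dc in dcs) {
    out[[sprintf("%s%d", prefix, dc$cluster_id)]] <- evaluate_dc(dc, grid, mode = mode)
  }
  out
}
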