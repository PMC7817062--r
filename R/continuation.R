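#' Steady states of the scalar switch kinetics by brute-force root scanning
#'
#' Finds all roots of \eqn{f(X)(X_T - X) - g(X) X = 0} in \eqn{[0, X_T]} by
#' a dense sign-change scan followed by bisection refinement. This is the
#' slow-but-transparent oracle against which the continuation tracer is
#' checked; it is also used to seed the tracer.
#'
#' @param params a [feedback_params()] object.
#' @param a_value basal activation rate.
#' @param X_T total protein concentration, \eqn{\ge 0}.
#' @param grid_n number of scan points (at least 2000 by default).
#' @return A data.frame with columns `X` and `stable` (logical), ordered by
#'   `X`. Stability is the sign of \eqn{\partial F/\partial X}: negative
#'   means stable (the system is one-dimensional in `X`).
#' @examples
#' steady_states(feedback_params(), a_value = 0.3, X_T = 2)
#' @export
steady_states <- function(params, a_value = params$a, X_T, grid_n = 2001) {
  stopifnot(X_T >= 0)
  if (X_T == 0) {
    return(data.frame(X = 0, stable = switch_residual_dX(0, 0, params, a_value) < 0))
  }
  xs <- seq(0, X_T, length.out = max(grid_n, 2000L))
  Fv <- switch_residual(xs, X_T, params, a_value)
  roots <- xs[Fv == 0]
  sc <- which(Fv[-1] * Fv[-length(Fv)] < 0)
  for (i in sc) {
    r <- uniroot(function(x) switch_residual(x, X_T, params, a_value),
                 lower = xs[i], upper = xs[i + 1], tol = 1e-13)
    roots <- c(roots, r$root)
  }
  roots <- sort(unique(roots))
  data.frame(X = roots,
             stable = switch_residual_dX(roots, X_T, params, a_value) < 0)
}

# Partial of the residual with respect to the continued parameter.
residual_dp <- function(vary, X, p, params, a_value, X_T_fixed) {
  if (vary == "X_T") switch_residual_dXT(X, p, params, a_value)
  else switch_residual_da(X, X_T_fixed, params, p)
}

residual_val <- function(vary, X, p, params, a_value, X_T_fixed) {
  if (vary == "X_T") switch_residual(X, p, params, a_value)
  else switch_residual(X, X_T_fixed, params, p)
}

residual_dX <- function(vary, X, p, params, a_value, X_T_fixed) {
  if (vary == "X_T") switch_residual_dX(X, p, params, a_value)
  else switch_residual_dX(X, X_T_fixed, params, p)
}

#' Trace a steady-state response curve by pseudo-arclength continuation
#'
#' Follows the branch of steady states of the scalar kinetics as one
#' parameter (total protein `X_T`, or the basal rate `a` at fixed `X_T`)
#' varies, using a secant predictor and a Newton corrector on the extended
#' system (residual plus arclength constraint). Folded (bistable) segments
#' are traversed; the parameter's direction of travel reverses at each
#' saddle node. Step length adapts by halving on corrector failure and
#' growing on fast convergence, within `[1e-5, 1e-1]`.
#'
#' @param params a [feedback_params()] object.
#' @param vary which parameter to vary: `"X_T"` or `"a"`.
#' @param range numeric length-2; the parameter interval to cover. May
#'   include negative values when `vary = "a"` (the left fold of a strongly
#'   irreversible switch sits at negative `a`).
#' @param a_value basal rate held fixed when `vary = "X_T"`.
#' @param X_T total protein held fixed when `vary = "a"`.
#' @param step initial arclength step.
#' @param max_points safety cap on the number of continuation points.
#' @return An object of class `"response_curve"`: a data.frame with columns
#'   `parameter`, `X`, `stable`, with attributes `vary`, `params`,
#'   `a_value`/`X_T_fixed` and `saddle_nodes` (see [find_saddle_nodes()]).
#'   Every point satisfies the steady-state equation to better than 1e-8.
#' @examples
#' rc <- trace_response_curve(feedback_params(), vary = "X_T",
#'                            range = c(0, 4), a_value = 0.3)
#' attr(rc, "saddle_nodes")
#' @export
trace_response_curve <- function(params, vary = c("X_T", "a"), range,
                                 a_value = params$a, X_T = NULL,
                                 step = 1e-2, max_points = 50000L) {
  vary <- match.arg(vary)
  stopifnot(length(range) == 2L, range[2] > range[1])
  if (vary == "a" && is.null(X_T)) stop("X_T must be given when vary = 'a'")
  X_T_fixed <- X_T
  # Start where the branch is single-valued: at low X_T (lowest root) when
  # varying X_T; at the high-a end (highest root) when varying a, since the
  # low-activity branch need not exist at the left end (a may be negative).
  if (vary == "X_T") {
    p0 <- range[1]; dir <- 1
    x0 <- min(steady_states(params, a_value, max(p0, 0))$X)
  } else {
    p0 <- range[2]; dir <- -1
    xs <- seq(0, X_T_fixed, length.out = 2001)
    Fv <- switch_residual(xs, X_T_fixed, params, p0)
    sc <- which(Fv[-1] * Fv[-length(Fv)] < 0)
    if (length(sc) == 0)
      stop("no steady state found at the start of the range")
    j <- sc[length(sc)]
    x0 <- uniroot(function(x) switch_residual(x, X_T_fixed, params, p0),
                  lower = xs[j], upper = xs[j + 1], tol = 1e-13)$root
  }

  Fn  <- function(x, p) residual_val(vary, x, p, params, a_value, X_T_fixed)
  Fx  <- function(x, p) residual_dX(vary, x, p, params, a_value, X_T_fixed)
  Fp  <- function(x, p) residual_dp(vary, x, p, params, a_value, X_T_fixed)

  # polish the start point in x at fixed p
  for (i in 1:50) {
    fv <- Fn(x0, p0); if (abs(fv) < 1e-12) break
    x0 <- x0 - fv / Fx(x0, p0)
    x0 <- max(x0, 0)
  }

  h <- step; hmin <- 1e-5; hmax <- 5e-2
  pts_p <- numeric(0); pts_x <- numeric(0)
  pts_p[1] <- p0; pts_x[1] <- x0
  # second point: natural continuation a small step into the range
  p1 <- p0 + dir * h; x1 <- x0
  for (i in 1:50) {
    fv <- Fn(x1, p1); if (abs(fv) < 1e-12) break
    x1 <- x1 - fv / Fx(x1, p1)
  }
  pts_p[2] <- p1; pts_x[2] <- x1

  k <- 2L
  while (k < max_points) {
    tp <- pts_p[k] - pts_p[k - 1]; tx <- pts_x[k] - pts_x[k - 1]
    nrm <- sqrt(tp^2 + tx^2)
    tp <- tp / nrm; tx <- tx / nrm
    ok <- FALSE
    while (!ok) {
      pp <- pts_p[k] + h * tp; xp <- pts_x[k] + h * tx
      p <- pp; x <- xp
      conv <- FALSE
      for (it in 1:8) {
        r1 <- Fn(x, p)
        r2 <- tx * (x - xp) + tp * (p - pp)
        J11 <- Fx(x, p); J12 <- Fp(x, p)
        det <- J11 * tp - J12 * tx
        if (!is.finite(det) || abs(det) < 1e-14) break
        dx <- (r1 * tp - J12 * r2) / det
        dp <- (J11 * r2 - r1 * tx) / det
        x <- x - dx; p <- p - dp
        if (abs(r1) < 1e-10 && sqrt(dx^2 + dp^2) < 1e-11) { conv <- TRUE; break }
      }
      # reject corrector solutions that slid far from the predictor
      # (branch jumps across a narrow fold)
      drift <- sqrt((x - xp)^2 + (p - pp)^2)
      if (conv && abs(Fn(x, p)) < 1e-9 && drift <= 2 * h) {
        ok <- TRUE
      } else {
        h <- h / 2
        if (h < hmin)
          stop(sprintf(paste0("continuation failed to converge near ",
                              "parameter = %.6g, X = %.6g"),
                       pts_p[k], pts_x[k]))
      }
    }
    k <- k + 1L
    pts_p[k] <- p; pts_x[k] <- x
    if (it <= 3 && h < hmax) h <- min(h * 1.5, hmax)
    # stop once we leave the requested range heading outward, or when the
    # branch runs into the X = 0 boundary (it would continue at unphysical
    # negative concentrations)
    if ((p > range[2] && tp > 0) || (p < range[1] && tp < 0)) break
    if (x < 1e-4 && tx < 0) break
  }

  stable <- vapply(seq_len(k), function(i) Fx(pts_x[i], pts_p[i]) < 0, logical(1))
  curve <- data.frame(parameter = pts_p[seq_len(k)], X = pts_x[seq_len(k)],
                      stable = stable)
  attr(curve, "vary") <- vary
  attr(curve, "params") <- params
  attr(curve, "a_value") <- a_value
  attr(curve, "X_T_fixed") <- X_T_fixed
  class(curve) <- c("response_curve", "data.frame")
  attr(curve, "saddle_nodes") <- find_saddle_nodes(curve)
  curve
}

#' @export
print.response_curve <- function(x, ...) {
  sn <- attr(x, "saddle_nodes")
  cat(sprintf("Steady-state response curve vs %s: %d points, %d saddle node(s)\n",
              attr(x, "vary"), nrow(x), nrow(sn)))
  if (nrow(sn) > 0) {
    for (i in seq_len(nrow(sn)))
      cat(sprintf("  fold at %s = %.6g, X = %.6g\n",
                  attr(x, "vary"), sn$parameter[i], sn$X[i]))
  }
  invisible(x)
}

#' Locate and refine the saddle-node (fold) points of a response curve
#'
#' Folds are detected where the continued parameter's direction of travel
#' reverses along the curve, then refined by a Newton iteration on the
#' defining system \eqn{F = 0}, \eqn{\partial F/\partial X = 0}. A generic
#' fold count is 0 or 2 per S-shaped branch; both residuals at the refined
#' point are below 1e-8.
#'
#' @param curve a `"response_curve"` from [trace_response_curve()].
#' @return data.frame with columns `parameter` and `X`, one row per fold,
#'   ordered by `parameter`.
#' @export
find_saddle_nodes <- function(curve) {
  stopifnot(inherits(curve, "response_curve"), nrow(curve) >= 3)
  vary <- attr(curve, "vary"); params <- attr(curve, "params")
  a_value <- attr(curve, "a_value"); X_T_fixed <- attr(curve, "X_T_fixed")
  dp <- diff(curve$parameter)
  idx <- which(dp[-1] * dp[-length(dp)] < 0) + 1L  # interior reversal points
  out <- data.frame(parameter = numeric(0), X = numeric(0))
  hfd <- 1e-6
  for (i in idx) {
    x <- curve$X[i]; p <- curve$parameter[i]
    for (it in 1:60) {
      r1 <- residual_val(vary, x, p, params, a_value, X_T_fixed)
      r2 <- residual_dX(vary, x, p, params, a_value, X_T_fixed)
      J11 <- r2
      J12 <- residual_dp(vary, x, p, params, a_value, X_T_fixed)
      J21 <- (residual_dX(vary, x + hfd, p, params, a_value, X_T_fixed) -
              residual_dX(vary, x - hfd, p, params, a_value, X_T_fixed)) / (2 * hfd)
      J22 <- (residual_dX(vary, x, p + hfd, params, a_value, X_T_fixed) -
              residual_dX(vary, x, p - hfd, params, a_value, X_T_fixed)) / (2 * hfd)
      det <- J11 * J22 - J12 * J21
      if (!is.finite(det) || abs(det) < 1e-14) break
      dx <- (r1 * J22 - J12 * r2) / det
      dpp <- (J11 * r2 - r1 * J21) / det
      x <- x - dx; p <- p - dpp
      if (abs(r1) < 1e-11 && abs(r2) < 1e-11) break
    }
    r1 <- residual_val(vary, x, p, params, a_value, X_T_fixed)
    r2 <- residual_dX(vary, x, p, params, a_value, X_T_fixed)
    if (abs(r1) < 1e-8 && abs(r2) < 1e-8)
      out <- rbind(out, data.frame(parameter = p, X = x))
  }
  if (nrow(out) > 1) {
    # drop near-duplicates from dense reversals around the same fold
    out <- out[order(out$parameter), , drop = FALSE]
    keep <- c(TRUE, diff(out$parameter) > 1e-7 | abs(diff(out$X)) > 1e-7)
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Slice a response curve at a fixed parameter value
#'
#' Interpolates the traced branch at `value` of the continued parameter and
#' polishes each crossing by Newton iteration on the steady-state equation,
#' so the returned roots are exact to near machine precision. Used to
#' compare the continuation against brute-force root finding.
#'
#' @param curve a `"response_curve"`.
#' @param value parameter value at which to slice.
#' @return sorted numeric vector of steady-state `X` values on the curve at
#'   `value` (may be empty if the curve does not reach it).
#' @export
slice_response_curve <- function(curve, value) {
  vary <- attr(curve, "vary"); params <- attr(curve, "params")
  a_value <- attr(curve, "a_value"); X_T_fixed <- attr(curve, "X_T_fixed")
  pr <- curve$parameter
  d <- pr - value
  cross <- which(d[-1] * d[-length(d)] <= 0)
  if (length(cross) == 0) return(numeric(0))
  roots <- vapply(cross, function(j) {
    p1 <- pr[j]; p2 <- pr[j + 1]
    x <- if (abs(p2 - p1) < 1e-14) mean(curve$X[j:(j + 1)])
         else curve$X[j] + (value - p1) / (p2 - p1) * (curve$X[j + 1] - curve$X[j])
    for (it in 1:50) {
      fv <- residual_val(vary, x, value, params, a_value, X_T_fixed)
      if (abs(fv) < 1e-13) break
      dv <- residual_dX(vary, x, value, params, a_value, X_T_fixed)
      if (!is.finite(dv) || abs(dv) < 1e-12) break
      xn <- x - fv / dv
      if (!is.finite(xn)) break
      x <- max(xn, 0)
    }
    x
  }, numeric(1))
  roots <- sort(roots)
  roots[c(TRUE, diff(roots) > 1e-9)]
}

#' Saddle-node midpoint convention for the modulation threshold X_c
#'
#' The modulation midpoint `X_c` of the dynamic-switch law is defined as
#' the mean of the two saddle-node \eqn{X_T}-coordinates of the static
#' bistable switch at the centre rate `a_bar`.
#'
#' @param params a [feedback_params()] object.
#' @param a_bar the static basal rate.
#' @param X_T_max upper end of the continuation range used to locate folds.
#' @return X_c (concentration). Errors if the static switch is not bistable
#'   (monotone response: X_c is undefined).
#' @examples
#' midpoint_Xc(feedback_params(), a_bar = 0.3)
#' @export
midpoint_Xc <- function(params, a_bar = params$a,
                        X_T_max = 10 * max(params$K, params$K_prime)) {
  sn <- static_folds(params, a_bar, X_T_max)
  mean(sn$parameter)
}

# Folds of the static response curve vs X_T; errors when not bistable.
static_folds <- function(params, a_bar, X_T_max = 10 * max(params$K, params$K_prime)) {
  rc <- trace_response_curve(params, vary = "X_T", range = c(0, X_T_max),
                             a_value = a_bar)
  sn <- attr(rc, "saddle_nodes")
  if (nrow(sn) != 2)
    stop(sprintf(paste0("static switch at a = %g is not bistable ",
                        "(%d saddle nodes found); X_c and the event ",
                        "thresholds are undefined"), a_bar, nrow(sn)))
  sn[order(sn$parameter), , drop = FALSE]
}

#' Event-detection thresholds from the static switch's saddle nodes
#'
#' The up-crossing threshold is the vertical (X) coordinate of the left
#' saddle node (the upper knee of the S-curve), the down threshold the X
#' coordinate of the right saddle node (lower knee), and the transition
#' threshold their average. These conventions drive the period detector and
#' the stochastic transition-time measurements.
#'
#' @inheritParams midpoint_Xc
#' @return list with `up`, `down`, `transition`, and the fold table `folds`
#'   (columns `parameter` = \eqn{X_T}, `X`).
#' @examples
#' event_thresholds(feedback_params(), a_bar = 0.3)
#' @export
event_thresholds <- function(params, a_bar = params$a,
                             X_T_max = 10 * max(params$K, params$K_prime)) {
  sn <- static_folds(params, a_bar, X_T_max)
  up <- sn$X[1]     # left fold (smaller X_T): upper knee
  down <- sn$X[2]   # right fold: lower knee
  list(up = up, down = down, transition = (up + down) / 2, folds = sn)
}

#' Two-parameter bistable region by slice scanning
#'
#' For each value of the basal rate `a` on a grid, the response curve
#' versus \eqn{X_T} is traced and its saddle-node \eqn{X_T}-coordinates
#' collected; the assembled point set bounds the bistable region in the
#' \eqn{(X_T, a)} plane. Slices without folds contribute no boundary
#' points.
#'
#' @param params a [feedback_params()] object.
#' @param a_grid numeric vector of `a` values to slice at.
#' @param X_T_max continuation range upper end for each slice.
#' @return data.frame with columns `a`, `X_T_lo`, `X_T_hi` (one row per
#'   bistable slice), plus attribute `boundary`: a data.frame of `(a, X_T)`
#'   boundary points.
#' @export
bistable_region_2d <- function(params, a_grid,
                               X_T_max = 10 * max(params$K, params$K_prime)) {
  rows <- lapply(a_grid, function(a) {
    sn <- tryCatch({
      rc <- trace_response_curve(params, vary = "X_T", range = c(0, X_T_max),
                                 a_value = a)
      attr(rc, "saddle_nodes")
    }, error = function(e) data.frame(parameter = numeric(0), X = numeric(0)))
    if (nrow(sn) == 2)
      data.frame(a = a, X_T_lo = min(sn$parameter), X_T_hi = max(sn$parameter))
    else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(a = numeric(0), X_T_lo = numeric(0),
                                      X_T_hi = numeric(0))
  boundary <- rbind(data.frame(a = out$a, X_T = out$X_T_lo),
                    data.frame(a = out$a, X_T = out$X_T_hi))
  attr(out, "boundary") <- boundary
  out
}
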