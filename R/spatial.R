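#' One-dimensional reaction--diffusion simulation of the switch
#'
#' Integrates the active/inactive protein pair
#' \eqn{\partial_t X = D_X \partial_x^2 X + \epsilon^{-1}(f(X)Y - g(X)X)},
#' \eqn{\partial_t Y = D_Y \partial_x^2 Y - \epsilon^{-1}(f(X)Y - g(X)X)}
#' with an explicit scheme (forward difference in time, centred in space)
#' and zero-flux boundaries. The basal rate may vary in space and time
#' through `a_profile`. The step must satisfy the diffusive stability
#' bound \eqn{dt \le dx^2 / (2 \max(D_X, D_Y))}; the default applies a
#' safety factor of 0.4 and a violating user-supplied `dt` is refused with
#' the admissible value reported.
#'
#' @param params a [feedback_params()] object.
#' @param a_profile basal rate: a scalar, a vector over the grid, or a
#'   function `f(x, t)` returning the profile at time `t`.
#' @param D_X,D_Y diffusion coefficients (default 5).
#' @param L domain length; `dx` grid spacing.
#' @param init optional list with numeric vectors `X`, `Y` over the grid.
#'   The default is a step profile: fully active (`X = X_T0`) left of
#'   `step_at`, fully inactive to the right, total `X + Y = X_T0`
#'   everywhere.
#' @param X_T0 total protein of the default step initial condition.
#' @param step_at position of the default step.
#' @param t_end end time; `dt` time step (`NULL` = stability bound x 0.4).
#' @param save_dt interval between stored snapshots.
#' @return A `"spatial_fields"` object: list with `x`, `times`, matrices
#'   `X`, `Y` (rows = times), the `a` profile(s), and the grid metadata.
#' @export
simulate_pde <- function(params, a_profile, D_X = 5, D_Y = 5,
                         L = 100, dx = 0.2, init = NULL,
                         X_T0 = 2, step_at = L / 2,
                         t_end, dt = NULL, save_dt = 0.5) {
  x <- seq(dx / 2, L - dx / 2, by = dx)
  nx <- length(x)
  dt_max <- dx^2 / (2 * max(D_X, D_Y))
  if (is.null(dt)) dt <- 0.4 * dt_max
  if (dt > dt_max)
    stop(sprintf("explicit-scheme stability violated: dt = %g > %g; use dt <= %g",
                 dt, dt_max, dt_max))
  if (is.null(init)) {
    X <- ifelse(x < step_at, X_T0, 0)
    Y <- X_T0 - X
  } else {
    X <- init$X; Y <- init$Y
    stopifnot(length(X) == nx, length(Y) == nx)
  }
  a_fun <- if (is.function(a_profile)) a_profile
           else function(xx, tt) rep_len(a_profile, length(xx))
  a_static <- !is.function(a_profile)
  a_now <- a_fun(x, 0)

  n_steps <- ceiling(t_end / dt)
  save_every <- max(1L, round(save_dt / dt))
  save_idx <- seq(0L, n_steps, by = save_every)
  n_save <- length(save_idx)
  Xs <- matrix(NA_real_, n_save, nx); Ys <- matrix(NA_real_, n_save, nx)
  as <- matrix(NA_real_, n_save, nx)
  Xs[1, ] <- X; Ys[1, ] <- Y; as[1, ] <- a_now
  si <- 2L

  cX <- D_X * dt / dx^2; cY <- D_Y * dt / dx^2
  inv_eps <- 1 / params$epsilon
  n <- params$n; m <- params$m
  Kn <- params$K^n; Km <- params$K_prime^m
  b <- params$b; ap <- params$a_prime; bp <- params$b_prime
  il <- c(1L, seq_len(nx - 1L)); ir <- c(seq.int(2L, nx), nx)  # mirrored ghosts

  for (s in seq_len(n_steps)) {
    if (!a_static) a_now <- a_fun(x, (s - 1) * dt)
    Xc <- pmax(X, 0)
    Xn <- Xc^n
    f <- a_now + b * Xn / (Kn + Xn)
    g <- ap + bp * Km / (Km + Xc^m)
    R <- inv_eps * (f * Y - g * Xc)
    lapX <- X[il] - 2 * X + X[ir]
    lapY <- Y[il] - 2 * Y + Y[ir]
    X <- X + cX * lapX + dt * R
    Y <- Y + cY * lapY - dt * R
    if (si <= n_save && s == save_idx[si]) {
      Xs[si, ] <- X; Ys[si, ] <- Y; as[si, ] <- a_now
      si <- si + 1L
    }
  }
  structure(list(x = x, times = save_idx * dt, X = Xs, Y = Ys, a = as,
                 params = params, D_X = D_X, D_Y = D_Y, dx = dx, dt = dt),
            class = "spatial_fields")
}

#' @export
print.spatial_fields <- function(x, ...) {
  cat(sprintf("Reaction-diffusion fields: %d snapshots of %d grid points (L = %g)\n",
              length(x$times), length(x$x), max(x$x) + x$dx / 2))
  invisible(x)
}

#' Front position of a single profile
#'
#' Linearly interpolated position where the `X` profile crosses `level`.
#' A profile with no crossing or with multiple crossings (not a simple
#' front) returns `NA` with the crossing count attached.
#'
#' @param x grid positions; `X` the profile.
#' @param level crossing level; conventionally the midpoint of the two
#'   stable branch values (see [front_level()]).
#' @return Position (same units as `x`), or `NA_real_` flagged with
#'   attribute `n_crossings`.
#' @export
front_position <- function(x, X, level) {
  d <- X - level
  idx <- which(d[-1] * d[-length(d)] < 0)
  exact <- which(d == 0)
  ncross <- length(idx) + length(exact)
  if (ncross != 1)
    return(structure(NA_real_, n_crossings = ncross))
  if (length(exact) == 1) return(structure(x[exact], n_crossings = 1L))
  j <- idx
  structure(x[j] + (0 - d[j]) / (d[j + 1] - d[j]) * (x[j + 1] - x[j]),
            n_crossings = 1L)
}

#' Default front-detection level: midpoint of the stable branches
#'
#' @param params a [feedback_params()] object.
#' @param a basal rate; `X_T` total protein.
#' @return Mean of the low and high stable steady-state `X` values.
#' @export
front_level <- function(params, a, X_T) {
  ss <- steady_states(params, a, X_T)
  st <- ss$X[ss$stable]
  if (length(st) < 2)
    stop("front_level: the kinetics are not bistable at this (a, X_T)")
  (min(st) + max(st)) / 2
}

#' Front velocity by linear fit of position versus time
#'
#' Tracks [front_position()] over the stored snapshots, discards an
#' initial transient (the step initial condition relaxing into the
#' travelling profile), and fits a straight line. Positive velocity means
#' the active state advances (the front moves right).
#'
#' @param fields a `"spatial_fields"` object.
#' @param level crossing level (see [front_level()]).
#' @param transient fraction of the run discarded before fitting.
#' @return list with `velocity`, `r_squared`, `positions` (data.frame
#'   `time`, `position`), and `poor_fit` (`TRUE` when R^2 < 0.99).
#' @export
front_velocity <- function(fields, level, transient = 0.1) {
  pos <- vapply(seq_along(fields$times), function(i)
    as.numeric(front_position(fields$x, fields$X[i, ], level)), numeric(1))
  keep <- fields$times >= transient * max(fields$times) & is.finite(pos)
  if (sum(keep) < 10)
    stop("front_velocity: fewer than 10 usable front positions after the transient")
  fit <- lm(pos[keep] ~ fields$times[keep])
  v <- unname(coef(fit)[2])
  r2 <- summary(fit)$r.squared
  out <- list(velocity = v, r_squared = r2,
              positions = data.frame(time = fields$times[keep],
                                     position = pos[keep]),
              poor_fit = r2 < 0.99)
  if (out$poor_fit)
    warning(sprintf("front velocity fit has R^2 = %.4f (< 0.99)", r2))
  out
}

#' Scan front velocity against the basal rate a
#'
#' Runs the reaction--diffusion model over a grid of spatially uniform
#' `a` values (fixed total protein) and measures the front velocity for
#' each. The front stalls (`velocity = 0`) at the Maxwell-type value of
#' `a` where neither state dominates; [stall_a()] interpolates that zero
#' crossing.
#'
#' @param params a [feedback_params()] object.
#' @param a_values grid of basal rates.
#' @param X_T total protein (initial `X + Y` everywhere).
#' @param t_end,L,dx,D_X,D_Y passed to [simulate_pde()].
#' @param step_at initial step position.
#' @return data.frame with columns `a`, `velocity`, `r_squared`.
#' @export
front_velocity_scan <- function(params, a_values, X_T = 2,
                                t_end = 20, L = 100, dx = 0.2,
                                D_X = 5, D_Y = 5, step_at = L / 2) {
  rows <- lapply(a_values, function(a) {
    lev <- front_level(params, a, X_T)
    fl <- simulate_pde(params, a_profile = a, D_X = D_X, D_Y = D_Y,
                       L = L, dx = dx, X_T0 = X_T, step_at = step_at,
                       t_end = t_end)
    fv <- suppressWarnings(front_velocity(fl, lev))
    data.frame(a = a, velocity = fv$velocity, r_squared = fv$r_squared)
  })
  do.call(rbind, rows)
}

#' Interpolated zero crossing of a velocity scan
#'
#' @param scan result of [front_velocity_scan()].
#' @return The basal rate at which the front velocity changes sign.
#' @export
stall_a <- function(scan) {
  v <- scan$velocity
  idx <- which(v[-1] * v[-length(v)] <= 0)
  if (length(idx) == 0) stop("no zero crossing of the front velocity in the scan")
  j <- idx[1]
  scan$a[j] - v[j] * (scan$a[j + 1] - scan$a[j]) / (v[j + 1] - v[j])
}

#' Front pinning and release in a heterogeneous a-profile
#'
#' Simulates a front moving into a region of decreasing basal rate. The
#' profile is a smooth hyperbolic tangent from `high_a` (left) down to
#' `low_a` (right); the front advances, stalls near the position where
#' the profile crosses the stall value, and resumes after the profile is
#' smoothly flipped at `flip_time`.
#'
#' @param params a [feedback_params()] object.
#' @param high_a,low_a the two plateau values of the profile.
#' @param X_T total protein.
#' @param profile_center,profile_width centre and width of the tanh
#'   transition region.
#' @param flip_time time at which the profile starts flipping;
#'   `ramp` the duration of the smooth flip.
#' @param t_end,L,dx,step_at grid/run controls (see [simulate_pde()]).
#' @return list with the `"spatial_fields"` object (`fields`), the front
#'   `positions` data.frame, the `pinned_position` (median front position
#'   over the window just before the flip), and `a_at_pin` (the profile
#'   value there at that moment).
#' @export
pinning_experiment <- function(params, high_a = 0.27, low_a = 0.13,
                               X_T = 2, profile_center = 60,
                               profile_width = 10,
                               flip_time = 25, ramp = 2,
                               t_end = 50, L = 100, dx = 0.2,
                               step_at = 20) {
  base <- function(xx) low_a + (high_a - low_a) *
    (1 - tanh((xx - profile_center) / profile_width)) / 2
  flipped <- function(xx) low_a + (high_a - low_a) *
    (1 + tanh((xx - (L - profile_center)) / profile_width)) / 2
  a_fun <- function(xx, tt) {
    if (tt <= flip_time) base(xx)
    else if (tt >= flip_time + ramp) flipped(xx)
    else {
      lam <- (tt - flip_time) / ramp
      (1 - lam) * base(xx) + lam * flipped(xx)
    }
  }
  fl <- simulate_pde(params, a_profile = a_fun, L = L, dx = dx,
                     X_T0 = X_T, step_at = step_at, t_end = t_end)
  lev <- front_level(params, (high_a + low_a) / 2, X_T)
  pos <- vapply(seq_along(fl$times), function(i)
    as.numeric(front_position(fl$x, fl$X[i, ], lev)), numeric(1))
  pre <- fl$times > 0.6 * flip_time & fl$times <= flip_time & is.finite(pos)
  pinned <- stats::median(pos[pre])
  a_at_pin <- base(pinned)
  list(fields = fl,
       positions = data.frame(time = fl$times, position = pos),
       pinned_position = pinned, a_at_pin = a_at_pin,
       flip_time = flip_time)
}
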