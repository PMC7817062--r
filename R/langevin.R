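#' Langevin (Euler--Maruyama) simulation with noise on the fast variable
#'
#' Integrates the transition or oscillator model as a stochastic
#' differential equation with additive noise of magnitude `sigma` on the
#' active-protein variable only; the slow variable evolves
#' deterministically (\eqn{dX_T = k_X\,dt}, or the degradation form for
#' the oscillator). The scheme is Euler--Maruyama with fixed step `dt`;
#' `X` is reflected at 0 by clipping so concentrations stay physical.
#' Multiple replicates are advanced in lockstep (one shared time grid,
#' independent noise), which is how the timing experiments are run.
#'
#' @param model `"transition"` or `"oscillator"`.
#' @param params a [feedback_params()] object.
#' @param mod optional [switch_modulation()]; a delay `tau > 0` reads the
#'   replicate's own `X_T` history (constant before the start).
#' @param k_X production rate.
#' @param sigma noise magnitude on `X` (concentration per sqrt(time)).
#' @param dt Euler--Maruyama step.
#' @param t_end end time.
#' @param init named initial state (`X`, `X_T`), shared by all replicates.
#' @param n_rep number of replicates.
#' @param record_every record the state every this many steps.
#' @param seed optional RNG seed (recorded in the result).
#' @return For `n_rep = 1`, a `"switch_trajectory"`. Otherwise a
#'   `"langevin_ensemble"`: list with `time`, matrices `X` and `X_T`
#'   (time x replicate), and the run metadata.
#' @export
simulate_langevin <- function(model = c("transition", "oscillator"),
                              params, mod = NULL, k_X, sigma,
                              dt = 1e-3, t_end,
                              init = c(X = 0, X_T = 0),
                              n_rep = 1L, record_every = 10L, seed = NULL) {
  model <- match.arg(model)
  stopifnot(sigma >= 0, dt > 0, t_end > 0, n_rep >= 1)
  mod <- resolve_mod(mod, params)
  if (!is.null(seed)) set.seed(seed)
  n_steps <- ceiling(t_end / dt)
  rec_idx <- seq(0, n_steps, by = record_every)
  n_rec <- length(rec_idx)
  Xr <- matrix(NA_real_, n_rec, n_rep)
  XTr <- matrix(NA_real_, n_rec, n_rep)
  X <- rep(init[["X"]], n_rep)
  XT <- rep(init[["X_T"]], n_rep)
  inv_eps <- 1 / params$epsilon
  sq <- sigma * sqrt(dt)
  delayed <- !is.null(mod) && mod$tau > 0
  lag_steps <- if (delayed) max(1L, round(mod$tau / dt)) else 0L
  if (delayed) {
    hist <- matrix(init[["X_T"]], lag_steps, n_rep)  # ring buffer of X_T
    hpos <- 0L
  }
  Xr[1, ] <- X; XTr[1, ] <- XT
  ri <- 2L
  for (s in seq_len(n_steps)) {
    a <- if (is.null(mod)) params$a
         else if (!delayed) modulated_a(XT, mod)
         else {
           hp <- (hpos %% lag_steps) + 1L
           XT_lag <- hist[hp, ]
           hist[hp, ] <- XT
           hpos <- hpos + 1L
           modulated_a(XT_lag, mod)
         }
    drift <- inv_eps * (activation_rate(X, params, a) * (XT - X) -
                        inactivation_rate(X, params) * X)
    Xn <- X + drift * dt + sq * rnorm(n_rep)
    XT <- XT + (if (model == "transition") k_X else k_X - XT * X) * dt
    X <- pmax(Xn, 0)
    if (ri <= n_rec && s == rec_idx[ri]) {
      Xr[ri, ] <- X; XTr[ri, ] <- XT
      ri <- ri + 1L
    }
  }
  time <- rec_idx * dt
  if (n_rep == 1L) {
    return(new_trajectory(data.frame(time = time, X = Xr[, 1], X_T = XTr[, 1]),
                          paste0("langevin_", model), params, mod, k_X,
                          seed = seed, extra = list(sigma = sigma, dt = dt)))
  }
  structure(list(time = time, X = Xr, X_T = XTr, model = model,
                 params = params, mod = mod, k_X = k_X, sigma = sigma,
                 dt = dt, seed = seed),
            class = "langevin_ensemble")
}

#' @export
print.langevin_ensemble <- function(x, ...) {
  cat(sprintf("Langevin ensemble (%s model): %d replicates, t in [0, %g], sigma = %g\n",
              x$model, ncol(x$X), max(x$time), x$sigma))
  invisible(x)
}

#' First-crossing transition time of a trajectory
#'
#' Time at which `X` first crosses `threshold` from below (linear
#' interpolation between samples). The threshold convention is the average
#' of the saddle-node vertical coordinates of the static switch (the
#' `transition` entry of [event_thresholds()]).
#'
#' @param traj a `"switch_trajectory"` (needs `time` and `X`).
#' @param threshold crossing level.
#' @return The crossing time, or `NA_real_` when the trajectory never
#'   transitions.
#' @export
transition_time <- function(traj, threshold) {
  if (traj$X[1] >= threshold) return(traj$time[1])
  tc <- crossing_times(traj$time, traj$X, threshold, +1)
  if (length(tc) == 0) NA_real_ else tc[1]
}

# Vectorised transition times for a Langevin ensemble.
ensemble_transition_times <- function(ens, threshold) {
  vapply(seq_len(ncol(ens$X)), function(j) {
    transition_time(data.frame(time = ens$time, X = ens$X[, j]), threshold)
  }, numeric(1))
}

#' Transition-timing and period robustness experiments
#'
#' Runs the stochastic model over a set of modulation conditions and
#' summarises the variability of the measured event.
#'
#' For `what = "transition"`: replicated runs of the transition model; per
#' condition the transition-time mean, sd and CV (plus a bootstrap
#' standard error of the CV); replicates that never transition are
#' excluded and counted. For `what = "period"`: one long oscillator run
#' per condition and the CV over its detected periods.
#'
#' Conditions are given as a data.frame with any of the columns `delta_a`,
#' `kappa`, `tau` (missing columns take the defaults).
#'
#' @param variant `"langevin"` or `"ssa"`.
#' @param what `"transition"` or `"period"`.
#' @param conditions data.frame of conditions (see Details).
#' @param params a [feedback_params()] object.
#' @param a_bar centre basal rate.
#' @param kappa,tau default modulation steepness and delay.
#' @param k_X production rate.
#' @param sigma Langevin noise magnitude.
#' @param omega SSA system size.
#' @param replicates replicates per condition (transition experiments).
#' @param t_end run length; defaults: 10 for transition experiments,
#'   2000 (Langevin) or 4000 (SSA) for period experiments.
#' @param dt Euler--Maruyama step.
#' @param seed master seed; per-replicate streams are spawned from it.
#' @return data.frame with one row per condition: the condition columns
#'   plus `n`, `n_failed`, `mean`, `sd`, `cv`, `cv_se`.
#' @export
run_timing_experiment <- function(variant = c("langevin", "ssa"),
                                  what = c("transition", "period"),
                                  conditions, params,
                                  a_bar = 0.3, kappa = 5, tau = 0,
                                  k_X = 1, sigma = 0.6, omega = 20,
                                  replicates = 200, t_end = NULL,
                                  dt = 1e-3, seed = 1) {
  variant <- match.arg(variant)
  what <- match.arg(what)
  if (is.null(t_end))
    t_end <- if (what == "transition") 10
             else if (variant == "langevin") 2000 else 4000
  th <- event_thresholds(params, a_bar)
  Xc <- midpoint_Xc(params, a_bar)
  if (!("delta_a" %in% names(conditions))) conditions$delta_a <- 0
  if (!("kappa" %in% names(conditions))) conditions$kappa <- kappa
  if (!("tau" %in% names(conditions))) conditions$tau <- tau
  rows <- vector("list", nrow(conditions))
  for (ci in seq_len(nrow(conditions))) {
    da <- conditions$delta_a[ci]; kp <- conditions$kappa[ci]
    tu <- conditions$tau[ci]
    mod <- if (da == 0 && tu == 0) NULL
           else switch_modulation(a_bar, da, kp, X_c = Xc, tau = tu)
    base <- feedback_params(a = a_bar, b = params$b, K = params$K,
                            n = params$n, a_prime = params$a_prime,
                            b_prime = params$b_prime,
                            K_prime = params$K_prime, m = params$m,
                            epsilon = params$epsilon)
    cond_seed <- seed + 7919L * ci
    if (what == "transition") {
      if (variant == "langevin") {
        ens <- simulate_langevin("transition", base, mod = mod, k_X = k_X,
                                 sigma = sigma, dt = dt, t_end = t_end,
                                 n_rep = replicates, seed = cond_seed)
        tt <- ensemble_transition_times(ens, th$transition)
      } else {
        tt <- vapply(seq_len(replicates), function(r) {
          tr <- simulate_ssa("transition", base, mod = mod, k_X = k_X,
                             omega = omega, t_end = t_end,
                             seed = cond_seed + r,
                             threshold = th$transition)
          attr(tr, "first_passage")
        }, numeric(1))
      }
      ok <- tt[is.finite(tt)]
      st <- if (length(ok) >= 2) cv_statistics(ok, boot_se = TRUE)
            else list(mean = NA_real_, sd = NA_real_, cv = NA_real_,
                      cv_se = NA_real_)
      rows[[ci]] <- data.frame(delta_a = da, kappa = kp, tau = tu,
                               n = length(ok), n_failed = sum(!is.finite(tt)),
                               mean = st$mean, sd = st$sd, cv = st$cv,
                               cv_se = st$cv_se)
    } else {
      tr <- if (variant == "langevin")
        simulate_langevin("oscillator", base, mod = mod, k_X = k_X,
                          sigma = sigma, dt = dt, t_end = t_end,
                          n_rep = 1L, seed = cond_seed)
      else simulate_ssa("oscillator", base, mod = mod, k_X = k_X,
                        omega = omega, t_end = t_end, seed = cond_seed)
      ps <- detect_period(tr, th$up, th$down)
      st <- if (ps$n >= 2) cv_statistics(ps$values, boot_se = TRUE)
            else list(mean = NA_real_, sd = NA_real_, cv = NA_real_,
                      cv_se = NA_real_)
      rows[[ci]] <- data.frame(delta_a = da, kappa = kp, tau = tu,
                               n = ps$n, n_failed = 0L,
                               mean = st$mean, sd = st$sd, cv = st$cv,
                               cv_se = st$cv_se)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  attr(out, "thresholds") <- th
  out
}
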