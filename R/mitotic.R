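#' Parameters of the two-compartment mitotic-entry model
#'
#' The model tracks total Cyclin B--Cdk1 complexes (`cyc`), active Cdk1
#' (`cdk1`) and Cdc25 levels (`cdc25`) in nucleus (`_n`) and cytoplasm
#' (`_c`). Cdk1 activation in each compartment is driven by
#' Cdc25-level-times-activity Hill kinetics and opposed by a fixed Wee1
#' level times its (Cdk1-inhibited) activity; the Wee1 level is higher in
#' the nucleus (`wee1_n = 1.3` vs `wee1_c = 1`), which is the modelled
#' asymmetry. Cyclin is synthesised only in the cytoplasm at rate `k_s`.
#' Nucleocytoplasmic transport is slow relative to the activation
#' kinetics; the rate subscript names the destination compartment. Two
#' spatial feedbacks modulate import multiplicatively:
#' \eqn{I_{Cyc}(Cdk1_n) = 0.1 + c_{cyc} Cdk1_n} (active nuclear Cdk1 pulls
#' Cyclin B in) and \eqn{I_{Cdc}(Cdk1_c) = 1 + c_{cdc} Cdk1_c} (active
#' cytoplasmic Cdk1 pulls Cdc25 in). Cdc25 and Wee1 levels are scaled so
#' that 1 is the reference level.
#'
#' All defaults live in this one constructor. The Hill constants reuse the
#' generic switch parameterisation (basal 0.1, span 1, half-saturation 1,
#' exponent 5) so that a compartment with Cdc25 = Wee1 = 1 carries a
#' bistable Cdk1-vs-Cyclin response; transport and synthesis rates are an
#' order of magnitude slower than the activation kinetics.
#'
#' @param k_s Cyclin B synthesis rate (cytoplasm only).
#' @param wee1_n,wee1_c fixed Wee1 levels (nucleus > cytoplasm).
#' @param a_cdc25,b_cdc25,K_cdc25,m_cdc25 Cdc25 activity Hill constants.
#' @param a_wee1,b_wee1,K_wee1,m_wee1 Wee1 activity Hill constants.
#' @param k_n_cyc,k_c_cyc Cyclin B--Cdk1 import/export rates.
#' @param k_n_cdc25,k_c_cdc25 Cdc25 import/export rates.
#' @param c_cyc,c_cdc import-feedback coefficients of `I_Cyc`, `I_Cdc`.
#' @return An object of class `"mitotic_params"`.
#' @export
mitotic_params <- function(k_s = 0.15,
                           wee1_n = 1.3, wee1_c = 1,
                           a_cdc25 = 0.1, b_cdc25 = 1, K_cdc25 = 1,
                           m_cdc25 = 5,
                           a_wee1 = 0.1, b_wee1 = 1, K_wee1 = 1,
                           m_wee1 = 5,
                           k_n_cyc = 0.3, k_c_cyc = 0.05,
                           k_n_cdc25 = 0.1, k_c_cdc25 = 0.05,
                           c_cyc = 1 / 30, c_cdc = 1 / 60) {
  p <- as.list(environment())
  lapply(p, function(v) stopifnot(is.numeric(v), length(v) == 1L, v >= 0))
  pos <- setdiff(names(p), c("c_cyc", "c_cdc"))  # feedbacks may be switched off
  for (nm in pos) if (p[[nm]] <= 0) stop(sprintf("'%s' must be > 0", nm))
  if (wee1_n < wee1_c)
    stop("the modelled asymmetry requires wee1_n >= wee1_c")
  structure(p, class = "mitotic_params")
}

#' @export
print.mitotic_params <- function(x, ...) {
  cat("Two-compartment mitotic-entry parameters\n")
  cat(sprintf("  synthesis k_s = %g (cytoplasm); Wee1 levels n/c = %g / %g\n",
              x$k_s, x$wee1_n, x$wee1_c))
  cat(sprintf("  transport: Cyc %g/%g, Cdc25 %g/%g (import/export)\n",
              x$k_n_cyc, x$k_c_cyc, x$k_n_cdc25, x$k_c_cdc25))
  invisible(x)
}

#' Import-rate modulation by active Cdk1
#'
#' @param cdk1 active Cdk1 concentration (nuclear for `"cyc"`, cytoplasmic
#'   for `"cdc"`).
#' @param params a [mitotic_params()] object.
#' @param which `"cyc"` (Cyclin B--Cdk1 import) or `"cdc"` (Cdc25 import).
#' @return Multiplier applied to the corresponding nuclear import rate;
#'   `I_Cyc(0) = 0.1`, `I_Cdc(0) = 1`, both strictly increasing.
#' @export
import_modulation <- function(cdk1, params, which = c("cyc", "cdc")) {
  which <- match.arg(which)
  stopifnot(all(cdk1 >= 0))
  if (which == "cyc") 0.1 + params$c_cyc * cdk1
  else 1 + params$c_cdc * cdk1
}

# Effective scalar-switch parameters of one compartment at given Cdc25 and
# Wee1 levels: activation f = cdc25*(a25 + b25*Hill), inactivation
# g = wee1*(aW + bW*antiHill) have exactly the generic switch's form.
compartment_params <- function(params, cdc25, wee1) {
  feedback_params(a = cdc25 * params$a_cdc25, b = cdc25 * params$b_cdc25,
                  K = params$K_cdc25, n = params$m_cdc25,
                  a_prime = wee1 * params$a_wee1,
                  b_prime = wee1 * params$b_wee1,
                  K_prime = params$K_wee1, m = params$m_wee1,
                  epsilon = 1)
}

#' Right-hand side of the two-compartment mitotic-entry model
#'
#' Six coupled ODEs for `cyc_n`, `cyc_c`, `cdk1_n`, `cdk1_c`, `cdc25_n`,
#' `cdc25_c`. Transport terms cancel pairwise, so total Cdc25 is conserved
#' exactly and total Cyclin grows at exactly `k_s`.
#'
#' @param state named numeric vector with the six variables.
#' @param params a [mitotic_params()] object.
#' @return Named vector of derivatives.
#' @export
rhs_mitotic <- function(state, params) {
  cyc_n <- state[["cyc_n"]]; cyc_c <- state[["cyc_c"]]
  k1n <- state[["cdk1_n"]]; k1c <- state[["cdk1_c"]]
  c25n <- state[["cdc25_n"]]; c25c <- state[["cdc25_c"]]

  icyc <- import_modulation(max(k1n, 0), params, "cyc")
  icdc <- import_modulation(max(k1c, 0), params, "cdc")

  act <- function(cdk1, cdc25) {
    ck <- max(cdk1, 0)
    cdc25 * (params$a_cdc25 + params$b_cdc25 * ck^params$m_cdc25 /
               (params$K_cdc25^params$m_cdc25 + ck^params$m_cdc25))
  }
  inact <- function(cdk1, wee1) {
    ck <- max(cdk1, 0)
    wee1 * (params$a_wee1 + params$b_wee1 * params$K_wee1^params$m_wee1 /
              (params$K_wee1^params$m_wee1 + ck^params$m_wee1))
  }

  t_cyc <- params$k_n_cyc * icyc * cyc_c - params$k_c_cyc * cyc_n
  t_cdk <- params$k_n_cyc * icyc * k1c - params$k_c_cyc * k1n
  t_cdc <- params$k_n_cdc25 * icdc * c25c - params$k_c_cdc25 * c25n

  c(cyc_n = t_cyc,
    cyc_c = -t_cyc + params$k_s,
    cdk1_n = t_cdk + act(k1n, c25n) * (cyc_n - k1n) -
      inact(k1n, params$wee1_n) * k1n,
    cdk1_c = -t_cdk + params$k_s + act(k1c, c25c) * (cyc_c - k1c) -
      inact(k1c, params$wee1_c) * k1c,
    cdc25_n = t_cdc,
    cdc25_c = -t_cdc)
}

#' Simulate mitotic entry and detect the compartment activation jumps
#'
#' Integrates the two-compartment model from the standard initial
#' conditions (no Cyclin, `cdc25_n = 1`, `cdc25_c = 2`) and detects the
#' Cdk1 activation jump in each compartment as the first crossing of that
#' compartment's transition threshold -- the average of the saddle-node
#' vertical coordinates of its instantaneous (t = 0) response curve.
#' Under the defaults the cytoplasm activates first; the jump there
#' accelerates Cdc25 import, pulls the nuclear threshold down and
#' triggers nuclear activation.
#'
#' @param params a [mitotic_params()] object.
#' @param init named initial state; default as above.
#' @param t_end,dt_out integration controls.
#' @return A `"switch_trajectory"`-style data.frame of all six variables
#'   with attribute `events`: list with `t_jump_c`, `t_jump_n` and the
#'   per-compartment thresholds used.
#' @export
simulate_mitotic_entry <- function(params = mitotic_params(),
                                   init = c(cyc_n = 0, cyc_c = 0,
                                            cdk1_n = 0, cdk1_c = 0,
                                            cdc25_n = 1, cdc25_c = 2),
                                   t_end = 150, dt_out = 0.05) {
  fn <- function(t, y, p) list(unname(rhs_mitotic(y, params)))
  out <- deSolve::lsoda(init, seq(0, t_end, by = dt_out), fn, NULL,
                        rtol = 1e-8, atol = 1e-10)
  if (attr(out, "istate")[1] < 0) stop("mitotic-entry integration failed")
  df <- as.data.frame(out)
  names(df)[1] <- "time"

  th_c <- tryCatch(
    event_thresholds(compartment_params(params, init[["cdc25_c"]],
                                        params$wee1_c))$transition,
    error = function(e) NA_real_)
  th_n <- tryCatch(
    event_thresholds(compartment_params(params, init[["cdc25_n"]],
                                        params$wee1_n))$transition,
    error = function(e) NA_real_)
  tj <- function(xcol, th) {
    if (!is.finite(th)) return(NA_real_)
    tc <- crossing_times(df$time, df[[xcol]], th, +1)
    if (length(tc) == 0) NA_real_ else tc[1]
  }
  events <- list(t_jump_c = tj("cdk1_c", th_c), t_jump_n = tj("cdk1_n", th_n),
                 threshold_c = th_c, threshold_n = th_n)
  new_trajectory(df, "mitotic_entry", params, NULL, NA,
                 extra = list(events = events))
}

#' Instantaneous per-compartment response curve
#'
#' Quasi-steady-state view of one compartment: the Cdk1 steady state
#' versus total Cyclin, holding the compartment's current Cdc25 and Wee1
#' levels fixed. As Cdc25 accumulates in the nucleus the nuclear
#' activation threshold (right fold) moves to lower Cyclin.
#'
#' @param state named state vector (a row of [simulate_mitotic_entry()]
#'   output works).
#' @param params a [mitotic_params()] object.
#' @param compartment `"nucleus"` or `"cytoplasm"`.
#' @param cyc_max range of total Cyclin to trace.
#' @return A `"response_curve"` (see [trace_response_curve()]); a
#'   non-bistable snapshot gives a monotone curve with zero folds.
#' @export
mitotic_response_curve <- function(state, params,
                                   compartment = c("nucleus", "cytoplasm"),
                                   cyc_max = 6) {
  compartment <- match.arg(compartment)
  cdc25 <- if (compartment == "nucleus") state[["cdc25_n"]] else state[["cdc25_c"]]
  wee1 <- if (compartment == "nucleus") params$wee1_n else params$wee1_c
  trace_response_curve(compartment_params(params, cdc25, wee1),
                       vary = "X_T", range = c(0, cyc_max))
}
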