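# Shared fixtures: the standard feedback parameter set and the event
# thresholds / modulation midpoint of the static switch at a_bar = 0.3.
std_params <- feedback_params()
std_folds <- local({
  rc <- trace_response_curve(std_params, "X_T", c(0, 4), a_value = 0.3)
  attr(rc, "saddle_nodes")
})
std_th <- event_thresholds(std_params, 0.3)
std_Xc <- midpoint_Xc(std_params, 0.3)

# Brute-force fold locator: scan X_T for 1 -> 3 -> 1 root-count changes and
# bisect the boundaries. Independent of the continuation tracer.
bruteforce_folds <- function(params, a_value, X_T_max = 6, grid = 400) {
  xts <- seq(1e-3, X_T_max, length.out = grid)
  counts <- vapply(xts, function(xt)
    nrow(steady_states(params, a_value, xt)), integer(1))
  ch <- which(diff(counts) != 0)
  vapply(ch, function(j) {
    lo <- xts[j]; hi <- xts[j + 1]
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      if (nrow(steady_states(params, a_value, mid)) == counts[j]) lo <- mid
      else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}
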