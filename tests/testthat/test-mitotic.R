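test_that("import modulation has the stated intercepts and grows with Cdk1", {
  mp <- mitotic_params()
  expect_equal(import_modulation(0, mp, "cyc"), 0.1)
  expect_equal(import_modulation(0, mp, "cdc"), 1)
  ck <- seq(0, 10, length.out = 50)
  expect_true(all(diff(import_modulation(ck, mp, "cyc")) > 0))
  expect_true(all(diff(import_modulation(ck, mp, "cdc")) > 0))
})

test_that("transport cancels: Cdc25 conserved, total Cyclin grows at k_s", {
  mp <- mitotic_params()
  st <- c(cyc_n = 0.5, cyc_c = 1.2, cdk1_n = 0.1, cdk1_c = 0.9,
          cdc25_n = 1.1, cdc25_c = 1.9)
  d <- rhs_mitotic(st, mp)
  expect_equal(unname(d["cdc25_n"] + d["cdc25_c"]), 0)
  expect_equal(unname(d["cyc_n"] + d["cyc_c"]), mp$k_s)
})

test_that("the full run conserves Cdc25 and respects Cdk1 <= Cyc", {
  tr <- simulate_mitotic_entry(t_end = 100)
  tot <- tr$cdc25_n + tr$cdc25_c
  expect_lt(max(abs(tot - tot[1])), 1e-8)
  cyc <- tr$cyc_n + tr$cyc_c
  fit <- lm(cyc ~ tr$time)
  expect_equal(unname(coef(fit)[2]), mitotic_params()$k_s, tolerance = 1e-6)
  expect_true(all(tr$cdk1_n <= tr$cyc_n + 1e-6))
  expect_true(all(tr$cdk1_c <= tr$cyc_c + 1e-6))
  expect_true(all(tr[-1] >= -1e-8))
})

test_that("cytoplasmic Cdk1 activates first; nuclear activity then overtakes", {
  tr <- simulate_mitotic_entry(t_end = 120)
  ev <- attr(tr, "events")
  expect_true(is.finite(ev$t_jump_c) && is.finite(ev$t_jump_n))
  expect_lt(ev$t_jump_c, ev$t_jump_n)
  # after nuclear activation the nucleus keeps accumulating activity while
  # the cytoplasm settles
  late <- tr[tr$time > ev$t_jump_n + 20, ]
  expect_gt(tail(late$cdk1_n, 1), tail(late$cdk1_c, 1))
  span <- function(v) diff(range(v))
  expect_lt(span(late$cdk1_c), 0.4 * span(late$cdk1_n))
})

test_that("a symmetrised control loses most of the activation-ordering gap", {
  tr <- simulate_mitotic_entry(t_end = 120)
  ev <- attr(tr, "events")
  gap <- ev$t_jump_n - ev$t_jump_c
  mp0 <- mitotic_params(wee1_n = 1, wee1_c = 1, c_cyc = 0, c_cdc = 0,
                        k_n_cyc = 1, k_c_cyc = 0.1,
                        k_n_cdc25 = 0.1, k_c_cdc25 = 0.1)
  tr0 <- simulate_mitotic_entry(mp0,
                                init = c(cyc_n = 0, cyc_c = 0, cdk1_n = 0,
                                         cdk1_c = 0, cdc25_n = 1.5,
                                         cdc25_c = 1.5),
                                t_end = 120)
  ev0 <- attr(tr0, "events")
  gap0 <- ev0$t_jump_n - ev0$t_jump_c
  expect_lt(gap0, 0.3 * gap)
})

test_that("instantaneous response curves shift as Cdc25 redistributes", {
  mp <- mitotic_params()
  tr <- simulate_mitotic_entry(mp, t_end = 60)
  s0 <- unlist(tr[1, -1])
  rn0 <- mitotic_response_curve(s0, mp, "nucleus")
  rc0 <- mitotic_response_curve(s0, mp, "cytoplasm")
  fold <- function(rc) max(attr(rc, "saddle_nodes")$parameter)
  # initially the nuclear activation threshold lies far to the right
  expect_gt(fold(rn0), fold(rc0))
  # and moves left as Cdc25 is imported
  s50 <- unlist(tr[which.min(abs(tr$time - 50)), -1])
  expect_lt(fold(mitotic_response_curve(s50, mp, "nucleus")), fold(rn0))
  # doubling Cdc25 at fixed Wee1 lowers the activation threshold
  hi <- s0; hi[["cdc25_n"]] <- 2 * s0[["cdc25_n"]]
  expect_lt(fold(mitotic_response_curve(hi, mp, "nucleus")), fold(rn0))
})

test_that("decoupled compartments reduce to the standalone bistable kinetics", {
  mp <- mitotic_params(k_s = 1e-12, k_n_cyc = 1e-12, k_c_cyc = 1e-12,
                       k_n_cdc25 = 1e-12, k_c_cdc25 = 1e-12)
  init <- c(cyc_n = 2, cyc_c = 2, cdk1_n = 0.1, cdk1_c = 0.1,
            cdc25_n = 1, cdc25_c = 2)
  tr <- simulate_mitotic_entry(mp, init = init, t_end = 100)
  expect_lt(max(abs(tr$cyc_n - 2)), 1e-8)  # compartment Cyc conserved
  # each compartment settles on a steady state of its own scalar kinetics
  ss_n <- steady_states(dynswitch:::compartment_params(mp, 1, mp$wee1_n),
                        X_T = 2)
  ss_c <- steady_states(dynswitch:::compartment_params(mp, 2, mp$wee1_c),
                        X_T = 2)
  expect_lt(min(abs(tail(tr$cdk1_n, 1) - ss_n$X[ss_n$stable])), 1e-5)
  expect_lt(min(abs(tail(tr$cdk1_c, 1) - ss_c$X[ss_c$stable])), 1e-5)
})
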