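test_that("the derivative evaluator is mass-action and conservative", {
  net <- generate_network()
  f <- build_rate_function(net)
  y0 <- initial_state(net)

  # bimolecular flux arithmetic: k * c_PLC * c_RTK
  expect_equal(unname(y0["RTK"]), 0.05)
  d <- f(y0)
  sp <- net$species
  expect_equal(sum(d * sp$plc_content), 0, tolerance = 1e-15)
  expect_equal(sum(d * sp$rtk_content), 0, tolerance = 1e-15)

  set.seed(3)
  y <- stats::runif(17, 0, 0.1)
  d <- f(y)
  expect_equal(sum(d * sp$plc_content), 0, tolerance = 1e-12)
  expect_equal(sum(d * sp$rtk_content), 0, tolerance = 1e-12)

  # all-zero rate constants give a zero field and a constant trajectory
  p0 <- plcg_parameters(k_on_nSH2 = 0, k_off_nSH2 = 0, k_phos = 0,
                        k_dephos = 0, k_bind_c = 0, k_unbind_c = 0,
                        k_bind_p = 0, k_unbind_p = 0, k_act = 0,
                        k_inact = 0)
  net0 <- generate_network(params = p0)
  expect_equal(max(abs(build_rate_function(net0)(y))), 0)
  tr0 <- simulate_network(net0, t_end = 10)
  expect_equal(max(abs(sweep(tr0$conc, 2, tr0$conc[1, ]))), 0)
})

test_that("a single bimolecular binding flux follows mass action exactly", {
  # isolated check: at c_PLC = 0.02, c_RTK = 0.05, k = 1 /uM/s the flux
  # is 0.001 uM/s into the complex
  net <- generate_network()
  j <- which(net$reactions$rate_name == "k_on_nSH2")[1]
  re <- as.integer(strsplit(net$reactions$reactants[j], ";")[[1]])
  y <- numeric(17)
  y[re[1]] <- 0.02
  y[re[2]] <- 0.05
  flux <- reaction_fluxes(net, y)[j]
  expect_equal(flux, 0.001)
})

test_that("simulation conserves totals and reaches the analytic cytosolic equilibrium", {
  # receptor-free system reduces to the 3-state chain
  # autoinhibited <-> uninhibited <-> active, with equilibrium active
  # fraction K_a / (1 + K_c + K_a)
  p <- plcg_parameters(rtk_total = 0, k_phos = 0)
  net <- generate_network(params = p)
  ss <- steady_state(net)
  expect_true(ss$converged)
  expect_equal(ss$active_fraction_ss, 0.1 / 101.1, tolerance = 1e-4)

  tot <- conserved_totals(ss$trajectory)
  expect_lt(max(abs(tot$plc - 0.02)) / 0.02, 1e-6)

  # base activation run conserves both totals
  netb <- generate_network()
  trb <- simulate_network(netb, t_end = 2000)
  totb <- conserved_totals(trb)
  expect_lt(max(abs(totb$plc - 0.02)) / 0.02, 1e-6)
  expect_lt(max(abs(totb$rtk - 0.05)) / 0.05, 1e-6)
})

test_that("steady state does not depend on the initial distribution of PLC", {
  net <- generate_network()
  ref <- steady_state(net)$active_fraction_ss
  set.seed(11)
  sp <- net$species
  for (i in 1:3) {
    w <- stats::runif(16)
    y0 <- stats::setNames(numeric(17), sp$label)
    y0[sp$kind != "rtk_free"] <- 0.02 * w / sum(w)
    # keep the receptor total fixed: free receptor = total - bound PLC
    y0["RTK"] <- 0.05 - sum(y0 * sp$rtk_content)
    ss <- steady_state(net, y0 = y0)
    expect_equal(ss$active_fraction_ss, ref, tolerance = 1e-5)
  }
})

test_that("with phosphorylation cycles disabled the long-time state is detailed-balanced", {
  p <- plcg_parameters(k_phos = 0, k_dephos = 0)
  net <- generate_network(params = p)
  ss <- steady_state(net)
  v <- reaction_fluxes(net, ss$final_state)

  # pair each reaction with its reverse (reactant/product sets swapped)
  sig <- paste(net$reactions$reactants, net$reactions$products)
  rev_sig <- paste(net$reactions$products, net$reactions$reactants)
  paired <- 0
  for (j in seq_along(sig)) {
    jr <- match(sig[j], rev_sig)
    if (!is.na(jr) && v[j] > 0) {
      expect_equal(v[j], v[jr], tolerance = 1e-5)
      paired <- paired + 1
    }
  }
  # without phosphorylation only the 6 unphosphorylated states carry
  # mass, leaving 14 reversible pairs with nonzero flux
  expect_gt(paired, 10)
})

test_that("activation half-time interpolation matches closed forms", {
  # single-exponential rise: t_half = ln 2 / lambda
  lambda <- 0.05
  tt <- seq(0, 400, by = 0.5)
  traj <- list(times = tt, active_fraction = 0.3 * (1 - exp(-lambda * tt)))
  expect_equal(activation_halftime(traj, 0.3), log(2) / lambda,
               tolerance = 1e-3)

  # true two-state relaxation: rate kf + kr
  tr2 <- two_state_trajectory(0.02, 0.08, tt)
  traj2 <- list(times = tr2$time, active_fraction = tr2$active_fraction)
  expect_equal(activation_halftime(traj2, 0.2), log(2) / 0.1,
               tolerance = 1e-3)

  # refinement invariance
  fine <- seq(0, 400, by = 0.05)
  trajf <- list(times = fine, active_fraction = 0.3 * (1 - exp(-lambda * fine)))
  expect_equal(activation_halftime(trajf, 0.3),
               activation_halftime(traj, 0.3), tolerance = 1e-3)

  expect_error(activation_halftime(list(times = 1:3,
                                        active_fraction = c(0, 0.01, 0.02)),
                                   1), "not bracketed")
})

test_that("steady-state activity responds monotonically to single rate edits", {
  a_ss_of <- function(...) {
    p <- plcg_parameters(...)
    steady_state(generate_network(params = p))$active_fraction_ss
  }
  base <- a_ss_of()
  expect_lt(a_ss_of(k_bind_c = 1000), base)   # stronger autoinhibition
  expect_gt(a_ss_of(k_unbind_c = 10), base)   # weaker autoinhibition
  expect_gt(a_ss_of(k_bind_p = 1000), base)   # stronger pTyr capture
  expect_gt(a_ss_of(k_act = 0.1), base)       # faster membrane insertion
  expect_gt(a_ss_of(k_phos = 10), base)       # faster phosphorylation
})

test_that("dose-response curves are monotone and ordered by phospho-state", {
  doses <- c(0.005, 0.015, 0.03, 0.05)
  wt <- dose_response(rtk_values = doses)
  expect_true(all(diff(wt$active_fraction_ss) > 0))

  y783f <- dose_response(plcg_parameters(k_phos = 0), doses)
  mim <- dose_response(rtk_values = doses, phosphomimetic = TRUE)
  expect_true(all(y783f$active_fraction_ss < mim$active_fraction_ss))
  expect_true(all(y783f$active_fraction_ss < wt$active_fraction_ss))

  # zero-receptor limit equals the cytosol-only equilibrium
  lim <- dose_response(plcg_parameters(k_phos = 0), 0)
  expect_equal(lim$active_fraction_ss, 0.1 / 101.1, tolerance = 1e-4)

  # saturation: the 10 -> 100 step moves the curve less than 1 -> 10
  a1 <- dose_response(plcg_parameters(k_phos = 1), 0.03)$active_fraction_ss
  a10 <- dose_response(plcg_parameters(k_phos = 10), 0.03)$active_fraction_ss
  a100 <- dose_response(plcg_parameters(k_phos = 100), 0.03)$active_fraction_ss
  expect_lt(a100 - a10, a10 - a1)
})

test_that("the decay protocol preserves rebinding and measures a clean half-life", {
  res <- decay_protocol()
  expect_gt(res$half_life, 0)
  # monotone decay toward zero after the switch
  af <- res$post$active_fraction
  expect_lt(utils::tail(af, 1), 0.05 * res$active_at_switch)
  expect_true(all(diff(af) < 1e-9))

  # half-life grows with the membrane-association rate (10x)
  res_hi <- decay_protocol(plcg_parameters(k_act = 0.1))
  expect_gt(res_hi$half_life, res$half_life)

  # ... and is much less sensitive to the phosphorylation rate
  res_ph <- decay_protocol(plcg_parameters(k_phos = 10))
  fold_act <- res_hi$half_life / res$half_life
  fold_phos <- res_ph$half_life / res$half_life
  expect_gt(fold_act, 2)
  expect_lt(abs(log(fold_phos)), 0.5 * abs(log(fold_act)))
})
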