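# Reduced kinetic model: rate laws, conservation, steady states,
# stoichiometric closure, thermodynamic sanity.

test_that("ATPase rate law satisfies its Michaelis identities", {
  d <- demand_spec(k = 1, km_atp = 0.5)
  expect_equal(atpase_rate(0.5, d), 0.5)     # half-saturation
  expect_equal(atpase_rate(0, d), 0)
  expect_equal(atpase_rate(3 * 0.5, d), 0.75)  # 3/(3+1)
  atp <- seq(0, 10, by = 0.5)
  expect_true(all(diff(atpase_rate(atp, d)) > 0))
  expect_true(all(atpase_rate(atp, d) < 1))
  expect_error(atpase_rate(-1, d), "non-negative")
})

test_that("default parameters are positive, pure, and yield a fit resting neuron", {
  expect_identical(default_parameters(), default_parameters())
  expect_true(all(unlist(default_parameters()) > 0))
  ss <- cached_ss(5, 0, "low")
  expect_gte(ss$state[["atp_cyt"]], 1)
  expect_equal(ss$state[["atp_cyt"]], 2.5, tolerance = 0.05)
})

test_that("conserved pairs receive exactly opposite derivatives", {
  s <- metabolic_state(params = params)
  d <- rhs(s, params, external_conditions(2, 1),
           demand_spec(0.1, params$atpase_km))
  expect_identical(d[["atp_cyt"]] + d[["adp_cyt"]], 0)
  expect_identical(d[["nadh_cyt"]] + d[["nad_cyt"]], 0)
  expect_identical(d[["atp_mit"]] + d[["adp_mit"]], 0)
  expect_identical(d[["nadh_mit"]] + d[["nad_mit"]], 0)
  expect_error(rhs(replace(s, 1, NaN), params, external_conditions(2, 1),
                   demand_spec(0.1, 0.25)), "non-finite")
})

test_that("without any carbon source ATP drains and no flux runs", {
  # de-energized mitochondria: no residual ANT/synthase supply
  s <- metabolic_state(glc_cyt = 0, pyr_cyt = 0, lac_cyt = 0,
                      atp_cyt = 2, atp_mit = 0, nadh_mit = 0,
                      fadh2_equiv_mit = 0, dpsi = 10, dph = 0.05,
                      params = params)
  cond <- external_conditions(0, 0)
  dem <- demand_spec(0.1, params$atpase_km)
  d <- rhs(s, params, cond, dem)
  fl <- neuroenergetics:::model_fluxes(s, params, cond, dem)
  expect_equal(fl$v_gly, 0)
  expect_equal(fl$v_tca, 0)
  expect_lt(d[["atp_cyt"]], 0)
})

test_that("a short integration matches the rhs to first order", {
  s <- metabolic_state(params = params)
  cond <- external_conditions(3, 1)
  dem <- demand_spec(0.2, params$atpase_km)
  h <- 1e-6  # below the fastest (membrane-potential) timescale
  tr <- integrate_model(s, c(0, h), params, cond, dem)
  fd <- (tr[2, -1] - tr[1, -1]) / h
  an <- rhs(s, params, cond, dem)
  scale <- pmax(abs(an), 1e-3)
  expect_lt(max(abs(fd - an) / scale), 1e-3)
})

test_that("pools are conserved along a 60 s trajectory", {
  tr <- integrate_model(initial_state("energized", params),
                        seq(0, 60, by = 5), params,
                        external_conditions(2, 2),
                        demand_level("intermediate", params))
  drift <- function(x) max(abs(x - x[1])) / abs(x[1])
  expect_lt(drift(tr[, "atp_cyt"] + tr[, "adp_cyt"]), 1e-8)
  expect_lt(drift(tr[, "atp_mit"] + tr[, "adp_mit"]), 1e-8)
  expect_lt(drift(tr[, "nadh_cyt"] + tr[, "nad_cyt"]), 1e-8)
  expect_lt(drift(tr[, "nadh_mit"] + tr[, "nad_mit"]), 1e-8)
})

test_that("steady state satisfies the paper-level regime checks", {
  # glucose only: net lactate release
  expect_gt(cached_ss(5, 0, "low")$fluxes$j_lac, 0)
  # lactate only at low demand: fit, net lactate uptake
  ss <- cached_ss(0, 5, "low")
  expect_gte(ss$state[["atp_cyt"]], 1)
  expect_lt(ss$fluxes$j_lac, 0)
  # no carbon at all: deficit
  expect_lt(cached_ss(0, 0, "low")$state[["atp_cyt"]], 1)
})

test_that("steady-state balances close and respond linearly to perturbation", {
  ss <- cached_ss(5, 0, "intermediate")
  expect_true(all(abs(balance_residuals(ss$fluxes)) < 1e-6))
  fl <- ss$fluxes
  fl$j_glc <- fl$j_glc + 1
  expect_equal(unname(balance_residuals(fl)["carbon"]), 6,
               tolerance = 1e-9)
})

test_that("complete lactate oxidation consumes 3 O2 per lactate", {
  ss <- cached_ss(0, 5, "low")
  ratio <- ss$fluxes$j_o2 / (-ss$fluxes$j_lac)
  expect_equal(ratio, 3, tolerance = 0.01)
})

test_that("LDH and MCT2 vanish at their equilibrium ratios", {
  p <- params
  # LDH: pyr*nadh = lac*nad/Keq
  s <- metabolic_state(pyr_cyt = 0.1, nadh_cyt = 0.005,
                      lac_cyt = 0.1 * 0.005 * p$ldh_keq /
                        (p$pool_n_cyt - 0.005), params = p)
  fl <- neuroenergetics:::model_fluxes(
    s, p, external_conditions(1, 1), demand_spec(0, p$atpase_km))
  expect_equal(fl$v_ldh, 0, tolerance = 1e-12)
  # MCT2: internal lactate equals the proton-weighted external level
  cond <- external_conditions(1, 2, ph_ext = 7.3)
  le <- 2 * 10^(p$ph_cyt - 7.3)
  s2 <- metabolic_state(lac_cyt = le, params = p)
  fl2 <- neuroenergetics:::model_fluxes(s2, p, cond,
                                        demand_spec(0, p$atpase_km))
  expect_equal(fl2$v_mct, 0, tolerance = 1e-12)
})

test_that("60 mmHg oxygen is saturating", {
  a60 <- steady_state(params, external_conditions(3, 2, po2 = 60),
                      "intermediate")$state[["atp_cyt"]]
  a120 <- steady_state(params, external_conditions(3, 2, po2 = 120),
                       "intermediate")$state[["atp_cyt"]]
  expect_lt(abs(a120 - a60) / a60, 0.01)
})

test_that("demand levels are ordered and ATP responds monotonically", {
  ks <- vapply(c("low", "intermediate", "high"),
               function(l) demand_level(l, params)$k, numeric(1))
  expect_true(all(diff(ks) > 0))
  expect_identical(demand_level("low", params), demand_level("low", params))
  expect_error(demand_level("extreme", params))

  kgrid <- seq(0.05, 0.4, length.out = 5)
  res <- vapply(kgrid, function(k) {
    ss <- steady_state(params, external_conditions(3, 1),
                       demand_spec(k, params$atpase_km))
    c(ss$state[["atp_cyt"]], ss$fluxes$j_glc)
  }, numeric(2))
  expect_true(all(diff(res[1, ]) <= 1e-6))   # ATP non-increasing
  expect_true(all(diff(res[2, ]) >= -1e-6))  # glucose influx non-decreasing
})

test_that("the steady state is independent of the documented initial conditions", {
  conds <- list(c(4.2, 0.3, "low"), c(0.8, 3.5, "intermediate"),
                c(2.5, 2.5, "high"), c(0.1, 4.8, "low"))
  for (cc in conds) {
    a <- steady_state(params,
                      external_conditions(as.numeric(cc[1]),
                                          as.numeric(cc[2])),
                      cc[3], init = "energized")$state
    b <- steady_state(params,
                      external_conditions(as.numeric(cc[1]),
                                          as.numeric(cc[2])),
                      cc[3], init = "deenergized")$state
    expect_lt(max(abs(a - b) / pmax(abs(a), 1e-6)), 1e-6)
  }
})

test_that("root refinement agrees with a pure long-horizon integration", {
  set.seed(7)
  for (i in 1:4) {
    glc <- runif(1, 0.5, 5); lac <- runif(1, 0, 5)
    lvl <- sample(c("low", "intermediate"), 1)
    cond <- external_conditions(glc, lac)
    dem <- demand_level(lvl, params)
    ss <- steady_state(params, cond, dem)
    tr <- integrate_model(initial_state("energized", params),
                          c(0, 20000), params, cond, dem)
    oracle <- tr[nrow(tr), -1]
    rel <- abs(ss$state - oracle[names(ss$state)]) /
      pmax(abs(ss$state), 1e-6)
    expect_lt(max(rel), 1e-5)
  }
})

test_that("non-convergence raises a classed error carrying the last state", {
  # an impossible tolerance forces the failure path
  err <- tryCatch(
    steady_state(params, external_conditions(1, 1), "low",
                 tol = 1e-18, t_integrate = 1),
    neuro_nonconvergence = function(e) e)
  expect_s3_class(err, "neuro_nonconvergence")
  expect_true(!is.null(err$state))
})
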