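test_that("effective phosphorylation rate saturates at three degrons", {
  p <- kinetic_params(k_phos = 0.4)
  expect_equal(effective_phospho_rate(0, p), 0)
  expect_equal(effective_phospho_rate(2, p), 2 * effective_phospho_rate(1, p))
  expect_equal(effective_phospho_rate(4, p), effective_phospho_rate(3, p))
  expect_equal(effective_phospho_rate(5, p), effective_phospho_rate(3, p))
  expect_true(all(diff(effective_phospho_rate(0:5, p)) >= 0))
  expect_error(effective_phospho_rate(6, p), "0, 5")
  # smooth alternative keeps the asymptote and monotonicity
  ps <- kinetic_params(k_phos = 0.4, smooth_saturation = TRUE)
  expect_true(all(diff(effective_phospho_rate(0:5, ps)) > 0))
  expect_lt(effective_phospho_rate(5, ps), ps$k_phos * ps$m_sat)
})

test_that("binding occupancy reflects scenario and ABA dose", {
  p <- kinetic_params(K_bind = 0.25, kinase_total = 1)
  base <- 1 / (1 + 0.25)
  expect_equal(binding_occupancy(10, 0, scenario(), p), base)
  expect_equal(binding_occupancy(10, 100, scenario(domains_matched = FALSE), p), 0)
  expect_equal(binding_occupancy(10, 0, scenario(binding_mode = "aba_inducible"), p), 0)
  # at 100 uM ABA with K_aba = 1, n = 2 occupancy is >= 99% of its asymptote
  occ100 <- binding_occupancy(10, 100, scenario(binding_mode = "aba_inducible"), p)
  expect_gte(occ100, 0.99 * base)
  expect_equal(occ100, base * 100^2 / (1 + 100^2))
  # swapped orientation at half efficiency
  expect_equal(binding_occupancy(10, 0, scenario(binding_mode = "constitutive_swapped"), p),
               base * 0.5)
})

test_that("disabling the degradation arm gives the analytic steady state", {
  p <- kinetic_params(k_basal_deg = 0)
  for (s in list(scenario(kinase_active = FALSE),
                 scenario(degron_functional = FALSE),
                 scenario(domains_matched = FALSE))) {
    ss <- steady_state(p, s, list(alpha = 10))
    expect_equal(ss[["total"]], p$k_syn / p$k_dil, tolerance = 1e-12)
  }
  # the same balance with phosphorylation formally present but rate zero
  ss0 <- steady_state(kinetic_params(k_phos = 0, k_basal_deg = 0),
                      scenario(), list(alpha = 10))
  expect_equal(ss0[["S"]], 100)
})

test_that("the three negative controls are trajectory-equivalent", {
  p <- kinetic_params()
  times <- seq(0, 240, by = 30)
  scens <- list(dead = scenario(kinase_active = FALSE),
                broken = scenario(degron_functional = FALSE),
                unmatched = scenario(domains_matched = FALSE))
  trajs <- lapply(scens, function(s) {
    simulate_kinetics(p, s, list(alpha = 10), times)$total
  })
  expect_equal(trajs$dead, trajs$broken, tolerance = 1e-9)
  expect_equal(trajs$dead, trajs$unmatched, tolerance = 1e-9)
  # and all equal the k_phos = 0 parameterization of the functional scenario
  zero <- simulate_kinetics(kinetic_params(k_phos = 0), scenario(),
                            list(alpha = 10), times)$total
  expect_equal(trajs$broken, zero, tolerance = 1e-9)
})

test_that("linear-regime trajectories match the matrix-exponential closed form", {
  # constitutively active kinase pins K* = K_tot, leaving a linear
  # two-state system for (S, Sp)
  p <- kinetic_params(k_phos = 0.2)
  s <- scenario(constitutive_kinase = TRUE)
  times <- seq(0, 300, by = 20)
  traj <- simulate_kinetics(p, s, list(alpha = 0), times, init = "zero")
  bocc <- binding_occupancy(0, 0, s, p)
  rp <- p$k_phos * min(p$m, p$m_sat) * bocc * p$kinase_total
  basal <- p$k_basal_deg * min(p$m, 5)
  M <- rbind(c(-(p$k_dil + basal + rp), p$k_deph),
             c(rp, -(p$k_deg + p$k_dil + p$k_deph)))
  closed <- linear_ode_solution(M, b = c(p$k_syn, 0), x0 = c(0, 0), times)
  expect_equal(traj$S, closed[, 1], tolerance = 1e-3)
  expect_equal(traj$Sp, closed[, 2], tolerance = 1e-3)
  expect_equal(traj$total[-1], rowSums(closed)[-1], tolerance = 1e-3)
})

test_that("total substrate is conserved when all sources and sinks are off", {
  p <- kinetic_params(k_syn = 0, k_dil = 0, k_deg = 0, k_basal_deg = 0,
                      binding = "explicit")
  s <- scenario(constitutive_kinase = TRUE)
  traj <- simulate_kinetics(p, s, list(alpha = 0), times = seq(0, 200, 20),
                            init = c(K1 = 1, S1 = 10, C1 = 0, Sp1 = 0))
  expect_equal(traj$total, rep(10, nrow(traj)), tolerance = 1e-7)
  # mass moves between pools even though the total is conserved
  expect_gt(max(traj$Sp), 0.5)
})

test_that("trajectories are non-negative across random parameter draws", {
  set.seed(6)
  for (i in 1:8) {
    p <- kinetic_params(k_phos = runif(1, 0, 1), k_deg = runif(1, 0.05, 1),
                        k_deph = runif(1, 0, 0.2), m = sample(0:5, 1),
                        k_basal_deg = runif(1, 0, 0.01))
    tr <- simulate_kinetics(p, scenario(), list(alpha = runif(1, 0, 10)),
                            times = seq(0, 300, 50))
    expect_true(all(as.matrix(tr[c("S", "complex", "Sp", "Kstar", "total")]) >= -1e-8))
  }
})

test_that("steady state agrees with long-time integration", {
  set.seed(9)
  for (i in 1:5) {
    p <- kinetic_params(k_phos = runif(1, 0.1, 0.8), k_deg = runif(1, 0.1, 1),
                        m = sample(1:5, 1))
    ss <- steady_state(p, scenario(), list(alpha = 3))
    tr <- simulate_kinetics(p, scenario(), list(alpha = 3), times = c(0, 1e4))
    expect_equal(ss[["total"]], tr$total[2], tolerance = 1e-3)
  }
  # explicit-binding mode too
  pe <- kinetic_params(binding = "explicit")
  sse <- steady_state(pe, scenario(), list(alpha = 5))
  tre <- simulate_kinetics(pe, scenario(), list(alpha = 5), times = c(0, 1e4))
  expect_equal(sse[["total"]], tre$total[2], tolerance = 1e-3)
})

test_that("steady-state reporter is monotone in k_phos, degron count and ABA", {
  base <- kinetic_params()
  tot_kphos <- vapply(c(0, 0.1, 0.3, 0.6, 1), function(k) {
    steady_state(kinetic_params(k_phos = k), scenario(),
                 list(alpha = 10))[["total"]]
  }, numeric(1))
  expect_true(all(diff(tot_kphos) <= 1e-9))
  tot_m <- vapply(0:3, function(m) {
    steady_state(kinetic_params(m = m), scenario(), list(alpha = 10))[["total"]]
  }, numeric(1))
  expect_true(all(diff(tot_m) <= 1e-9))
  tot_aba <- vapply(c(0, 0.1, 1, 3, 10, 100), function(a) {
    steady_state(base, scenario(binding_mode = "aba_inducible"),
                 list(alpha = 10, aba = a))[["total"]]
  }, numeric(1))
  expect_true(all(diff(tot_aba) <= 1e-9))
  # ABA response is threshold-like around K_aba = 1 uM
  expect_gt(tot_aba[2] / tot_aba[1], 0.9)   # 0.1 uM: little effect
  expect_lt(tot_aba[4] / tot_aba[1], 0.5)   # 3 uM: strong degradation
})

test_that("constitutively active kinase degrades only the functional target", {
  p <- kinetic_params()
  s_fun <- scenario(constitutive_kinase = TRUE)
  s_ctl <- scenario(constitutive_kinase = TRUE, degron_functional = FALSE)
  fun <- steady_state(p, s_fun, list(alpha = 0))
  ctl <- steady_state(p, s_ctl, list(alpha = 0))
  expect_gt(ctl[["total"]] / fun[["total"]], 1)
})

test_that("simulated trajectories match an independent RK4 oracle", {
  cases <- list(
    list(p = kinetic_params(), s = scenario(), alpha = 10, aba = 0),
    list(p = kinetic_params(m = 3), s = scenario(binding_mode = "aba_inducible"),
         alpha = 10, aba = 10),
    list(p = kinetic_params(), s = scenario(promoter = "pfus1"), alpha = 1, aba = 0))
  times <- seq(0, 240, by = 40)
  for (cs in cases) {
    traj <- simulate_kinetics(cs$p, cs$s, list(alpha = cs$alpha, aba = cs$aba), times)
    oracle <- rk4_kinetics(cs$p, cs$s, cs$alpha, cs$aba, times)
    expect_equal(traj$total, oracle$total, tolerance = 1e-2)
  }
})

test_that("finite shared pools create competition; infinite pools do not", {
  # unlimited machinery: identical response with and without competitor
  p_inf <- kinetic_params()
  f_inf <- competition_fold_change(p_inf, scenario(), "substrate",
                                   list(alpha = 10), t_end = 120)
  expect_equal(f_inf[["fold_alone"]], f_inf[["fold_with_competitor"]],
               tolerance = 1e-6)
  k_inf <- competition_fold_change(p_inf, scenario(), "kinase",
                                   list(alpha = 10), t_end = 120)
  expect_equal(k_inf[["fold_alone"]], k_inf[["fold_with_competitor"]],
               tolerance = 1e-6)
  # finite SCF capacity: the competing substrate strictly weakens degradation
  p_scf <- kinetic_params(scf_capacity = 5)
  f_scf <- competition_fold_change(p_scf, scenario(), "substrate",
                                   list(alpha = 10), t_end = 120)
  expect_lt(f_scf[["fold_with_competitor"]], f_scf[["fold_alone"]])
  # finite Ste7 capacity: the competing kinase weakens activation
  p_ste7 <- kinetic_params(ste7_capacity = 0.5)
  f_ste7 <- competition_fold_change(p_ste7, scenario(), "kinase",
                                    list(alpha = 10), t_end = 120)
  expect_lt(f_ste7[["fold_with_competitor"]], f_ste7[["fold_alone"]])
})

test_that("two-substrate competition matches a direct coupled-ODE oracle", {
  p <- kinetic_params(scf_capacity = 5)
  s <- scenario(competitor = "substrate")
  times <- c(0, 60, 120)
  traj <- simulate_kinetics(p, s, list(alpha = 10), times)
  # independent RK4 of the full coupled two-substrate system
  occ_a <- 10 / (p$K_alpha + 10)
  bocc <- 1 / (1 + p$K_bind / p$kinase_total)
  eff <- p$k_phos * min(p$m, p$m_sat)
  basal <- p$k_basal_deg * min(p$m, 5)
  rhs <- function(y) {
    K <- y[1]; S1 <- y[2]; Sp1 <- y[3]; S2 <- y[4]; Sp2 <- y[5]
    dK <- p$k_act * occ_a * (p$kinase_total - K) - p$k_inact * K
    kdeg <- p$k_deg * p$scf_capacity / (p$scf_capacity + Sp1 + Sp2)
    rp <- eff * bocc * K
    c(dK,
      p$k_syn - (p$k_dil + basal + rp) * S1 + p$k_deph * Sp1,
      rp * S1 - (kdeg + p$k_dil + p$k_deph) * Sp1,
      p$k_syn - (p$k_dil + basal + rp) * S2 + p$k_deph * Sp2,
      rp * S2 - (kdeg + p$k_dil + p$k_deph) * Sp2)
  }
  ss0 <- steady_state(p, scenario(), list(alpha = 0))
  y <- c(0, ss0[["S"]], ss0[["Sp"]], ss0[["S"]], ss0[["Sp"]])
  dt <- 0.01; t_now <- 0; tot <- c(y[2] + y[3])
  for (tt in times[-1]) {
    while (t_now < tt - 1e-9) {
      h <- min(dt, tt - t_now)
      k1 <- rhs(y); k2 <- rhs(y + h / 2 * k1)
      k3 <- rhs(y + h / 2 * k2); k4 <- rhs(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t_now <- t_now + h
    }
    tot <- c(tot, y[2] + y[3])
  }
  expect_equal(traj$total, tot, tolerance = 1e-2)
})
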