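test_that("zero and offset correction follow the dialect rules", {
  # Accuri: zeros become 1, everything else untouched
  acc <- manual_events(c(0, 5, 0))
  expect_equal(clean_events(acc)$fl1_a, c(1, 5, 1))
  acc2 <- manual_events(c(3, 5, 7))
  expect_equal(clean_events(acc2)$fl1_a, c(3, 5, 7))
  # cleaning an already-clean Accuri table is the identity
  expect_equal(clean_events(clean_events(acc))$fl1_a, c(1, 5, 1))
  # VYB: shift by |batch minimum| + 1
  vyb <- manual_events(c(-50, 0, 10), dialect = "vyb")
  expect_equal(clean_events(vyb)$fl1_a, c(1, 51, 61))
  # shared day-level batch minimum overrides the per-table one
  vyb2 <- manual_events(c(-10, 5), dialect = "vyb")
  expect_equal(clean_events(vyb2, batch_min = c(fl1_a = -50))$fl1_a, c(41, 56))
  bad <- manual_events(1:3, dialect = "other")
  expect_error(clean_events(bad), "dialect")
})

test_that("anomaly gating removes a transient FSC burst and nothing else", {
  # moderate size dispersion: the gate targets transients, and a clean
  # read of this population stays entirely inside 5 robust SDs
  spec <- population_spec(n_events = 5000, size_cv = 0.1, seed = 17)
  tab <- generate_population(spec)
  # clean read: nothing removed at the default threshold
  gated <- gate_anomalies(tab, window = 5, mad_threshold = 5)
  expect_identical(nrow(gated), nrow(tab))
  expect_identical(events_metadata(gated)$n_gated, 0L)
  # inject a 2-second burst of 10x FSC events at known indices
  burst <- which(tab$t_acquire >= 20 & tab$t_acquire <= 22)
  expect_gt(length(burst), 50)
  tab2 <- tab
  tab2$fsc_a[burst] <- tab2$fsc_a[burst] * 10
  gated2 <- gate_anomalies(tab2, window = 5, mad_threshold = 5)
  expect_identical(events_metadata(gated2)$n_gated, length(burst))
  expect_equal(sort(gated2$t_acquire), sort(tab$t_acquire[-burst]))
  # infinite threshold is the identity
  same <- gate_anomalies(tab2, window = 5, mad_threshold = Inf)
  expect_identical(nrow(same), nrow(tab2))
  # over-wide window falls back to one global window with a warning
  expect_warning(gate_anomalies(tab, window = 1e6), "global")
})

test_that("size normalization divides fluorescence by FSC-A", {
  tab <- manual_events(c(1000, 1), fsc = c(500, 100))
  norm <- size_normalize(tab)
  expect_equal(norm$fl1_a_norm, c(2, 0.01))
  expect_identical(names(norm), c("fsc_a", "fl1_a", "t_acquire", "fl1_a_norm"))
  # exact proportionality leaves zero variance
  prop <- manual_events(c(100, 200, 400), fsc = c(50, 100, 200))
  expect_equal(var(size_normalize(prop)$fl1_a_norm), 0)
  bad <- manual_events(c(1, 2), fsc = c(0, 100))
  expect_error(size_normalize(bad), "clean_events")
})

test_that("population summaries use type-7 quantiles and linear-scale CV", {
  tab <- manual_events(c(1, 2, 3))
  s <- summarize_population(tab, channel = "fl1_a")
  expect_equal(s$median, 2)
  expect_equal(c(s$q1, s$q3), c(1.5, 2.5))
  const <- manual_events(rep(4.2, 10))
  sc <- summarize_population(const, channel = "fl1_a")
  expect_equal(sc$cv, 0)
  expect_equal(sc$median, 4.2)
  # log-normal CV has the closed form sqrt(exp(sigma^2) - 1)
  sigma <- sqrt(log(1 + 0.3^2))
  set.seed(8)
  x <- rlnorm(1e5, 0, sigma)
  slog <- summarize_population(manual_events(x), channel = "fl1_a")
  expect_equal(slog$cv, sqrt(exp(sigma^2) - 1), tolerance = 0.02)
  expect_error(summarize_population(manual_events(numeric())), "empty")
})

test_that("summaries are invariant to event order", {
  spec <- population_spec(n_events = 3000, seed = 19)
  tab <- size_normalize(clean_events(generate_population(spec)))
  set.seed(4)
  perm <- mapkrewire:::event_table(
    as.data.frame(tab)[sample(nrow(tab)), , drop = FALSE],
    events_metadata(tab))
  a <- summarize_population(tab)
  b <- summarize_population(perm)
  expect_equal(a$median, b$median)
  expect_equal(c(a$q1, a$q3, a$cv), c(b$q1, b$q3, b$cv))
})

test_that("fold change is oriented untreated over treated", {
  u <- summarize_population(manual_events(rep(5, 5)), channel = "fl1_a")
  t1 <- summarize_population(manual_events(rep(1, 5)), channel = "fl1_a")
  fc <- fold_change(u, t1)
  expect_equal(fc$fold, 5)
  expect_equal(fc$log10_fold, 0.699, tolerance = 1e-3)
  expect_equal(fold_change(u, u)$fold, 1)
})

test_that("the full pipeline recovers the generator's calibrated fold drop", {
  # the kinetic defaults are calibrated to a ~3.7-fold concentration drop
  # 3 h after saturating pheromone; the processed medians must agree with
  # the generator's own ground truth
  p <- kinetic_params()
  traj <- simulate_kinetics(p, scenario(), list(alpha = 10), c(0, 180))
  truth_scale <- traj$total[2] / traj$total[1]
  spec <- population_spec(n_events = 10000, seed = 29)
  tc <- generate_timecourse(spec, p, c(0, 180), scen = scenario(),
                            inputs = list(alpha = 10))
  summ <- lapply(tc, function(t) {
    summarize_population(size_normalize(clean_events(t)))
  })
  fc <- fold_change(summ[[1]], summ[[2]])
  # oracle: expected medians including the autofluorescence floor
  sdl <- function(cv) sqrt(log(1 + cv^2))
  set.seed(1234)
  nn <- 2e5
  sz <- exp(rnorm(nn, log(spec$size_median), sdl(spec$size_cv)))
  med_norm <- function(scale) {
    conc <- exp(rnorm(nn, log(spec$conc_median * scale), sdl(spec$conc_cv)))
    median(conc + spec$autofluorescence / sz)
  }
  oracle_fold <- med_norm(1) / med_norm(truth_scale)
  expect_equal(fc$fold, oracle_fold, tolerance = 0.03)
  expect_equal(1 / truth_scale, 3.7, tolerance = 0.05)
})

test_that("CV reduction matches its definition and a Monte-Carlo oracle", {
  mk <- function(cv) structure(list(median = 1, q1 = 1, q3 = 1, cv = cv,
                                    n_events = 10L, channel = "fl1_a",
                                    metadata = list()),
                               class = "population_summary")
  expect_equal(cv_reduction(mk(0.3), mk(0.1)), 100 * (1 - 1 / 3))
  # constant cell size: normalization rescales by a constant, reduction 0
  spec0 <- population_spec(n_events = 5000, size_cv = 0, autofluorescence = 0,
                           noise_frac = 0, seed = 41)
  tab0 <- size_normalize(clean_events(generate_population(spec0)))
  raw0 <- summarize_population(tab0, "fl1_a")
  nrm0 <- summarize_population(tab0, "fl1_a_norm")
  expect_equal(cv_reduction(raw0, nrm0), 0, tolerance = 1e-10)
  # size-correlated population: reduction matches the oracle within 2 points
  spec <- population_spec(n_events = 10000, size_cv = 0.4, conc_cv = 0.1,
                          autofluorescence = 0, noise_frac = 0, seed = 43)
  tab <- size_normalize(clean_events(generate_population(spec)))
  red <- cv_reduction(summarize_population(tab, "fl1_a"),
                      summarize_population(tab, "fl1_a_norm"))
  oracle <- mc_cv_reduction(2e5, spec$size_median, 0.4, spec$conc_median,
                            0.1, autofl = 0, seed = 77)
  expect_lt(abs(red - oracle), 2)
})

test_that("size normalization strictly reduces CV on size-correlated populations", {
  for (cfg in list(c(0.3, 0.1, 51), c(0.4, 0.2, 52), c(0.5, 0.3, 53))) {
    spec <- population_spec(n_events = 6000, size_cv = cfg[1], conc_cv = cfg[2],
                            autofluorescence = 0, noise_frac = 0, seed = cfg[3])
    tab <- size_normalize(clean_events(generate_population(spec)))
    raw <- summarize_population(tab, "fl1_a")
    nrm <- summarize_population(tab, "fl1_a_norm")
    expect_lt(nrm$cv, raw$cv)
  }
})
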