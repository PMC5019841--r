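# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: plain Monte-Carlo draws, a hand-rolled
# fixed-step RK4 integrator, and an eigen-decomposition matrix
# exponential for linear systems.

# Monte-Carlo oracle for the fluorescence-size correlation of a
# size x concentration population (no autofluorescence, no noise).
mc_size_fluor_r2 <- function(n, size_median, size_cv, conc_median, conc_cv,
                             seed) {
  set.seed(seed)
  sdl <- function(cv) sqrt(log(1 + cv^2))
  size <- exp(rnorm(n, log(size_median), sdl(size_cv)))
  conc <- exp(rnorm(n, log(conc_median), sdl(conc_cv)))
  cor(size * conc, size)^2
}

# Monte-Carlo oracle for the CV reduction achieved by dividing
# fluorescence by size.
mc_cv_reduction <- function(n, size_median, size_cv, conc_median, conc_cv,
                            autofl, seed) {
  set.seed(seed)
  sdl <- function(cv) sqrt(log(1 + cv^2))
  size <- exp(rnorm(n, log(size_median), sdl(size_cv)))
  conc <- exp(rnorm(n, log(conc_median), sdl(conc_cv)))
  fl <- size * conc + autofl
  cv <- function(x) sd(x) / mean(x)
  100 * (1 - cv(fl / size) / cv(fl))
}

# Fixed-step RK4 integration of the quasi-steady-state kinetic model,
# written directly from the model equations (independent of deSolve and
# of the package's RHS function). Supports the single-substrate,
# no-competitor scenarios used in the oracle tests.
rk4_kinetics <- function(p, s, alpha, aba, times, dt = 0.02, y0 = NULL) {
  occ_a <- alpha / (p$K_alpha + alpha)
  bocc <- if (!s$domains_matched) 0 else {
    b <- 1 / (1 + p$K_bind / p$kinase_total)
    if (s$binding_mode == "aba_inducible") {
      b * aba^p$n_aba / (p$K_aba^p$n_aba + aba^p$n_aba)
    } else if (s$binding_mode == "constitutive_swapped") {
      b * p$swap_efficiency
    } else b
  }
  eff <- p$k_phos * min(p$m, p$m_sat)
  basal <- p$k_basal_deg * min(p$m, 5)
  arm <- as.numeric(s$kinase_active && s$degron_functional)
  rhs <- function(y) {
    K <- y[1]; S <- y[2]; Sp <- y[3]
    dK <- if (s$constitutive_kinase) 0 else {
      p$k_act * occ_a * (p$kinase_total - K) - p$k_inact * K
    }
    kfrac <- K / p$kinase_total
    syn <- p$k_syn * if (s$promoter == "pfus1") {
      h <- kfrac^p$n_tx / (p$K_tx^p$n_tx + kfrac^p$n_tx)
      p$tx_leak + (1 - p$tx_leak) * h
    } else 1
    rp <- eff * bocc * K * arm
    dS <- syn - (p$k_dil + basal + rp) * S + p$k_deph * Sp
    dSp <- rp * S - (p$k_deg + p$k_dil + p$k_deph) * Sp
    c(dK, dS, dSp)
  }
  if (is.null(y0)) {
    # untreated steady state: K = 0 at alpha = 0, then linear balance
    K0 <- if (s$constitutive_kinase) p$kinase_total else 0
    kfrac <- K0 / p$kinase_total
    syn0 <- p$k_syn * if (s$promoter == "pfus1") {
      h <- kfrac^p$n_tx / (p$K_tx^p$n_tx + kfrac^p$n_tx)
      p$tx_leak + (1 - p$tx_leak) * h
    } else 1
    rp0 <- eff * bocc * K0 * arm
    A <- rbind(c(-(p$k_dil + basal + rp0), p$k_deph),
               c(rp0, -(p$k_deg + p$k_dil + p$k_deph)))
    x <- solve(A, c(-syn0, 0))
    y0 <- c(K0, x[1], x[2])
  }
  out <- matrix(NA_real_, length(times), 4,
                dimnames = list(NULL, c("time", "K", "S", "Sp")))
  y <- y0; t_now <- times[1]
  out[1, ] <- c(t_now, y)
  for (i in seq_along(times)[-1]) {
    while (t_now < times[i] - 1e-12) {
      h <- min(dt, times[i] - t_now)
      k1 <- rhs(y)
      k2 <- rhs(y + h / 2 * k1)
      k3 <- rhs(y + h / 2 * k2)
      k4 <- rhs(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t_now <- t_now + h
    }
    out[i, ] <- c(t_now, y)
  }
  df <- as.data.frame(out)
  df$total <- df$S + df$Sp
  df
}

# Closed-form solution of dx/dt = M x + b via eigen decomposition:
# x(t) = xss + V exp(L t) V^-1 (x0 - xss) with xss = -M^-1 b.
linear_ode_solution <- function(M, b, x0, times) {
  xss <- solve(M, -b)
  eg <- eigen(M)
  Vi <- solve(eg$vectors)
  t(vapply(times, function(t) {
    Re(xss + eg$vectors %*% (exp(eg$values * t) * (Vi %*% (x0 - xss))))
  }, numeric(length(x0))))
}

# Brute-force grid argmax oracle for interior maxima of a dose-response
# function.
grid_argmax <- function(f, lower = 1e-4, upper = 1e4, n = 1e4) {
  x <- exp(seq(log(lower), log(upper), length.out = n))
  y <- f(x)
  i <- which.max(y)
  if (i == 1 || i == n) return(NA_real_)
  x[i]
}

# Small event table built by hand for micro-examples.
manual_events <- function(fl, fsc = rep(100, length(fl)), dialect = "accuri") {
  mapkrewire:::event_table(
    data.frame(fsc_a = fsc, fl1_a = fl,
               t_acquire = seq(0, 1, length.out = length(fl))),
    list(dialect = dialect))
}
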