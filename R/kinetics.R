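#' Rate constants for the retargeted-kinase degradation model
#'
#' Parameters of the mechanistic ODE model of kinase-directed,
#' phosphodegron-mediated reporter degradation. The model tracks active
#' kinase `K*`, free substrate `S`, kinase-substrate complex (explicit
#' binding mode only) and phospho-tagged substrate `Sp`; the observable
#' reporter signal is proportional to `S + complex + Sp`.
#'
#' The study system provides no measured rate constants, so every
#' default here is a calibration choice: dilution matches slow log-phase
#' growth, and the phosphorylation/degradation arm is calibrated so that
#' the fully functional constitutive strain shows a ~3.7-fold drop in
#' total reporter three hours after saturating pheromone induction, the
#' magnitude characteristic of this class of synthetic degradation
#' circuits.
#'
#' @param k_syn substrate synthesis rate (conc/min).
#' @param k_dil dilution/turnover rate (1/min).
#' @param k_act kinase activation rate per unit receptor occupancy (1/min).
#' @param k_inact kinase deactivation rate (1/min).
#' @param K_bind kinase-substrate interaction dissociation constant
#'   (same concentration units as `kinase_total`).
#' @param k_phos per-degron phosphorylation rate in complex (1/min).
#' @param k_deph dephosphorylation rate (1/min).
#' @param k_deg degradation rate of phospho-tagged substrate via
#'   SCF/Cdc4 (1/min).
#' @param k_basal_deg basal degradation per unphosphorylated degron
#'   (1/min); scales with `min(m, 5)` and captures the lowered steady
#'   state of multi-degron reporters.
#' @param m phosphodegron count, integer 0-5.
#' @param m_sat degron count at which the phosphorylation rate saturates
#'   (default 3).
#' @param K_alpha alpha-factor half-occupancy constant (uM).
#' @param K_aba ABA half-binding constant (uM).
#' @param n_aba ABA Hill coefficient.
#' @param kinase_total total retargeted kinase pool (conc; the active
#'   fraction `K*/kinase_total` lies in `[0, 1]`).
#' @param ste7_capacity shared MAPKK (Ste7) pool available for kinase
#'   activation; `Inf` disables upstream competition.
#' @param scf_capacity shared SCF/Cdc4 degradation capacity; `Inf`
#'   disables degradation-machinery competition.
#' @param swap_efficiency binding efficiency of the swapped
#'   domain-orientation variant relative to the original (default 0.5).
#' @param tx_leak leaky fraction of synthesis for the pathway-driven
#'   (pFUS1) promoter.
#' @param K_tx half-activation of pFUS1 transcription in units of active
#'   kinase fraction.
#' @param n_tx transcriptional Hill coefficient of pFUS1.
#' @param binding `"qss"` treats binding as quasi-steady-state occupancy
#'   (default, non-stiff); `"explicit"` integrates the complex species.
#' @param k_off complex dissociation rate used in explicit binding mode
#'   (1/min); `k_on` is derived as `k_off / K_bind`.
#' @param smooth_saturation logical; replace the piecewise-linear degron
#'   saturation `min(m, m_sat)` by the smooth form
#'   `m_sat * m / (m_sat + m)` with the same asymptote.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(k_syn = 1,
                           k_dil = 0.01,
                           k_act = 0.1,
                           k_inact = 0.5,
                           K_bind = 0.25,
                           k_phos = 0.32,
                           k_deph = 0.05,
                           k_deg = 0.5,
                           k_basal_deg = 0.002,
                           m = 1L,
                           m_sat = 3L,
                           K_alpha = 1,
                           K_aba = 1,
                           n_aba = 2,
                           kinase_total = 1,
                           ste7_capacity = Inf,
                           scf_capacity = Inf,
                           swap_efficiency = 0.5,
                           tx_leak = 0.05,
                           K_tx = 0.02,
                           n_tx = 2,
                           binding = c("qss", "explicit"),
                           k_off = 10,
                           smooth_saturation = FALSE) {
  binding <- match.arg(binding)
  for (nm in c("k_syn", "k_dil", "k_act", "k_inact", "k_phos", "k_deph",
               "k_deg", "k_basal_deg", "tx_leak")) {
    check_number(get(nm), nm, min = 0)
  }
  for (nm in c("K_bind", "K_alpha", "K_aba", "K_tx", "kinase_total", "k_off")) {
    check_number(get(nm), nm, min = 0, strict_min = TRUE)
  }
  if (!is.numeric(m) || length(m) != 1L || m != round(m) || m < 0 || m > 5) {
    stop_param("`m` must be an integer between 0 and 5")
  }
  if (m_sat < 1) stop_param("`m_sat` must be >= 1")
  if (!(is.infinite(ste7_capacity) || ste7_capacity > 0)) {
    stop_param("`ste7_capacity` must be positive or Inf")
  }
  if (!(is.infinite(scf_capacity) || scf_capacity > 0)) {
    stop_param("`scf_capacity` must be positive or Inf")
  }
  structure(list(
    k_syn = k_syn, k_dil = k_dil, k_act = k_act, k_inact = k_inact,
    K_bind = K_bind, k_phos = k_phos, k_deph = k_deph, k_deg = k_deg,
    k_basal_deg = k_basal_deg, m = as.integer(m), m_sat = m_sat,
    K_alpha = K_alpha, K_aba = K_aba, n_aba = n_aba,
    kinase_total = kinase_total, ste7_capacity = ste7_capacity,
    scf_capacity = scf_capacity, swap_efficiency = swap_efficiency,
    tx_leak = tx_leak, K_tx = K_tx, n_tx = n_tx,
    binding = binding, k_off = k_off,
    smooth_saturation = isTRUE(smooth_saturation)
  ), class = "kinetic_params")
}

#' Experimental scenario switches for the kinetic model
#'
#' Encodes the control and variant strain classes: dead kinase (K42R),
#' broken phosphodegron (phospho-acceptor threonines mutated), unmatched
#' interaction domains, ABA-inducible versus constitutive colocalization,
#' domain-orientation swap, constitutively active MEK1-ERK2 fusion
#' (bypasses the pheromone input), pathway-driven (pFUS1) reporter
#' transcription, and upstream/degradation-machinery competitors.
#'
#' All three classical negative controls (dead kinase, broken degron,
#' unmatched domains) disable the same phosphorylation-dependent
#' degradation arm and are trajectory-equivalent; basal weak binding of
#' the unphosphorylated degron to the degradation machinery is phospho-
#' independent and remains active in all of them.
#'
#' @param kinase_active `FALSE` models the catalytically dead K42R kinase.
#' @param degron_functional `FALSE` models the T->M/A degron mutant.
#' @param domains_matched `FALSE` models mismatched interaction domains
#'   (no colocalization).
#' @param binding_mode `"constitutive"`, `"aba_inducible"`, or
#'   `"constitutive_swapped"` (domain orientation flipped, reduced
#'   efficiency).
#' @param constitutive_kinase `TRUE` models the MEK1-ERK2 fusion: the
#'   kinase is fully active regardless of pheromone dose.
#' @param promoter `"constitutive"` (TDH3-like) or `"pfus1"` (reporter
#'   synthesis proportional to pathway activity; the hybrid incoherent
#'   feed-forward configuration).
#' @param competitor `"none"`, `"kinase"` (second retargeted kinase
#'   sharing the Ste7 pool) or `"substrate"` (second degron reporter
#'   sharing SCF capacity).
#' @return An object of class `kinetic_scenario`.
#' @export
scenario <- function(kinase_active = TRUE,
                     degron_functional = TRUE,
                     domains_matched = TRUE,
                     binding_mode = c("constitutive", "aba_inducible",
                                      "constitutive_swapped"),
                     constitutive_kinase = FALSE,
                     promoter = c("constitutive", "pfus1"),
                     competitor = c("none", "kinase", "substrate")) {
  structure(list(
    kinase_active = isTRUE(kinase_active),
    degron_functional = isTRUE(degron_functional),
    domains_matched = isTRUE(domains_matched),
    binding_mode = match.arg(binding_mode),
    constitutive_kinase = isTRUE(constitutive_kinase),
    promoter = match.arg(promoter),
    competitor = match.arg(competitor)
  ), class = "kinetic_scenario")
}

#' Effective phosphorylation rate for a multi-degron substrate
#'
#' Phosphorylation scales linearly with degron count up to the
#' saturation count `m_sat` (default 3) and is flat beyond it:
#' `k_phos * min(m, m_sat)`. A smooth alternative with the same
#' asymptote is available via `smooth_saturation` in [kinetic_params()].
#'
#' @param m degron count, integer 0-5.
#' @param p a [kinetic_params()] object.
#' @return Rate in 1/min.
#' @export
effective_phospho_rate <- function(m, p) {
  stopifnot(inherits(p, "kinetic_params"))
  if (any(m < 0 | m > 5)) stop_param("`m` must lie in [0, 5]")
  if (p$smooth_saturation) {
    p$k_phos * p$m_sat * m / (p$m_sat + m)
  } else {
    p$k_phos * pmin(m, p$m_sat)
  }
}

#' Kinase-substrate colocalization occupancy
#'
#' Fraction of substrate colocalized with the retargeted kinase under a
#' scenario: `1 / (1 + K_bind / kinase_total)` for constitutive
#' interaction domains, scaled by `swap_efficiency` for the flipped
#' orientation, multiplied by the ABA occupancy Hill term
#' `aba^n / (K_aba^n + aba^n)` in ABA-inducible mode, and 0 for
#' mismatched domains.
#'
#' @param alpha alpha-factor dose (uM); part of the interface for
#'   symmetry with the pathway input, not used by binding itself.
#' @param aba ABA dose (uM).
#' @param s a [scenario()] object.
#' @param p a [kinetic_params()] object.
#' @return Occupancy fraction in `[0, 1]`.
#' @export
binding_occupancy <- function(alpha, aba, s, p) {
  stopifnot(inherits(s, "kinetic_scenario"), inherits(p, "kinetic_params"))
  if (any(alpha < 0) || any(aba < 0)) stop_param("doses must be non-negative")
  if (!s$domains_matched) return(0 * aba)
  base <- 1 / (1 + p$K_bind / p$kinase_total)
  switch(s$binding_mode,
    constitutive = base + 0 * aba,
    constitutive_swapped = base * p$swap_efficiency + 0 * aba,
    aba_inducible = {
      an <- aba^p$n_aba
      base * an / (p$K_aba^p$n_aba + an)
    })
}

# Receptor occupancy of the pheromone input (Michaelis form; the pathway
# has no published upstream dose-transfer function).
alpha_occupancy <- function(alpha, p) alpha / (p$K_alpha + alpha)

# pFUS1-driven synthesis multiplier as a function of active kinase fraction.
tx_activity <- function(kfrac, p) {
  h <- kfrac^p$n_tx / (p$K_tx^p$n_tx + kfrac^p$n_tx)
  p$tx_leak + (1 - p$tx_leak) * h
}

# Whether the phosphorylation-dependent degradation arm is live.
phospho_arm_on <- function(s) s$kinase_active && s$degron_functional

# Steady-state active kinase for given inputs (closed form when the Ste7
# pool is unlimited, scalar root otherwise).
kinase_steady_state <- function(p, s, alpha) {
  if (s$constitutive_kinase) return(p$kinase_total)
  occ <- alpha_occupancy(alpha, p)
  a <- p$k_act * occ
  if (a == 0) return(0)
  if (is.infinite(p$ste7_capacity)) {
    return(a * p$kinase_total / (a + p$k_inact))
  }
  P <- p$ste7_capacity
  f <- function(K) {
    inact_pool <- p$kinase_total - K
    a * inact_pool * P / (P + inact_pool) - p$k_inact * K
  }
  uniroot(f, c(0, p$kinase_total), tol = 1e-14)$root
}

# Right-hand side of the kinetic ODE system. State layout:
#   K1 [, K2]            active kinase(s)
#   S1, C1, Sp1          reporter substrate (C1 fixed at 0 in QSS mode)
#   [S2, C2, Sp2]        competitor substrate
kinetic_rhs <- function(t, state, parms) {
  p <- parms$p
  s <- parms$s
  alpha <- parms$alpha
  aba <- parms$aba

  occ_a <- alpha_occupancy(alpha, p)
  bocc <- binding_occupancy(alpha, aba, s, p)
  eff <- effective_phospho_rate(p$m, p)
  basal <- p$k_basal_deg * min(p$m, 5)
  n_kin <- if (s$competitor == "kinase") 2L else 1L
  n_sub <- if (s$competitor == "substrate") 2L else 1L

  K <- state[seq_len(n_kin)]
  rest <- state[-seq_len(n_kin)]
  S <- rest[seq(1, by = 3, length.out = n_sub)]
  C <- rest[seq(2, by = 3, length.out = n_sub)]
  Sp <- rest[seq(3, by = 3, length.out = n_sub)]

  # kinase activation, throttled by the shared Ste7 pool when finite
  if (s$constitutive_kinase) {
    dK <- rep(0, n_kin)
  } else {
    inact <- p$kinase_total - K
    ste7 <- if (is.infinite(p$ste7_capacity)) 1 else {
      p$ste7_capacity / (p$ste7_capacity + sum(inact))
    }
    dK <- p$k_act * occ_a * inact * ste7 - p$k_inact * K
  }

  kfrac <- K[1] / p$kinase_total
  syn <- p$k_syn * if (s$promoter == "pfus1") tx_activity(kfrac, p) else 1
  arm <- if (phospho_arm_on(s)) 1 else 0

  # SCF/Cdc4 capacity shared across all phospho-tagged substrate
  scf <- if (is.infinite(p$scf_capacity)) 1 else {
    p$scf_capacity / (p$scf_capacity + sum(Sp))
  }
  kdeg <- p$k_deg * scf

  dS <- numeric(n_sub); dC <- numeric(n_sub); dSp <- numeric(n_sub)
  for (i in seq_len(n_sub)) {
    # competitor substrate has a fully functional arm driven by the same kinase
    arm_i <- if (i == 1L) arm else 1
    if (p$binding == "qss") {
      rp <- eff * bocc * K[1] * arm_i
      dS[i] <- syn - (p$k_dil + basal + rp) * S[i] + p$k_deph * Sp[i]
      dC[i] <- 0
      dSp[i] <- rp * S[i] - (kdeg + p$k_dil + p$k_deph) * Sp[i]
    } else {
      # explicit complex: colocalization is activity-independent; catalysis
      # in complex is gated by the active kinase fraction
      kon <- p$k_off / p$K_bind
      bind_scale <- bocc / (1 / (1 + p$K_bind / p$kinase_total))  # aba/mismatch scaling
      if (!is.finite(bind_scale)) bind_scale <- 0
      kon_eff <- kon * p$kinase_total * bind_scale
      rp <- eff * kfrac * arm_i
      dS[i] <- syn - (p$k_dil + basal) * S[i] - kon_eff * S[i] +
        p$k_off * C[i] + p$k_deph * Sp[i]
      dC[i] <- kon_eff * S[i] - (p$k_off + p$k_dil + basal + rp) * C[i]
      dSp[i] <- rp * C[i] - (kdeg + p$k_dil + p$k_deph) * Sp[i]
    }
  }
  list(c(dK, rbind(dS, dC, dSp)))
}

kinetic_state_names <- function(s) {
  nm <- if (s$competitor == "kinase") c("K1", "K2") else "K1"
  sub <- c("S1", "C1", "Sp1")
  if (s$competitor == "substrate") sub <- c(sub, "S2", "C2", "Sp2")
  c(nm, sub)
}

#' Simulate the retargeted-kinase degradation model
#'
#' Integrates the scenario-configured ODE system with a stiff-capable
#' solver. By default the simulation starts from the untreated steady
#' state (the pre-induction log-phase culture) and the pheromone input
#' is applied at `t = 0`.
#'
#' @param p a [kinetic_params()] object.
#' @param s a [scenario()] object.
#' @param inputs list with elements `alpha` and `aba` (uM).
#' @param times output times in minutes, starting at 0.
#' @param init `"untreated"` (steady state at `alpha = 0`, same ABA),
#'   `"zero"` (all species 0), or a named numeric state vector.
#' @param rtol,atol integrator tolerances.
#' @return A `kinetic_trajectory` data frame with columns `time`, `S`,
#'   `complex`, `Sp`, `Kstar` and `total` (= S + complex + Sp, the
#'   reporter signal).
#' @examples
#' p <- kinetic_params()
#' traj <- simulate_kinetics(p, scenario(), list(alpha = 10, aba = 0),
#'                           times = seq(0, 180, by = 15))
#' traj$total[1] / traj$total[nrow(traj)]  # fold drop after 3 h
#' @export
simulate_kinetics <- function(p, s, inputs = list(alpha = 0, aba = 0),
                              times, init = "untreated",
                              rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(p, "kinetic_params"), inherits(s, "kinetic_scenario"))
  if (times[1] != 0 || is.unsorted(times, strictly = TRUE)) {
    stop_param("`times` must be strictly increasing and start at 0")
  }
  alpha <- inputs$alpha %||% 0
  aba <- inputs$aba %||% 0
  nms <- kinetic_state_names(s)

  if (is.numeric(init)) {
    y0 <- init
    if (length(y0) != length(nms)) stop_param("`init` has wrong length")
  } else if (identical(init, "zero")) {
    y0 <- setNames(numeric(length(nms)), nms)
    if (s$constitutive_kinase) y0[grep("^K", nms)] <- p$kinase_total
  } else {
    s0 <- s; s0$competitor <- "none"
    ss <- steady_state(p, s0, list(alpha = 0, aba = aba))
    y0 <- setNames(numeric(length(nms)), nms)
    y0["K1"] <- ss[["Kstar"]]
    if ("K2" %in% nms) y0["K2"] <- ss[["Kstar"]]
    y0["S1"] <- ss[["S"]]; y0["C1"] <- ss[["complex"]]; y0["Sp1"] <- ss[["Sp"]]
    if ("S2" %in% nms) {
      # competitor substrate starts at its own untreated steady state
      y0["S2"] <- ss[["S"]]; y0["C2"] <- ss[["complex"]]; y0["Sp2"] <- ss[["Sp"]]
    }
  }

  parms <- list(p = p, s = s, alpha = alpha, aba = aba)
  sol <- try(deSolve::ode(y = y0, times = times, func = kinetic_rhs,
                          parms = parms, method = "lsoda",
                          rtol = rtol, atol = atol), silent = TRUE)
  if (inherits(sol, "try-error")) {
    stop_param("ODE integration failed (alpha=%g, aba=%g): %s",
               alpha, aba, attr(sol, "condition")$message)
  }
  sol <- as.data.frame(sol)
  names(sol) <- c("time", nms)
  out <- data.frame(time = sol$time,
                    S = sol$S1, complex = sol$C1, Sp = sol$Sp1,
                    Kstar = sol$K1)
  out$total <- out$S + out$complex + out$Sp
  if (any(out[-1] < -1e-8)) {
    warning("negative concentrations beyond integrator tolerance")
  }
  structure(out, class = c("kinetic_trajectory", "data.frame"),
            params = p, scenario = s, inputs = list(alpha = alpha, aba = aba),
            full_state = sol)
}

#' Steady state of the retargeted-kinase degradation model
#'
#' Solves the ODE right-hand side for its fixed point: the active-kinase
#' balance in closed form (or a bracketed scalar root under a finite
#' Ste7 pool), then the substrate subsystem, which is linear given the
#' kinase level except under finite SCF capacity where the tagged-pool
#' balance is solved by a bracketed root. The returned state is verified
#' against the ODE right-hand side.
#'
#' @inheritParams simulate_kinetics
#' @param tol residual tolerance for the fixed-point check.
#' @return Named vector with `S`, `complex`, `Sp`, `Kstar`, `total`.
#' @export
steady_state <- function(p, s, inputs = list(alpha = 0, aba = 0), tol = 1e-8) {
  stopifnot(inherits(p, "kinetic_params"), inherits(s, "kinetic_scenario"))
  if (s$competitor != "none") {
    stop_param("closed-form steady state supports competitor = 'none'; use simulate_kinetics")
  }
  alpha <- inputs$alpha %||% 0
  aba <- inputs$aba %||% 0
  Kss <- kinase_steady_state(p, s, alpha)
  kfrac <- Kss / p$kinase_total
  syn <- p$k_syn * if (s$promoter == "pfus1") tx_activity(kfrac, p) else 1
  bocc <- binding_occupancy(alpha, aba, s, p)
  eff <- effective_phospho_rate(p$m, p)
  basal <- p$k_basal_deg * min(p$m, 5)
  arm <- if (phospho_arm_on(s)) 1 else 0

  solve_sub_qss <- function(kdeg) {
    rp <- eff * bocc * Kss * arm
    A <- rbind(c(-(p$k_dil + basal + rp), p$k_deph),
               c(rp, -(kdeg + p$k_dil + p$k_deph)))
    x <- solve(A, c(-syn, 0))
    c(S = x[1], complex = 0, Sp = x[2])
  }
  solve_sub_explicit <- function(kdeg) {
    kon_eff <- {
      bind_scale <- bocc / (1 / (1 + p$K_bind / p$kinase_total))
      if (!is.finite(bind_scale)) bind_scale <- 0
      (p$k_off / p$K_bind) * p$kinase_total * bind_scale
    }
    rp <- eff * kfrac * arm
    A <- rbind(
      c(-(p$k_dil + basal + kon_eff), p$k_off, p$k_deph),
      c(kon_eff, -(p$k_off + p$k_dil + basal + rp), 0),
      c(0, rp, -(kdeg + p$k_dil + p$k_deph)))
    x <- solve(A, c(-syn, 0, 0))
    c(S = x[1], complex = x[2], Sp = x[3])
  }
  solve_sub <- if (p$binding == "qss") solve_sub_qss else solve_sub_explicit

  if (is.infinite(p$scf_capacity)) {
    st <- solve_sub(p$k_deg)
  } else {
    # self-consistent tagged pool under shared SCF capacity
    g <- function(Sp_guess) {
      kdeg <- p$k_deg * p$scf_capacity / (p$scf_capacity + Sp_guess)
      solve_sub(kdeg)[["Sp"]] - Sp_guess
    }
    hi <- min(max(1, syn / max(p$k_dil, 1e-12)), 1e12)
    root <- uniroot(g, c(0, hi), extendInt = "downX", tol = 1e-12)$root
    kdeg <- p$k_deg * p$scf_capacity / (p$scf_capacity + root)
    st <- solve_sub(kdeg)
  }

  nms <- kinetic_state_names(s)
  y <- setNames(numeric(length(nms)), nms)
  y["K1"] <- Kss; y["S1"] <- st[["S"]]; y["C1"] <- st[["complex"]]
  y["Sp1"] <- st[["Sp"]]
  resid <- kinetic_rhs(0, y, list(p = p, s = s, alpha = alpha, aba = aba))[[1]]
  if (max(abs(resid)) > tol * max(1, max(abs(y)))) {
    stop_param("steady-state residual %.3g exceeds tolerance", max(abs(resid)))
  }
  c(S = st[["S"]], complex = st[["complex"]], Sp = st[["Sp"]],
    Kstar = Kss, total = st[["S"]] + st[["complex"]] + st[["Sp"]])
}

#' Reporter fold change with and without a competing module
#'
#' Runs paired induction time courses of the standard one-kinase,
#' one-substrate system alone and with a competitor: a second
#' retargeted kinase drawing on the shared upstream MAPKK (Ste7) pool,
#' or a second degron substrate drawing on the shared SCF/Cdc4
#' degradation capacity. Both pools are modeled as conserved saturable
#' resources; with finite capacity the competitor can only weaken the
#' reporter response.
#'
#' @inheritParams simulate_kinetics
#' @param base a [scenario()] describing the reporter system (its
#'   `competitor` field is overridden).
#' @param competitor `"kinase"` or `"substrate"`.
#' @param t_end induction time at which the fold change is read (min).
#' @return Named vector `c(fold_alone, fold_with_competitor)`, each the
#'   ratio of total reporter at `t = 0` to `t = t_end`.
#' @export
competition_fold_change <- function(p, base, competitor = c("kinase", "substrate"),
                                    inputs = list(alpha = 10, aba = 100),
                                    t_end = 120) {
  competitor <- match.arg(competitor)
  stopifnot(inherits(base, "kinetic_scenario"))
  times <- c(0, t_end)
  s_alone <- base; s_alone$competitor <- "none"
  s_comp <- base; s_comp$competitor <- competitor
  fold <- function(s) {
    tr <- simulate_kinetics(p, s, inputs, times)
    tr$total[1] / tr$total[nrow(tr)]
  }
  c(fold_alone = fold(s_alone), fold_with_competitor = fold(s_comp))
}
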