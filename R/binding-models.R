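# 1:1 binding and stability models: equilibrium/kinetic ELISA, competitive
# inhibition (K_I), SPR sensorgrams, one-site ITC, and two-state thermal
# melts with GuHCl extrapolation. Concentrations are molar throughout;
# display formatting to nM/pM is left to the caller.

R_GAS <- 8.31446261815324 # J mol^-1 K^-1

new_ab_fit <- function(subclass, params, data, fitted, rss, extra = list()) {
  structure(
    c(list(params = params, data = data, fitted = fitted, rss = rss), extra),
    class = c(subclass, "ab_fit")
  )
}

#' @export
print.ab_fit <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  print(tibble(term = names(x$params), estimate = unlist(x$params)))
  cat("residual sum of squares: ", format(x$rss, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Equilibrium dissociation constant from rate constants
#'
#' `K_D = k_off / k_on` for a 1:1 interaction. The SPR rates
#' `k_on = 2.6e5 M^-1 s^-1`, `k_off = 1.2e-4 s^-1` give `K_D = 0.46 nM`.
#'
#' @param k_on Association rate constant, M^-1 s^-1 (> 0).
#' @param k_off Dissociation rate constant, s^-1 (>= 0).
#' @return K_D in molar.
#' @export
kd_from_rates <- function(k_on, k_off) {
  if (any(k_on <= 0)) stop("k_on must be positive", call. = FALSE)
  if (any(k_off < 0)) stop("k_off must be non-negative", call. = FALSE)
  k_off / k_on
}

#' @rdname kd_from_rates
#' @param K_D Equilibrium dissociation constant, M.
#' @export
koff_from_kd <- function(K_D, k_on) {
  if (any(k_on <= 0)) stop("k_on must be positive", call. = FALSE)
  K_D * k_on
}

#' Validated kinetic parameter set
#'
#' @param k_on,k_off Rate constants (positive).
#' @param K_D Optional; when given it must equal `k_off/k_on` to 1e-9
#'   relative.
#' @return One-row tibble `k_on`, `k_off`, `K_D`.
#' @export
kinetic_params <- function(k_on, k_off, K_D = NULL) {
  stopifnot(k_on > 0, k_off > 0)
  kd <- kd_from_rates(k_on, k_off)
  if (!is.null(K_D) && abs(K_D - kd) > 1e-9 * kd) {
    stop("K_D inconsistent with k_off/k_on", call. = FALSE)
  }
  tibble(k_on = k_on, k_off = k_off, K_D = kd)
}

#' Equilibrium bound fraction of a 1:1 interaction
#'
#' Excess-analyte isotherm `c/(c + K_D)`; the depletion-corrected variant
#' solves the exact mass balance for a finite total target concentration
#' and reports the bound fraction of target.
#'
#' @param conc Free (excess mode) or total (depletion mode) analyte
#'   concentration, M.
#' @param K_D Dissociation constant, M.
#' @param target_tot Total target concentration, M; when supplied the
#'   depletion-corrected quadratic is used.
#' @return Bound fraction in [0, 1]; 0 when both `conc` and `K_D` are zero.
#' @export
bound_fraction_equilibrium <- function(conc, K_D, target_tot = NULL) {
  stopifnot(all(conc >= 0), all(K_D >= 0))
  if (is.null(target_tot)) {
    out <- ifelse(conc == 0 & K_D == 0, 0, conc / (conc + K_D))
    return(out)
  }
  stopifnot(target_tot > 0)
  s <- conc + target_tot + K_D
  cx <- (s - sqrt(s^2 - 4 * conc * target_tot)) / 2
  cx / target_tot
}

#' Simulate a kinetic ELISA concentration-by-time grid
#'
#' Pseudo-first-order 1:1 binding of an analyte dilution series to coated
#' target read out at several incubation times:
#' `OD(c, t) = od_max * c/(c+K_D) * (1 - exp(-(k_on c + k_off) t))`.
#'
#' @param params Tibble/list with `k_on`, `k_off` (and `K_D`), e.g. from
#'   [kinetic_params()].
#' @param concs Analyte concentrations, M.
#' @param times Incubation times, s (non-negative).
#' @param od_max Saturating OD amplitude.
#' @param noise_sd Gaussian noise SD on OD.
#' @param seed Optional integer seed.
#' @return Tibble `conc_M`, `time_s`, `od`.
#' @export
simulate_kinetic_elisa <- function(params, concs, times, od_max = 1,
                                   noise_sd = 0, seed = NULL) {
  if (any(times < 0)) stop("negative incubation times", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  kd <- params$K_D %||% kd_from_rates(params$k_on, params$k_off)
  grid <- expand.grid(conc_M = concs, time_s = times)
  od <- od_max * bound_fraction_equilibrium(grid$conc_M, kd) *
    (1 - exp(-(params$k_on * grid$conc_M + params$k_off) * grid$time_s))
  tibble(conc_M = grid$conc_M, time_s = grid$time_s,
         od = od + stats::rnorm(nrow(grid), 0, noise_sd))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

multistart_nls <- function(data, formula, start_grid, lower = NULL,
                           upper = NULL) {
  best <- NULL
  for (i in seq_len(nrow(start_grid))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data,
                        start = as.list(start_grid[i, , drop = FALSE]),
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    stop("fit failed to converge from every start point", call. = FALSE)
  }
  best
}

#' Fit the kinetic ELISA model
#'
#' Least squares over the full concentration-by-time grid with two free
#' binding parameters, `K_D` and `k_on` (`k_off` reported as their
#' product), plus the amplitude `od_max` (co-fitted by default, or fixed).
#' Parameters are searched in log space with log-spaced multistarts (K_D
#' over 1e-12..1e-6 M, k_on over 1e3..1e8 M^-1 s^-1) to avoid local minima
#' on plateaued curves.
#'
#' @param data Tibble `conc_M`, `time_s`, `od` (>= 3 concentrations, >= 2
#'   times).
#' @param od_max Fix the amplitude at this value; `NULL` co-fits it.
#' @return `ab_kinelisa_fit` with `params` `K_D`, `k_on`, `k_off`,
#'   `od_max`.
#' @export
fit_kinetic_elisa <- function(data, od_max = NULL) {
  stopifnot(all(c("conc_M", "time_s", "od") %in% names(data)))
  if (length(unique(data$conc_M[data$conc_M > 0])) < 3 ||
      length(unique(data$time_s[data$time_s > 0])) < 2) {
    stop("need >= 3 concentrations and >= 2 time points", call. = FALSE)
  }
  amp0 <- od_max %||% max(data$od)
  starts <- expand.grid(lkd = seq(-12, -6, length.out = 5),
                        lkon = seq(3, 8, length.out = 4))
  starts$amp <- amp0
  fixed_amp <- !is.null(od_max)
  if (fixed_amp) {
    form <- od ~ amp0 * (conc_M / (conc_M + 10^lkd)) *
      (1 - exp(-(10^lkon * conc_M + 10^lkd * 10^lkon) * time_s))
    starts <- starts[, c("lkd", "lkon")]
  } else {
    form <- od ~ amp * (conc_M / (conc_M + 10^lkd)) *
      (1 - exp(-(10^lkon * conc_M + 10^lkd * 10^lkon) * time_s))
  }
  env_data <- cbind(data, amp0 = amp0)
  best <- multistart_nls(env_data, form, starts)
  cf <- stats::coef(best$fit)
  kd <- 10^cf[["lkd"]]
  kon <- 10^cf[["lkon"]]
  params <- list(K_D = kd, k_on = kon, k_off = kd * kon,
                 od_max = if (fixed_amp) od_max else cf[["amp"]])
  new_ab_fit("ab_kinelisa_fit", params, data,
             fitted = stats::fitted(best$fit), rss = best$rss)
}

#' Free ligand concentration in the presence of an inhibitor
#'
#' Exact 1:1 mass balance for ligand L sequestered by inhibitor I with
#' dissociation constant `K_I`: the complex concentration is the smaller
#' root of `C^2 - (L+I+K_I) C + L I = 0`, and `L_free = L_tot - C`. Always
#' within `[0, L_tot]` and monotone decreasing in `I_tot`.
#'
#' @param L_tot Total ligand (target) concentration, M.
#' @param I_tot Total inhibitor concentration, M (vectorized).
#' @param K_I Inhibition constant, M.
#' @return Free ligand concentration, M.
#' @export
free_ligand_with_inhibitor <- function(L_tot, I_tot, K_I) {
  stopifnot(all(L_tot >= 0), all(I_tot >= 0), all(K_I >= 0))
  # solve the mass balance for the free ligand F = L - C directly
  # (F^2 + F (I - L + K) - K L = 0, positive root), written so no
  # difference of nearly equal numbers occurs for any parameter regime
  b <- I_tot - L_tot + K_I
  disc <- sqrt(b^2 + 4 * K_I * L_tot)
  lf <- ifelse(b >= 0,
               ifelse(b + disc > 0, 2 * K_I * L_tot / (b + disc), L_tot),
               (disc - b) / 2)
  pmin(L_tot, pmax(0, lf))
}

#' Fit a four-parameter logistic dose-response
#'
#' `response = bottom + (top - bottom) * conc^h / (conc^h + ec50^h)`,
#' monotone in concentration. Used as the calibration model for
#' inhibition-constant fitting.
#'
#' @param conc Dose, M.
#' @param response Measured response.
#' @return `ab_4pl_fit` with `bottom`, `top`, `lec50` (log10 M), `h`.
#' @export
fit_4pl <- function(conc, response) {
  stopifnot(length(conc) == length(response), length(conc) >= 4)
  if (stats::sd(response) < 1e-12) {
    stop("flat calibration: dose-response unidentifiable", call. = FALSE)
  }
  pos <- conc > 0
  dat <- tibble(conc = conc, response = response)
  starts <- expand.grid(
    lec50 = seq(log10(min(conc[pos])), log10(max(conc[pos])), length.out = 6),
    h = c(0.8, 1, 1.5)
  )
  starts$bottom <- min(response)
  starts$top <- max(response)
  form <- response ~ bottom + (top - bottom) /
    (1 + (10^lec50 / pmax(conc, 1e-300))^h)
  best <- multistart_nls(dat, form, starts)
  cf <- as.list(stats::coef(best$fit))
  new_ab_fit("ab_4pl_fit", cf, dat, stats::fitted(best$fit), best$rss)
}

predict_4pl <- function(fit, conc) {
  p <- fit$params
  p$bottom + (p$top - p$bottom) / (1 + (10^p$lec50 / pmax(conc, 1e-300))^p$h)
}

#' Fit a functional inhibition constant through a calibration curve
#'
#' Models a cell-based inhibition experiment run at a fixed target
#' concentration `L_tot` with increasing inhibitor: the predicted response
#' at inhibitor concentration I is the calibration dose-response evaluated
#' at the free target concentration `L_free(L_tot, I, K_I)` from the exact
#' mass balance. The calibration is represented by a monotone
#' four-parameter logistic; `K_I` is found by least squares on a log10
#' grid refined by golden-section search.
#'
#' @param calibration Tibble `target_M`, `response`.
#' @param inhibition Tibble `inhibitor_M`, `response`.
#' @param L_tot Fixed target concentration of the inhibition series, M.
#' @return `ab_inhibition_fit` with `params` `K_I` plus the calibration
#'   fit.
#' @export
fit_inhibition <- function(calibration, inhibition, L_tot) {
  stopifnot(all(c("target_M", "response") %in% names(calibration)),
            all(c("inhibitor_M", "response") %in% names(inhibition)),
            L_tot > 0)
  if (all(inhibition$inhibitor_M == 0)) {
    stop("all-zero inhibitor series: K_I unidentifiable", call. = FALSE)
  }
  cal <- fit_4pl(calibration$target_M, calibration$response)
  sse <- function(lki) {
    lf <- free_ligand_with_inhibitor(L_tot, inhibition$inhibitor_M, 10^lki)
    sum((inhibition$response - predict_4pl(cal, lf))^2)
  }
  grid <- seq(-14, -4, by = 0.25)
  g <- vapply(grid, sse, numeric(1))
  i0 <- which.min(g)
  lo <- grid[max(1, i0 - 1)]
  hi <- grid[min(length(grid), i0 + 1)]
  opt <- stats::optimize(sse, lower = lo, upper = hi, tol = 1e-10)
  ki <- 10^opt$minimum
  lf <- free_ligand_with_inhibitor(L_tot, inhibition$inhibitor_M, ki)
  new_ab_fit("ab_inhibition_fit",
             list(K_I = ki, L_tot = L_tot), inhibition,
             fitted = predict_4pl(cal, lf), rss = opt$objective,
             extra = list(calibration_fit = cal))
}

#' Simulate a 1:1 Langmuir SPR sensorgram
#'
#' Association `R(t) = Req (1 - exp(-(k_on c + k_off) t))` with
#' `Req = Rmax c/(c + K_D)`, followed by exponential dissociation from the
#' association end level; the response is continuous at the phase boundary.
#'
#' @param params Kinetic parameters (`k_on`, `k_off`).
#' @param conc Analyte concentration, M.
#' @param Rmax Saturating response, RU.
#' @param t_assoc,t_dissoc Phase durations, s (positive).
#' @param dt Time step, s.
#' @param noise_sd Gaussian noise SD, RU.
#' @param seed Optional integer seed.
#' @return Tibble `time_s`, `ru`, `conc_M`, `phase`.
#' @export
simulate_sensorgram <- function(params, conc, Rmax, t_assoc = 180,
                                t_dissoc = 1200, dt = 1, noise_sd = 0,
                                seed = NULL) {
  stopifnot(t_assoc > 0, t_dissoc > 0, conc >= 0, Rmax >= 0)
  if (!is.null(seed)) set.seed(seed)
  kd <- params$K_D %||% kd_from_rates(params$k_on, params$k_off)
  ta <- seq(0, t_assoc, by = dt)
  td <- seq(dt, t_dissoc, by = dt)
  req <- Rmax * bound_fraction_equilibrium(conc, kd)
  ra <- req * (1 - exp(-(params$k_on * conc + params$k_off) * ta))
  r_end <- ra[length(ra)]
  rd <- r_end * exp(-params$k_off * td)
  out <- tibble(
    time_s = c(ta, t_assoc + td),
    ru = c(ra, rd),
    conc_M = conc,
    phase = c(rep("association", length(ta)), rep("dissociation", length(td)))
  )
  out$ru <- out$ru + stats::rnorm(nrow(out), 0, noise_sd)
  out
}

#' Global 1:1 fit of a sensorgram set
#'
#' Fits `k_on`, `k_off` and `Rmax` shared across all analyte
#' concentrations (association and dissociation phases jointly), in log
#' space with multistarts.
#'
#' @param sensorgrams Tibble stacking >= 2 concentrations of
#'   [simulate_sensorgram()]-shaped data (`time_s`, `ru`, `conc_M`,
#'   `phase`); association-phase time is measured from injection start and
#'   the dissociation phase follows a shared `t_assoc`.
#' @param t_assoc Association-phase duration, s.
#' @return `ab_spr_fit` with `params` `k_on`, `k_off`, `K_D`, `Rmax`.
#' @export
fit_sensorgrams <- function(sensorgrams, t_assoc = 180) {
  stopifnot(all(c("time_s", "ru", "conc_M", "phase") %in% names(sensorgrams)))
  if (length(unique(sensorgrams$conc_M[sensorgrams$conc_M > 0])) < 2) {
    stop("need >= 2 analyte concentrations for a global fit", call. = FALSE)
  }
  dat <- as_tibble(sensorgrams)
  dat$t_a <- pmin(dat$time_s, t_assoc)
  dat$t_d <- pmax(dat$time_s - t_assoc, 0)
  model_ru <- function(lkon, lkoff, Rmax, conc, t_a, t_d) {
    kon <- 10^lkon
    koff <- 10^lkoff
    req <- Rmax * conc / (conc + koff / kon)
    r_assoc <- req * (1 - exp(-(kon * conc + koff) * t_a))
    r_assoc * exp(-koff * t_d)
  }
  starts <- expand.grid(lkon = seq(3, 8, length.out = 4),
                        lkoff = seq(-6, -1, length.out = 4))
  starts$Rmax <- max(dat$ru)
  form <- ru ~ model_ru(lkon, lkoff, Rmax, conc_M, t_a, t_d)
  best <- multistart_nls(dat, form, starts)
  cf <- stats::coef(best$fit)
  kon <- 10^cf[["lkon"]]
  koff <- 10^cf[["lkoff"]]
  params <- list(k_on = kon, k_off = koff, K_D = koff / kon,
                 Rmax = cf[["Rmax"]])
  new_ab_fit("ab_spr_fit", params, dat, stats::fitted(best$fit), best$rss,
             extra = list(t_assoc = t_assoc))
}

itc_total_heat <- function(N, K_D, dH, Mt, Xt, V0) {
  sites <- N * Mt
  s <- sites + Xt + K_D
  cx <- (s - sqrt(s^2 - 4 * sites * Xt)) / 2
  cx * dH * V0 # Joules in the cell
}

# fast vector path shared by the simulator and the fitter
itc_heats_vec <- function(N, K_D, dH, cell_M, syringe_M, inj_vol, V0) {
  vcum <- cumsum(inj_vol)
  Mt <- cell_M * (1 - vcum / (2 * V0)) / (1 + vcum / (2 * V0))
  Xt <- syringe_M * (vcum / V0) / (1 + vcum / (2 * V0))
  Q <- itc_total_heat(N, K_D, dH, Mt, Xt, V0)
  Qprev <- c(0, Q[-length(Q)])
  list(Mt = Mt, Xt = Xt,
       dQ = Q - Qprev + (inj_vol / V0) * (Q + Qprev) / 2)
}

#' Per-injection heats of a one-site ITC titration
#'
#' Standard single-site total-heat model with displaced-volume
#' bookkeeping: after the i-th injection the cell concentrations are
#' diluted by the cumulative injected volume, the complex concentration
#' follows the exact 1:1 mass balance with stoichiometry `N`, and the
#' measured heat of injection i is the difference in cell heat content
#' plus the heat carried out by the displaced volume.
#'
#' @param N Binding stoichiometry (sites per cell molecule).
#' @param K_D Dissociation constant, M.
#' @param dH Molar binding enthalpy, J/mol (negative = exothermic).
#' @param cell_M Cell (macromolecule) concentration, M.
#' @param syringe_M Syringe (titrant) concentration, M.
#' @param injection_volumes_L Injection volumes, L (e.g. an initial 3 uL
#'   then 5-uL injections).
#' @param cell_volume_L Cell volume, L (default 1.4 mL, VP-ITC).
#' @param temperature_K Temperature (default 303.15 K, i.e. 30 C).
#' @param noise_sd Gaussian noise SD on heats, J.
#' @param seed Optional integer seed.
#' @return Tibble `injection`, `volume_L`, `Xt`, `Mt`, `molar_ratio`,
#'   `heat_J`.
#' @export
itc_one_site_heats <- function(N, K_D, dH, cell_M, syringe_M,
                               injection_volumes_L,
                               cell_volume_L = 1.4e-3,
                               temperature_K = 303.15,
                               noise_sd = 0, seed = NULL) {
  stopifnot(N > 0, K_D > 0, cell_M > 0, syringe_M > 0,
            all(injection_volumes_L > 0), cell_volume_L > 0)
  if (!is.null(seed)) set.seed(seed)
  hv <- itc_heats_vec(N, K_D, dH, cell_M, syringe_M, injection_volumes_L,
                      cell_volume_L)
  tibble(
    injection = seq_along(injection_volumes_L),
    volume_L = injection_volumes_L, Xt = hv$Xt, Mt = hv$Mt,
    molar_ratio = hv$Xt / hv$Mt,
    heat_J = hv$dQ + stats::rnorm(length(hv$dQ), 0, noise_sd)
  )
}

#' Fit the one-site model to ITC injection heats
#'
#' Recovers stoichiometry `N`, `K_D` and `dH` (plus a constant
#' per-injection dilution-heat offset) from per-injection heats, then
#' reports the thermodynamic decomposition `dG = RT ln K_D` and
#' `T dS = dH - dG`. Warns when the Wiseman c-value
#' (`N * cell_M / K_D`) is outside [1, 1e4], where `K_D` is weakly
#' identifiable.
#'
#' @param heats Tibble `injection`, `volume_L`, `heat_J` (first injection
#'   is dropped from the fit if `drop_first` is `TRUE`, standard practice
#'   for the small priming injection).
#' @param cell_M,syringe_M,cell_volume_L,temperature_K Experiment
#'   geometry, as in [itc_one_site_heats()].
#' @param drop_first Exclude injection 1 from the residuals.
#' @return `ab_itc_fit` with `params` `N`, `K_D`, `dH`, `dG`, `dS`,
#'   `offset`.
#' @export
fit_itc <- function(heats, cell_M, syringe_M, cell_volume_L = 1.4e-3,
                    temperature_K = 303.15, drop_first = TRUE) {
  stopifnot(all(c("injection", "volume_L", "heat_J") %in% names(heats)))
  # parameters searched as (log N, log10 K_D clamped, dH, offset) so the
  # simplex cannot wander into non-physical values
  model_heats <- function(lN, lkd, dH, offset) {
    lkd <- min(max(lkd, -15), -2)
    lN <- min(max(lN, -5), 5)
    itc_heats_vec(exp(lN), 10^lkd, dH, cell_M, syringe_M,
                  heats$volume_L, cell_volume_L)$dQ + offset
  }
  w <- rep(1, nrow(heats))
  if (drop_first) w[1] <- 0
  sse <- function(p) {
    sum(w * (heats$heat_J - model_heats(p[1], p[2], p[3], p[4]))^2)
  }
  # data-driven starts: dH from the saturated early injections (high
  # c-value titrations start on a plateau at dH per mole injected)
  mol_inj <- syringe_M * heats$volume_L
  ndh <- heats$heat_J / mol_inj
  dh0 <- stats::median(ndh[2:min(5, length(ndh))])
  if (!is.finite(dh0) || dh0 == 0) dh0 <- -5e4
  best <- NULL
  for (lkd0 in c(-10.5, -8.5, -6.5)) {
    o <- stats::optim(c(0, lkd0, dh0, 0), sse, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  # polish with a second pass from the best point
  best <- stats::optim(best$par, sse, method = "Nelder-Mead",
                       control = list(maxit = 3000, reltol = 1e-15))
  p <- best$par
  p[1] <- exp(min(max(p[1], -5), 5)) # back to N
  kd <- 10^min(max(p[2], -15), -2)
  cval <- p[1] * cell_M / kd
  if (cval < 1 || cval > 1e4) {
    warning("ITC c-value ", format(cval, digits = 3),
            " outside [1, 1e4]: K_D weakly identifiable", call. = FALSE)
  }
  dG <- R_GAS * temperature_K * log(kd) # J/mol, negative for K_D < 1 M
  dS <- (p[3] - dG) / temperature_K
  params <- list(N = p[1], K_D = kd, dH = p[3], dG = dG, dS = dS,
                 offset = p[4], temperature_K = temperature_K)
  new_ab_fit("ab_itc_fit", params, heats,
             fitted = model_heats(p[1], p[2], p[3], p[4]), rss = best$value,
             extra = list(c_value = cval))
}

#' Fit a two-state thermal melt
#'
#' Two-state sigmoid with linear folded/unfolded baselines:
#' `y(T) = (yf + mf T + (yu + mu T) K) / (1 + K)` with
#' `K = exp((T - Tm)/w)`; `Tm` is the transition midpoint. A midpoint
#' outside the scanned window is flagged as extrapolated.
#'
#' @param temperature Temperatures, same unit as the reported Tm
#'   (typically C); >= 5 points spanning the transition.
#' @param signal Spectroscopic signal (e.g. CD ellipticity).
#' @param baselines Fit linear baseline slopes (`TRUE`) or flat baselines.
#' @return `ab_melt_fit` with `params` `Tm`, `width`, baseline terms, and
#'   `extrapolated` flag.
#' @export
fit_melt_curve <- function(temperature, signal, baselines = TRUE) {
  stopifnot(length(temperature) == length(signal), length(temperature) >= 5)
  dat <- tibble(temperature = temperature, signal = signal)
  rng <- range(temperature)
  if (stats::sd(signal) < 1e-12) {
    stop("no transition in the scanned window", call. = FALSE)
  }
  starts <- expand.grid(
    Tm = seq(rng[1], rng[2], length.out = 5),
    w = diff(rng) / c(5, 10, 20)
  )
  starts$yf <- signal[which.min(temperature)]
  starts$yu <- signal[which.max(temperature)]
  if (baselines && length(temperature) >= 10) {
    starts$mf <- 0
    starts$mu <- 0
    form <- signal ~ (yf + mf * temperature +
                        (yu + mu * temperature) * exp((temperature - Tm) / w)) /
      (1 + exp((temperature - Tm) / w))
  } else {
    form <- signal ~ (yf + yu * exp((temperature - Tm) / w)) /
      (1 + exp((temperature - Tm) / w))
  }
  best <- multistart_nls(dat, form, starts)
  cf <- as.list(stats::coef(best$fit))
  extrapolated <- cf$Tm < rng[1] || cf$Tm > rng[2]
  if (extrapolated) {
    warning("fitted Tm lies outside the scanned temperature window",
            call. = FALSE)
  }
  new_ab_fit("ab_melt_fit", c(cf, list(Tm = cf$Tm)), dat,
             stats::fitted(best$fit), best$rss,
             extra = list(extrapolated = extrapolated))
}

#' Extrapolate melting temperatures to zero denaturant
#'
#' Ordinary least squares of Tm against GuHCl concentration; the intercept
#' estimates the melting temperature in the absence of denaturant, the
#' slope its sensitivity (degrees per molar).
#'
#' @param T_m Melting temperatures (>= 2).
#' @param guhcl_M Matching GuHCl concentrations, M (>= 2 distinct).
#' @return One-row tibble `slope`, `tm_at_zero`, `r_squared`, `n`.
#' @export
extrapolate_tm <- function(T_m, guhcl_M) {
  stopifnot(length(T_m) == length(guhcl_M), length(T_m) >= 2,
            length(unique(guhcl_M)) >= 2)
  fit <- stats::lm(T_m ~ guhcl_M)
  s <- suppressWarnings(summary(fit)) # exact lines are legitimate here
  tibble(
    slope = unname(stats::coef(fit)[2]),
    tm_at_zero = unname(stats::coef(fit)[1]),
    r_squared = s$r.squared,
    n = length(T_m)
  )
}
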