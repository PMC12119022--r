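# State vector layout for the slurry model (indices used by the integrator)
.ST_CP <- 1L; .ST_CF <- 2L; .ST_RF <- 3L; .ST_SS <- 4L
.ST_VFA <- 5L; .ST_INERT <- 6L
.ST_B1 <- 7L; .ST_B2 <- 8L; .ST_B3 <- 9L
.ST_MASS <- 10L
.ST_LEN <- 10L
.ST_NAMES <- c("cp", "cf", "rf", "ss", "vfa", "inert",
               "b1", "b2", "b3", "mass")

#' Kinetic parameter set for the slurry methane model
#'
#' Organic-matter pools (protein, fat, degradable residual fibre, and a
#' fast starch+sugar pool) hydrolyse to VFA with first-order,
#' temperature-dependent rate constants (Arrhenius-type,
#' `alpha(T) = alpha20 * exp(theta * (T - 20))`). A slow surface
#' respiration removes pool COD aerobically at rate `R(T)` with the same
#' temperature form. VFA is consumed by three methanogen populations
#' (biomass in g DM, stoichiometric composition C5H7O2N, 1.42 g COD/g DM)
#' with Monod kinetics, Gaussian temperature optima, and a shared VFA
#' inhibition term `1 / (1 + (VFA / k_i)^2)`; consumed VFA COD splits into
#' CH4 COD and new biomass by the growth yield. Decayed biomass returns to
#' the protein pool. Fresh excreta carry a methanogen inoculum
#' (`inoculum`, g biomass DM per kg influent solids, split equally over
#' the three populations); without it a frequently emptied pit would wash
#' the community out entirely, which is not observed in practice.
#'
#' The constants are the package's own calibration: they reproduce the
#' published qualitative behaviour (diet orderings, barn-vs-storage shares,
#' spillage response) but are not a normative parameter set; see the
#' methods vignette.
#'
#' @param ... overrides for any default element.
#' @return object of class `kinetic_params`.
#' @export
kinetic_params <- function(...) {
  p <- list(
    alpha20 = c(cp = 0.020, cf = 0.005, rf = 0.008, ss = 0.30),  # 1/day at 20 degC
    theta_hyd = 0.08,        # 1/degC temperature sensitivity of hydrolysis
    resp20 = 0.008,          # 1/day surface respiration at 20 degC
    theta_resp = 0.08,
    umax = c(3, 5, 8),       # g COD VFA / g DM biomass / day
    ks = c(0.30, 0.45, 0.60),# g VFA / kg slurry (half-saturation)
    topt = c(22, 32, 42),    # degC optima of the three populations
    sigma_t = 8,             # degC width of the temperature response
    yield = 0.05,            # g DM biomass per g COD VFA consumed
    decay = 0.01,            # 1/day biomass decay
    ki = 14,                 # g VFA / kg slurry inhibition constant
    inhib_exp = 2,
    inoculum = 9.5,          # g DM methanogen biomass per kg influent solids
    cod_biomass = 1.42,      # g COD per g DM biomass (C5H7O2N)
    cod_vfa = 1.07,          # g COD per g VFA (acetate)
    dt = 0.05)               # integration step, day
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown))
    stop("unknown kinetic parameter(s): ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  stopifnot(all(p$alpha20 > 0), all(p$umax > 0), all(p$ks > 0),
            p$yield > 0, p$yield * p$cod_biomass < 1,
            p$decay >= 0, p$ki > 0, p$dt > 0, p$dt <= 1)
  structure(p, class = "kinetic_params")
}

#' First-order hydrolysis rate constant of a pool at a temperature
#'
#' Strictly increasing in temperature; the fast starch+sugar pool is
#' constructed to hydrolyse at least as fast as every other pool at equal
#' temperature.
#'
#' @param pool one of `"cp"`, `"cf"`, `"rf"`, `"ss"`.
#' @param temperature degC, within \[-5, 45\].
#' @param params a [kinetic_params()].
#' @return 1/day.
#' @export
hydrolysis_rate <- function(pool, temperature, params = kinetic_params()) {
  pool <- match.arg(pool, names(params$alpha20))
  stopifnot(all(temperature >= -5), all(temperature <= 45))
  params$alpha20[[pool]] * exp(params$theta_hyd * (temperature - 20))
}

#' Build an empty slurry state
#'
#' @param mass initial slurry mass, kg (a small heel remains after pit
#'   emptying and carries the inoculum).
#' @param biomass initial biomass of each methanogen population, g DM.
#' @return named numeric state vector.
#' @export
manure_state <- function(mass = 1, biomass = c(0.01, 0.01, 0.01)) {
  s <- numeric(.ST_LEN)
  names(s) <- .ST_NAMES
  s[.ST_MASS] <- mass
  s[.ST_B1:.ST_B3] <- biomass
  s
}

#' Map an excreta profile (plus feed spillage) to daily slurry influent
#'
#' Excreted nutrients are converted to chemical oxygen demand with
#' standard oxidation stoichiometry (carbohydrate-like pools 1.19,
#' protein 1.42, lipid 2.90, VFA as acetate 1.07 g COD/g), applied once
#' here. Faecal iNDF goes to the inert pool; degradable residual fibre,
#' protein, fat and the small faecal starch+sugar residue to the
#' degradable pools; faecal VFA to the VFA pool. Spilled feed contributes
#' its undigested nutrient masses at diet composition, with starch+sugar
#' entering the fast pool. Water collects urine, faecal water, and the
#' water in spilled feed; urine urea-N is tracked as a non-COD solute.
#'
#' @param excreta an [excreta_profile()].
#' @param spillage_fraction fraction of feed intake spilled into the pit,
#'   in \[0, 0.2\].
#' @return object of class `influent_stream`: named numeric vector with
#'   elements `cp, cf, rf, ss, vfa, inert` (g COD/day), `water` and
#'   `solids` (kg/day), plus attribute `urea_n` (g N/day).
#' @export
excreta_to_influent <- function(excreta, spillage_fraction = 0) {
  stopifnot(inherits(excreta, "excreta_profile"))
  if (spillage_fraction < 0 || spillage_fraction > 0.2)
    stop("spillage_fraction must be in [0, 0.2]")
  COD_CARB <- 1.19; COD_PROT <- 1.42; COD_LIPID <- 2.90; COD_VFA <- 1.07
  ex <- excreta$excreted
  comp <- excreta$intake$composition
  feed_asfed <- excreta$intake$feed_asfed

  spill_asfed <- spillage_fraction * feed_asfed
  spill_dm <- spill_asfed * comp$dm / 1000
  spill <- function(conc) spill_dm * conc / 1000
  spill_deg_rf <- spill(max(comp$rf - comp$indf, 0))

  v <- c(
    cp = ex[["cp"]] * COD_PROT + spill(comp$cp) * COD_PROT,
    cf = ex[["cf"]] * COD_LIPID + spill(comp$cf) * COD_LIPID,
    rf = ex[["degradable_rf"]] * COD_CARB + spill_deg_rf * COD_CARB,
    ss = ex[["ss"]] * COD_CARB + spill(comp$starch + comp$sugar) * COD_CARB,
    vfa = excreta$fecal_vfa * COD_VFA,
    inert = (ex[["indf"]] + spill(comp$indf)) * COD_CARB,
    water = (excreta$urine_volume +
               (excreta$feces_mass - excreta$feces_dm) +
               (spill_asfed - spill_dm)) / 1000,
    solids = (excreta$feces_dm + spill_dm) / 1000)
  if (any(v < 0)) stop("negative influent flow computed")
  structure(v, urea_n = excreta$urea_n, class = "influent_stream")
}

#' COD content of a slurry state
#' @param state a state vector from [manure_state()] or a simulation.
#' @param params a [kinetic_params()] (biomass COD factor).
#' @return g COD.
#' @export
state_cod <- function(state, params = kinetic_params()) {
  sum(state[c(.ST_CP, .ST_CF, .ST_RF, .ST_SS, .ST_VFA, .ST_INERT)]) +
    params$cod_biomass * sum(state[.ST_B1:.ST_B3])
}

#' Advance the slurry state by one integration step
#'
#' One explicit step of length `dt`: each degradable pool follows
#' `in - alpha(T) pool - R(T) pool`, hydrolysed COD enters the VFA pool,
#' VFA uptake is the sum over the three populations of
#' `biomass x umax x f_T x VFA/(K_S + VFA) x inhibition`, consumed VFA
#' splits into emitted CH4 COD and biomass growth by the yield, and
#' biomass decay returns to the protein pool. Non-negativity guards scale
#' transfers so no pool is driven below zero.
#'
#' @param state state vector.
#' @param influent an [excreta_to_influent()] stream (daily rates), or a
#'   zero vector.
#' @param temperature slurry temperature, degC.
#' @param params a [kinetic_params()].
#' @param dt step length, day (<= 1).
#' @return list `state` (updated), `ch4_cod`, `resp_cod` (g COD emitted /
#'   respired during the step), and `inhibition` (factor in \[0, 1\], 1 = no
#'   inhibition).
#' @export
step_manure <- function(state, influent, temperature,
                        params = kinetic_params(), dt = params$dt) {
  if (dt > 1) stop("dt must be <= 1 day")
  res <- .sim_core(days = 1L, temp = temperature,
                   influent = matrix(as.numeric(influent)[1:8], nrow = 1),
                   additions = NULL, removals = NULL, params = params,
                   dt = dt, init = state, substeps_total = 1L)
  list(state = res$final_state, ch4_cod = res$acc[["ch4_cod"]],
       resp_cod = res$acc[["resp_cod"]],
       inhibition = res$ledger$inhibition_mean[1])
}

# Core fixed-step integrator. `influent` is a days x 8 matrix
# (cp, cf, rf, ss, vfa, inert g COD/day; water, solids kg/day).
# `additions`: list of list(day, state) applied at the start of the day.
# `removals`: data.frame(day, fraction) applied at the end of the day;
# removed material is returned as batches. `substeps_total` lets
# step_manure() run a single sub-step of length dt.
.sim_core <- function(days, temp, influent, additions, removals, params,
                      dt, init, substeps_total = NULL) {
  a20 <- as.numeric(params$alpha20); th <- params$theta_hyd
  r20 <- params$resp20; thr <- params$theta_resp
  umax <- params$umax; ks <- params$ks; topt <- params$topt
  sig <- params$sigma_t; Y <- params$yield; bdec <- params$decay
  ki <- params$ki; iex <- params$inhib_exp
  codb <- params$cod_biomass; codv <- params$cod_vfa

  s <- as.numeric(init)
  if (length(temp) == 1L) temp <- rep(temp, days)
  nsub <- if (is.null(substeps_total)) max(1L, round(1 / dt)) else
    substeps_total
  dt_eff <- if (is.null(substeps_total)) 1 / nsub else dt

  add_by_day <- NULL
  if (length(additions)) {
    add_by_day <- vector("list", days)
    for (b in additions) {
      d <- b$day
      if (d >= 1 && d <= days)
        add_by_day[[d]] <- c(add_by_day[[d]], list(b$state))
    }
  }
  rem_frac <- numeric(days)
  if (!is.null(removals) && nrow(removals)) {
    ok <- removals$day >= 1 & removals$day <= days
    rem_frac[removals$day[ok]] <- removals$fraction[ok]
  }

  led_ch4 <- numeric(days); led_resp <- numeric(days)
  led_vfa <- numeric(days); led_inh <- numeric(days)
  led_inh3 <- matrix(0, days, 3)
  led_cod <- numeric(days); led_mass <- numeric(days)
  acc_in <- 0; acc_ch4 <- 0; acc_resp <- 0; acc_rem <- 0
  init_cod <- sum(s[1:6]) + codb * sum(s[7:9])
  batches <- list()

  for (d in seq_len(days)) {
    if (!is.null(add_by_day) && length(add_by_day[[d]])) {
      for (st in add_by_day[[d]]) {
        s <- s + as.numeric(st)
        acc_in <- acc_in + sum(st[1:6]) + codb * sum(st[7:9])
      }
    }
    Tday <- temp[d]
    ef <- exp(th * (Tday - 20))
    al <- a20 * ef                       # cp, cf, rf, ss
    Rr <- r20 * exp(thr * (Tday - 20))
    ft <- exp(-0.5 * ((Tday - topt) / sig)^2)
    infl <- as.numeric(influent[d, ])
    # fresh excreta carry a methanogen inoculum riding on the solids
    b_in <- params$inoculum * infl[8] / 3
    acc_in <- acc_in + sum(infl[1:6]) + codb * 3 * b_in
    day_ch4 <- 0; day_resp <- 0; inh_acc <- 0; inh3_acc <- c(0, 0, 0)

    for (k in seq_len(nsub)) {
      # pool losses (hydrolysis + respiration), guarded
      hyd_tot <- 0
      for (p in 1:4) {
        lr <- (al[p] + Rr) * dt_eff
        loss <- s[p] * lr
        if (loss > s[p]) loss <- s[p]
        hy <- loss * al[p] / (al[p] + Rr)
        rp <- loss - hy
        s[p] <- s[p] - loss + infl[p] * dt_eff
        hyd_tot <- hyd_tot + hy
        day_resp <- day_resp + rp
      }
      # VFA pool and methanogenesis
      vfa_avail <- s[5] + hyd_tot + infl[5] * dt_eff
      conc <- if (s[10] > 0) (s[5] / codv) / s[10] else 0
      inh <- 1 / (1 + (conc / ki)^iex)
      mm <- conc / (ks + conc)
      upt <- s[7:9] * umax * ft * mm * inh * dt_eff
      ut <- sum(upt)
      if (ut > vfa_avail && ut > 0) {
        upt <- upt * vfa_avail / ut
        ut <- vfa_avail
      }
      s[5] <- vfa_avail - ut
      ch4 <- ut * (1 - Y * codb)
      growth <- Y * upt
      dec <- s[7:9] * bdec * dt_eff
      s[7:9] <- s[7:9] + growth - dec + b_in * dt_eff
      s[1] <- s[1] + codb * sum(dec)     # decayed biomass -> protein pool
      s[6] <- s[6] + infl[6] * dt_eff
      s[10] <- s[10] + (infl[7] + infl[8]) * dt_eff
      day_ch4 <- day_ch4 + ch4
      inh_acc <- inh_acc + inh
      inh3_acc <- inh3_acc + inh      # VFA inhibition is shared across populations
    }

    acc_ch4 <- acc_ch4 + day_ch4
    acc_resp <- acc_resp + day_resp
    led_ch4[d] <- day_ch4; led_resp[d] <- day_resp
    led_vfa[d] <- if (s[10] > 0) (s[5] / codv) / s[10] else 0
    led_inh[d] <- inh_acc / nsub
    led_inh3[d, ] <- inh3_acc / nsub
    led_mass[d] <- s[10]

    f <- rem_frac[d]
    if (f > 0) {
      removed <- f * s
      s <- s - removed
      acc_rem <- acc_rem + sum(removed[1:6]) + codb * sum(removed[7:9])
      batches[[length(batches) + 1L]] <-
        list(day = d, state = stats::setNames(removed, .ST_NAMES))
    }
    led_cod[d] <- sum(s[1:6]) + codb * sum(s[7:9])
  }

  final_cod <- sum(s[1:6]) + codb * sum(s[7:9])
  ledger <- data.frame(
    day = seq_len(days), temperature = temp[seq_len(days)],
    ch4_g = led_ch4 / 4,                # 4 g COD per g CH4
    ch4_cod = led_ch4, respired_cod = led_resp,
    co2_g = (led_ch4 / 4) / 16 * 44 + led_resp * 44 / 32,
    vfa_conc = led_vfa, inhibition_mean = led_inh,
    inhibition_1 = led_inh3[, 1], inhibition_2 = led_inh3[, 2],
    inhibition_3 = led_inh3[, 3],
    state_cod = led_cod, slurry_mass = led_mass)
  list(ledger = ledger, batches = batches,
       final_state = stats::setNames(s, .ST_NAMES),
       acc = c(initial_cod = init_cod, in_cod = acc_in, ch4_cod = acc_ch4,
               resp_cod = acc_resp, removed_cod = acc_rem,
               final_cod = final_cod))
}

#' Relative COD balance gap of a simulation
#'
#' Every simulation tracks chemical oxygen demand entering (influent,
#' batch additions, initial state), leaving (CH4, surface respiration,
#' removed batches) and remaining. The balance
#' `initial + in = CH4 + respired + removed + final` should close to well
#' under 0.1% of throughput.
#'
#' @param sim result of [simulate_barn()], [simulate_storage()] or the
#'   stepper.
#' @return relative gap (dimensionless).
#' @export
cod_balance <- function(sim) {
  a <- sim$acc
  gap <- (a[["initial_cod"]] + a[["in_cod"]]) -
    (a[["ch4_cod"]] + a[["resp_cod"]] + a[["removed_cod"]] +
       a[["final_cod"]])
  denom <- max(a[["initial_cod"]] + a[["in_cod"]], 1e-12)
  abs(gap) / denom
}

#' Simulate methane from the barn slurry pit
#'
#' Constant in-barn slurry temperature; daily influent from the animals
#' while the section is occupied (influent pauses during the empty days of
#' each production cycle, which is how occupancy enters the per-place
#' accounting); washing water added on the first empty day of each cycle;
#' at every removal interval, and at each cycle end, all but a residual
#' fraction of the pit content is transferred as a batch to the outdoor
#' store.
#'
#' @param config a [pig_category_config()].
#' @param influent an [excreta_to_influent()] stream (per animal place/day).
#' @param params a [kinetic_params()].
#' @param horizon simulation length, days (>= one cycle).
#' @param init initial state, default a near-empty inoculated pit.
#' @return list with `ledger` (daily data.frame), `batches` (transfers to
#'   storage), `final_state`, `acc` (COD accounting).
#' @export
simulate_barn <- function(config, influent, params = kinetic_params(),
                          horizon = 365, init = manure_state()) {
  stopifnot(inherits(config, "pig_config"))
  if (horizon < config$cycle_period)
    stop("horizon must cover at least one production cycle")
  days <- as.integer(horizon)
  active <- config$cycle_period - config$empty_days
  pos <- (seq_len(days) - 1L) %% config$cycle_period
  occupied <- pos < active

  infl <- matrix(0, days, 8)
  infl[occupied, ] <- matrix(as.numeric(influent)[1:8], sum(occupied), 8,
                             byrow = TRUE)
  # washing water arrives when the section is emptied for cleaning
  wash_day <- which(pos == active)
  if (config$wash_water > 0 && length(wash_day))
    infl[wash_day, 7] <- infl[wash_day, 7] + config$wash_water

  rem_days <- seq(config$removal_interval, days,
                  by = config$removal_interval)
  cycle_end <- which(pos == (active - 1L))
  rem_days <- sort(unique(c(rem_days, cycle_end)))
  removals <- data.frame(day = rem_days,
                         fraction = 1 - config$residual_fraction)

  .sim_core(days, temp = config$manure_temp_barn, influent = infl,
            additions = NULL, removals = removals, params = params,
            dt = params$dt, init = init)
}

#' Simulate methane from the outdoor slurry store
#'
#' Storage temperature follows the monthly series (day 1 = 1 January);
#' barn batches arrive on their removal day; the covered tank exchanges no
#' rain or evaporation; the removal schedule (default: 80% in spring, 20%
#' in autumn) is applied every simulated year.
#'
#' @param batches list of batches from [simulate_barn()].
#' @param storage a [storage_config()].
#' @param params a [kinetic_params()].
#' @param horizon days.
#' @param init initial state.
#' @return same structure as [simulate_barn()].
#' @export
simulate_storage <- function(batches, storage = storage_config(),
                             params = kinetic_params(), horizon = 365,
                             init = manure_state()) {
  stopifnot(inherits(storage, "storage_config"))
  days <- as.integer(horizon)
  temps <- monthly_to_daily(storage$monthly_temps, days)
  years <- seq(0L, days %/% 365L)
  rem <- do.call(rbind, lapply(years, function(y)
    data.frame(day = storage$removal_schedule$day + 365L * y,
               fraction = storage$removal_schedule$fraction)))
  rem <- rem[rem$day <= days, , drop = FALSE]
  infl <- matrix(0, days, 8)
  .sim_core(days, temp = temps, influent = infl, additions = batches,
            removals = rem, params = params, dt = params$dt, init = init)
}
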