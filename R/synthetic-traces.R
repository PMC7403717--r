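#' Parameters for one synthetic pulsatile area trace
#'
#' Defines the ground-truth model behind a synthetic apical-area time series:
#' a slow polynomial drift, a train of contraction pulses, and Gaussian
#' measurement noise. Each pulse constricts the cell by
#' `pulse_amplitude_um2` through a raised-cosine half wave lasting half a
#' pulse period, then relaxes along a normalized exponential back to a level
#' that permanently retains `ratchet_efficiency` of the pulse amplitude, so a
#' fully ratcheted cell (`ratchet_efficiency = 1`) shrinks as a staircase
#' while a non-ratcheted cell (`0`) returns to baseline after every pulse.
#'
#' The pulse period is realized internally as the nearest whole number of
#' sampling intervals so that pulses are aligned to the sampling grid; the
#' discrete peak constriction and expansion rates of a noiseless trace are
#' then exact closed-form functions of the parameters (see
#' [peak_rate_per_unit_amplitude()]).
#'
#' @param duration_s trace length in seconds (must cover at least ten frames).
#' @param dt_s sampling interval in seconds. The default 3.8 s corresponds to
#'   the acquisition rate implied by a 10-frame (~38 s) smoothing window.
#' @param initial_area_um2 apical area at time zero, in um^2.
#' @param pulse_period_s full contraction-relaxation cycle length in seconds
#'   (typical measured periods fall in 60-90 s).
#' @param pulse_amplitude_um2 transient area loss per pulse, um^2. May be a
#'   vector with one value per pulse.
#' @param ratchet_efficiency fraction in \[0, 1\] of each pulse's constriction
#'   that is retained after relaxation.
#' @param trend_coeffs ascending polynomial coefficients (c0, c1, c2, c3) of a
#'   slow baseline drift in um^2 as a function of time in seconds, added to
#'   the pulse train.
#' @param noise_sd_um2 SD of i.i.d. Gaussian measurement noise on the area.
#' @param reporter_gain increase of the reporter intensity per um^2 of
#'   instantaneous constriction; the reporter rises while the cell constricts
#'   and stays flat while it expands (intensity never decreases).
#' @param relax_tau_s time constant of the exponential relaxation, seconds.
#' @param constrict_frac fraction of the pulse period spent in the
#'   raised-cosine constriction phase (default 0.5); the remainder is the
#'   relaxation phase. Smaller values model cells whose relaxation is slower
#'   than their contraction.
#' @param lead_s quiescent plateau before the first pulse onset; default half
#'   a pulse period. Snapped to the sampling grid. Ignored when `phase_frac`
#'   is given.
#' @param phase_frac optional cycle phase in \[0, 1) at time zero. When set,
#'   the trace carries no quiescent plateaus: pulses run back-to-back from
#'   before the first frame to the last frame (with partial cycles at both
#'   ends), as in continuously pulsing cells. Snapped to the sampling grid.
#' @param seed integer seed for the noise stream.
#' @return A list of validated parameters, class `pulse_trace_params`.
#' @seealso [gen_pulse_trace()]
#' @export
pulse_trace_params <- function(duration_s = 475, dt_s = 3.8, initial_area_um2 = 41,
                               pulse_period_s = 76, pulse_amplitude_um2 = 4,
                               ratchet_efficiency = 0.85,
                               trend_coeffs = c(0, 0, 0, 0), noise_sd_um2 = 0,
                               reporter_gain = 2, relax_tau_s = pulse_period_s / 8,
                               constrict_frac = 0.5, lead_s = NULL,
                               phase_frac = NULL, seed = 1) {
  if (dt_s <= 0) ap_stop("dt_s must be positive", "invalid_parameters")
  if (duration_s < 10 * dt_s) ap_stop("duration_s must cover at least 10 frames", "invalid_parameters")
  if (ratchet_efficiency < 0 || ratchet_efficiency > 1)
    ap_stop("ratchet_efficiency must lie in [0, 1]", "invalid_parameters")
  if (any(pulse_amplitude_um2 < 0)) ap_stop("pulse_amplitude_um2 must be >= 0", "invalid_parameters")
  if (pulse_period_s < 2 * dt_s) ap_stop("pulse_period_s must span at least two frames", "invalid_parameters")
  if (relax_tau_s <= 0) ap_stop("relax_tau_s must be positive", "invalid_parameters")
  if (constrict_frac <= 0 || constrict_frac >= 1)
    ap_stop("constrict_frac must lie in (0, 1)", "invalid_parameters")
  if (is.null(lead_s)) lead_s <- pulse_period_s / 2
  if (!is.null(phase_frac) && (phase_frac < 0 || phase_frac >= 1))
    ap_stop("phase_frac must lie in [0, 1)", "invalid_parameters")
  structure(list(duration_s = duration_s, dt_s = dt_s,
                 initial_area_um2 = initial_area_um2,
                 pulse_period_s = pulse_period_s,
                 pulse_amplitude_um2 = pulse_amplitude_um2,
                 ratchet_efficiency = ratchet_efficiency,
                 trend_coeffs = trend_coeffs, noise_sd_um2 = noise_sd_um2,
                 reporter_gain = reporter_gain, relax_tau_s = relax_tau_s,
                 constrict_frac = constrict_frac, lead_s = lead_s,
                 phase_frac = phase_frac, seed = as.integer(seed)),
            class = "pulse_trace_params")
}

# grid geometry shared by the generator and the rate calibration
pulse_grid <- function(params) {
  m_p <- max(2L, as.integer(round(params$pulse_period_s / params$dt_s)))
  cf <- if (is.null(params$constrict_frac)) 0.5 else params$constrict_frac
  m_c <- min(m_p - 1L, max(1L, as.integer(round(m_p * cf))))
  list(m_p = m_p, m_c = m_c, m_r = m_p - m_c,
       lead_i = as.integer(round(params$lead_s / params$dt_s)))
}

#' Discrete peak rates of a unit-amplitude noiseless pulse
#'
#' For a grid-aligned pulse of amplitude 1 um^2 the maximal finite-difference
#' constriction rate (over the raised-cosine phase) and expansion rate (first
#' interval of the normalized exponential relaxation, per unit of *released*
#' amplitude) are closed forms of the grid geometry. These are what
#' [constriction_rate()] with `smooth_window = 1` measures on such a trace,
#' and what [gen_cohort()] inverts to hit target peak rates.
#'
#' @param dt_s sampling interval, seconds.
#' @param pulse_period_s pulse period, seconds.
#' @param relax_tau_s relaxation time constant, seconds (for the expansion
#'   component).
#' @param constrict_frac fraction of the period spent constricting.
#' @return list with `constriction` and `expansion`, both in um^2/min per
#'   um^2 of (released) amplitude.
#' @export
peak_rate_per_unit_amplitude <- function(dt_s, pulse_period_s, relax_tau_s,
                                         constrict_frac = 0.5) {
  g <- pulse_grid(list(dt_s = dt_s, pulse_period_s = pulse_period_s,
                       constrict_frac = constrict_frac, lead_s = 0))
  j <- 0:(g$m_c - 1)
  unit_c <- (60 / (2 * dt_s)) * max(cos(pi * j / g$m_c) - cos(pi * (j + 1) / g$m_c))
  t_r <- g$m_r * dt_s
  unit_e <- if (g$m_r > 0)
    60 * (1 - exp(-dt_s / relax_tau_s)) / (dt_s * (1 - exp(-t_r / relax_tau_s)))
  else NA_real_
  list(constriction = unit_c, expansion = unit_e)
}

#' Generate a synthetic pulsatile apical-area trace
#'
#' Simulates one cell's apical area through repeated contraction pulses with
#' partial ratcheting, a slow polynomial drift, an optional reporter channel,
#' and Gaussian noise (see [pulse_trace_params()] for the model). With zero
#' noise and no drift the trace obeys exact conservation: after `k` complete
#' pulses of amplitude `A` and ratchet efficiency `e` the plateau area equals
#' `initial - k * e * A`.
#'
#' @param params a [pulse_trace_params()] object.
#' @param embryo_id,cell_id identifiers attached to the trace.
#' @return A [cell_trace()] whose `"ground_truth"` attribute records pulse
#'   onset times, times of maximal constriction rate and of minimal area, the
#'   per-pulse retained constriction, and the clean (noise-free) area.
#' @examples
#' p <- pulse_trace_params(ratchet_efficiency = 1, noise_sd_um2 = 0)
#' tr <- gen_pulse_trace(p)
#' all(diff(tr$area_um2) <= 1e-12)   # full ratchet: staircase
#' @export
gen_pulse_trace <- function(params, embryo_id = "emb1", cell_id = "cell1") {
  stopifnot(inherits(params, "pulse_trace_params"))
  dt <- params$dt_s
  n <- as.integer(floor(params$duration_s / dt)) + 1L
  t <- (seq_len(n) - 1) * dt
  g <- pulse_grid(params)
  n_pulses <- max(0L, as.integer((n - 1L - g$lead_i) %/% g$m_p))
  amp <- rep_len(params$pulse_amplitude_um2, max(1L, n_pulses))
  e <- params$ratchet_efficiency
  tau <- params$relax_tau_s
  t_r <- g$m_r * dt

  pulse <- numeric(n)                     # deviation from the running baseline
  onset_times <- numeric(0)
  if (is.null(params$phase_frac)) {
    # plateau mode: quiescent lead, complete pulses only, trailing plateau
    retained <- 0
    if (n_pulses > 0) {
      for (k in seq_len(n_pulses)) {
        o <- g$lead_i + (k - 1L) * g$m_p  # 0-based onset sample
        onset_times <- c(onset_times, o * dt)
        a <- amp[k]
        jc <- 0:g$m_c
        pulse[o + jc + 1L] <- -retained - a * (1 - cos(pi * jc / g$m_c)) / 2
        if (g$m_r > 0) {
          jr <- 1:g$m_r
          rel <- (exp(-jr * dt / tau) - exp(-t_r / tau)) / (1 - exp(-t_r / tau))
          pulse[o + g$m_c + jr + 1L] <- -retained - e * a - (1 - e) * a * rel
        }
        retained <- retained + e * a
        tail_from <- o + g$m_p + 2L
        if (tail_from <= n) pulse[tail_from:n] <- -retained
      }
    }
  } else {
    # continuous mode: back-to-back cycles with a phase offset, partial
    # cycles at both trace ends, no flat segments
    a <- amp[1]
    phase_i <- as.integer(round(params$phase_frac * g$m_p))
    u <- (seq_len(n) - 1L) + phase_i      # samples since the train origin
    cyc <- u %/% g$m_p
    s <- u %% g$m_p
    w <- numeric(n)
    inc <- s <= g$m_c
    w[inc] <- a * (1 - cos(pi * s[inc] / g$m_c)) / 2
    if (g$m_r > 0 && any(!inc)) {
      sr <- (s[!inc] - g$m_c) * dt
      rel <- (exp(-sr / tau) - exp(-t_r / tau)) / (1 - exp(-t_r / tau))
      w[!inc] <- e * a + (1 - e) * a * rel
    }
    pulse <- -(cyc * e * a + w)
    k_first <- ceiling(phase_i / g$m_p)
    onset_times <- ((k_first:(k_first + (n %/% g$m_p) + 1L)) * g$m_p - phase_i) * dt
    onset_times <- onset_times[onset_times >= 0 & onset_times <= (n - 1L) * dt]
    n_pulses <- length(onset_times)
  }

  clean <- params$initial_area_um2 + polyval_asc(params$trend_coeffs, t) + pulse
  if (any(clean <= 0))
    ap_stop("parameter set drives area <= 0", "invalid_parameters")

  area <- if (params$noise_sd_um2 > 0)
    with_seed(params$seed, clean + stats::rnorm(n, 0, params$noise_sd_um2))
  else clean

  # reporter accumulates with every instantaneous constriction of the clean
  # signal and never decreases (stable during expansion)
  constr_steps <- pmax(0, -diff(clean))
  intensity <- 100 + params$reporter_gain * cumsum(c(0, constr_steps))

  tr <- cell_trace(times_s = t, area_um2 = pmax(area, .Machine$double.eps),
                   intensity = intensity,
                   embryo_id = embryo_id, cell_id = cell_id)
  attr(tr, "ground_truth") <- list(
    pulse_onset_s = onset_times,
    constriction_peak_s = onset_times + g$m_c * dt / 2,
    area_min_s = onset_times + g$m_c * dt,
    retained_um2 = e * rep_len(amp, max(0L, n_pulses)),
    clean_area_um2 = clean,
    params = params)
  tr
}

# per-class phenotype traits of the cohort generator; trend_frac is the
# fraction of the initial area removed (negative: added) by a linear drift
# over the first 420 s -- chosen so each class lands strictly inside its
# category band at the 7-min evaluation for all +/-2.5 sd parameter draws
cohort_class_traits <- function() {
  list(
    constricted = list(ratchet_efficiency = 0.57, trend_frac = 0.46),
    impaired    = list(ratchet_efficiency = 0.10, trend_frac = 0.10),
    expanded    = list(ratchet_efficiency = 0.00, trend_frac = -0.18))
}

#' Parameters for a synthetic cell cohort
#'
#' Describes a population of cells split over the three contractile behaviour
#' classes observed in spectrin-depleted embryos (constricted / impaired /
#' expanded), each with target distributions of per-cell peak constriction
#' and expansion rates. Class counts follow `class_mix` exactly through
#' largest-remainder rounding, so printed mixtures reproduce at any `n`.
#'
#' @param n_cells total number of cells.
#' @param class_mix named fractions over
#'   `c("constricted", "impaired", "expanded")`; must sum to 1.
#' @param class_rate_params per-class list with elements `constriction` and
#'   `expansion`, each `c(mean =, sd =)` in um^2/min. Defaults follow the
#'   measured group statistics: control-like constricting cells
#'   9.9 +/- 1.1 constriction and 3.2 +/- 0.8 expansion; impaired cells
#'   7.5 +/- 1.2 and 5.1 +/- 1.4. Expanded-cell rates are not reported for
#'   the measured data, so plausible defaults are supplied.
#' @param n_embryos cells are assigned round-robin to this many embryos.
#' @param noise_sd_um2 measurement noise on the area channel.
#' @param initial_area c(mean, sd) of initial apical area, um^2.
#' @param duration_s,dt_s,pulse_period_s trace geometry, see
#'   [pulse_trace_params()].
#' @param class_traits per-class ratchet efficiency and linear-trend
#'   fraction; see `apicalpulse:::cohort_class_traits` for the defaults.
#' @param seed integer master seed; per-cell streams are derived by stable
#'   hashing of (seed, embryo, cell).
#' @return A validated list, class `cohort_params`.
#' @export
cohort_params <- function(n_cells = 300,
                          class_mix = c(constricted = 0.91, impaired = 0.09, expanded = 0),
                          class_rate_params = list(
                            constricted = list(constriction = c(mean = 9.9, sd = 1.1),
                                               expansion = c(mean = 3.2, sd = 0.8)),
                            impaired = list(constriction = c(mean = 7.5, sd = 1.2),
                                            expansion = c(mean = 5.1, sd = 1.4)),
                            expanded = list(constriction = c(mean = 5.0, sd = 1.5),
                                            expansion = c(mean = 6.0, sd = 1.5))),
                          n_embryos = 5, noise_sd_um2 = 0,
                          initial_area = c(mean = 41, sd = 2),
                          duration_s = 432, dt_s = 3.8, pulse_period_s = 76,
                          class_traits = cohort_class_traits(), seed = 1) {
  classes <- c("constricted", "impaired", "expanded")
  if (is.null(names(class_mix))) names(class_mix) <- classes
  class_mix <- class_mix[classes]
  class_mix[is.na(class_mix)] <- 0
  if (abs(sum(class_mix) - 1) > 1e-8) ap_stop("class_mix must sum to 1", "invalid_parameters")
  if (any(class_mix < 0)) ap_stop("class_mix fractions must be >= 0", "invalid_parameters")
  if (n_cells < 1) ap_stop("n_cells must be >= 1", "invalid_parameters")
  for (cl in classes) {
    rp <- class_rate_params[[cl]]
    if (is.null(rp) || any(c(rp$constriction["sd"], rp$expansion["sd"]) < 0))
      ap_stop("class_rate_params must give non-negative sds for every class", "invalid_parameters")
  }
  structure(list(n_cells = as.integer(n_cells), class_mix = class_mix,
                 class_rate_params = class_rate_params,
                 n_embryos = as.integer(n_embryos),
                 noise_sd_um2 = noise_sd_um2, initial_area = initial_area,
                 duration_s = duration_s, dt_s = dt_s,
                 pulse_period_s = pulse_period_s,
                 class_traits = class_traits, seed = as.integer(seed)),
            class = "cohort_params")
}

#' Largest-remainder apportionment of counts to fractions
#'
#' @param n total count.
#' @param fractions non-negative fractions summing to 1.
#' @return integer counts summing to `n`; the printed mixture is reproduced
#'   exactly whenever `n * fractions` are whole numbers.
#' @examples
#' largest_remainder_counts(300, c(0.50, 0.44, 0.06))  # 150 132 18
#' @export
largest_remainder_counts <- function(n, fractions) {
  quota <- n * fractions
  counts <- floor(quota + 1e-9)
  short <- n - sum(counts)
  if (short > 0) {
    ord <- order(quota - counts, decreasing = TRUE)
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  }
  as.integer(counts)
}

# solve the relaxation time constant so the discrete first-interval expansion
# rate equals `target` um^2/min for released amplitude (1-e)*A; monotone in
# tau, solved by uniroot; infeasible targets are clipped to the nearest
# achievable rate
solve_relax_tau <- function(target, released_amp, dt, t_r) {
  if (released_amp <= 0 || t_r <= 0) return(t_r / 2)
  gfun <- function(tau)
    released_amp * 60 * (1 - exp(-dt / tau)) / (dt * (1 - exp(-t_r / tau)))
  lo <- dt / 20; hi <- 50 * t_r
  target <- min(max(target, gfun(hi) * 1.0001), gfun(lo) * 0.9999)
  stats::uniroot(function(tau) gfun(tau) - target, c(lo, hi), tol = 1e-10)$root
}

#' Generate a cohort of synthetic cell traces with known behaviour classes
#'
#' Builds `n_cells` pulsatile traces split over the constricted / impaired /
#' expanded behaviour classes. Per cell, target peak constriction and
#' expansion rates are drawn from the class distributions and the pulse
#' amplitude and relaxation time constant are solved in closed form
#' (including the constant rate contribution of the class's linear drift) so
#' that, on a noiseless trace, the rates recovered by the analysis pipeline
#' ([mean_peak_rate()]) equal the drawn targets.
#'
#' @param params a [cohort_params()] object.
#' @return A `trace_cohort` (list of [cell_trace()]) whose `"truth"`
#'   attribute is a data frame of per-cell class labels, embryo ids and drawn
#'   target rates.
#' @export
gen_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  classes <- c("constricted", "impaired", "expanded")
  counts <- largest_remainder_counts(params$n_cells, params$class_mix)
  labels <- rep(classes, counts)
  dt <- params$dt_s
  # asymmetric cycle: relaxation takes most of the period, so even slow
  # target expansion rates are reachable by the exponential release
  cf <- 0.35
  g <- pulse_grid(list(dt_s = dt, pulse_period_s = params$pulse_period_s,
                       constrict_frac = cf, lead_s = 0))
  t_r <- g$m_r * dt

  traces <- vector("list", params$n_cells)
  truth <- vector("list", params$n_cells)
  for (i in seq_len(params$n_cells)) {
    cl <- labels[i]
    embryo <- sprintf("emb%d", 1L + (i - 1L) %% params$n_embryos)
    cell <- sprintf("cell%04d", i)
    cell_seed <- stable_hash(params$seed, embryo, cell)
    tr_cl <- params$class_traits[[cl]]
    rp <- params$class_rate_params[[cl]]

    draws <- with_seed(cell_seed, list(
      c_rate = rnorm_clipped(1, rp$constriction["mean"], rp$constriction["sd"], lower = 0.5),
      e_rate = rnorm_clipped(1, rp$expansion["mean"], rp$expansion["sd"], lower = 0.5),
      a0 = rnorm_clipped(1, params$initial_area["mean"], params$initial_area["sd"], k = 2),
      jitter = sample.int(g$m_p, 1) - 1L))

    # linear drift removing trend_frac of the initial area over 420 s;
    # its constant slope adds `boost` um^2/min to every constriction rate
    c1 <- -tr_cl$trend_frac * draws$a0 / 420
    boost <- -c1 * 60
    tau0 <- params$pulse_period_s / 8
    unit <- peak_rate_per_unit_amplitude(dt, params$pulse_period_s, tau0, cf)
    amp <- max((draws$c_rate - boost) / unit$constriction, 0.2)
    released <- (1 - tr_cl$ratchet_efficiency) * amp
    tau <- solve_relax_tau(draws$e_rate + boost, released, dt, t_r)

    p <- pulse_trace_params(
      duration_s = params$duration_s, dt_s = dt,
      initial_area_um2 = draws$a0, pulse_period_s = params$pulse_period_s,
      pulse_amplitude_um2 = amp, ratchet_efficiency = tr_cl$ratchet_efficiency,
      trend_coeffs = c(0, c1, 0, 0), noise_sd_um2 = params$noise_sd_um2,
      relax_tau_s = tau, constrict_frac = cf, phase_frac = draws$jitter / g$m_p,
      seed = cell_seed)
    traces[[i]] <- gen_pulse_trace(p, embryo_id = embryo, cell_id = cell)
    truth[[i]] <- data.frame(cell_id = cell, embryo_id = embryo, class = cl,
                             target_constriction_rate = unname(draws$c_rate),
                             target_expansion_rate = unname(draws$e_rate),
                             initial_area_um2 = unname(draws$a0),
                             pulse_amplitude_um2 = amp,
                             stringsAsFactors = FALSE)
  }
  cohort <- as_trace_cohort(traces)
  attr(cohort, "truth") <- do.call(rbind, truth)
  cohort
}
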