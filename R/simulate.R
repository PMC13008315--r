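#' Simulate a Transwell permeability timecourse
#'
#' Two-compartment transport across the cell layer with the sampling
#' protocol of the bidirectional assay: between sampling events the
#' receiver mass obeys `dM_r/dt = P * SA * (C_d - C_r)` (back-diffusion
#' included, so the simulator can also produce data that violate the sink
#' assumption of the downstream Papp estimator); at each sample time the
#' receiver concentration is recorded with multiplicative lognormal
#' measurement noise, then `sample_volume` of receiver medium is withdrawn
#' and replaced with blank buffer. The donor chamber is depleted by the
#' transferred mass and never replenished.
#'
#' The between-event dynamics are linear, so the interval solution is the
#' exact exponential relaxation toward the joint equilibrium; no numerical
#' ODE integration is involved.
#'
#' @param design an [assay_design()].
#' @param truth a [transport_truth()]; the permeability matching
#'   `design$direction` is used (`true_papp_AB` for AB).
#' @param n_replicates number of replicate wells (default 3, the assay's
#'   standard triplicate).
#' @param compound_id identifier written into the output table.
#' @param lag_min optional lag before transport starts, minutes (default 0).
#' @return A `data.frame` (class `timecourse_table`) with columns
#'   `compound_id`, `direction`, `replicate`, `time_min`, `conc_uM`, and the
#'   design attached as attribute `"design"`. Concentrations are uM.
#' @examples
#' tc <- simulate_timecourse(assay_design(),
#'                           transport_truth(5e-6, noise_cv = 0), 1)
#' head(tc)
#' @export
simulate_timecourse <- function(design, truth, n_replicates = 3,
                                compound_id = "compound", lag_min = 0) {
  validate_design(design)
  stopifnot(inherits(truth, "transport_truth"), n_replicates >= 1,
            lag_min >= 0)
  papp <- if (design$direction == "AB") truth$true_papp_AB else truth$true_papp_BA

  set.seed(truth$seed)
  rows <- lapply(seq_len(n_replicates), function(rep_i) {
    conc <- simulate_one_well(design, papp, truth$noise_cv, lag_min)
    data.frame(compound_id = compound_id,
               direction = design$direction,
               replicate = rep_i,
               time_min = design$sample_times,
               conc_uM = as.numeric(conc),  # drop the audit ledger attribute
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "design") <- design
  class(out) <- c("timecourse_table", class(out))
  out
}

# One well: returns measured receiver concentrations (uM) at sample_times.
# The full event ledger (donor/receiver/removed masses) is attached as an
# attribute so mass-balance tests can audit every event.
simulate_one_well <- function(design, papp, noise_cv, lag_min = 0) {
  p_min <- papp * 60                       # cm/s -> cm/min
  sa <- design$membrane_area_SA
  v_d <- design$donor_volume
  v_r <- design$receiver_volume
  v_s <- design$sample_volume
  m_d <- design$donor_concentration_C0 * v_d  # nmol (uM * mL)
  m_r <- 0
  removed <- 0
  times <- design$sample_times
  sdlog <- sqrt(log1p(noise_cv^2))

  conc <- numeric(length(times))
  ledger <- data.frame(time_min = times, donor_nmol = NA_real_,
                       receiver_nmol = NA_real_, removed_nmol = NA_real_)
  t_prev <- 0
  for (k in seq_along(times)) {
    dt <- times[k] - t_prev
    eff_dt <- max(0, min(times[k], lag_min) - t_prev)  # transport-free part
    dt_active <- dt - eff_dt
    if (dt_active > 0 && p_min > 0) {
      lambda <- p_min * sa * (1 / v_d + 1 / v_r)
      m_tot <- m_d + m_r
      m_r_eq <- m_tot * v_r / (v_d + v_r)
      m_r <- m_r_eq + (m_r - m_r_eq) * exp(-lambda * dt_active)
      m_d <- m_tot - m_r
    }
    c_true <- m_r / v_r
    noise <- if (noise_cv > 0) stats::rlnorm(1, -sdlog^2 / 2, sdlog) else 1
    conc[k] <- c_true * noise
    # physical withdrawal uses the true concentration, not the measured one
    taken <- v_s * c_true
    m_r <- m_r - taken
    removed <- removed + taken
    ledger$donor_nmol[k] <- m_d
    ledger$receiver_nmol[k] <- m_r
    ledger$removed_nmol[k] <- removed
    t_prev <- times[k]
  }
  attr(conc, "ledger") <- ledger
  conc
}

#' Simulate a bidirectional compound panel
#'
#' Runs [simulate_timecourse()] in both the AB and BA directions for each
#' compound. The BA design is derived from the AB design by swapping donor
#' and receiver chambers ([swap_design()]). Replicate noise draws differ
#' between directions and compounds but the whole panel is deterministic
#' given the per-compound seeds.
#'
#' @param compounds a named list of [transport_truth()] objects; names are
#'   compound identifiers.
#' @param design the AB-direction [assay_design()].
#' @param n_replicates replicate wells per direction (default 3).
#' @return A `timecourse_table` covering both directions for all compounds.
#' @export
simulate_bidirectional_panel <- function(compounds, design, n_replicates = 3) {
  stopifnot(length(compounds) >= 1)
  ids <- names(compounds)
  if (is.null(ids) || any(ids == "")) {
    ids <- paste0("compound_", seq_along(compounds))
  }
  design_ba <- swap_design(design)
  out <- do.call(rbind, lapply(seq_along(compounds), function(i) {
    truth <- compounds[[i]]
    # decorrelate the BA noise stream without a second user-facing seed
    truth_ba <- truth
    truth_ba$seed <- truth$seed + 104729L
    rbind(simulate_timecourse(design, truth, n_replicates, ids[i]),
          simulate_timecourse(design_ba, truth_ba, n_replicates, ids[i]))
  }))
  rownames(out) <- NULL
  attr(out, "design") <- design
  class(out) <- c("timecourse_table", class(out))
  out
}

#' Synthetic toxicokinetic parameter table
#'
#' Stand-in for the per-compound outputs of a high-throughput
#' toxicokinetics (HTTK) workflow: fraction unbound in blood (Fub) and the
#' steady-state serum concentration at a 1 mg/kg/day reference dose.
#' Fub is drawn log-uniformly over 10^-2.5 .. 1 and Css,serum lognormally
#' around 1 uM (sdlog 1.5), covering the spread typically seen in HTTK
#' output for environmental chemicals and drugs.
#'
#' @param compound_ids character vector of compound identifiers.
#' @param seed integer RNG seed.
#' @param reference_dose_mg_kg_day reference dose, default 1.
#' @return A `data.frame` with columns `compound_id`, `casrn` (NA), `fub`,
#'   `css_serum_uM`, `reference_dose_mg_kg_day`.
#' @export
make_toxkinetic_table <- function(compound_ids, seed = 1L,
                                  reference_dose_mg_kg_day = 1) {
  if (length(compound_ids) < 1) stop("need at least one compound", call. = FALSE)
  set.seed(as.integer(seed))
  n <- length(compound_ids)
  fub <- 10^stats::runif(n, -2.5, 0)
  css <- stats::rlnorm(n, meanlog = 0, sdlog = 1.5)
  data.frame(compound_id = as.character(compound_ids),
             casrn = NA_character_,
             fub = fub,
             css_serum_uM = css,
             reference_dose_mg_kg_day = reference_dose_mg_kg_day,
             stringsAsFactors = FALSE)
}
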