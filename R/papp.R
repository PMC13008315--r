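#' Cumulative transported mass from receiver samples
#'
#' The assay withdraws `sample_volume` from the receiver chamber at each
#' timepoint and replaces it with blank buffer, so the raw receiver
#' concentration underestimates the transported mass at later timepoints.
#' The corrected cumulative mass at timepoint k is the mass currently in
#' the receiver plus everything removed in earlier samples:
#'
#'   M_k = V_receiver * C_k + sum_{i<k} V_sample * C_i
#'
#' With concentrations in uM (= nmol/mL) and volumes in mL, M is in nmol.
#'
#' @param samples a single replicate's timecourse: `data.frame` with
#'   columns `time_min` and `conc_uM` (or numeric vectors via `time_min` /
#'   `conc_uM` columns of a subset of a `timecourse_table`).
#' @param design an [assay_design()].
#' @return A `data.frame` (class `cumulative_mass_series`) with columns
#'   `time_min`, `conc_uM`, `mass_nmol`; the design is attached as
#'   attribute `"design"`.
#' @examples
#' s <- data.frame(time_min = c(30, 60), conc_uM = c(10, 20))
#' cumulative_receiver_mass(s, assay_design())$mass_nmol  # 15, 32
#' @export
cumulative_receiver_mass <- function(samples, design) {
  validate_design(design)
  t <- samples$time_min
  c_uM <- samples$conc_uM
  if (anyDuplicated(t)) stop("duplicate timepoints", call. = FALSE)
  if (is.unsorted(t, strictly = TRUE)) {
    stop("timepoints must be strictly increasing", call. = FALSE)
  }
  if (any(c_uM < 0)) stop("negative concentrations", call. = FALSE)
  removed_before <- design$sample_volume * c(0, cumsum(c_uM)[-length(c_uM)])
  mass <- design$receiver_volume * c_uM + removed_before
  out <- data.frame(time_min = t, conc_uM = c_uM, mass_nmol = mass)
  attr(out, "design") <- design
  class(out) <- c("cumulative_mass_series", class(out))
  out
}

#' Fit the flux (dM/dt) by ordinary least squares
#'
#' Regresses cumulative transported mass on time with a free intercept;
#' the intercept absorbs lag time and pre-steady-state transients, the
#' slope is the flux dM/dt in nmol/min.
#'
#' @param series a [cumulative_receiver_mass()] result (or any data.frame
#'   with `time_min` and `mass_nmol`).
#' @return A list with `slope` (nmol/min), `intercept` (nmol),
#'   `r_squared`, and `slope_se`. For a perfectly flat series (no flux)
#'   `r_squared` is reported as 1: the flat line fits exactly.
#' @export
fit_flux <- function(series) {
  t <- series$time_min
  m <- series$mass_nmol
  if (length(t) < 3) stop("need at least 3 timepoints to fit flux", call. = FALSE)
  if (stats::var(t) == 0) stop("zero variance in time", call. = FALSE)
  fit <- stats::lm(m ~ t)
  co <- stats::coef(fit)
  ss_tot <- sum((m - mean(m))^2)
  r2 <- if (ss_tot <= .Machine$double.eps * max(1, mean(m)^2) * length(m)) {
    1
  } else {
    1 - sum(stats::residuals(fit)^2) / ss_tot
  }
  # closed-form slope SE (avoids summary.lm() warnings on exact fits)
  n <- length(t)
  se <- if (n > 2) {
    sqrt(sum(stats::residuals(fit)^2) / (n - 2) / sum((t - mean(t))^2))
  } else {
    NA_real_
  }
  list(slope = unname(co[["t"]]), intercept = unname(co[["(Intercept)"]]),
       r_squared = r2, slope_se = se)
}

#' Apparent permeability coefficient from a fitted flux
#'
#' `Papp = (dM/dt) / (C0 * SA * 60)` with the flux in nmol/min, the donor
#' concentration C0 in uM (= nmol/mL) and the membrane area SA in cm2; the
#' factor 60 converts minutes to seconds, so Papp is in cm/s.
#'
#' @param slope fitted flux dM/dt, nmol/min.
#' @param design an [assay_design()] supplying C0 and SA.
#' @return Papp in cm/s (negative slopes are floored at 0; they are flagged
#'   upstream).
#' @export
compute_papp <- function(slope, design) {
  if (design$donor_concentration_C0 <= 0) stop("C0 must be > 0", call. = FALSE)
  if (design$membrane_area_SA <= 0) stop("SA must be > 0", call. = FALSE)
  max(0, slope) / (design$donor_concentration_C0 *
                     design$membrane_area_SA * 60)
}

#' Quality-control flags for one replicate
#'
#' @param series a [cumulative_receiver_mass()] result.
#' @param fit the [fit_flux()] result for the same series.
#' @param design the [assay_design()].
#' @param qc a [qc_config()].
#' @return Character vector, a subset of `SINK_VIOLATION`,
#'   `POOR_LINEARITY`, `CENSORED_FAST`.
#' @export
quality_flags <- function(series, fit, design, qc = qc_config()) {
  flags <- character(0)
  donor_mass0 <- design$donor_concentration_C0 * design$donor_volume
  transferred_frac <- series$mass_nmol[nrow(series)] / donor_mass0
  if (transferred_frac > qc$sink_fraction) flags <- c(flags, "SINK_VIOLATION")
  if (fit$r_squared < qc$r2_min) flags <- c(flags, "POOR_LINEARITY")
  # equilibrium receiver concentration of the closed two-chamber system
  c_eq <- design$donor_concentration_C0 * design$donor_volume /
    (design$donor_volume + design$receiver_volume)
  if (series$conc_uM[1] > qc$censor_first_frac * c_eq) {
    flags <- c(flags, "CENSORED_FAST")
  }
  flags
}

#' Papp estimate container
#'
#' @param papp mean apparent permeability, cm/s; when censored, the lower
#'   bound (equal to `censor_bound`).
#' @param sd sample standard deviation across replicates, cm/s
#'   (`NA` for a single replicate -- never reported as 0).
#' @param n_replicates replicate count.
#' @param r_squared mean regression r-squared across replicates.
#' @param flags union of replicate QC flags.
#' @param censor_bound lower bound, cm/s, present iff `CENSORED_FAST`.
#' @return An object of class `papp_estimate`.
#' @export
papp_estimate <- function(papp, sd = NA_real_, n_replicates = 1L,
                          r_squared = NA_real_, flags = character(0),
                          censor_bound = NA_real_) {
  if (papp < 0) stop("papp must be >= 0", call. = FALSE)
  if (!is.na(sd) && sd < 0) stop("sd must be >= 0", call. = FALSE)
  if ("CENSORED_FAST" %in% flags && is.na(censor_bound)) {
    stop("censored estimate requires censor_bound", call. = FALSE)
  }
  structure(list(papp = papp, sd = sd, n_replicates = as.integer(n_replicates),
                 r_squared = r_squared, flags = flags,
                 censor_bound = censor_bound),
            class = "papp_estimate")
}

#' @export
print.papp_estimate <- function(x, ...) {
  v <- if (is_papp_censored(x)) paste0("> ", format(x$censor_bound * 1e6)) else
    format(signif(x$papp * 1e6, 3))
  sd <- if (is.na(x$sd)) "NA" else format(signif(x$sd * 1e6, 3))
  cat(sprintf("Papp %s x1e-6 cm/s (sd %s, n = %d)%s\n", v, sd, x$n_replicates,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' @rdname papp_estimate
#' @param x object to test.
#' @export
is_papp_censored <- function(x) {
  inherits(x, "papp_estimate") && "CENSORED_FAST" %in% x$flags
}

# papp_estimate (or numeric) -> bbb_bound in cm/s
papp_as_bound <- function(x) {
  if (inherits(x, "papp_estimate")) {
    if (is_papp_censored(x)) bound(x$censor_bound, "lower") else
      bound(x$papp, "point")
  } else {
    as_bound(x)
  }
}

#' Aggregate per-replicate Papp values into one estimate
#'
#' Mean and sample (n-1) standard deviation across replicates; QC flags are
#' the union over replicates. If any replicate is censored the aggregate is
#' censored at the common bound. A single replicate has `sd = NA`, not 0.
#'
#' @param estimates list of per-replicate `papp_estimate` objects (as
#'   produced with `n_replicates = 1`), or a numeric vector of Papp values
#'   in cm/s.
#' @return A `papp_estimate`.
#' @export
aggregate_replicates <- function(estimates) {
  if (is.numeric(estimates)) {
    estimates <- lapply(estimates, papp_estimate)
  }
  if (length(estimates) < 1) stop("no replicates to aggregate", call. = FALSE)
  flags <- sort(unique(unlist(lapply(estimates, `[[`, "flags"))))
  r2 <- mean(vapply(estimates, `[[`, numeric(1), "r_squared"))
  if ("CENSORED_FAST" %in% flags) {
    bound_v <- max(vapply(estimates, function(e)
      if (is.na(e$censor_bound)) -Inf else e$censor_bound, numeric(1)))
    return(papp_estimate(bound_v, NA_real_, length(estimates), r2, flags,
                         censor_bound = bound_v))
  }
  vals <- vapply(estimates, `[[`, numeric(1), "papp")
  papp_estimate(mean(vals),
                if (length(vals) > 1) stats::sd(vals) else NA_real_,
                length(vals), r2, flags)
}

#' Estimate Papp for one compound/direction from replicate timecourses
#'
#' Full per-condition pipeline: optional LOQ substitution, cumulative-mass
#' correction, OLS flux fit, Eq.-style Papp conversion, QC flagging, and
#' replicate aggregation. Censored-fast replicates are reported as the
#' lower bound `qc$censor_papp` rather than an unreliable slope.
#'
#' @param timecourse rows of a `timecourse_table` for one compound and
#'   direction (columns `replicate`, `time_min`, `conc_uM`).
#' @param design the [assay_design()] matching the direction.
#' @param qc a [qc_config()].
#' @return A `papp_estimate`.
#' @export
estimate_papp <- function(timecourse, design, qc = qc_config()) {
  reps <- split(timecourse, timecourse$replicate)
  per_rep <- lapply(reps, function(df) {
    df <- df[order(df$time_min), , drop = FALSE]
    loq_flag <- character(0)
    if (!is.na(qc$loq)) {
      below <- df$conc_uM < qc$loq
      if (any(below)) {
        df$conc_uM[below] <- qc$loq / 2
        loq_flag <- "BELOW_LOQ"
      }
    }
    series <- cumulative_receiver_mass(df, design)
    fit <- fit_flux(series)
    flags <- c(quality_flags(series, fit, design, qc), loq_flag)
    if ("CENSORED_FAST" %in% flags) {
      papp_estimate(qc$censor_papp, NA_real_, 1L, fit$r_squared, flags,
                    censor_bound = qc$censor_papp)
    } else {
      papp_estimate(compute_papp(fit$slope, design), NA_real_, 1L,
                    fit$r_squared, flags)
    }
  })
  aggregate_replicates(per_rep)
}

#' Estimate the full bidirectional panel
#'
#' @param timecourse a `timecourse_table` covering one or both directions
#'   for any number of compounds.
#' @param design_ab the AB-direction [assay_design()].
#' @param design_ba the BA design; defaults to [swap_design()] of `design_ab`.
#' @param qc a [qc_config()].
#' @return A `data.frame`, one row per compound, with columns
#'   `compound_id`, and for each direction present: `papp_<dir>`,
#'   `sd_<dir>`, `n_<dir>`, `r2_<dir>`, `<dir>_censored`, `flags_<dir>`
#'   (semicolon-joined). Papp values are cm/s.
#' @export
estimate_panel <- function(timecourse, design_ab,
                           design_ba = swap_design(design_ab),
                           qc = qc_config()) {
  stopifnot(nrow(timecourse) > 0)
  ids <- unique(timecourse$compound_id)
  rows <- lapply(ids, function(id) {
    row <- list(compound_id = id)
    for (dir in c("AB", "BA")) {
      sub <- timecourse[timecourse$compound_id == id &
                          timecourse$direction == dir, , drop = FALSE]
      suffix <- tolower(dir)
      if (nrow(sub) == 0) {
        row[paste0(c("papp_", "sd_", "n_", "r2_"), suffix)] <- NA_real_
        row[[paste0(suffix, "_censored")]] <- NA
        row[[paste0("flags_", suffix)]] <- NA_character_
        next
      }
      des <- if (dir == "AB") design_ab else design_ba
      est <- estimate_papp(sub, des, qc)
      row[[paste0("papp_", suffix)]] <- est$papp
      row[[paste0("sd_", suffix)]] <- est$sd
      row[[paste0("n_", suffix)]] <- est$n_replicates
      row[[paste0("r2_", suffix)]] <- est$r_squared
      row[[paste0(suffix, "_censored")]] <- is_papp_censored(est)
      row[[paste0("flags_", suffix)]] <- paste(est$flags, collapse = ";")
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Rebuild a papp_estimate from one row of an estimate_panel data.frame.
row_to_estimate <- function(row, dir) {
  suffix <- tolower(dir)
  flags <- row[[paste0("flags_", suffix)]]
  flags <- if (is.na(flags) || flags == "") character(0) else
    strsplit(flags, ";", fixed = TRUE)[[1]]
  papp <- row[[paste0("papp_", suffix)]]
  if (is.na(papp)) return(NULL)
  papp_estimate(papp,
                sd = row[[paste0("sd_", suffix)]],
                n_replicates = row[[paste0("n_", suffix)]],
                r_squared = row[[paste0("r2_", suffix)]],
                flags = flags,
                censor_bound = if ("CENSORED_FAST" %in% flags) papp else NA_real_)
}
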