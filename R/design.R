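#' Transwell assay design
#'
#' Geometry and sampling schedule of a bidirectional Transwell permeability
#' assay. Defaults describe a standard 12 mm insert (membrane area
#' 1.12 cm2, apical chamber 0.5 mL, basolateral chamber 1.5 mL) dosed at
#' 50 uM, with 0.2 mL receiver samples taken at 30, 60, 90, 120, 150 and
#' 180 min and replaced with blank buffer. For the apical-to-basolateral
#' (AB, blood-to-brain surrogate) direction the apical chamber is the
#' donor; [swap_design()] derives the matching basolateral-to-apical (BA)
#' design.
#'
#' @param donor_concentration_C0 initial donor concentration, uM.
#' @param donor_volume donor chamber volume, mL.
#' @param receiver_volume receiver chamber volume, mL.
#' @param membrane_area_SA filter support area, cm2.
#' @param sample_volume volume removed (and replaced) per sample, mL.
#' @param sample_times sampling times, minutes, strictly increasing, > 0.
#' @param direction `"AB"` or `"BA"`.
#' @return An object of class `assay_design`.
#' @examples
#' d <- assay_design()
#' swap_design(d)$direction
#' @export
assay_design <- function(donor_concentration_C0 = 50,
                         donor_volume = 0.5,
                         receiver_volume = 1.5,
                         membrane_area_SA = 1.12,
                         sample_volume = 0.2,
                         sample_times = c(30, 60, 90, 120, 150, 180),
                         direction = c("AB", "BA")) {
  direction <- match.arg(direction)
  des <- structure(
    list(donor_concentration_C0 = donor_concentration_C0,
         donor_volume = donor_volume,
         receiver_volume = receiver_volume,
         membrane_area_SA = membrane_area_SA,
         sample_volume = sample_volume,
         sample_times = as.numeric(sample_times),
         direction = direction),
    class = "assay_design")
  validate_design(des)
  des
}

validate_design <- function(design) {
  with(design, {
    if (donor_concentration_C0 <= 0) stop("C0 must be > 0", call. = FALSE)
    if (donor_volume <= 0 || receiver_volume <= 0 || membrane_area_SA <= 0 ||
        sample_volume <= 0) {
      stop("volumes and membrane area must be > 0", call. = FALSE)
    }
    if (sample_volume >= receiver_volume) {
      stop("sample_volume must be smaller than receiver_volume", call. = FALSE)
    }
    if (length(sample_times) < 1L || any(sample_times <= 0) ||
        any(diff(sample_times) <= 0)) {
      stop("sample_times must be strictly increasing and > 0", call. = FALSE)
    }
  })
  invisible(design)
}

#' @rdname assay_design
#' @param design an `assay_design`.
#' @export
swap_design <- function(design) {
  stopifnot(inherits(design, "assay_design"))
  assay_design(
    donor_concentration_C0 = design$donor_concentration_C0,
    donor_volume = design$receiver_volume,
    receiver_volume = design$donor_volume,
    membrane_area_SA = design$membrane_area_SA,
    sample_volume = design$sample_volume,
    sample_times = design$sample_times,
    direction = if (design$direction == "AB") "BA" else "AB")
}

#' @export
print.assay_design <- function(x, ...) {
  cat(sprintf(
    "Transwell design [%s]: C0 %g uM, donor %g mL, receiver %g mL, SA %g cm2\n",
    x$direction, x$donor_concentration_C0, x$donor_volume,
    x$receiver_volume, x$membrane_area_SA))
  cat(sprintf("  samples of %g mL at %s min\n", x$sample_volume,
              paste(x$sample_times, collapse = ", ")))
  invisible(x)
}

#' Ground-truth transport parameters for simulation
#'
#' @param true_papp_AB,true_papp_BA true apparent permeabilities, cm/s.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   measurement noise on receiver concentrations (default 0.05, a typical
#'   HPLC assay CV).
#' @param seed integer RNG seed making the simulation reproducible.
#' @return An object of class `transport_truth`.
#' @export
transport_truth <- function(true_papp_AB, true_papp_BA = true_papp_AB,
                            noise_cv = 0.05, seed = 1L) {
  if (true_papp_AB < 0 || true_papp_BA < 0) {
    stop("permeabilities must be >= 0", call. = FALSE)
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  structure(list(true_papp_AB = true_papp_AB, true_papp_BA = true_papp_BA,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "transport_truth")
}

#' Human physiology used for in vitro to in vivo extrapolation
#'
#' @param A_BBB_m2 total surface area of brain capillary endothelium, m2.
#'   Default 20 m2, the standard adult-human value.
#' @param V_ref_L reference distribution volume, L, that normalises the
#'   permeability-surface-area clearance into a first-order rate constant.
#'   Default 5 L (systemic blood). The first-order uptake model leaves this
#'   volume implicit; it is surfaced here as an explicit, configurable
#'   parameter because half-lives scale directly with it.
#' @return An object of class `physiology_config`.
#' @export
physiology_config <- function(A_BBB_m2 = 20, V_ref_L = 5) {
  if (A_BBB_m2 <= 0 || V_ref_L <= 0) {
    stop("A_BBB_m2 and V_ref_L must be > 0", call. = FALSE)
  }
  structure(list(A_BBB_m2 = A_BBB_m2, V_ref_L = V_ref_L),
            class = "physiology_config")
}

#' Quality-control thresholds for Papp estimation
#'
#' @param sink_fraction flag `SINK_VIOLATION` when more than this fraction
#'   of the initial donor mass has crossed by the last timepoint
#'   (default 0.10, standard Transwell practice).
#' @param r2_min flag `POOR_LINEARITY` when the cumulative-mass regression
#'   r-squared falls below this (default 0.90).
#' @param censor_papp report `CENSORED_FAST` compounds as a lower bound at
#'   this permeability, cm/s (default 500e-6, the "> 500" convention).
#' @param censor_first_frac flag `CENSORED_FAST` when the first measured
#'   receiver concentration already exceeds this fraction of its
#'   equilibrium value (default 0.5): transport was essentially complete
#'   before the first sample, so the slope carries no information.
#' @param loq limit of quantification, uM; concentrations below it are
#'   replaced by `loq / 2` and `BELOW_LOQ` flagged. `NA` disables.
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(sink_fraction = 0.10, r2_min = 0.90,
                      censor_papp = 500e-6, censor_first_frac = 0.5,
                      loq = NA_real_) {
  if (sink_fraction <= 0 || r2_min <= 0 || censor_papp <= 0 ||
      censor_first_frac <= 0) {
    stop("all thresholds must be positive", call. = FALSE)
  }
  structure(list(sink_fraction = sink_fraction, r2_min = r2_min,
                 censor_papp = censor_papp,
                 censor_first_frac = censor_first_frac, loq = loq),
            class = "qc_config")
}

#' Permeability rate-class boundaries
#'
#' Papp_AB below `slow_max` is "Slow"; below `moderate_max` "Moderate";
#' below `veryfast_min` "Fast"; at or above it (or censored there)
#' "Very fast". Defaults 1, 12 and 500 (x1e-6 cm/s) reproduce the
#' published class boundaries of the triculture panel.
#'
#' @param slow_max,moderate_max,veryfast_min boundaries in cm/s.
#' @return An object of class `rate_thresholds`.
#' @export
rate_thresholds <- function(slow_max = 1e-6, moderate_max = 12e-6,
                            veryfast_min = 500e-6) {
  v <- c(slow_max, moderate_max, veryfast_min)
  if (any(v <= 0) || any(diff(v) <= 0)) {
    stop("rate-class boundaries must be positive and strictly increasing",
         call. = FALSE)
  }
  structure(list(slow_max = slow_max, moderate_max = moderate_max,
                 veryfast_min = veryfast_min), class = "rate_thresholds")
}
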