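#' Permeability-surface-area transport clearance
#'
#' `PS = Fub * A_BBB * Papp_AB`: the product of the fraction unbound in
#' blood, the brain capillary endothelial surface area and the in vitro
#' AB permeability. It has units of volume per time and represents the
#' transport clearance of compound from blood into brain. With A_BBB in
#' m2 (20 m2 = 2e5 cm2) and Papp in cm/s the product is cm3/s; the result
#' is returned in mL/min.
#'
#' @param fub fraction unbound in blood, in (0, 1].
#' @param papp_ab AB permeability, cm/s; a [papp_estimate()] or [bound()]
#'   propagates censoring ("> 500e-6" gives a lower-bounded clearance).
#' @param physiology a [physiology_config()].
#' @return Clearance in mL/min (numeric, or [bound()] for censored input).
#' @examples
#' ps_clearance(1, 3e-6, physiology_config())  # 36 mL/min
#' @export
ps_clearance <- function(fub, papp_ab, physiology = physiology_config()) {
  if (is.na(fub) || fub <= 0 || fub > 1) {
    stop("fub must be in (0, 1]", call. = FALSE)
  }
  a_cm2 <- physiology$A_BBB_m2 * 1e4
  bound_transform(papp_as_bound(papp_ab),
                  function(p) fub * a_cm2 * p * 60)  # cm3/s -> mL/min
}

#' First-order brain-uptake rate constant
#'
#' Converts the PS clearance (volume/time) into a rate constant (1/time)
#' by normalising with the reference distribution volume:
#' `k = PS / V_ref`. Returned in 1/s.
#'
#' @param ps clearance in mL/min (numeric or [bound()]).
#' @param physiology a [physiology_config()] supplying `V_ref_L`.
#' @return k in 1/s (numeric or [bound()]).
#' @examples
#' uptake_rate_constant(36, physiology_config())  # 1.2e-4 per s
#' @export
uptake_rate_constant <- function(ps, physiology = physiology_config()) {
  v_ref_mL <- physiology$V_ref_L * 1000
  bound_transform(ps, function(x) {
    if (x < 0) stop("PS must be >= 0", call. = FALSE)
    x / v_ref_mL / 60
  })
}

#' Brain-uptake half-life
#'
#' `t1/2 = ln(2) / k`: the time for the blood concentration (absent other
#' elimination routes) to fall by half through net transfer into brain.
#' Infinite at k = 0. A lower-bounded k (censored-fast permeability)
#' yields an upper-bounded half-life.
#'
#' @param k rate constant, 1/s (numeric or [bound()]).
#' @return Half-life in seconds (numeric, possibly `Inf`, or [bound()]).
#' @export
uptake_half_life <- function(k) {
  if (bound_value(as_bound(k)) < 0) stop("k must be >= 0", call. = FALSE)
  bound_transform(k, function(x) if (x == 0) Inf else log(2) / x,
                  decreasing = TRUE)
}

#' Steady-state brain concentration under chronic exposure
#'
#' At steady state the ratio of brain to serum concentration is set by the
#' balance of passive permeability and active transport, summarised by the
#' efflux ratio: `Css_brain = Css_serum / ER`. The fraction unbound does
#' not enter here (protein binding is assumed similar in blood and brain).
#' An upper-bounded ER ("< x") yields a lower-bounded brain concentration
#' and vice versa.
#'
#' @param css_serum steady-state serum concentration, uM.
#' @param er efflux ratio (numeric > 0 or [bound()]).
#' @return Css_brain in uM (numeric or [bound()]).
#' @examples
#' css_brain(1, 2.5)   # 0.4: an effluxed compound reaches 40% of serum
#' @export
css_brain <- function(css_serum, er) {
  if (css_serum < 0) stop("Css_serum must be >= 0", call. = FALSE)
  if (bound_value(as_bound(er)) <= 0) {
    stop("efflux ratio must be > 0", call. = FALSE)
  }
  bound_transform(er, function(x) css_serum / x, decreasing = TRUE)
}

#' Linearly rescale toxicokinetic parameters to a new dose
#'
#' Steady-state serum concentrations from the toxicokinetic model are
#' linear in dose, so a table computed at the reference dose is rescaled
#' by `dose / reference_dose`.
#'
#' @param params toxicokinetic table (`compound_id`, `fub`,
#'   `css_serum_uM`, `reference_dose_mg_kg_day`).
#' @param dose target dose, mg/kg/day.
#' @return The table with `css_serum_uM` and `reference_dose_mg_kg_day`
#'   updated.
#' @export
scale_dose <- function(params, dose) {
  if (dose < 0) stop("dose must be >= 0", call. = FALSE)
  ref <- params$reference_dose_mg_kg_day
  if (any(ref == 0)) stop("reference dose must be > 0", call. = FALSE)
  params$css_serum_uM <- params$css_serum_uM * dose / ref
  params$reference_dose_mg_kg_day <- dose
  params
}

#' Predict brain exposure for a compound panel
#'
#' Joins bidirectional transport results with toxicokinetic parameters and
#' computes, per compound, the acute-uptake quantities (PS clearance,
#' rate constant k, half-life) and the chronic steady-state brain
#' concentration. Compounds missing toxicokinetic parameters (or missing
#' one direction) are kept in the output with explicit notes, never
#' silently dropped. Censored permeabilities propagate as bounds: a
#' "> 500e-6" AB permeability gives lower-bounded PS and k, an
#' upper-bounded half-life, and (through the "< x" efflux ratio) a
#' lower-bounded Css_brain.
#'
#' @param results a [bidirectional_results()] table.
#' @param params a toxicokinetic table (see [make_toxkinetic_table()]).
#' @param physiology a [physiology_config()].
#' @param dose dose in mg/kg/day at which to report Css (default: the
#'   table's reference dose, i.e. no rescaling).
#' @return A `data.frame`, one row per compound in `results`, with columns
#'   `compound_id`, `ps_mL_min`, `ps_bound_type`, `k_per_s`,
#'   `k_bound_type`, `t_half_s`, `t_half_bound_type`, `css_serum_uM`,
#'   `css_brain_uM`, `css_brain_bound_type`, `notes`. An infinite
#'   half-life is the honest value for zero permeability and survives the
#'   CSV round-trip as the token `Inf`.
#' @export
predict_panel <- function(results, params, physiology = physiology_config(),
                          dose = NULL) {
  if (nrow(results) == 0) stop("empty results table", call. = FALSE)
  if (!is.null(dose)) params <- scale_dose(params, dose)
  matched <- intersect(results$compound_id, params$compound_id)
  if (length(matched) == 0) {
    stop("no compound identifiers match between results and toxicokinetic ",
         "parameters; unmatched: ",
         paste(utils::head(results$compound_id, 10), collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(seq_len(nrow(results)), function(i) {
    row <- results[i, ]
    id <- row$compound_id
    notes <- character(0)
    tk <- params[params$compound_id == id, , drop = FALSE]
    fub <- if (nrow(tk) >= 1) tk$fub[1] else NA_real_
    css_serum <- if (nrow(tk) >= 1) tk$css_serum_uM[1] else NA_real_

    ab <- row_to_estimate(row, "AB")
    ps <- k <- th <- NULL
    if (is.null(ab)) {
      notes <- c(notes, "acute-incomplete: no AB permeability")
    } else if (is.na(fub)) {
      notes <- c(notes, "acute-incomplete: missing Fub")
    } else {
      ps <- ps_clearance(fub, ab, physiology)
      k <- uptake_rate_constant(ps, physiology)
      th <- uptake_half_life(k)
    }

    cb <- NULL
    er <- if (is.na(row$er)) NA_real_ else
      cols_to_bound(row$er, row$er_bound_type)
    if (!is_bound(er) && is.na(er)) {
      notes <- c(notes, "chronic-incomplete: no efflux ratio")
    } else if (is.na(css_serum)) {
      notes <- c(notes, "chronic-incomplete: missing Css_serum")
    } else {
      cb <- css_brain(css_serum, er)
    }

    num <- function(x) if (is.null(x)) NA_real_ else bound_value(x)
    typ <- function(x) if (is.null(x)) NA_character_ else bound_type(x)
    data.frame(compound_id = id,
               ps_mL_min = num(ps), ps_bound_type = typ(ps),
               k_per_s = num(k), k_bound_type = typ(k),
               t_half_s = num(th), t_half_bound_type = typ(th),
               css_serum_uM = css_serum,
               css_brain_uM = num(cb), css_brain_bound_type = typ(cb),
               notes = paste(notes, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
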