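#' Efflux ratio
#'
#' `ER = Papp_BA / Papp_AB`. An ER above 1 indicates net active export
#' toward the blood side, below 1 net import toward the brain side.
#' Censored inputs propagate as typed bounds: an AB value known only as
#' "> L" gives an ER known only as "< Papp_BA / L", and vice versa.
#'
#' @param papp_ab,papp_ba [papp_estimate()] objects, numerics (cm/s), or
#'   [bound()] objects.
#' @return Numeric ER, or a [bound()] when either input is censored.
#'   `NA` (with a warning) when both inputs are censored.
#' @examples
#' efflux_ratio(0.57e-6, 1.0e-6)                     # 1.754
#' efflux_ratio(bound(500e-6, "lower"), 117e-6)      # "< 0.234"
#' @export
efflux_ratio <- function(papp_ab, papp_ba) {
  ab <- papp_as_bound(papp_ab)
  ba <- papp_as_bound(papp_ba)
  if (ab$type != "point" && ba$type != "point") {
    warning("both permeabilities censored; efflux ratio indeterminate")
    return(NA_real_)
  }
  if (ab$type == "point" && ab$value == 0) {
    stop("Papp_AB is 0; efflux ratio undefined", call. = FALSE)
  }
  if (ab$type == "point" && ba$type == "point") {
    return(ba$value / ab$value)
  }
  v <- ba$value / ab$value
  # dividing by a lower bound caps the ratio; by an upper bound floors it
  type <- if (ab$type != "point") flip_type(ab$type) else ba$type
  bound(v, type)
}

#' Efflux-ratio uncertainty
#'
#' Two propagation rules for the standard deviation of the ER given the
#' replicate standard deviations of the two Papp values:
#' * `"largest"`: `ER * max(sd_AB/Papp_AB, sd_BA/Papp_BA)` -- the larger of
#'   the two relative errors, the convention used for the published error
#'   bars;
#' * `"quadrature"` (default): `ER * sqrt((sd_AB/Papp_AB)^2 +
#'   (sd_BA/Papp_BA)^2)` -- first-order propagation for an independent
#'   ratio.
#' Both are first-order approximations; neither is exact for noisy ratios.
#'
#' @param papp_ab,papp_ba [papp_estimate()] objects with `sd` available.
#' @param method `"quadrature"` or `"largest"`.
#' @return Numeric sd of the ER; `NA` when either sd is missing or an
#'   input is censored (absent uncertainty, never 0).
#' @export
er_uncertainty <- function(papp_ab, papp_ba,
                           method = c("quadrature", "largest")) {
  method <- match.arg(method)
  if (!inherits(papp_ab, "papp_estimate")) papp_ab <- papp_estimate(papp_ab)
  if (!inherits(papp_ba, "papp_estimate")) papp_ba <- papp_estimate(papp_ba)
  if (is_papp_censored(papp_ab) || is_papp_censored(papp_ba)) return(NA_real_)
  if (is.na(papp_ab$sd) || is.na(papp_ba$sd)) return(NA_real_)
  if (papp_ab$papp == 0 || papp_ba$papp == 0) return(NA_real_)
  er <- papp_ba$papp / papp_ab$papp
  rel_ab <- papp_ab$sd / papp_ab$papp
  rel_ba <- papp_ba$sd / papp_ba$papp
  switch(method,
         largest = er * max(rel_ab, rel_ba),
         quadrature = er * sqrt(rel_ab^2 + rel_ba^2))
}

#' Permeability rate class
#'
#' Classifies a compound by its AB-direction Papp: `Slow` below 1e-6 cm/s,
#' `Moderate` from 1 to 12 (x1e-6), `Fast` from 12 to 500, `Very fast` at
#' or beyond 500 (typically a censored "> 500" estimate).
#'
#' @param papp_ab a [papp_estimate()], numeric (cm/s) or [bound()].
#' @param thresholds a [rate_thresholds()].
#' @return One of `"Slow"`, `"Moderate"`, `"Fast"`, `"Very fast"`.
#' @export
classify_rate <- function(papp_ab, thresholds = rate_thresholds()) {
  b <- papp_as_bound(papp_ab)
  if (b$type == "lower" && b$value >= thresholds$veryfast_min) return("Very fast")
  v <- b$value
  if (v >= thresholds$veryfast_min) return("Very fast")
  if (v < thresholds$slow_max) return("Slow")
  if (v < thresholds$moderate_max) return("Moderate")
  "Fast"
}

#' Directional-transport call
#'
#' `Efflux` when ER >= 2.5 (strong apical efflux transporter activity),
#' `Influx` when ER < 0.4 (active influx), `NoBias` otherwise. A censored
#' ER is classified only when the bound itself decides the call (e.g.
#' "< 0.24" is unambiguously `Influx`); otherwise `NoBias` is returned
#' with attribute `indeterminate = TRUE`.
#'
#' @param er numeric ER or a [bound()].
#' @param efflux_min,influx_max call thresholds (defaults 2.5 and 0.4).
#' @return `"Efflux"`, `"Influx"` or `"NoBias"` (possibly with attribute
#'   `indeterminate`).
#' @export
classify_transport <- function(er, efflux_min = 2.5, influx_max = 0.4) {
  if (!is_bound(er) && is.na(er)) {
    out <- "NoBias"
    attr(out, "indeterminate") <- TRUE
    return(out)
  }
  b <- as_bound(er)
  if (b$type == "point") {
    if (b$value >= efflux_min) return("Efflux")
    if (b$value < influx_max) return("Influx")
    return("NoBias")
  }
  if (b$type == "upper" && b$value <= influx_max) return("Influx")
  if (b$type == "lower" && b$value >= efflux_min) return("Efflux")
  # the bound straddles a decision threshold: no defensible call
  out <- "NoBias"
  attr(out, "indeterminate") <- TRUE
  out
}

#' Format an efflux ratio for reporting
#'
#' Report convention: two decimals, except one significant figure below
#' 0.01; censored ratios carry their inequality sign.
#'
#' @param er numeric ER or [bound()].
#' @return Character scalar.
#' @export
format_er <- function(er) {
  b <- as_bound(er)
  prefix <- switch(b$type, point = "", lower = "> ", upper = "< ")
  v <- b$value
  body <- if (is.na(v)) "NA" else if (abs(v) < 0.01) {
    format(signif(v, 1), scientific = FALSE, trim = TRUE)
  } else {
    formatC(v, format = "f", digits = 2)
  }
  paste0(prefix, body)
}

#' Combine paired AB/BA estimates into bidirectional results
#'
#' Adds the efflux ratio (bound-aware), its uncertainty, the permeability
#' rate class and the directional-transport call to an [estimate_panel()]
#' table (or any table in its schema, such as the packaged reference
#' panel fixture).
#'
#' @param estimates `data.frame` in the [estimate_panel()] schema.
#' @param thresholds a [rate_thresholds()].
#' @param er_method uncertainty method passed to [er_uncertainty()].
#' @param efflux_min,influx_max transport-call thresholds.
#' @return The input with columns `er`, `er_bound_type`, `er_sd`,
#'   `rate_class`, `transport_call`, `transport_indeterminate` appended.
#' @export
bidirectional_results <- function(estimates, thresholds = rate_thresholds(),
                                  er_method = c("quadrature", "largest"),
                                  efflux_min = 2.5, influx_max = 0.4) {
  er_method <- match.arg(er_method)
  n <- nrow(estimates)
  er <- numeric(n); er_type <- character(n); er_sd <- numeric(n)
  rate <- character(n); call <- character(n); indet <- logical(n)
  for (i in seq_len(n)) {
    ab <- row_to_estimate(estimates[i, ], "AB")
    ba <- row_to_estimate(estimates[i, ], "BA")
    if (is.null(ab) || is.null(ba)) {
      er[i] <- NA_real_; er_type[i] <- NA_character_; er_sd[i] <- NA_real_
      rate[i] <- if (!is.null(ab)) classify_rate(ab, thresholds) else NA_character_
      call[i] <- NA_character_; indet[i] <- NA
      next
    }
    e <- withCallingHandlers(
      efflux_ratio(ab, ba),
      warning = function(w) invokeRestart("muffleWarning"))
    e_missing <- !is_bound(e) && is.na(e)
    er[i] <- if (e_missing) NA_real_ else bound_value(e)
    er_type[i] <- if (e_missing) NA_character_ else bound_type(e)
    er_sd[i] <- er_uncertainty(ab, ba, er_method)
    rate[i] <- classify_rate(ab, thresholds)
    tcall <- classify_transport(if (e_missing) NA_real_ else e,
                                efflux_min, influx_max)
    call[i] <- as.character(tcall)
    indet[i] <- isTRUE(attr(tcall, "indeterminate"))
  }
  estimates$er <- er
  estimates$er_bound_type <- er_type
  estimates$er_sd <- er_sd
  estimates$rate_class <- rate
  estimates$transport_call <- call
  estimates$transport_indeterminate <- indet
  estimates
}
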