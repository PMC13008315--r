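#' Load the packaged bidirectional reference panel
#'
#' The published triculture assay results for the 48-compound panel:
#' per-compound AB and BA apparent permeabilities (mean and s.d. of
#' triplicates, x1e-6 cm/s as printed), the printed efflux ratio, and the
#' printed permeability-rate class. The two compounds whose AB transport
#' was too fast to quantify are stored as typed "> 500e-6 cm/s" bounds,
#' and their printed efflux ratios as "< x" bounds.
#'
#' The table is returned in the [estimate_panel()] schema (values in
#' cm/s) plus `casrn`, `key` (CASRN, or a slugified compound name for the
#' entries without one), `er_printed`, `er_printed_bound_type` and
#' `rate_printed`, so it can be fed directly to
#' [bidirectional_results()] and [predict_panel()].
#'
#' @return A `data.frame` with 48 rows.
#' @export
load_reference_panel <- function() {
  path <- system.file("extdata", "bbb_triculture_panel.csv",
                      package = "bbbivive", mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  key <- ifelse(is.na(raw$casrn) | raw$casrn %in% c("", "na"),
                slugify(raw$compound), raw$casrn)
  data.frame(
    compound_id = raw$compound,
    casrn = ifelse(raw$casrn %in% c("", "na"), NA_character_, raw$casrn),
    key = key,
    papp_ab = raw$papp_ab_1e6 * 1e-6,
    sd_ab = raw$sd_ab_1e6 * 1e-6,
    n_ab = 3L,
    r2_ab = NA_real_,
    ab_censored = raw$ab_censored,
    flags_ab = ifelse(raw$ab_censored, "CENSORED_FAST", ""),
    papp_ba = raw$papp_ba_1e6 * 1e-6,
    sd_ba = raw$sd_ba_1e6 * 1e-6,
    n_ba = 3L,
    r2_ba = NA_real_,
    ba_censored = raw$ba_censored,
    flags_ba = ifelse(raw$ba_censored, "CENSORED_FAST", ""),
    er_printed = raw$er_printed,
    er_printed_bound_type = ifelse(raw$er_censored, "upper", "point"),
    rate_printed = raw$rate_printed,
    stringsAsFactors = FALSE)
}

slugify <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", "-", x)
  gsub("^-|-$", "", x)
}

#' Read and write timecourse tables
#'
#' Tidy CSV with columns `compound_id`, `direction`, `replicate`,
#' `time_min`, `conc_uM`, plus a key-value sidecar file describing the
#' assay design (written next to the table as `<path>.design`).
#'
#' @param tc a `timecourse_table` (with a design attribute).
#' @param path CSV path.
#' @param design optional [assay_design()] overriding the attribute.
#' @return `read_timecourse()` returns a `timecourse_table` with the
#'   design re-attached; `write_timecourse()` returns `path` invisibly.
#' @export
write_timecourse <- function(tc, path, design = attr(tc, "design")) {
  utils::write.csv(as.data.frame(tc)[, c("compound_id", "direction",
                                         "replicate", "time_min", "conc_uM")],
                   path, row.names = FALSE)
  if (!is.null(design)) {
    write_design(design, paste0(path, ".design"))
  }
  invisible(path)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path) {
  tc <- utils::read.csv(path, stringsAsFactors = FALSE)
  design_path <- paste0(path, ".design")
  if (file.exists(design_path)) {
    attr(tc, "design") <- read_design(design_path)
  }
  class(tc) <- c("timecourse_table", class(tc))
  tc
}

write_design <- function(design, path) {
  lines <- c(
    sprintf("donor_concentration_C0 = %.15g", design$donor_concentration_C0),
    sprintf("donor_volume = %.15g", design$donor_volume),
    sprintf("receiver_volume = %.15g", design$receiver_volume),
    sprintf("membrane_area_SA = %.15g", design$membrane_area_SA),
    sprintf("sample_volume = %.15g", design$sample_volume),
    sprintf("sample_times = %s",
            paste(format(design$sample_times, trim = TRUE), collapse = ",")),
    sprintf("direction = %s", design$direction))
  writeLines(lines, path)
  invisible(path)
}

read_design <- function(path) {
  kv <- utils::read.table(path, sep = "=", strip.white = TRUE,
                          stringsAsFactors = FALSE,
                          col.names = c("key", "value"))
  get <- function(k) kv$value[kv$key == k]
  assay_design(
    donor_concentration_C0 = as.numeric(get("donor_concentration_C0")),
    donor_volume = as.numeric(get("donor_volume")),
    receiver_volume = as.numeric(get("receiver_volume")),
    membrane_area_SA = as.numeric(get("membrane_area_SA")),
    sample_volume = as.numeric(get("sample_volume")),
    sample_times = as.numeric(strsplit(get("sample_times"), ",")[[1]]),
    direction = get("direction"))
}

#' Read and write machine-readable result tables
#'
#' Plain UTF-8 CSV with a header; missing values as `NA`; censoring kept
#' in typed columns (`*_censored`, `*_bound_type`) rather than encoded in
#' value strings, so the round-trip preserves bounds and infinities
#' exactly.
#'
#' @param x the table to write.
#' @param path CSV path.
#' @return Readers return a `data.frame`; writers return `path` invisibly.
#' @export
write_estimates <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_estimates
#' @export
read_estimates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("flags_ab", "flags_ba")) {
    if (col %in% names(df)) df[[col]][is.na(df[[col]])] <- ""
  }
  df
}

#' @rdname write_estimates
#' @export
write_brain_exposure <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_estimates
#' @export
read_brain_exposure <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read and write toxicokinetic parameter tables
#'
#' Schema: `compound_id`, `casrn`, `fub`, `css_serum_uM`,
#' `reference_dose_mg_kg_day`.
#'
#' @param x,path table and CSV path.
#' @return As for [write_estimates()].
#' @export
write_toxkinetics <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_toxkinetics
#' @export
read_toxkinetics <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("compound_id", "fub", "css_serum_uM")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("toxicokinetic table missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(df$reference_dose_mg_kg_day)) df$reference_dose_mg_kg_day <- 1
  bad <- !is.na(df$fub) & (df$fub <= 0 | df$fub > 1)
  if (any(bad)) stop("fub outside (0, 1] for: ",
                     paste(df$compound_id[bad], collapse = ", "), call. = FALSE)
  df
}

#' Compare measured AB permeabilities with an external permeability table
#'
#' Inner join on CASRN, then the squared Pearson correlation between the
#' paired permeabilities. Censored rows carry no usable point value and
#' are excluded (their count is reported).
#'
#' @param measured table with `casrn` (or `key`), `papp_ab`, and
#'   optionally `ab_censored`.
#' @param external table with `casrn` and `papp` (cm/s or any common
#'   scale; the correlation is scale invariant).
#' @return A list of class `bbb_comparison`: `n_paired`, `r_squared`,
#'   `n_censored_excluded`, and the paired `data.frame`.
#' @export
compare_external <- function(measured, external) {
  key_m <- if (!is.null(measured$casrn)) measured$casrn else measured$key
  keep <- !is.na(key_m) & key_m %in% external$casrn
  censored <- if (!is.null(measured$ab_censored)) measured$ab_censored else FALSE
  n_censored <- sum(keep & censored)
  keep <- keep & !censored
  pairs <- data.frame(
    casrn = key_m[keep],
    papp_measured = measured$papp_ab[keep],
    stringsAsFactors = FALSE)
  pairs$papp_external <-
    external$papp[match(pairs$casrn, external$casrn)]
  pairs <- pairs[stats::complete.cases(pairs), , drop = FALSE]
  if (nrow(pairs) < 3) {
    stop("comparison declined: only ", nrow(pairs),
         " paired compounds (need at least 3)", call. = FALSE)
  }
  r2 <- stats::cor(pairs$papp_measured, pairs$papp_external)^2
  structure(list(n_paired = nrow(pairs), r_squared = r2,
                 n_censored_excluded = n_censored, pairs = pairs),
            class = "bbb_comparison")
}

#' @export
print.bbb_comparison <- function(x, ...) {
  cat(sprintf("External permeability comparison: n = %d pairs, r^2 = %.3f",
              x$n_paired, x$r_squared))
  if (x$n_censored_excluded > 0) {
    cat(sprintf(" (%d censored rows excluded)", x$n_censored_excluded))
  }
  cat("\n")
  invisible(x)
}

#' Render the standard report files
#'
#' Writes deterministic, figure-ready CSVs into `dir`:
#' * `panel_report.csv` -- the bidirectional panel in display units
#'   (x1e-6 cm/s, "mean +/- sd" strings, ">"/"<" bound encoding), sorted
#'   by ascending Papp_AB;
#' * `efflux_ratio_report.csv` -- long format (compound, er,
#'   er_uncertainty, papp_ab) for ER bar plots;
#' * `css_report.csv` -- paired serum/brain steady-state concentrations
#'   sorted by decreasing Css_serum (skipped with a warning when
#'   `exposures` is `NULL` or empty);
#' * `run_manifest.json` -- every threshold actually applied.
#'
#' @param results a [bidirectional_results()] table.
#' @param exposures a [predict_panel()] table or `NULL`.
#' @param dir output directory (created if needed).
#' @param qc,thresholds,physiology the configuration objects used
#'   upstream, recorded in the manifest.
#' @return Invisibly, the paths written.
#' @export
render_reports <- function(results, exposures = NULL, dir = ".",
                           qc = qc_config(), thresholds = rate_thresholds(),
                           physiology = physiology_config()) {
  if (nrow(results) == 0) stop("empty results table", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)

  ord <- order(results$papp_ab)
  rep1 <- results[ord, ]
  fmt_pm <- function(v, sd, censored) {
    ifelse(censored, paste0("> ", format(v * 1e6, trim = TRUE)),
           paste0(format(signif(v * 1e6, 3), trim = TRUE), " ± ",
                  format(signif(sd * 1e6, 2), trim = TRUE)))
  }
  panel <- data.frame(
    compound = rep1$compound_id,
    casrn = if (!is.null(rep1$casrn)) rep1$casrn else NA_character_,
    papp_ab_1e6 = fmt_pm(rep1$papp_ab, rep1$sd_ab, rep1$ab_censored),
    papp_ba_1e6 = fmt_pm(rep1$papp_ba, rep1$sd_ba, rep1$ba_censored),
    efflux_ratio = vapply(seq_len(nrow(rep1)), function(i) {
      if (is.na(rep1$er[i])) return("NA")
      format_er(cols_to_bound(rep1$er[i], rep1$er_bound_type[i]))
    }, character(1)),
    rate_class = rep1$rate_class,
    transport_call = rep1$transport_call,
    n = rep1$n_ab,
    flags = paste0(rep1$flags_ab,
                   ifelse(rep1$flags_ab != "" & rep1$flags_ba != "", "|", ""),
                   rep1$flags_ba),
    stringsAsFactors = FALSE)
  p <- file.path(dir, "panel_report.csv")
  utils::write.csv(panel, p, row.names = FALSE)
  paths <- c(paths, p)

  er_long <- data.frame(compound = results$compound_id,
                        er = results$er,
                        er_bound_type = results$er_bound_type,
                        er_uncertainty = results$er_sd,
                        papp_ab = results$papp_ab,
                        stringsAsFactors = FALSE)
  p <- file.path(dir, "efflux_ratio_report.csv")
  utils::write.csv(er_long, p, row.names = FALSE)
  paths <- c(paths, p)

  if (is.null(exposures) || nrow(exposures) == 0) {
    warning("no brain-exposure table; css_report.csv skipped")
  } else {
    ord <- order(-exposures$css_serum_uM)
    p <- file.path(dir, "css_report.csv")
    utils::write.csv(exposures[ord, ], p, row.names = FALSE)
    paths <- c(paths, p)
  }

  manifest <- list(
    qc = unclass(qc), rate_thresholds = unclass(thresholds),
    physiology = unclass(physiology),
    files = basename(paths))
  p <- file.path(dir, "run_manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}
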