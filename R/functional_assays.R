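# IL-2 dose-response summaries (AUC as response magnitude, the ~41 nM point
# as sensitivity), engagement-induced endocytosis deltas, and percent-of-
# control summary tables comparing mutant cell lines with paired controls.

#' Construct an IL-2 dose-response series
#'
#' A peptide titration (by convention starting at 30 uM with 1:3 dilution
#' steps) with replicate IL-2 readings per dose.
#'
#' @param conc_nM Numeric vector of concentrations in nM, one per row of
#'   `replicates` (repeated per replicate) or per dose.
#' @param il2 Numeric IL-2 readings (pg/mL or OD), parallel to `conc_nM`.
#' @param rep Optional replicate index, parallel to `conc_nM`.
#' @param line_id Cell-line tag.
#' @return An object of class `dose_series` (a data.frame with attributes).
#' @export
dose_series <- function(conc_nM, il2, rep = NULL, line_id = "line") {
  stopifnot(length(conc_nM) == length(il2))
  df <- data.frame(conc_nM = as.numeric(conc_nM), il2 = as.numeric(il2))
  df$rep <- if (is.null(rep)) stats::ave(df$conc_nM, df$conc_nM,
                                         FUN = seq_along) else as.integer(rep)
  doses <- sort(unique(df$conc_nM))
  if (length(doses) < 2L) stop("need at least 2 doses", call. = FALSE)
  if (any(table(df$conc_nM) < 1L)) stop("each dose needs >= 1 replicate",
                                        call. = FALSE)
  structure(df, class = c("dose_series", "data.frame"), line_id = line_id)
}

dose_means <- function(s) {
  agg <- stats::aggregate(il2 ~ conc_nM, data = as.data.frame(s), FUN = mean)
  agg[order(agg$conc_nM), ]
}

#' Dose-response area under the curve (response magnitude)
#'
#' Trapezoid AUC of the mean IL-2 reading against the dose axis with zero
#' baseline. By default the x-axis is log10 concentration (doses plotted on a
#' log axis); zero-peptide wells are excluded (log undefined). The
#' alternative `"index"` axis uses the dilution step number (unit spacing).
#'
#' @param s A `dose_series`.
#' @param x_axis `"log10"` (default) or `"index"`.
#' @return The AUC (units: IL-2 units x dose-axis units).
#' @export
dose_response_auc <- function(s, x_axis = c("log10", "index")) {
  x_axis <- match.arg(x_axis)
  m <- dose_means(s)
  if (x_axis == "log10") m <- m[m$conc_nM > 0, ]
  if (nrow(m) < 2L) stop("AUC needs >= 2 (positive) doses", call. = FALSE)
  x <- switch(x_axis, log10 = log10(m$conc_nM), index = seq_len(nrow(m)))
  trapz(x, m$il2)
}

#' Sensitivity: mean response at the low-dose titration point
#'
#' Returns the mean replicate IL-2 at the measured titration point nearest the
#' target dose. For the standard series (30 uM top, 1:3 steps) the 41 nM
#' sensitivity point is the 7th dose, 30000/3^6 = 41.15 nM. No curve
#' interpolation is performed: the measured point itself is reported.
#'
#' @param s A `dose_series`.
#' @param target_nM Target dose in nM (default 41).
#' @return Mean IL-2 at the nearest dose.
#' @export
sensitivity_at <- function(s, target_nM = 41) {
  m <- dose_means(s)
  m <- m[m$conc_nM > 0, ]
  rel <- abs(m$conc_nM - target_nM) / target_nM
  k <- which.min(rel)
  if (rel[k] > 0.25) {
    stop(sprintf("no measured dose within 25%% of %g nM (nearest: %g nM)",
                 target_nM, m$conc_nM[k]), call. = FALSE)
  }
  m$il2[k]
}

#' Engagement-induced endocytosis: change in surface gMFI
#'
#' Each replicate surface gMFI (TCR or CD4) measured after culture at 10 uM
#' agonist peptide is subtracted from the average gMFI at 0 uM. Positive
#' values indicate internalization; negative values (surface increase) are
#' preserved.
#'
#' @param gmfi_0uM Replicate gMFIs at 0 uM peptide.
#' @param gmfi_10uM Replicate gMFIs at 10 uM peptide.
#' @return Numeric vector `mean(gmfi_0uM) - gmfi_10uM`.
#' @export
#' @examples
#' endocytosis_delta(c(100, 102, 98), 60)  # 40
endocytosis_delta <- function(gmfi_0uM, gmfi_10uM) {
  if (length(gmfi_0uM) < 1L || length(gmfi_10uM) < 1L) {
    stop("need >= 1 replicate at each peptide dose", call. = FALSE)
  }
  mean(gmfi_0uM) - gmfi_10uM
}

#' Percent of paired control, rounded to a whole number
#'
#' `100 x mutant / control`, rounded half away from zero. The sign of a
#' negative metric (e.g. a surface-increase endocytosis delta) is preserved.
#'
#' @param metric_mutant,metric_control Scalar metric values.
#' @return Integer percent of control.
#' @export
#' @examples
#' percent_of_control(30.4, 49.9)  # 61
percent_of_control <- function(metric_mutant, metric_control) {
  stopifnot(length(metric_mutant) == 1L, length(metric_control) == 1L)
  if (!is.finite(metric_control) || metric_control == 0) {
    stop("control metric must be nonzero", call. = FALSE)
  }
  as.integer(round_half_away(100 * metric_mutant / metric_control))
}

#' Assemble a percent-of-control summary table
#'
#' Builds the summary matrix reporting each line's assay metrics as integer
#' percent of its paired control. Control lines (paired to themselves) read
#' 100 in every measured column; metrics missing for a line are reported `ND`.
#'
#' @param metrics Named list: one named numeric vector of metric values per
#'   cell line.
#' @param pairings Named character vector mapping each line to its control
#'   line (controls map to themselves).
#' @return A data.frame of class `summary_table` (character cells, `ND` for
#'   missing assays), rows in `metrics` order.
#' @export
build_summary_table <- function(metrics, pairings) {
  stopifnot(is.list(metrics), !is.null(names(metrics)))
  lines <- names(metrics)
  if (!all(lines %in% names(pairings))) {
    stop("every line needs an entry in pairings", call. = FALSE)
  }
  if (!all(pairings[lines] %in% lines)) {
    bad <- lines[!pairings[lines] %in% lines]
    stop(sprintf("unpaired line(s): control missing for %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  cols <- unique(unlist(lapply(metrics, names)))
  out <- matrix("ND", nrow = length(lines), ncol = length(cols),
                dimnames = list(lines, cols))
  for (ln in lines) {
    ctrl <- metrics[[pairings[[ln]]]]
    for (cn in names(metrics[[ln]])) {
      mv <- metrics[[ln]][[cn]]
      cv <- if (cn %in% names(ctrl)) ctrl[[cn]] else NA_real_
      if (is.finite(mv) && is.finite(cv) && cv != 0) {
        out[ln, cn] <- as.character(percent_of_control(mv, cv))
      }
    }
  }
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  class(df) <- c("summary_table", "data.frame")
  df
}

#' Read / write dose-response CSV (`conc_nM`, `rep`, `il2_pg_ml`)
#'
#' @param path File path.
#' @param line_id Cell-line tag for the returned series.
#' @return `read_dose_csv` returns a `dose_series`.
#' @export
read_dose_csv <- function(path, line_id = "line") {
  df <- utils::read.csv(path)
  stopifnot(all(c("conc_nM", "rep", "il2_pg_ml") %in% names(df)))
  dose_series(df$conc_nM, df$il2_pg_ml, rep = df$rep, line_id = line_id)
}

#' @rdname read_dose_csv
#' @param s A `dose_series`.
#' @export
write_dose_csv <- function(s, path) {
  stopifnot(inherits(s, "dose_series"))
  utils::write.csv(
    data.frame(conc_nM = s$conc_nM, rep = s$rep, il2_pg_ml = s$il2),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
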