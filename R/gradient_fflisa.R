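# Sucrose-gradient FFLISA analysis: fraction-1 background subtraction,
# CD4 percent-of-total, channel normalization to CD4, and DRM/DSM AUC.
# Fractions 1-6 hold detergent-resistant (raft, DRM) material that floats up
# the gradient; fractions 6-10 hold detergent-soluble (DSM) material.

GRADIENT_CHANNELS <- c("CD4", "LCK", "CTxB")

#' Construct a 10-fraction gradient profile
#'
#' Holds per-fraction geometric-mean fluorescence intensities (gMFI) for the
#' CD4, LCK and CTxB channels of a bead-capture FFLISA read across a sucrose
#' gradient, with named layers (`raw`, and `subtracted` once
#' [subtract_fraction1()] has run).
#'
#' @param raw Numeric 10 x 3 matrix (fractions x channels) of raw gMFI;
#'   columns named `CD4`, `LCK`, `CTxB` (a data.frame is accepted).
#' @return An object of class `gradient_profile`.
#' @export
gradient_profile <- function(raw) {
  raw <- as.matrix(raw)
  if (nrow(raw) != 10L) {
    stop("a gradient profile has exactly 10 fractions", call. = FALSE)
  }
  if (!all(GRADIENT_CHANNELS %in% colnames(raw))) {
    stop("raw matrix must have columns CD4, LCK, CTxB", call. = FALSE)
  }
  raw <- raw[, GRADIENT_CHANNELS, drop = FALSE]
  if (any(!is.finite(raw)) || any(raw < 0)) {
    stop("raw gMFI values must be finite and non-negative", call. = FALSE)
  }
  rownames(raw) <- as.character(1:10)
  structure(list(layers = list(raw = raw)), class = "gradient_profile")
}

#' @export
print.gradient_profile <- function(x, ...) {
  cat(sprintf("<gradient_profile> layers: %s\n",
              paste(names(x$layers), collapse = ", ")))
  print(round(x$layers[[length(x$layers)]], 3))
  invisible(x)
}

#' Subtract the fraction-1 background from a gradient profile
#'
#' The top fraction of the gradient contains no membrane material; its raw
#' gMFI is the assay background. Per channel, the fraction-1 value is
#' subtracted from every fraction (so fraction 1 becomes 0); negative results
#' are floored at 0 since negative gMFI is nonphysical.
#'
#' @param p A `gradient_profile` with a `raw` layer.
#' @return The profile with a `subtracted` layer added.
#' @export
subtract_fraction1 <- function(p) {
  stopifnot(inherits(p, "gradient_profile"))
  raw <- p$layers$raw
  sub <- sweep(raw, 2L, raw[1L, ], "-")
  sub[sub < 0] <- 0
  p$layers$subtracted <- sub
  p
}

get_subtracted <- function(p) {
  if (is.null(p$layers$subtracted)) {
    stop("background-subtracted layer missing: run subtract_fraction1() first",
         call. = FALSE)
  }
  p$layers$subtracted
}

#' CD4 signal in each fraction as percent of total CD4 signal
#'
#' `fx %% of total = fx CD4 gMFI / sum(f1:f10) CD4 gMFI x 100`, computed on the
#' background-subtracted layer. The result sums to 100.
#'
#' @param p A `gradient_profile` after [subtract_fraction1()].
#' @return Numeric vector of 10 percentages.
#' @export
cd4_percent_of_total <- function(p) {
  cd4 <- get_subtracted(p)[, "CD4"]
  total <- sum(cd4)
  if (total <= 0) {
    stop("total background-subtracted CD4 signal is zero; cannot normalize",
         call. = FALSE)
  }
  100 * cd4 / total
}

#' Normalize the LCK or CTxB signal to the CD4 signal per fraction
#'
#' `Normalized fx LCK = fx LCK gMFI / fx CD4 gMFI x fx CD4 %% of total`,
#' computed on background-subtracted values. Fractions with zero CD4 signal
#' return 0: no CD4-bound signal can be attributed there.
#'
#' @param p A `gradient_profile` after [subtract_fraction1()].
#' @param channel `"LCK"` or `"CTxB"`.
#' @return Numeric vector of 10 normalized values.
#' @export
normalize_channel_to_cd4 <- function(p, channel = c("LCK", "CTxB")) {
  channel <- match.arg(channel)
  sub <- get_subtracted(p)
  cd4 <- sub[, "CD4"]
  pct <- cd4_percent_of_total(p)
  out <- ifelse(cd4 > 0, sub[, channel] / cd4 * pct, 0)
  unname(out)
}

#' DRM / DSM area under the curve of a normalized gradient trace
#'
#' Trapezoid-rule AUC over the unit-spaced fraction index with zero baseline:
#' fractions 1-6 give the DRM (raft) AUC, fractions 6-10 the DSM AUC.
#' Because fraction 6 is the shared endpoint, `drm_auc + dsm_auc = total_auc`
#' exactly.
#'
#' @param normalized Numeric vector of 10 per-fraction values.
#' @return A list of class `auc_result` with `drm_auc`, `dsm_auc`, `total_auc`.
#' @export
#' @examples
#' auc_drm_dsm(c(0, 10, 60, 10, 0, 0, 20, 20, 10, 0))  # DRM 80, DSM 50
auc_drm_dsm <- function(normalized) {
  normalized <- as.numeric(normalized)
  if (length(normalized) != 10L) {
    stop("expected 10 per-fraction values", call. = FALSE)
  }
  drm <- trapz(1:6, normalized[1:6])
  dsm <- trapz(6:10, normalized[6:10])
  structure(list(drm_auc = drm, dsm_auc = dsm, total_auc = drm + dsm),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("<auc_result> DRM (f1-6) %.4g | DSM (f6-10) %.4g | total %.4g\n",
              x$drm_auc, x$dsm_auc, x$total_auc))
  invisible(x)
}

#' Read / write gradient CSV (`fraction`, `channel`, `gmfi`[, `layer`])
#'
#' @param path File path.
#' @return `read_gradient_csv` returns a `gradient_profile` built from the raw
#'   layer rows (rows without a `layer` column are treated as raw).
#' @export
read_gradient_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("fraction", "channel", "gmfi") %in% names(df)))
  if ("layer" %in% names(df)) df <- df[df$layer == "raw", ]
  raw <- matrix(NA_real_, 10L, length(GRADIENT_CHANNELS),
                dimnames = list(1:10, GRADIENT_CHANNELS))
  for (ch in GRADIENT_CHANNELS) {
    rows <- df[df$channel == ch, ]
    if (nrow(rows) != 10L) {
      stop(sprintf("channel %s: expected 10 fractions, found %d", ch,
                   nrow(rows)), call. = FALSE)
    }
    raw[rows$fraction, ch] <- rows$gmfi
  }
  gradient_profile(raw)
}

#' @rdname read_gradient_csv
#' @param p A `gradient_profile`.
#' @export
write_gradient_csv <- function(p, path) {
  stopifnot(inherits(p, "gradient_profile"))
  rows <- do.call(rbind, lapply(names(p$layers), function(layer) {
    m <- p$layers[[layer]]
    data.frame(fraction = rep(1:10, ncol(m)),
               channel = rep(colnames(m), each = 10L),
               gmfi = as.vector(m), layer = layer)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
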