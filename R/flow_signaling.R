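# Paired-stimulation flow-histogram analysis: bin-by-bin background
# subtraction of the null-stimulation histogram from the agonist histogram,
# percent responders, background-subtracted mean/SEM, and display smoothing.

#' Construct a binned flow-cytometry histogram
#'
#' Represents one exported intensity histogram (cells per intensity bin) for a
#' single stimulation condition and phospho-channel, as exported from a flow
#' analysis package.
#'
#' @param bin_edges Strictly increasing numeric vector of `n + 1` bin edges
#'   (log10 intensity).
#' @param counts Non-negative numeric vector of `n` per-bin event counts.
#' @param label Stimulation tag, `"null"` or `"agonist"`.
#' @param channel Phospho-target name (e.g. `"pCD3z"`, `"pZAP70"`, `"pPLCg1"`).
#' @return An object of class `flow_histogram`.
#' @export
#' @examples
#' flow_histogram(0:5, c(0, 10, 20, 10, 0), label = "agonist")
flow_histogram <- function(bin_edges, counts, label = c("null", "agonist"),
                           channel = "pCD3z") {
  label <- match.arg(label)
  bin_edges <- as.numeric(bin_edges)
  counts <- as.numeric(counts)
  if (any(diff(bin_edges) <= 0)) {
    stop("bin_edges must be strictly increasing", call. = FALSE)
  }
  if (length(counts) != length(bin_edges) - 1L) {
    stop("counts must have length(bin_edges) - 1 entries", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(
    list(bin_edges = bin_edges, counts = counts, label = label,
         channel = channel),
    class = "flow_histogram"
  )
}

#' @export
print.flow_histogram <- function(x, ...) {
  cat(sprintf("<flow_histogram> %s / %s: %d bins, %g events\n",
              x$channel, x$label, length(x$counts), sum(x$counts)))
  invisible(x)
}

bin_centers <- function(edges) (edges[-1] + edges[-length(edges)]) / 2

#' Bin-by-bin background subtraction of a paired null stimulation
#'
#' Subtracts the null-stimulation histogram from the agonist-stimulation
#' histogram bin by bin, yielding the signed per-bin excess of agonist events
#' over background. If total event counts differ, the null counts are first
#' rescaled to the agonist total so the differences sum to zero.
#'
#' @param agonist,null `flow_histogram` objects with identical bin edges and
#'   channel.
#' @param rescale If `TRUE` (default) rescale null counts to match the agonist
#'   total before subtracting.
#' @return An object of class `diff_histogram` with fields `bin_edges`,
#'   `bin_centers`, `diffs`, `total_agonist`, `total_null`, `smoothed`.
#' @export
#' @examples
#' a <- flow_histogram(0:5, c(0, 10, 20, 10, 0), "agonist")
#' n <- flow_histogram(0:5, c(5, 20, 10, 5, 0), "null")
#' subtract_background(a, n)$diffs
subtract_background <- function(agonist, null, rescale = TRUE) {
  stopifnot(inherits(agonist, "flow_histogram"), inherits(null, "flow_histogram"))
  if (!isTRUE(all.equal(agonist$bin_edges, null$bin_edges))) {
    stop("bin edges of agonist and null histograms differ", call. = FALSE)
  }
  if (!identical(agonist$channel, null$channel)) {
    stop("agonist and null histograms are from different channels",
         call. = FALSE)
  }
  ta <- sum(agonist$counts)
  tn <- sum(null$counts)
  null_counts <- null$counts
  if (rescale && tn > 0 && ta != tn) {
    null_counts <- null_counts * ta / tn
  }
  structure(
    list(bin_edges = agonist$bin_edges,
         bin_centers = bin_centers(agonist$bin_edges),
         diffs = agonist$counts - null_counts,
         total_agonist = ta,
         total_null = tn,
         channel = agonist$channel,
         smoothed = FALSE),
    class = "diff_histogram"
  )
}

#' @export
print.diff_histogram <- function(x, ...) {
  cat(sprintf("<diff_histogram> %s: %d bins, %g agonist events%s\n",
              x$channel, length(x$diffs), x$total_agonist,
              if (x$smoothed) " (smoothed, display layer)" else ""))
  invisible(x)
}

#' Percent of agonist-stimulated cells responding above background
#'
#' Intensity bins with positive background-subtracted values are considered to
#' contain cells that responded to the agonist above the paired null. Returns
#' the positive difference mass as a percentage of the agonist event total.
#'
#' @param d A `diff_histogram`.
#' @return Percent responders in `[0, 100]`.
#' @export
percent_responders <- function(d) {
  stopifnot(inherits(d, "diff_histogram"))
  if (d$total_agonist <= 0) {
    stop("percent responders undefined: zero agonist events", call. = FALSE)
  }
  100 * sum(pmax(d$diffs, 0)) / d$total_agonist
}

#' Response statistics of a background-subtracted histogram
#'
#' Mean intensity and SEM are computed on the positive part of the
#' background-subtracted data: bins with negative differences contribute no
#' responder mass. The mean is the positive-mass-weighted average of bin
#' centers; the SEM is the weighted SD divided by `sqrt(positive_mass)`
#' (positive mass acts as the effective n).
#'
#' @param d A `diff_histogram`.
#' @return A list of class `response_stats` with `percent_responders`,
#'   `mean_intensity`, `sem_intensity`, `positive_mass`. Mean/SEM are `NA`
#'   when no bin is positive.
#' @export
response_stats <- function(d) {
  stopifnot(inherits(d, "diff_histogram"))
  pos <- pmax(d$diffs, 0)
  pm <- sum(pos)
  if (pm <= 0) {
    out <- list(percent_responders = 0, mean_intensity = NA_real_,
                sem_intensity = NA_real_, positive_mass = 0)
  } else {
    mu <- sum(pos * d$bin_centers) / pm
    v <- sum(pos * (d$bin_centers - mu)^2) / pm
    out <- list(percent_responders = percent_responders(d),
                mean_intensity = mu,
                sem_intensity = sqrt(v / pm),
                positive_mass = pm)
  }
  class(out) <- "response_stats"
  out
}

#' @export
print.response_stats <- function(x, ...) {
  cat(sprintf(
    "<response_stats> %%responders=%.2f mean=%.4g sem=%.4g pos.mass=%g\n",
    x$percent_responders, x$mean_intensity, x$sem_intensity, x$positive_mass))
  invisible(x)
}

#' Nearest-neighbour smoothing of a difference histogram (display layer)
#'
#' Centered moving average over `window` bins, truncated at the edges
#' (each bin is averaged over the neighbours actually available). Smoothing is
#' for graphing only; statistics are always computed on unsmoothed differences.
#'
#' @param d A `diff_histogram`.
#' @param window Positive integer number of nearest-neighbour bins
#'   (default 500). Even windows are widened to the next odd value so the
#'   average is centered.
#' @return A smoothed `diff_histogram` flagged `smoothed = TRUE`.
#' @export
smooth_diffs <- function(d, window = 500L) {
  stopifnot(inherits(d, "diff_histogram"))
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  half <- window %/% 2L
  n <- length(d$diffs)
  if (half == 0L) {
    sm <- d$diffs
  } else {
    cs <- cumsum(c(0, d$diffs))
    i <- seq_len(n)
    lo <- pmax(i - half, 1L)
    hi <- pmin(i + half, n)
    sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  d$diffs <- sm
  d$smoothed <- TRUE
  d
}

#' Normalize a mutant response statistic to its paired control
#'
#' Each mutant cell line is paired with a control line processed in parallel;
#' the mutant's background-subtracted mean intensity is expressed as a
#' fraction of the control's (multiply by 100 for summary tables).
#'
#' @param mutant,control `response_stats` objects.
#' @return `mutant$mean_intensity / control$mean_intensity`.
#' @export
normalize_to_control <- function(mutant, control) {
  stopifnot(inherits(mutant, "response_stats"),
            inherits(control, "response_stats"))
  if (!is.finite(control$mean_intensity) || control$mean_intensity <= 0) {
    stop("control mean intensity must be positive for normalization",
         call. = FALSE)
  }
  mutant$mean_intensity / control$mean_intensity
}

#' Read / write histogram CSV (`bin_lo`, `bin_hi`, `count`)
#'
#' @param path File path.
#' @param label,channel Passed to [flow_histogram()] when reading.
#' @return `read_histogram_csv` returns a `flow_histogram`.
#' @export
read_histogram_csv <- function(path, label = "null", channel = "pCD3z") {
  df <- utils::read.csv(path)
  stopifnot(all(c("bin_lo", "bin_hi", "count") %in% names(df)))
  df <- df[order(df$bin_lo), ]
  if (any(abs(df$bin_hi[-nrow(df)] - df$bin_lo[-1]) > 1e-9)) {
    stop("histogram bins are not contiguous", call. = FALSE)
  }
  flow_histogram(c(df$bin_lo, df$bin_hi[nrow(df)]), df$count,
                 label = label, channel = channel)
}

#' @rdname read_histogram_csv
#' @param h A `flow_histogram`.
#' @export
write_histogram_csv <- function(h, path) {
  stopifnot(inherits(h, "flow_histogram"))
  n <- length(h$counts)
  utils::write.csv(
    data.frame(bin_lo = h$bin_edges[-(n + 1L)], bin_hi = h$bin_edges[-1L],
               count = h$counts),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
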