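# Seeded synthetic-data generators for the assay-side modules. Each generator
# is a pure function of its parameters (including the seed): every operation
# draws from its own named RNG stream derived from the seed, so adding draws
# to one stream never shifts another, and reruns are byte-identical.

#' Simulate a paired null/agonist flow-histogram pair
#'
#' Emulates intensity histograms from paired stimulations of T-cell:APC
#' couples: a null-peptide APC (background) versus an agonist-peptide APC.
#' Per-event log10 intensities are drawn from a lognormal background; under
#' agonist stimulation a fraction of cells (the responders) is shifted
#' upward. Both histograms are binned on identical edges (default 64 bins
#' over log10 intensity 0-5: the resolution is matched to the 10^4-event
#' sample size so per-bin counting noise stays below the percent-responder
#' detection floor; see the methods vignette).
#'
#' @param n_events Events per stimulation (default `1e4`, the per-sample
#'   couple count collected in this assay family).
#' @param responder_fraction Fraction of agonist-stimulated cells that
#'   respond, in `[0, 1]`.
#' @param null_log_mean,null_log_sd Mean and SD of non-responder log10
#'   intensity.
#' @param shift Upward log10-intensity shift of responders (>= 0).
#' @param n_bins,bin_range Binning: number of bins and `(lo, hi)` log10 range.
#' @param seed Integer seed.
#' @return A list with `null` and `agonist` [flow_histogram()]s and the
#'   drawn responder count `n_responders`.
#' @export
gen_flow_pair <- function(n_events = 10000L, responder_fraction = 0.3,
                          null_log_mean = 1.5, null_log_sd = 0.15,
                          shift = 1.0, n_bins = 64L, bin_range = c(0, 5),
                          seed = 1L, channel = "pCD3z") {
  if (n_events < 1L) stop("n_events must be >= 1", call. = FALSE)
  if (responder_fraction < 0 || responder_fraction > 1) {
    stop("responder_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (shift < 0) stop("shift must be >= 0", call. = FALSE)
  if (bin_range[1] >= bin_range[2]) {
    stop("bin_range must satisfy lo < hi", call. = FALSE)
  }
  edges <- seq(bin_range[1], bin_range[2], length.out = n_bins + 1L)
  bin_events <- function(x) {
    x <- pmin(pmax(x, bin_range[1]), bin_range[2])
    idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
    tabulate(idx, nbins = n_bins)
  }
  null_x <- with_stream(seed, "flow_null",
                        stats::rnorm(n_events, null_log_mean, null_log_sd))
  ag <- with_stream(seed, "flow_agonist", {
    k <- stats::rbinom(1L, n_events, responder_fraction)
    x <- stats::rnorm(n_events, null_log_mean, null_log_sd)
    if (k > 0L) x[seq_len(k)] <- x[seq_len(k)] + shift
    list(x = x, k = k)
  })
  list(null = flow_histogram(edges, bin_events(null_x), "null", channel),
       agonist = flow_histogram(edges, bin_events(ag$x), "agonist", channel),
       n_responders = ag$k)
}

#' Simulate a 10-fraction sucrose-gradient FFLISA profile
#'
#' Builds per-channel gMFI traces as a constant assay background plus
#' Gaussian-shaped peaks at the DRM and DSM centers plus noise, clipped at 0.
#' Fraction 1 receives background (and noise) only, so downstream fraction-1
#' subtraction recovers the peaks.
#'
#' @param drm_center,dsm_center Peak centers, fraction indices in 1..10.
#' @param amplitudes Named list per channel of `c(drm = , dsm = )` peak
#'   amplitudes. Defaults place CD4 in both compartments, LCK mostly in the
#'   DRM, and the raft marker CTxB almost entirely in the DRM.
#' @param peak_sd Gaussian peak width in fraction units.
#' @param background_offset Background gMFI added to every fraction.
#' @param noise_sd SD of additive gaussian noise.
#' @param seed Integer seed.
#' @return A [gradient_profile()] (raw layer only).
#' @export
gen_gradient_profile <- function(drm_center = 3, dsm_center = 8,
                                 amplitudes = list(
                                   CD4 = c(drm = 300, dsm = 300),
                                   LCK = c(drm = 200, dsm = 50),
                                   CTxB = c(drm = 400, dsm = 20)),
                                 peak_sd = 1.0, background_offset = 50,
                                 noise_sd = 5, seed = 1L) {
  if (drm_center < 1 || drm_center > 10 || dsm_center < 1 || dsm_center > 10) {
    stop("peak centers must lie in 1..10", call. = FALSE)
  }
  if (background_offset < 0) stop("background_offset must be >= 0",
                                  call. = FALSE)
  stopifnot(all(GRADIENT_CHANNELS %in% names(amplitudes)))
  f <- 1:10
  raw <- sapply(GRADIENT_CHANNELS, function(ch) {
    a <- amplitudes[[ch]]
    peaks <- a[["drm"]] * exp(-(f - drm_center)^2 / (2 * peak_sd^2)) +
      a[["dsm"]] * exp(-(f - dsm_center)^2 / (2 * peak_sd^2))
    peaks[1L] <- 0  # fraction 1 is pure background
    y <- background_offset + peaks
    if (noise_sd > 0) {
      y <- y + with_stream(seed, paste0("gradient_", ch),
                           stats::rnorm(10L, 0, noise_sd))
    }
    pmax(y, 0)
  })
  gradient_profile(raw)
}

#' Four-parameter logistic dose-response mean
#'
#' `bottom + (top - bottom) / (1 + (ec50 / conc)^hill)`.
#'
#' @param conc_nM Concentration(s) in nM (> 0).
#' @param bottom,top,ec50,hill 4PL parameters (`ec50` in nM).
#' @return Expected response.
#' @export
fourpl <- function(conc_nM, bottom = 0, top = 2000, ec50 = 500, hill = 1.5) {
  bottom + (top - bottom) / (1 + (ec50 / conc_nM)^hill)
}

#' Simulate an IL-2 dose-response titration
#'
#' Concentrations follow `top_conc_uM / dilution^k` for `k = 0 .. n_points-1`
#' (default: 30 uM top with 1:3 steps, so the 7th dose is 30000/729 = 41.15
#' nM, the standard low-dose sensitivity point). Replicate readings are the
#' 4PL mean times multiplicative lognormal noise with coefficient of
#' variation `cv` (mean exactly 1).
#'
#' @param top_conc_uM Top concentration in uM.
#' @param dilution Dilution factor (> 1).
#' @param n_points Number of titration points (>= 2).
#' @param bottom,top,ec50,hill 4PL parameters ([fourpl()]).
#' @param cv Coefficient of variation of the multiplicative noise.
#' @param n_reps Replicates per dose.
#' @param seed Integer seed.
#' @param line_id Cell-line tag.
#' @return A [dose_series()].
#' @export
gen_dose_series <- function(top_conc_uM = 30, dilution = 3, n_points = 12L,
                            bottom = 0, top = 2000, ec50 = 500, hill = 1.5,
                            cv = 0.1, n_reps = 3L, seed = 1L,
                            line_id = "line") {
  if (dilution <= 1) stop("dilution must be > 1", call. = FALSE)
  if (n_points < 2L) stop("need >= 2 titration points", call. = FALSE)
  conc <- top_conc_uM * 1000 / dilution^(seq_len(n_points) - 1L)
  mu <- fourpl(conc, bottom, top, ec50, hill)
  conc_all <- rep(conc, each = n_reps)
  mu_all <- rep(mu, each = n_reps)
  noise <- if (cv > 0) {
    s2 <- log(1 + cv^2)
    with_stream(seed, "dose_noise",
                stats::rlnorm(length(mu_all), -s2 / 2, sqrt(s2)))
  } else {
    rep(1, length(mu_all))
  }
  dose_series(conc_all, mu_all * noise,
              rep = rep(seq_len(n_reps), times = n_points), line_id = line_id)
}
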