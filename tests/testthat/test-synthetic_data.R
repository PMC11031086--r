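# Synthetic-data generators: determinism, parameter validation, and the
# structural ground-truth guarantees the analysis tests rely on.

test_that("gen_flow_pair bins all events on shared edges, deterministically", {
  pair <- gen_flow_pair(n_events = 10000L, responder_fraction = 0.3,
                        shift = 0.5, seed = 3)
  expect_equal(pair$null$bin_edges, pair$agonist$bin_edges)
  expect_equal(sum(pair$null$counts), 10000)
  expect_equal(sum(pair$agonist$counts), 10000)
  pair2 <- gen_flow_pair(n_events = 10000L, responder_fraction = 0.3,
                         shift = 0.5, seed = 3)
  expect_identical(pair, pair2)                        # seeded determinism
  expect_false(identical(
    pair$agonist$counts,
    gen_flow_pair(n_events = 10000L, responder_fraction = 0.3,
                  shift = 0.5, seed = 4)$agonist$counts))

  expect_error(gen_flow_pair(responder_fraction = 1.2), "responder_fraction")
  expect_error(gen_flow_pair(bin_range = c(2, 2)), "lo < hi")
})

test_that("gen_flow_pair null and saturation cases behave as stated", {
  # responder_fraction 0: difference mass ~ 0 (single-seed smoke; the
  # 20-seed bound lives in test-acceptance.R)
  p0 <- gen_flow_pair(responder_fraction = 0, seed = 5)
  d0 <- subtract_background(p0$agonist, p0$null)
  expect_lt(percent_responders(d0), 3)
  # responder_fraction 1 with a large shift: agonist mass sits above the
  # null support
  p1 <- gen_flow_pair(responder_fraction = 1, shift = 2, seed = 5)
  top_null <- max(which(p1$null$counts > 0))
  n_bins <- length(p1$agonist$counts)
  expect_gt(sum(p1$agonist$counts[(top_null + 1):n_bins]) / 10000, 0.99)
})

test_that("gen_gradient_profile places peaks and keeps fraction 1 background", {
  flat <- gen_gradient_profile(amplitudes = list(CD4 = c(drm = 0, dsm = 0),
                                                 LCK = c(drm = 0, dsm = 0),
                                                 CTxB = c(drm = 0, dsm = 0)),
                               background_offset = 40, noise_sd = 0, seed = 1)
  expect_equal(unname(flat$layers$raw), matrix(40, 10, 3),
               ignore_attr = TRUE)
  single <- gen_gradient_profile(drm_center = 3,
                                 amplitudes = list(CD4 = c(drm = 100, dsm = 0),
                                                   LCK = c(drm = 100, dsm = 0),
                                                   CTxB = c(drm = 100, dsm = 0)),
                                 noise_sd = 0, seed = 1)
  expect_equal(unname(which.max(single$layers$raw[, "LCK"])), 3)
  expect_equal(unname(single$layers$raw[1, "LCK"]), 50)  # background only
  expect_identical(gen_gradient_profile(seed = 9), gen_gradient_profile(seed = 9))
  expect_error(gen_gradient_profile(drm_center = 0), "1..10")
})

test_that("gen_dose_series follows the titration and the 4PL mean", {
  s <- gen_dose_series(cv = 0, seed = 1)
  conc <- sort(unique(s$conc_nM), decreasing = TRUE)
  expect_equal(conc, 30000 / 3^(0:11))
  expect_equal(conc[7], 30000 / 729, tolerance = 1e-12)  # ~41.15 nM
  # cv = 0 -> replicates equal the 4PL mean exactly
  expect_equal(s$il2, fourpl(s$conc_nM))
  # flat curve (bottom = top): AUC = top x log10 span
  flat <- gen_dose_series(bottom = 300, top = 300, cv = 0, seed = 1)
  span <- log10(30000) - log10(30000 / 3^11)
  expect_equal(dose_response_auc(flat), 300 * span)
  expect_identical(gen_dose_series(seed = 2), gen_dose_series(seed = 2))
  expect_error(gen_dose_series(dilution = 1), "dilution")
})

test_that("gen_protein_msa plants conserved and covarying columns", {
  tr <- symmetric_tree(8, 0.4)
  cls <- c(rep("conserved", 5), rep("neutral", 10), rep("covary:1", 2))
  b <- gen_protein_msa(tr, cls, seed = 7)
  expect_equal(dim(b$protein), c(8L, 17L))
  for (j in 1:5) expect_length(unique(b$protein[, j]), 1L)
  # covary pair: column 17 is a bijective relabelling of column 16
  map <- table(b$protein[, 16], b$protein[, 17])
  expect_true(all(rowSums(map > 0) == 1) && all(colSums(map > 0) <= 1))
  expect_identical(gen_protein_msa(tr, cls, seed = 7)$protein, b$protein)
  expect_error(gen_protein_msa(tr, c("neutral", "covary:1")), "exactly two")
  expect_error(gen_protein_msa("((a:1,b:1", c("neutral", "neutral")),
               "Newick")
})

test_that("gen_codon_alignment respects omega = 0 and zero branch lengths", {
  tr <- symmetric_tree(4, 0.5)
  b0 <- gen_codon_alignment(tr, rep(0, 15), seed = 2)
  expect_true(all(apply(b0$protein, 2, function(x) length(unique(x)) == 1)))
  trz <- tr; trz$edge.length[] <- 0
  bz <- gen_codon_alignment(trz, rep(1, 15), seed = 2)
  expect_true(all(apply(bz$codon, 2, function(x) length(unique(x)) == 1)))
  expect_identical(gen_codon_alignment(tr, rep(0.5, 10), seed = 3)$codon,
                   gen_codon_alignment(tr, rep(0.5, 10), seed = 3)$codon)
  trn <- ape::read.tree(text = "(a,b,c);")
  expect_error(gen_codon_alignment(trn, rep(1, 5)), "branch lengths")
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(gen_flow_pair(seed = 1))
  invisible(gen_dose_series(seed = 1))
  invisible(gen_codon_alignment(symmetric_tree(4, 0.1), rep(1, 5), seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("make_covariation_fixture has the stated deterministic structure", {
  fx <- make_covariation_fixture()
  expect_equal(nrow(fx$pairs), 401 * 400 / 2)            # 80,200
  expect_equal(nrow(fx$sites), 401)
  get_mi <- function(i, j) fx$pairs$mi_raw[fx$pairs$i == i & fx$pairs$j == j]
  expect_equal(get_mi(1, 2), 9.0)
  expect_equal(get_mi(59, 60), 0.1)
  expect_equal(get_mi(8, 31), 9.0)                       # 401st high-MI pair
  expect_equal(get_mi(8, 32), 0.1)                       # 402nd is background
  expect_equal(sum(fx$pairs$mi_raw == 9.0), 401)
  expect_identical(make_covariation_fixture(), fx)       # no randomness
})
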