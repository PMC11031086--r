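# Alignment handling, conservation scoring, mutual information and the
# covariation calling rule.

test_that("strip_nonreference_columns drops reference insertions", {
  b <- strip_nonreference_columns(toy_protein_msa())
  expect_equal(ncol(b$protein), 5L)
  expect_equal(b$positions, 48:52)
  expect_false(any(b$protein["mouse", ] == "-"))

  # reference without gaps -> identity
  m <- rbind(r1 = c("A", "C", "D"), r2 = c("A", "-", "D"))
  b2 <- msa_bundle(m, ref_id = "r1", ref_offset = 48L)
  expect_identical(strip_nonreference_columns(b2)$protein, b2$protein)
  expect_equal(strip_nonreference_columns(b2)$positions, 48:50)

  # "A-CD" example: gap column removed, numbering 48..50
  m3 <- rbind(ref = c("A", "-", "C", "D"), other = c("A", "K", "C", "E"))
  b3 <- strip_nonreference_columns(msa_bundle(m3, ref_id = "ref"))
  expect_equal(ncol(b3$protein), 3L)
  expect_equal(b3$positions, 48:50)

  allgap <- msa_bundle(rbind(ref = c("-", "-"), o = c("A", "C")),
                       ref_id = "ref")
  expect_error(strip_nonreference_columns(allgap), "all gaps")

  expect_error(msa_bundle(m3, ref_id = "nope"), "not found")
})

test_that("codon layer is trimmed in register with the protein layer", {
  prot <- rbind(ref = c("K", "-", "L"), o = c("K", "A", "L"))
  cod <- rbind(ref = c("AAG", "---", "CTT"), o = c("AAA", "GCT", "CTG"))
  b <- strip_nonreference_columns(msa_bundle(prot, codon = cod, ref_id = "ref"))
  expect_equal(dim(b$codon), c(2L, 2L))
  expect_equal(unname(b$codon["o", ]), c("AAA", "CTG"))
  # inconsistent translation is rejected at construction
  bad <- cod; bad["o", 3] <- "GGG"
  expect_error(msa_bundle(prot, codon = bad, ref_id = "ref"), "translate")
})

test_that("column_frequencies gives the logo layer with gap fractions", {
  cf <- column_frequencies(toy_protein_msa())
  expect_equal(unname(cf$freq["K", 1]), 1)                  # invariant column
  expect_equal(unname(cf$freq[c("A", "S", "T"), 2]),
               c(2, 2, 1) / 5)
  expect_equal(unname(cf$gap_fraction[3]), 3 / 5)
  expect_true(all(abs(colSums(cf$freq)[cf$n_scored > 0] - 1) < 1e-12))
  # 10 rows: 6 L, 3 I, 1 gap
  m <- matrix(c(rep("L", 6), rep("I", 3), "-"), ncol = 1,
              dimnames = list(paste0("s", 1:10), NULL))
  cf2 <- column_frequencies(m)
  expect_equal(unname(cf2$freq["L", 1]), 6 / 9)
  expect_equal(unname(cf2$freq["I", 1]), 3 / 9)
  expect_equal(unname(cf2$gap_fraction), 0.1)
})

test_that("conservation scores are entropy z-scores with mean 0 / SD 1", {
  # two columns with entropies 0 and 1 -> scores -1 and +1
  m <- cbind(rep("K", 4), c("A", "A", "V", "V"))
  rownames(m) <- paste0("s", 1:4)
  sc <- conservation_scores(m)
  expect_equal(sc$entropy, c(0, 1))
  expect_equal(sc$conservation, c(-1, 1))

  # mean 0 / SD 1 (population) on any valid alignment; invariant column is
  # the minimum
  b <- gen_protein_msa(symmetric_tree(8, 0.5),
                       c(rep("conserved", 3), rep("neutral", 12)), seed = 2)
  sc2 <- conservation_scores(b)
  expect_lt(abs(mean(sc2$conservation)), 1e-9)
  expect_lt(abs(sqrt(mean(sc2$conservation^2)) - 1), 1e-9)
  expect_equal(which(sc2$conservation == min(sc2$conservation)),
               which(sc2$entropy == 0))

  expect_error(conservation_scores(cbind(rep("K", 3), rep("A", 3))),
               "identical variability")
})

test_that("mutual_information matches the brute-force oracle", {
  set.seed(42)
  for (rep_ in 1:5) {
    n_row <- sample(6:10, 1)
    n_col <- sample(3:6, 1)
    m <- matrix(sample(c("A", "C", "D", "E", "-"), n_row * n_col,
                       replace = TRUE, prob = c(rep(0.23, 4), 0.08)),
                n_row, n_col, dimnames = list(paste0("s", 1:n_row), NULL))
    pt <- mutual_information(m, min_coverage = 0)
    for (k in seq_len(nrow(pt))) {
      i <- pt$i[k]; j <- pt$j[k]
      keep <- m[, i] %in% coreceptR:::AA20 & m[, j] %in% coreceptR:::AA20
      if (sum(keep) < 2) {
        expect_true(is.na(pt$mi_raw[k]))
      } else {
        expect_equal(pt$mi_raw[k], mi_oracle(m[, i], m[, j]),
                     tolerance = 1e-12)
      }
    }
    expect_true(all(pt$mi_raw >= -1e-12, na.rm = TRUE))   # non-negative
  }
})

test_that("mutual_information analytic cases and coverage rule", {
  # two perfectly coupled columns over 4 equiprobable states -> 2 bits
  s4 <- c("A", "C", "D", "E")
  m <- cbind(rep(s4, 5), rep(s4, 5), rep(s4, each = 5))
  rownames(m) <- paste0("s", 1:20)
  pt <- mutual_information(m)
  expect_equal(pt$mi_raw[pt$i == 1 & pt$j == 2], 2)
  # two identical columns uniform over 20 states -> log2(20)
  m20 <- cbind(coreceptR:::AA20, coreceptR:::AA20, rep("K", 20))
  rownames(m20) <- paste0("s", 1:20)
  pt20 <- mutual_information(m20, min_coverage = 0.5)
  expect_equal(pt20$mi_raw[1], log2(20))
  # a pair below joint coverage is unscored
  gappy <- cbind(c("A", "C", rep("-", 8)), c("A", "C", rep("-", 8)),
                 rep("K", 10))
  rownames(gappy) <- paste0("s", 1:10)
  ptg <- mutual_information(gappy, min_coverage = 0.5)
  expect_true(is.na(ptg$mi_raw[ptg$i == 1 & ptg$j == 2]))
})

test_that("APC subtracts the average product of column means", {
  b <- gen_protein_msa(symmetric_tree(8, 0.6), rep("neutral", 6), seed = 9)
  pt <- mutual_information(b, min_coverage = 0)
  cols <- sort(unique(c(pt$i, pt$j)))
  col_mean <- vapply(cols, function(c_) {
    mean(pt$mi_raw[pt$i == c_ | pt$j == c_])
  }, numeric(1))
  names(col_mean) <- cols
  overall <- mean(pt$mi_raw)
  expected <- pt$mi_raw - col_mean[as.character(pt$i)] *
    col_mean[as.character(pt$j)] / overall
  expect_equal(pt$mi_apc, unname(expected), tolerance = 1e-12)
})

test_that("planted covarying pair has top MI against neutral background", {
  b <- gen_protein_msa(symmetric_tree(16, 0.6),
                       c(rep("neutral", 10), rep("covary:1", 2)), seed = 4)
  pt <- mutual_information(b, min_coverage = 0)
  top <- pt[which.max(pt$mi_raw), ]
  expect_equal(c(top$i, top$j), c(58, 59))   # offset 48: columns 11 and 12
})

test_that("call_covariation applies the dual-threshold rule strictly", {
  sites <- data.frame(position = 1:6,
                      conservation = c(-0.8, -0.6, -0.4, -0.35, -0.9, 0.2))
  pairs <- data.frame(i = c(1, 1, 3, 1, 5),
                      j = c(2, 3, 4, 5, 6),
                      mi_raw = c(4.5, 4.5, 8.5, 4.0, 9.0))
  out <- call_covariation(pairs, sites,
                          covariation_criteria(select_fraction = 1))
  expect_equal(out$covary_call, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(out$rule_fired[1], "low_MI_rule")   # MI 4.5, both < -0.5
  expect_equal(out$rule_fired[3], "high_MI_rule")  # MI 8.5, both < -0.3
  # boundary: MI exactly 4 with deep conservation is NOT called
  expect_false(out$covary_call[4])
  # partner above the conservation cut blocks the call
  expect_false(out$covary_call[5])
})

test_that("the select-fraction cap keeps the top-MI pairs", {
  sites <- data.frame(position = 1:5, conservation = rep(-1, 5))
  pairs <- expand.grid(i = 1:4, j = 2:5)
  pairs <- pairs[pairs$i < pairs$j, ]
  pairs$mi_raw <- seq(5, 5 + nrow(pairs) - 1)
  out <- call_covariation(pairs, sites,
                          covariation_criteria(select_fraction = 0.2))
  expect_equal(sum(out$covary_call), floor(0.2 * nrow(pairs)))
  expect_true(all(out$mi_raw[out$covary_call] >=
                    max(out$mi_raw[!out$covary_call])))
})
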