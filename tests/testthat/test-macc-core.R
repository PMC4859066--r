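test_that("MACC slope equals the closed-form OLS slope on -ln(concentration)", {
  conc <- c(1.5, 6.25, 25, 100)
  x <- -log(conc)
  s <- make_series(cbind(c(1, 4, 5), c(2, 3, 5), c(3, 2, 5), c(4, 1, 5)))
  m <- fit_macc(s)
  v <- track_values(m)
  # signal rising with digestion depth = inaccessible = negative slope
  expect_equal(v[1L], ols_slope(x, 1:4))
  expect_equal(v[1L], -0.715, tolerance = 1e-3)
  # sign symmetry
  expect_equal(v[2L], -v[1L])
  # constant response: slope 0, P = 1 by convention
  expect_equal(v[3L], 0)
  expect_equal(unname(unlist(m$pvalues))[3L], 1)

  # agreement with lm() on random bins
  set.seed(21)
  y <- matrix(rexp(400), ncol = 4)
  mr <- fit_macc(make_series(y))
  fits <- apply(y, 1L, function(row) unname(coef(lm(row ~ x))[2L]))
  expect_equal(track_values(mr), fits, tolerance = 1e-10)
  # and the P value matches cor.test's Pearson t-test
  p_ct <- apply(y, 1L, function(row) cor.test(x, row)$p.value)
  expect_equal(unlist(mr$pvalues, use.names = FALSE), unname(p_ct),
               tolerance = 1e-12)
})

test_that("bins with no reads at any point are missing; the strict rule is available", {
  y <- rbind(c(0, 0, 0, 0), c(0, 1, 2, 3), c(1, 2, 3, 4))
  m <- fit_macc(make_series(y))
  expect_true(is.na(track_values(m)[1L]))
  expect_false(anyNA(track_values(m)[2:3]))
  m2 <- fit_macc(make_series(y), missing_rule = "any_zero")
  expect_equal(sum(is.na(track_values(m2))), 2L)
})

test_that("changing the log base rescales slopes by a constant and keeps P values", {
  set.seed(22)
  y <- matrix(rexp(200), ncol = 4)
  me <- fit_macc(make_series(y))
  m2 <- fit_macc(make_series(y), log_base = 2)
  expect_equal(track_values(m2), track_values(me) * log(2), tolerance = 1e-12)
  expect_equal(unlist(m2$pvalues, use.names = FALSE),
               unlist(me$pvalues, use.names = FALSE), tolerance = 1e-12)
})

test_that("Mann-Kendall P values match exhaustive enumeration for k = 4", {
  # independent oracle: enumerate all 24 orderings with nested loops
  s_stat <- function(y) {
    s <- 0
    for (i in 1:(length(y) - 1)) for (j in (i + 1):length(y))
      s <- s + sign(y[j] - y[i])
    s
  }
  perms <- as.matrix(expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4))
  perms <- perms[apply(perms, 1L, function(p) length(unique(p)) == 4L), ]
  s_all <- apply(perms, 1L, s_stat)
  for (row in seq_len(nrow(perms))) {
    expected <- mean(abs(s_all) >= abs(s_all[row]))
    expect_identical(mann_kendall_p(as.numeric(perms[row, ])), expected)
  }
  # spot values from the enumeration
  expect_equal(mann_kendall_p(c(1, 2, 3, 4)), 2 / 24)
  expect_equal(mann_kendall_p(c(4, 3, 2, 1)), 2 / 24)
})

test_that("Mann-Kendall handles ties and large k via the corrected normal approximation", {
  expect_equal(mann_kendall_p(c(1, 1, 1, 1)), 1)
  expect_error(mann_kendall_p(c(1, 2)), "k >= 3")
  # tie-free large-k branch agrees with cor.test's Kendall approximation in
  # being small for a strong trend and large for noise
  set.seed(3)
  trend <- seq_len(20) + rnorm(20, 0, 0.1)
  expect_lt(mann_kendall_p(trend), 1e-4)
  noise <- rnorm(20)
  expect_gt(mann_kendall_p(noise), 0.05)
})

test_that("(1-P) weighting shrinks insignificant bins and preserves signs", {
  y <- rbind(c(1, 2, 3, 4),      # perfect trend, P small
             c(5, 5, 5, 5),      # no trend, P = 1 -> weighted to 0
             c(1, 3, 2, 4))
  s <- make_series(y)
  m <- fit_macc(s)
  w <- significance_weight(m, "pearson")
  vm <- track_values(m); vw <- track_values(w)
  expect_equal(vw, vm * (1 - unlist(m$pvalues, use.names = FALSE)))
  expect_equal(vw[2L], 0)
  expect_true(all(sign(vw) == sign(vm) | vw == 0))
  expect_error(significance_weight(w, "pearson"), "already")

  # Mann-Kendall route reproduces per-bin mann_kendall_p()
  wmk <- significance_weight(m, "mann_kendall", series = s)
  pmk <- apply(y, 1L, mann_kendall_p)
  expect_equal(unlist(wmk$pvalues, use.names = FALSE), unname(pmk))
  expect_error(significance_weight(m, "mann_kendall"), "series")
})

test_that("per-bin GC fraction counts G/C among non-N bases", {
  seqs <- Biostrings::DNAStringSet(c(
    chrA = paste0(strrep("ATGC", 75),      # bin 1: 0.5
                  strrep("GGGCCC", 50),    # bin 2: 1.0
                  strrep("N", 300),        # bin 3: all N -> missing
                  strrep("ATNN", 75))))    # bin 4: 0 among non-N
  gc <- gc_content(seqs, c(chrA = 1200L), bin_size = 300L)
  expect_equal(gc$values$chrA, c(0.5, 1, NA, 0))

  expect_error(gc_content(seqs, c(chrB = 300L), bin_size = 300L), "chrB")

  # CpG flags mark overlapping bins
  gc2 <- gc_content(seqs, c(chrA = 1200L), bin_size = 300L,
                    cpg_islands = data.frame(chrom = "chrA", start = 310L,
                                             end = 320L))
  expect_equal(unlist(gc2$cpg, use.names = FALSE),
               c(FALSE, TRUE, FALSE, FALSE))
})

test_that("GC correction removes an injected trend and respects strata", {
  set.seed(31)
  n <- 4000
  gc_vals <- runif(n, 0.25, 0.75)
  signal <- rnorm(n, 0, 0.2)
  m <- make_macc(signal + 2 * (gc_vals - 0.5))
  gct <- make_track(gc_vals)
  corrected <- gc_correct(m, gct, seed = 5)
  expect_true(corrected$gc_corrected)
  expect_lt(abs(cor(track_values(corrected), gc_vals)), 0.05)
  # stratum mean is preserved
  # the added-back stratum mean keeps the global level (up to the small
  # difference between the mean of the fitted trend and the raw mean)
  expect_equal(mean(track_values(corrected)), mean(track_values(m)),
               tolerance = 0.01)

  # no bias -> correction is a near no-op
  m0 <- make_macc(signal)
  c0 <- gc_correct(m0, gct, seed = 5)
  expect_lt(max(abs(track_values(c0) - track_values(m0))), 0.1)

  # bias only inside "CpG" bins leaves the other stratum untouched
  cpg <- rep(c(TRUE, FALSE), length.out = n)
  biased <- signal + ifelse(cpg, 3 * (gc_vals - 0.5), 0)
  mb <- make_macc(biased)
  gcs <- gct
  gcs$cpg <- utils::relist(cpg, gcs$values)
  class(gcs) <- c("gc_track", class(gcs))
  cb <- gc_correct(mb, gcs, stratify_cpg = TRUE, seed = 5)
  expect_lt(max(abs(track_values(cb)[!cpg] - biased[!cpg])), 0.05)
  expect_lt(abs(cor(track_values(cb)[cpg], gc_vals[cpg])), 0.05)

  # tiny stratum is left uncorrected with a warning
  expect_warning(gc_correct(make_macc(signal[1:50]),
                            make_track(gc_vals[1:50])), "uncorrected")
})

test_that("median shifting zeroes the genome-wide median and preserves differences", {
  m <- make_macc(c(1, 2, 3), median_shifted = FALSE)
  s <- median_shift(m)
  expect_equal(track_values(s), c(-1, 0, 1))
  expect_equal(track_values(median_shift(s)), track_values(s))
  set.seed(41)
  m2 <- make_macc(rnorm(101), median_shifted = FALSE)
  s2 <- median_shift(m2)
  expect_equal(median(track_values(s2)), 0)
  expect_equal(diff(track_values(s2)), diff(track_values(m2)))
})

test_that("H3 enrichment is the pseudocounted ChIP/input ratio", {
  chip <- make_track(c(2, 4, 0))
  input <- make_track(c(2, 2, 0))
  e <- h3_enrichment(chip, input, pseudocount = 0)
  expect_equal(track_values(e)[1:2], c(1, 2))
  e2 <- h3_enrichment(chip, input, pseudocount = 0.5)
  expect_equal(track_values(e2)[3L], 1)
  e3 <- h3_enrichment(chip, input, pseudocount = 0, log2_scale = TRUE)
  expect_equal(track_values(e3)[1:2], c(0, 1))
  expect_error(h3_enrichment(chip, make_track(1:4)), "grid")
})

test_that("occupancy/MACC quadrant labels match a brute-force thresholding oracle", {
  # perfect concordance: no high-occupancy bin has low MACC
  n <- 100
  occ <- make_track(as.numeric(1:n))
  conc <- classify_occupancy_accessibility(occ, make_macc(as.numeric(1:n)))
  expect_equal(unname(conc$counts["high_occ_low_macc"]), 0L)
  # perfect anti-concordance: no high-occupancy bin has high MACC
  anti <- classify_occupancy_accessibility(occ, make_macc(as.numeric(n:1)))
  expect_equal(unname(anti$counts["high_occ_high_macc"]), 0L)

  set.seed(51)
  n <- 10000
  ov <- rnorm(n); mv <- rnorm(n)
  res <- classify_occupancy_accessibility(make_track(ov), make_macc(mv))
  thr_occ <- quantile(ov, 0.80, type = 7, names = FALSE)
  thr_lo <- quantile(mv, 0.05, type = 7, names = FALSE)
  thr_hi <- quantile(mv, 0.95, type = 7, names = FALSE)
  oracle <- rep("other", n)
  for (i in seq_len(n)) {
    if (ov[i] > thr_occ && mv[i] > thr_hi) oracle[i] <- "high_occ_high_macc"
    if (ov[i] > thr_occ && mv[i] < thr_lo) oracle[i] <- "high_occ_low_macc"
  }
  expect_identical(res$labels, oracle)
})
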