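brute_peaks <- function(v) {
  idx <- integer(0)
  for (i in seq_along(v)) {
    if (i == 1L || i == length(v)) next
    if (anyNA(v[(i - 1L):(i + 1L)])) next
    if (v[i - 1L] < v[i] && v[i] > v[i + 1L]) idx <- c(idx, i)
  }
  idx
}

test_that("local-maximum peak calling uses strict inequalities on both sides", {
  p <- call_local_peaks(make_macc(c(0, 2, 1, 3, 3, 1)))
  expect_equal(p$bin, 1L)  # the 3,3 plateau yields nothing
  expect_equal(nrow(call_local_peaks(make_macc(1:10))), 0L)
  # bins flanked by missing values are ineligible
  p2 <- call_local_peaks(make_macc(c(0, 5, NA, 1, 7, 2)))
  expect_equal(p2$bin, 4L)

  set.seed(81)
  for (rep in 1:100) {
    v <- rnorm(100)
    v[sample(100, 5)] <- NA
    m <- make_macc(v, n_chrom = 2L)
    got <- call_local_peaks(m)
    oracle <- do.call(rbind, lapply(names(m$values), function(ch) {
      idx <- brute_peaks(m$values[[ch]])
      if (length(idx)) data.frame(chrom = ch, bin = idx - 1L) else NULL
    }))
    if (is.null(oracle)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got[, c("chrom", "bin")],
                   oracle, ignore_attr = TRUE)
    }
  }
})

test_that("group thresholds follow the positive-score quantile convention", {
  # positive c-MACC scores 1..10: inclusive linear interpolation puts the
  # 80th percentile at 8.2, and membership needs c > 8.2 strictly
  cv <- c(-(1:5), 1:10)
  hv <- c(-(1:5), rep(100, 10))
  g <- assign_groups(make_macc(cv), make_macc(hv))
  expect_equal(unname(g$thresholds[["c_macc"]]), 8.2)
  # h-MACC far above its 10th percentile everywhere -> group1 empty
  expect_false(any(g$labels == "group1", na.rm = TRUE))
  expect_error(assign_groups(make_macc(-(1:10)), make_macc(1:10)),
               "positive c-MACC")
})

test_that("group assignment matches a brute-force quantile-and-compare oracle", {
  set.seed(82)
  for (rep in 1:20) {
    cv <- rnorm(500); hv <- rnorm(500)
    g <- assign_groups(make_macc(cv), make_macc(hv))
    pos_c <- cv[cv > 0]; pos_h <- hv[hv > 0]
    tc <- quantile(pos_c, 0.8, type = 7, names = FALSE)
    tl <- quantile(pos_h, 0.1, type = 7, names = FALSE)
    th <- quantile(pos_h, 0.9, type = 7, names = FALSE)
    oracle <- rep("none", 500)
    oracle[cv > tc & hv < tl] <- "group1"
    oracle[cv > tc & hv > th] <- "group2"
    expect_identical(g$labels, oracle)
    expect_false(any(oracle == "group1" & oracle == "group2"))
  }
})

test_that("bins absent from the histone pool count as h-MACC zero by default", {
  cv <- c(0.5, 6, -1, 5, 2)
  hv <- c(0.5, NA, -1, 4, 2)
  g <- assign_groups(make_macc(cv), make_macc(hv))
  # bin 2: strong c-MACC, no histone fragments at all -> group1
  expect_equal(g$labels[2L], "group1")
  g2 <- assign_groups(make_macc(cv), make_macc(hv), missing_h = "drop")
  expect_true(is.na(g2$labels[2L]))
})

test_that("ChIP Z-score site calling flags outliers and nests across thresholds", {
  expect_warning(s0 <- chip_zscore_sites(make_track(rep(2, 50)), 3),
                 "zero variance")
  expect_false(any(s0))

  set.seed(83)
  v <- rnorm(1000)
  v[123] <- mean(v) + 10 * sd(v)
  tr <- make_track(v)
  s3 <- chip_zscore_sites(tr, 3)
  # hand-computed oracle
  expect_identical(which(s3), which((v - mean(v)) / sd(v) > 3))
  expect_true(s3[123])
  s2 <- chip_zscore_sites(tr, 2); s5 <- chip_zscore_sites(tr, 5)
  expect_true(all(which(s5) %in% which(s2)))
})

test_that("representative-profile selection minimizes site-count variability", {
  set.seed(84)
  # profile A: 20 strong outliers give identical counts at every threshold
  # (CV 0); profile B: plain noise, whose counts collapse as Z grows
  a <- make_track(c(rnorm(2000), rep(50, 20)))
  b <- make_track(c(rnorm(2000), rnorm(20)))
  sel <- select_representative_profile(list(b, a))
  expect_equal(sel$index, 2L)
  # brute-force CV oracle
  cv_oracle <- vapply(list(b, a), function(p) {
    counts <- vapply(2:5, function(z) sum(chip_zscore_sites(p, z)),
                     numeric(1L))
    sd(counts) / mean(counts)
  }, numeric(1L))
  expect_equal(sel$cv, cv_oracle)
  one <- select_representative_profile(list(a))
  expect_identical(one$track, a)
})

test_that("randomized peak-site overlap brackets the analytic expectation", {
  set.seed(85)
  v <- rnorm(1000)
  m <- make_macc(v, n_chrom = 2L)
  peaks <- call_local_peaks(m)
  sites_all <- rep(TRUE, 1000)
  r <- overlap_with_sites(peaks, sites_all, m, seed = 1L)
  expect_equal(r$observed, 1)
  expect_equal(r$expected, 1)

  sites <- rep(FALSE, 1000)
  sites[sample(1000, 250)] <- TRUE
  r2 <- overlap_with_sites(peaks, sites, m, n_rand = 200L, seed = 2L)
  expect_equal(r2$expected, 0.25, tolerance = 0.05)
  # peaks entirely inside sites: site set = exactly the peak bins
  sites3 <- rep(FALSE, 1000)
  offs <- cumsum(c(0, lengths(m$values)))
  sites3[offs[match(peaks$chrom, names(m$values))] + peaks$bin + 1L] <- TRUE
  r3 <- overlap_with_sites(peaks, sites3, m, seed = 3L)
  expect_equal(r3$observed, 1)
  expect_lt(r3$expected, 1)
  # empty sites short-circuit
  r4 <- overlap_with_sites(peaks, rep(FALSE, 1000), m)
  expect_equal(c(r4$observed, r4$expected), c(0, 0))
})

test_that("annotation classes follow strand-aware windows and the priority rule", {
  genome <- c(chrA = 30000L)
  genes <- data.frame(chrom = "chrA", start = 10000L, end = 16000L,
                      strand = "+", id = "g1")
  ann <- build_annotation(genes, genome = genome, bin_size = 1000L,
                          window = 1000L)
  cls <- ann$classes$chrA
  expect_equal(cls[10], "promoter")      # [9000,10000)
  expect_equal(cls[11], "five_prime")    # [10000,11000)
  expect_equal(cls[16], "tes_prox")      # around TES at 15999
  expect_equal(cls[13], "gene_body")
  expect_equal(cls[1], "unannotated")

  # minus-strand mirror: TSS at the gene end
  genes_m <- data.frame(chrom = "chrA", start = 10000L, end = 16000L,
                        strand = "-", id = "g1")
  ann_m <- build_annotation(genes_m, genome = genome, bin_size = 1000L,
                            window = 1000L)
  expect_equal(ann_m$classes$chrA[17], "promoter")   # [16000,17000)
  expect_equal(ann_m$classes$chrA[16], "five_prime")

  # enhancer beats promoter
  ann_e <- build_annotation(genes, enhancers = data.frame(
    chrom = "chrA", start = 9100L, end = 9200L),
    genome = genome, bin_size = 1000L, window = 1000L)
  expect_equal(ann_e$classes$chrA[10], "enhancer")

  # TSS-proximal windows overlapping another gene are dropped from the class
  genes2 <- rbind(genes,
                  data.frame(chrom = "chrA", start = 8000L, end = 9500L,
                             strand = "+", id = "g2"))
  ann2 <- build_annotation(genes2, genome = genome, bin_size = 1000L,
                           window = 1000L)
  expect_false(ann2$classes$chrA[10] == "promoter")

  expect_error(build_annotation(
    data.frame(chrom = "chrA", start = 1L, end = 10L, strand = "."),
    genome = genome), "strand")
})

test_that("region enrichment is the query-vs-genome fraction ratio", {
  genome <- c(chrA = 10000L)
  genes <- data.frame(chrom = "chrA", start = 4000L, end = 5000L,
                      strand = "+", id = "g")
  ann <- build_annotation(genes, genome = genome, bin_size = 100L,
                          window = 100L)
  classes <- ann$classes$chrA
  # query = all bins -> every defined ratio is exactly 1
  r_all <- region_enrichment(rep(TRUE, 100), ann)
  expect_true(all(r_all$enrichment[r_all$genome_fraction > 0] == 1))
  # class covering 10% of the genome with 50% of the query inside -> 5.0
  body_bins <- which(classes == "gene_body")
  stopifnot(length(body_bins) >= 1L)
  query <- rep(FALSE, 100)
  query[c(body_bins[1L], which(classes == "unannotated")[1L])] <- TRUE
  r <- region_enrichment(query, ann)
  gb <- r[r$class == "gene_body", ]
  expect_equal(gb$enrichment, 0.5 / gb$genome_fraction)
})
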