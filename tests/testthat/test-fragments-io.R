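test_that("fragment length filter keeps only the 50-500 bp window, bounds inclusive", {
  bedpe <- tempfile(fileext = ".bedpe")
  # fragments of length 40, 150 and 600 bp
  writeLines(c("chrA\t100\t136\tchrA\t104\t140\tf1\t0\t+\t-",
               "chrA\t500\t536\tchrA\t614\t650\tf2\t0\t+\t-",
               "chrA\t1000\t1036\tchrA\t1564\t1600\tf3\t0\t+\t-"), bedpe)
  expect_warning(fs <- read_fragments(bedpe, 50, 500), "uniqueness")
  expect_equal(fs$library_size, 1L)
  expect_equal(fs$fragments$end - fs$fragments$start, 150L)

  # boundary: min_len = max_len = 150, all fragments exactly 150 bp
  bed <- tempfile(fileext = ".bed")
  writeLines(sprintf("chrA\t%d\t%d", c(0L, 300L, 900L), c(150L, 450L, 1050L)),
             bed)
  expect_warning(fs2 <- read_fragments(bed, 150, 150), "uniqueness")
  expect_equal(fs2$library_size, 3L)

  # nothing retained -> error
  expect_error(suppressWarnings(read_fragments(bedpe, 10, 20)),
               "no fragments retained")
})

test_that("BAM input forms fragments from proper pairs and needs an index", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chrA\tLN:10000",
    # proper pair, fragment [99, 249), MAPQ 60
    "r1\t99\tchrA\t100\t60\t36M\t=\t214\t150\t*\t*",
    "r1\t147\tchrA\t214\t60\t36M\t=\t100\t-150\t*\t*",
    # proper pair but MAPQ 0 (multi-mapper): dropped by uniqueness filter
    "r2\t99\tchrA\t300\t0\t36M\t=\t414\t150\t*\t*",
    "r2\t147\tchrA\t414\t0\t36M\t=\t300\t-150\t*\t*",
    # not properly paired: dropped
    "r3\t97\tchrA\t600\t60\t36M\t=\t714\t150\t*\t*",
    "r3\t145\tchrA\t714\t60\t36M\t=\t600\t-150\t*\t*"), sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = TRUE)
  fs <- read_fragments(bam, 50, 500)
  expect_equal(fs$library_size, 1L)
  expect_equal(fs$fragments$start, 99L)
  expect_equal(fs$fragments$end, 249L)

  noidx <- file.path(tempdir(), "noindex.bam")
  file.copy(bam, noidx, overwrite = TRUE)
  expect_error(read_fragments(noidx), "index")
})

test_that("anomalous-position filter flags outlier tag positions and removes their fragments", {
  # 499 fragments at distinct positions (each endpoint 1 tag), plus 300
  # duplicate fragments piling 300 tags on two positions
  base <- data.frame(chrom = "chrA",
                     start = seq(0L, by = 400L, length.out = 499L))
  base$end <- base$start + 150L
  hot <- data.frame(chrom = "chrA", start = rep(250000L, 300L),
                    end = rep(250150L, 300L))
  fs <- fragment_set(rbind(base, hot), concentration = 1.5)
  # independent oracle: per-position counts computed directly
  pos <- c(fs$fragments$start, fs$fragments$end - 1L)
  cnt <- table(pos)
  z <- (as.numeric(cnt) - mean(cnt)) / sd(cnt)
  expect_equal(sum(z > 7), 2L)  # the two hot endpoints
  suppressMessages(out <- filter_anomalous_positions(fs, 7))
  expect_equal(out$library_size, 499L)
  expect_false(any(out$fragments$start == 250000L))

  # all positions with equal counts -> zero variance -> nothing flagged
  suppressMessages(unif <- filter_anomalous_positions(
    fragment_set(base, concentration = 1.5), 7))
  expect_equal(unif$library_size, 499L)

  # infinite threshold -> identity
  suppressMessages(ident <- filter_anomalous_positions(fs, Inf))
  expect_equal(ident$fragments, fs$fragments)

  expect_error(filter_anomalous_positions(fs, 0), "z_threshold")
})

test_that("lowering the anomalous-position threshold never retains more fragments", {
  set.seed(11)
  fs <- make_fragments(2000)
  kept <- vapply(c(10, 5, 3, 2, 1), function(z)
    suppressMessages(filter_anomalous_positions(fs, z))$library_size,
    numeric(1L))
  expect_true(all(diff(kept) <= 0))
})

test_that("midpoint binning follows floor((start+end)/2) and conserves counts", {
  genome <- c(chrA = 1200L)
  fs <- fragment_set(data.frame(chrom = "chrA",
                                start = c(100L, 250L),
                                end = c(250L, 400L)),
                     concentration = 1.5)
  t <- bin_counts(fs, genome, 300L)
  # midpoints 175 -> bin 0 and 325 -> bin 1
  expect_equal(t$values$chrA, c(1, 1, 0, 0))

  set.seed(7)
  fs2 <- make_fragments(1000)
  genome2 <- c(chrA = 30000L, chrB = 15000L)
  t2 <- bin_counts(fs2, genome2, 300L)
  expect_equal(sum(track_values(t2)), fs2$library_size)
  # brute-force per-fragment loop oracle
  oracle <- list(chrA = numeric(100), chrB = numeric(50))
  for (i in seq_len(fs2$library_size)) {
    b <- ((fs2$fragments$start[i] + fs2$fragments$end[i]) %/% 2L) %/% 300L
    ch <- fs2$fragments$chrom[i]
    oracle[[ch]][b + 1L] <- oracle[[ch]][b + 1L] + 1
  }
  expect_identical(lapply(t2$values, as.numeric), oracle)

  bad <- fragment_set(data.frame(chrom = "chrZ", start = 0L, end = 100L),
                      concentration = 1)
  expect_error(bin_counts(bad, genome2, 300L), "chrZ")
})

test_that("normalization applies per-million and genome/100Mb scaling and is scale-invariant", {
  t <- make_track(c(100, 0, 50), normalized = FALSE)
  n1 <- normalize_track(t, library_size = 2e6, genome_size = 1e8)
  expect_equal(n1$values[[1L]][1L], 50)
  n2 <- normalize_track(t, library_size = 2e6, genome_size = 2e7)
  expect_equal(n2$values[[1L]][1L], 10)
  expect_error(normalize_track(n1, 1e6, 1e8), "already normalized")
  expect_error(normalize_track(t, 0, 1e8), "library_size")

  # doubling every count and the library size leaves the track unchanged
  t2 <- make_track(c(200, 0, 100), normalized = FALSE)
  nd <- normalize_track(t2, library_size = 4e6, genome_size = 1e8)
  expect_equal(track_values(nd), track_values(n1), tolerance = 1e-12)
})

test_that("pooled occupancy is the per-bin mean over titration points", {
  s <- make_series(cbind(c(1, 0), c(2, 10), c(3, 0), c(4, 10)))
  p <- pool_occupancy(s)
  expect_equal(track_values(p), c(2.5, 5))
  # identical tracks -> pooled equals any input
  s2 <- make_series(cbind(c(3, 7), c(3, 7), c(3, 7), c(3, 7)))
  expect_equal(track_values(pool_occupancy(s2)), c(3, 7))
  # mismatched grids refuse to combine
  expect_error(titration_series(list(make_track(1:4), make_track(1:5)),
                                c(1.5, 6.25)),
               "grid|normalized")
})

test_that("fragment-length histogram restricts by site midpoint and reports moments", {
  fr <- data.frame(chrom = "chrA",
                   start = c(0L, 1000L, 2000L),
                   end = c(150L, 1150L, 2110L))
  fs <- fragment_set(fr, concentration = 1.5)
  h <- fragment_length_distribution(fs)
  expect_equal(unname(h$counts[c("150", "110")]), c(2L, 1L))
  expect_equal(h$mean, mean(c(150, 150, 110)))

  # whole-genome sites are a no-op restriction
  all_sites <- data.frame(chrom = "chrA", start = 0L, end = 10000L)
  h2 <- fragment_length_distribution(fs, sites = all_sites)
  expect_equal(h2$counts, h$counts)

  # site covering only the 110-bp fragment
  h3 <- fragment_length_distribution(
    fs, sites = data.frame(chrom = "chrA", start = 2000L, end = 2200L))
  expect_equal(h3$mean, 110)

  expect_warning(
    h4 <- fragment_length_distribution(
      fs, sites = data.frame(chrom = "chrA", start = 9000L, end = 9100L)),
    "no fragments")
  expect_equal(sum(h4$counts), 0L)
})

test_that("replicate pooling concatenates fragments and checks metadata", {
  a <- make_fragments(100)
  b <- make_fragments(50)
  p <- pool_replicates(a, b)
  expect_equal(p$library_size, 150L)
  bad <- make_fragments(10, concentration = 25)
  expect_error(pool_replicates(a, bad), "share")
})
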