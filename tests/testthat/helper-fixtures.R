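# Small in-code fixtures shared across the suite.

# a normalized binned_track from a plain vector (one or more chromosomes)
make_track <- function(values, bin_size = 300L, n_chrom = 1L,
                       normalized = TRUE) {
  if (!is.list(values)) {
    per <- diff(round(seq(0, length(values), length.out = n_chrom + 1L)))
    values <- split(values, rep(seq_len(n_chrom), per))
    names(values) <- paste0("chrT", seq_len(n_chrom))
  }
  binned_track(values, bin_size = bin_size,
               chrom_sizes = stats::setNames(lengths(values) * bin_size,
                                             names(values)),
               normalized = normalized)
}

# a titration_series straight from a bins x k response matrix
make_series <- function(y, concentrations = c(1.5, 6.25, 25, 100),
                        bin_size = 300L, n_chrom = 1L) {
  y <- as.matrix(y)
  tracks <- lapply(seq_len(ncol(y)), function(j)
    make_track(y[, j], bin_size = bin_size, n_chrom = n_chrom))
  titration_series(tracks, concentrations)
}

# a macc_track with given values (already "fitted"), for downstream ops
make_macc <- function(values, bin_size = 300L, n_chrom = 1L,
                      median_shifted = TRUE) {
  t <- make_track(values, bin_size = bin_size, n_chrom = n_chrom)
  t$units <- "macc_slope"
  t$pvalues <- utils::relist(rep(0, length(unlist(t$values))), t$values)
  t$provenance <- "c-MACC"
  t$gc_corrected <- FALSE
  t$median_shifted <- median_shifted
  t$significance_weighted <- FALSE
  class(t) <- c("macc_track", class(t))
  t
}

# random fragments on a toy genome
make_fragments <- function(n, chrom_sizes = c(chrA = 30000L, chrB = 15000L),
                           len_mean = 150, len_sd = 20, concentration = 1.5) {
  chrom <- sample(names(chrom_sizes), n, replace = TRUE)
  len <- pmax(50L, pmin(500L, round(stats::rnorm(n, len_mean, len_sd))))
  start <- floor(stats::runif(n, 0, chrom_sizes[chrom] - len))
  fragment_set(data.frame(chrom = chrom, start = start, end = start + len),
               concentration = concentration)
}

# closed-form OLS slope, used as the independent oracle for fit_macc
ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# memoized medium-scale simulation shared by the acceptance checks
shared_sim_env <- new.env(parent = emptyenv())
shared_sim <- function() {
  if (is.null(shared_sim_env$sim)) {
    truth <- simulate_genome(10000L, seed = 101L)
    shared_sim_env$truth <- truth
    shared_sim_env$sim <- simulate_titration(truth, depth = 50, seed = 102L)
  }
  list(truth = shared_sim_env$truth, sim = shared_sim_env$sim)
}
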