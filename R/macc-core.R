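#' Fit MACC scores: per-bin regression slope across the MNase titration
#'
#' For every bin the ordinary least-squares slope of the normalized fragment
#' frequency against `x_j = -log(c_j)` is computed over the k titration
#' points, so that loci whose signal rises as MNase decreases (accessible
#' chromatin, scenario 1) obtain positive MACC and loci whose signal rises
#' with digestion depth (inaccessible, scenario 2) obtain negative MACC. The
#' log scale preserves similar spacing between consecutive points of an
#' exponential titration. Bins with no mapped reads at any titration point
#' are marked missing. Per-bin two-sided P values of the Pearson correlation
#' (t distribution on k - 2 df) are stored; zero-variance responses get
#' slope 0 with P = 1 by convention.
#'
#' @param series A [titration_series()].
#' @param log_base Base of the concentration logarithm (default `exp(1)`;
#'   changing the base rescales every slope by a constant and nothing else).
#' @param provenance `"c-MACC"` (whole chromatin) or `"h-MACC"`
#'   (histone-ChIP).
#' @param missing_rule `"all_zero"` marks a bin missing only when it has zero
#'   reads at every point; `"any_zero"` is the stricter variant.
#' @return A `macc_track` (subclass of `binned_track`) with per-bin `values`
#'   (slopes) and `pvalues`.
#' @export
fit_macc <- function(series, log_base = exp(1),
                     provenance = c("c-MACC", "h-MACC"),
                     missing_rule = c("all_zero", "any_zero")) {
  stopifnot(inherits(series, "titration_series"))
  provenance <- match.arg(provenance)
  missing_rule <- match.arg(missing_rule)
  conc <- series$concentrations
  if (length(unique(conc)) < 2L)
    stop("at least two distinct concentrations required")
  x <- -log(conc, base = log_base)
  y <- series_matrix(series)
  miss <- if (missing_rule == "all_zero") {
    rowSums(y != 0, na.rm = TRUE) == 0L | rowSums(is.na(y)) == ncol(y)
  } else {
    rowSums(y == 0 | is.na(y)) > 0L
  }
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope <- as.vector(y %*% xc) / sxx
  # Pearson r and its two-sided t-test P value, vectorized over bins
  k <- length(x)
  ybar <- rowMeans(y)
  syy <- rowSums((y - ybar)^2)
  r <- ifelse(syy > 0, slope * sqrt(sxx) / sqrt(syy), 0)
  r <- pmin(1, pmax(-1, r))
  pval <- rep(1, length(r))
  ok <- syy > 0 & abs(r) < 1
  tstat <- r[ok] * sqrt((k - 2) / (1 - r[ok]^2))
  pval[ok] <- 2 * stats::pt(-abs(tstat), df = k - 2)
  pval[syy > 0 & abs(r) >= 1] <- 0
  slope[syy == 0] <- 0
  slope[miss] <- NA_real_
  pval[miss] <- NA_real_
  out <- track_replace(series$tracks[[1L]], slope)
  out$units <- "macc_slope"
  out$pvalues <- utils::relist(pval, out$values)
  out$provenance <- provenance
  out$gc_corrected <- FALSE
  out$median_shifted <- FALSE
  out$significance_weighted <- FALSE
  class(out) <- c("macc_track", class(out))
  out
}

#' @export
print.macc_track <- function(x, ...) {
  NextMethod()
  cat(sprintf("  %s%s%s%s\n", x$provenance,
              if (x$gc_corrected) ", GC-corrected" else "",
              if (x$median_shifted) ", median-shifted" else "",
              if (x$significance_weighted) ", (1-P)-weighted" else ""))
  invisible(x)
}

#' Two-sided Mann-Kendall trend test P value
#'
#' Computes the Kendall S statistic of the responses against their
#' observation order. For k <= 10 with no ties the exact two-sided P value is
#' taken from the permutation distribution of S; otherwise the normal
#' approximation with continuity correction and the standard tie-corrected
#' variance is used.
#'
#' @param values Ordered numeric responses (k >= 3, no missing values).
#' @return Two-sided P value in (0, 1].
#' @export
mann_kendall_p <- function(values) {
  k <- length(values)
  if (k < 3L) stop("Mann-Kendall trend test needs k >= 3 observations")
  if (anyNA(values)) stop("missing values not allowed")
  s <- kendall_s(values)
  has_ties <- anyDuplicated(values) > 0L
  if (!has_ties && k <= 10L) {
    # exact permutation distribution of S (equivalently of Kendall's tau
    # against 1..k); enumerate all k! orderings of the ranks
    perms <- all_permutations(k)
    svals <- apply(perms, 1L, function(p) kendall_s(p))
    return(mean(abs(svals) >= abs(s)))
  }
  tie_tab <- table(values)
  t <- as.numeric(tie_tab[tie_tab > 1L])
  vs <- (k * (k - 1) * (2 * k + 5) - sum(t * (t - 1) * (2 * t + 5))) / 18
  if (vs <= 0) return(1)
  z <- (s - sign(s)) / sqrt(vs)   # continuity correction
  min(1, 2 * stats::pnorm(-abs(z)))
}

kendall_s <- function(y) {
  # S = sum over i < j of sign(y_j - y_i); lower triangle of outer(y, y, "-")
  # holds exactly the later-minus-earlier differences
  d <- outer(y, y, "-")
  sum(sign(d[lower.tri(d)]))
}

all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(k - 1L)
  out <- matrix(0L, nrow = k * nrow(sub), ncol = k)
  for (i in seq_len(k)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(k)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), k - 1L)
  }
  out
}

#' Down-weight MACC scores by fit significance
#'
#' Adjusts every score by the factor `(1 - P)` so that bins whose titration
#' response carries little evidence of a trend are shrunk toward zero.
#' With `method = "pearson"` the P values stored by [fit_macc()] are used;
#' with `"mann_kendall"` P values are recomputed per bin from the titration
#' responses via [mann_kendall_p()], which requires `series`.
#'
#' @param m A `macc_track`.
#' @param method `"pearson"` or `"mann_kendall"`.
#' @param series The originating [titration_series()] (required for
#'   `"mann_kendall"`).
#' @return The weighted `macc_track`.
#' @export
significance_weight <- function(m, method = c("pearson", "mann_kendall"),
                                series = NULL) {
  stopifnot(inherits(m, "macc_track"))
  method <- match.arg(method)
  if (isTRUE(m$significance_weighted))
    stop("track is already significance-weighted")
  v <- track_values(m)
  if (method == "pearson") {
    p <- unlist(m$pvalues, use.names = FALSE)
  } else {
    if (is.null(series))
      stop("series required to recompute Mann-Kendall P values")
    y <- series_matrix(series)
    p <- rep(NA_real_, length(v))
    def <- which(!is.na(v))
    # memoize on the S statistic / tie pattern: with k small most bins share
    # the handful of possible orderings
    key <- apply(y[def, , drop = FALSE], 1L, function(row)
      paste(rank(row, ties.method = "min"), collapse = ","))
    uniq <- !duplicated(key)
    pu <- vapply(def[uniq], function(i) mann_kendall_p(y[i, ]), numeric(1L))
    names(pu) <- key[uniq]
    p[def] <- pu[key]
  }
  m <- track_replace(m, v * (1 - p))
  m$pvalues <- utils::relist(p, m$values)
  m$significance_weighted <- TRUE
  m
}

#' Per-bin G+C fraction from a reference genome
#'
#' @param reference A [Biostrings::DNAStringSet] or path to a FASTA file
#'   covering every chromosome of the grid.
#' @param grid A `binned_track` defining the bin grid (values ignored), or a
#'   named vector of chromosome sizes together with `bin_size`.
#' @param bin_size Bin width, required when `grid` is a sizes vector.
#' @param cpg_islands Optional data.frame `(chrom, start, end)` or `GRanges`
#'   of CpG islands; overlapping bins are flagged for stratified correction.
#' @return A `gc_track`: a `binned_track` of G+C fractions in `[0, 1]`
#'   (all-N bins missing) with an optional logical `cpg` flag per bin.
#' @export
gc_content <- function(reference, grid, bin_size = NULL, cpg_islands = NULL) {
  seqs <- if (inherits(reference, "DNAStringSet")) reference
          else Biostrings::readDNAStringSet(reference)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (inherits(grid, "binned_track")) {
    sizes <- if (!is.null(grid$chrom_sizes)) grid$chrom_sizes else
      stats::setNames(lengths(grid$values) * grid$bin_size, names(grid$values))
    bin_size <- grid$bin_size
  } else {
    stopifnot(!is.null(bin_size))
    sizes <- as_chrom_sizes(grid)
  }
  missing_chrom <- setdiff(names(sizes), names(seqs))
  if (length(missing_chrom))
    stop("reference lacks chromosome(s): ",
         paste(missing_chrom, collapse = ", "))
  values <- lapply(names(sizes), function(chrom) {
    sq <- seqs[[chrom]]
    nb <- ceiling(sizes[[chrom]] / bin_size)
    starts <- (seq_len(nb) - 1L) * bin_size + 1L
    ends <- pmin(starts + bin_size - 1L, length(sq))
    v <- Biostrings::Views(sq, start = starts, end = ends)
    freq <- Biostrings::letterFrequency(v, c("GC", "AT"))
    denom <- freq[, "G|C"] + freq[, "A|T"]
    out <- ifelse(denom > 0, freq[, "G|C"] / denom, NA_real_)
    as.numeric(out)
  })
  names(values) <- names(sizes)
  gc <- binned_track(values, bin_size = bin_size, chrom_sizes = sizes,
                     normalized = FALSE, units = "gc_fraction")
  class(gc) <- c("gc_track", class(gc))
  if (!is.null(cpg_islands)) {
    gr <- if (inherits(cpg_islands, "GRanges")) cpg_islands else
      GenomicRanges::GRanges(cpg_islands$chrom,
                             IRanges::IRanges(start = cpg_islands$start + 1L,
                                              end = cpg_islands$end))
    bins <- track_granges(gc, keep_missing = TRUE)
    flag <- IRanges::overlapsAny(bins, gr)
    gc$cpg <- utils::relist(flag, gc$values)
  }
  gc
}

#' LOWESS GC-bias correction of MACC scores
#'
#' Removes the locally weighted scatterplot smoothing (LOWESS) trend of MACC
#' on per-bin G+C fraction, then adds the stratum's pre-correction mean back
#' so the global signal level is preserved. With `stratify_cpg = TRUE` the
#' correction is fit separately for bins inside and outside CpG islands, as
#' appropriate for mammalian genomes. The trend is fit on a random subsample
#' of bins (seed-controlled) and interpolated to all bins.
#'
#' @param m A `macc_track`.
#' @param gc A `gc_track` on the same grid (see [gc_content()]).
#' @param stratify_cpg Correct CpG-island and non-island bins separately
#'   (requires CpG flags on `gc`).
#' @param span LOWESS smoother span (fraction of points; default 0.3).
#' @param iterations Robustifying iterations (default 0). Robustness
#'   iterations downweight large residuals, but on MACC data the large
#'   residuals *are* the accessible/inaccessible signal bins, so robust
#'   fitting systematically underestimates the GC trend; the plain fit is
#'   the default.
#' @param subsample Maximum number of bins the trend is fit on (default
#'   10000); remaining bins get interpolated fitted values.
#' @param min_bins Minimum defined bins required per stratum (default 100);
#'   smaller strata are left uncorrected with a warning.
#' @param seed Integer seed for the subsampling.
#' @return The corrected `macc_track`.
#' @export
gc_correct <- function(m, gc, stratify_cpg = FALSE, span = 0.3,
                       iterations = 0L, subsample = 10000L,
                       min_bins = 100L, seed = 1L) {
  stopifnot(inherits(m, "macc_track"), inherits(gc, "binned_track"))
  stop_unless_same_grid(m, gc)
  v <- track_values(m)
  g <- track_values(gc)
  if (stratify_cpg) {
    if (is.null(gc$cpg))
      stop("stratify_cpg = TRUE requires CpG flags on the GC track ",
           "(supply cpg_islands to gc_content())")
    strata <- ifelse(unlist(gc$cpg, use.names = FALSE), "cpg", "noncpg")
  } else {
    strata <- rep("all", length(v))
  }
  out <- v
  for (s in unique(strata)) {
    idx <- which(strata == s & !is.na(v) & !is.na(g))
    if (length(idx) < min_bins) {
      warning(sprintf("stratum '%s' has %d defined bins (< %d); left uncorrected",
                      s, length(idx), min_bins))
      next
    }
    fit_idx <- idx
    if (length(idx) > subsample) {
      fit_idx <- local_seed(seed, sample(idx, subsample))
    }
    lw <- stats::lowess(g[fit_idx], v[fit_idx], f = span, iter = iterations)
    fitted <- stats::approx(lw$x, lw$y, xout = g[idx], rule = 2, ties = mean)$y
    out[idx] <- v[idx] - fitted + mean(v[idx])
  }
  m <- track_replace(m, out)
  m$gc_corrected <- TRUE
  m
}

local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Shift a MACC track so its genome-wide median is zero
#'
#' @param m A `macc_track`.
#' @return The shifted track; pairwise differences are preserved exactly.
#' @export
median_shift <- function(m) {
  stopifnot(inherits(m, "macc_track"))
  v <- track_values(m)
  if (all(is.na(v))) stop("no defined bins to median-shift")
  m <- track_replace(m, v - stats::median(v, na.rm = TRUE))
  m$median_shifted <- TRUE
  m
}

#' H3 enrichment: ChIP/input ratio of pooled fragment frequencies
#'
#' @param chip_pooled,input_pooled Pooled-occupancy tracks ([pool_occupancy()])
#'   of the H3-ChIP and ChIP-input titrations, on one grid.
#' @param pseudocount Added to numerator and denominator (default 0.5).
#' @param log2_scale Report log2 of the ratio?
#' @return A `binned_track` of (log2) enrichment ratios.
#' @export
h3_enrichment <- function(chip_pooled, input_pooled, pseudocount = 0.5,
                          log2_scale = FALSE) {
  stop_unless_same_grid(chip_pooled, input_pooled)
  ratio <- (track_values(chip_pooled) + pseudocount) /
    (track_values(input_pooled) + pseudocount)
  if (log2_scale) ratio <- log2(ratio)
  out <- track_replace(chip_pooled, ratio)
  out$units <- if (log2_scale) "log2_enrichment" else "enrichment"
  out
}

#' Classify bins by pooled occupancy and MACC (quadrant analysis)
#'
#' High-occupancy bins (top `1 - occ_top` fraction) are split by their MACC
#' score into high-occupancy/high-MACC (above the `macc_high` quantile) and
#' high-occupancy/low-MACC (below the `macc_low` quantile); everything else
#' is `"other"`. Thresholds use the inclusive linear-interpolation quantile
#' convention over defined, non-partial bins.
#'
#' @param occupancy Pooled-occupancy `binned_track`.
#' @param m A `macc_track` on the same grid.
#' @param occ_top Occupancy quantile defining "high occupancy" (default 0.80,
#'   i.e. top 20% of bins).
#' @param macc_low,macc_high MACC quantiles for the low/high tails (defaults
#'   0.05 and 0.95).
#' @return A list with `labels` (character vector per bin), `counts` and
#'   `thresholds`.
#' @export
classify_occupancy_accessibility <- function(occupancy, m, occ_top = 0.80,
                                             macc_low = 0.05,
                                             macc_high = 0.95) {
  stop_unless_same_grid(occupancy, m)
  stopifnot(occ_top > 0, occ_top < 1, macc_low > 0, macc_low < 1,
            macc_high > 0, macc_high < 1)
  occ <- track_values(occupancy)
  mv <- track_values(m)
  eligible <- !is.na(occ) & !is.na(mv) & !partial_bins(m)
  thr_occ <- stats::quantile(occ[eligible], occ_top, type = 7, names = FALSE)
  thr_lo <- stats::quantile(mv[eligible], macc_low, type = 7, names = FALSE)
  thr_hi <- stats::quantile(mv[eligible], macc_high, type = 7, names = FALSE)
  degenerate <- function(x, thr) mean(x[eligible] == thr) > 0.5
  if (degenerate(occ, thr_occ) || degenerate(mv, thr_lo) ||
      degenerate(mv, thr_hi))
    warning("degenerate value distribution: quantile ties span > 50% of bins")
  labels <- rep(NA_character_, length(occ))
  labels[eligible] <- "other"
  high_occ <- eligible & occ > thr_occ
  labels[high_occ & mv > thr_hi] <- "high_occ_high_macc"
  labels[high_occ & mv < thr_lo] <- "high_occ_low_macc"
  list(labels = labels,
       counts = table(factor(labels, levels = c("high_occ_high_macc",
                                                "high_occ_low_macc",
                                                "other"))),
       thresholds = c(occupancy = thr_occ, macc_low = thr_lo,
                      macc_high = thr_hi))
}
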