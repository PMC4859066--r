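#' Call strict local-maximum MACC peaks
#'
#' A peak is a bin whose c-MACC value strictly exceeds both adjacent bins
#' (`value[i-1] < value[i] > value[i+1]`). Bins at chromosome ends or
#' adjacent to missing bins are ineligible, and plateaus produce no peak.
#'
#' @param m A `macc_track`.
#' @return A `peak_set`: data.frame with `chrom`, `bin` (0-based index on the
#'   chromosome), `value`.
#' @export
call_local_peaks <- function(m) {
  stopifnot(inherits(m, "binned_track"))
  out <- lapply(names(m$values), function(chrom) {
    v <- m$values[[chrom]]
    n <- length(v)
    if (n < 3L) return(NULL)
    i <- 2:(n - 1L)
    ok <- !is.na(v[i - 1L]) & !is.na(v[i]) & !is.na(v[i + 1L]) &
      v[i - 1L] < v[i] & v[i] > v[i + 1L]
    idx <- i[ok]
    if (!length(idx)) return(NULL)
    data.frame(chrom = chrom, bin = idx - 1L, value = v[idx],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), bin = integer(),
                      value = numeric())
  rownames(out) <- NULL
  structure(out, class = c("peak_set", "data.frame"),
            bin_size = m$bin_size)
}

#' Assign bins to group 1 (non-histone protection) and group 2
#' (accessible nucleosomes)
#'
#' Thresholds come from the positive-score sub-distributions of the
#' median-shifted tracks (inclusive linear-interpolation quantiles) with
#' strict comparisons: group 1 = c-MACC higher than 80% of all positive
#' c-MACC scores and h-MACC lower than 10% of all positive h-MACC scores;
#' group 2 = the same c-MACC condition with h-MACC higher than 90% of all
#' positive h-MACC scores.
#'
#' Bins defined in c-MACC but missing in h-MACC carry no histone-protected
#' fragments at any titration point; by default (`missing_h = "zero"`) their
#' h-MACC is taken as 0 — the strongest form of the low-h signature —
#' `missing_h = "drop"` excludes them instead.
#'
#' @param c_track,h_track Median-shifted c-MACC and h-MACC tracks on one
#'   grid.
#' @param c_quantile Quantile of positive c-MACC scores (default 0.80).
#' @param h_low,h_high Quantiles of positive h-MACC scores (defaults 0.10 and
#'   0.90).
#' @param missing_h Treatment of bins missing in h-MACC only.
#' @return A `group_assignment`: list with `labels` (per-bin
#'   `"group1"`/`"group2"`/`"none"`, `NA` where ineligible) and `thresholds`.
#' @export
assign_groups <- function(c_track, h_track, c_quantile = 0.80,
                          h_low = 0.10, h_high = 0.90,
                          missing_h = c("zero", "drop")) {
  stop_unless_same_grid(c_track, h_track)
  missing_h <- match.arg(missing_h)
  if (!isTRUE(c_track$median_shifted) || !isTRUE(h_track$median_shifted))
    warning("group thresholds are defined on median-shifted tracks")
  cv <- track_values(c_track)
  hv <- track_values(h_track)
  if (missing_h == "zero") hv[is.na(hv) & !is.na(cv)] <- 0
  partial <- partial_bins(c_track)
  pos_c <- cv[!is.na(cv) & cv > 0 & !partial]
  pos_h <- hv[!is.na(hv) & hv > 0 & !partial]
  if (!length(pos_c)) stop("no positive c-MACC scores")
  if (!length(pos_h)) stop("no positive h-MACC scores")
  thr_c <- stats::quantile(pos_c, c_quantile, type = 7, names = FALSE)
  thr_h_low <- stats::quantile(pos_h, h_low, type = 7, names = FALSE)
  thr_h_high <- stats::quantile(pos_h, h_high, type = 7, names = FALSE)
  labels <- rep(NA_character_, length(cv))
  eligible <- !is.na(cv) & !is.na(hv)
  labels[eligible] <- "none"
  labels[eligible & cv > thr_c & hv < thr_h_low] <- "group1"
  labels[eligible & cv > thr_c & hv > thr_h_high] <- "group2"
  structure(list(labels = labels,
                 thresholds = c(c_macc = thr_c, h_macc_low = thr_h_low,
                                h_macc_high = thr_h_high),
                 chroms = track_chroms(c_track),
                 bin_size = c_track$bin_size),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c("group1", "group2", "none")))
  cat(sprintf(paste0("<group_assignment> group1 (NHP-like): %d bins; ",
                     "group2 (accessible nucleosome): %d bins\n"),
              tab[["group1"]], tab[["group2"]]))
  cat(sprintf("  thresholds: c-MACC > %.4g; h-MACC < %.4g | > %.4g\n",
              x$thresholds[["c_macc"]], x$thresholds[["h_macc_low"]],
              x$thresholds[["h_macc_high"]]))
  invisible(x)
}

#' Call protein (NHP) binding sites from a ChIP/input enrichment track
#'
#' Per-bin enrichment values are transformed into Z-scores over the defined
#' bins; bins with Z strictly above the threshold are returned as binding
#' sites.
#'
#' @param enrichment `binned_track` of ChIP/input enrichment.
#' @param z_threshold Z-score cutoff.
#' @return Logical vector (parallel to [track_values()]) marking site bins;
#'   empty (with a warning) when the enrichment has zero variance.
#' @export
chip_zscore_sites <- function(enrichment, z_threshold = 3) {
  v <- track_values(enrichment)
  def <- !is.na(v)
  mu <- mean(v[def])
  sdev <- stats::sd(v[def])
  sites <- rep(FALSE, length(v))
  if (is.na(sdev) || sdev == 0) {
    warning("enrichment has zero variance; no site bins called")
    return(sites)
  }
  sites[def] <- (v[def] - mu) / sdev > z_threshold
  sites
}

#' Select the representative enrichment profile for a protein
#'
#' When a protein is represented by several ChIP profiles, the one whose
#' site counts are least sensitive to the Z-score cutoff is kept: site
#' counts are computed at Z in `z_grid` and the profile with the smallest
#' coefficient of variation of those counts is selected (ties broken by
#' input order).
#'
#' @param profiles List of enrichment `binned_track`s for one protein.
#' @param z_grid Z-score thresholds scanned (default 2:5).
#' @return List with `track` (the selected profile), `index`, and the
#'   `cv` per profile.
#' @export
select_representative_profile <- function(profiles, z_grid = 2:5) {
  stopifnot(length(profiles) >= 1L)
  cv <- vapply(profiles, function(p) {
    counts <- vapply(z_grid, function(z)
      sum(suppressWarnings(chip_zscore_sites(p, z))), numeric(1L))
    if (mean(counts) == 0) return(Inf)
    stats::sd(counts) / mean(counts)
  }, numeric(1L))
  idx <- which.min(cv)   # which.min returns the first minimum: input order
  list(track = profiles[[idx]], index = idx, cv = cv)
}

#' Observed and expected overlap of MACC peaks with site bins
#'
#' The observed value is the fraction of peak bins that are site bins. The
#' expected value re-places the same number of peaks uniformly at random over
#' the eligible (defined, non-missing) bins and averages the resulting
#' overlap fraction over `n_rand` independent randomizations.
#'
#' @param peaks A `peak_set` ([call_local_peaks()]).
#' @param sites Logical site-bin vector on the same grid (e.g.
#'   [chip_zscore_sites()]).
#' @param m The `macc_track` defining eligibility (defined bins).
#' @param n_rand Number of randomizations (default 10).
#' @param seed Integer seed.
#' @return List with `observed`, `expected`, `n_peaks`.
#' @export
overlap_with_sites <- function(peaks, sites, m, n_rand = 10L, seed = 1L) {
  stopifnot(inherits(peaks, "peak_set"))
  v <- track_values(m)
  stopifnot(length(sites) == length(v))
  if (!any(sites)) return(list(observed = 0, expected = 0,
                               n_peaks = nrow(peaks)))
  # flat index of each peak bin on the concatenated grid
  offsets <- cumsum(c(0L, lengths(m$values)))
  names(offsets) <- c(names(m$values), "")
  flat <- offsets[peaks$chrom] + peaks$bin + 1L
  observed <- mean(sites[flat])
  eligible <- which(!is.na(v))
  expected <- local_seed(seed, {
    mean(vapply(seq_len(n_rand), function(i) {
      mean(sites[sample(eligible, nrow(peaks))])
    }, numeric(1L)))
  })
  list(observed = observed, expected = expected, n_peaks = nrow(peaks))
}

#' Peak bins of one group as a logical vector on the grid
#' @param peaks A `peak_set`.
#' @param groups A `group_assignment`.
#' @param group `"group1"` or `"group2"`.
#' @param m Track defining the grid.
#' @return A `peak_set` restricted to peaks whose bin carries the group
#'   label.
#' @export
peaks_in_group <- function(peaks, groups, group, m) {
  offsets <- cumsum(c(0L, lengths(m$values)))
  names(offsets) <- c(names(m$values), "")
  flat <- offsets[peaks$chrom] + peaks$bin + 1L
  keep <- !is.na(groups$labels[flat]) & groups$labels[flat] == group
  out <- peaks[keep, , drop = FALSE]
  structure(out, class = c("peak_set", "data.frame"),
            bin_size = attr(peaks, "bin_size"))
}

#' Write peaks or group labels as BED
#' @param peaks A `peak_set`.
#' @param path Output BED path (score = c-MACC value).
#' @param name Feature name column (default `"peak"`), recycled.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path, name = "peak") {
  bs <- attr(peaks, "bin_size")
  gr <- GenomicRanges::GRanges(
    peaks$chrom,
    IRanges::IRanges(start = peaks$bin * bs + 1L, width = bs),
    name = rep_len(name, nrow(peaks)),
    score = round(peaks$value, 6))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
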