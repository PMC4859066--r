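#' Site-centered average signal profile
#'
#' For each anchor site the track signal is sampled at every 1-bp offset in
#' `[-flank, flank]` by linear interpolation between bin-center values
#' (bin centers sit at `(i + 0.5) * bin_size`); minus-strand sites are
#' reversed so that positive offsets point downstream. Offsets are averaged
#' over sites and the mean profile smoothed with a centered running mean of
#' width `smooth_window` bp, truncated at the edges. Sites whose flank exits
#' the chromosome are dropped (their number is reported).
#'
#' @param track A `binned_track` or `macc_track`.
#' @param sites data.frame with `chrom`, `pos` (0-based anchor bp) and
#'   optionally `strand` (`"+"` assumed when absent).
#' @param flank Half-width of the profile in bp (>= bin size).
#' @param smooth_window Running-mean window in bp (default 40; 0 disables).
#' @return A `site_profile`: list with `offset` (bp), `mean` (smoothed),
#'   `mean_raw`, `n` (sites contributing per offset), `n_dropped`.
#' @export
site_profile <- function(track, sites, flank = 1000L, smooth_window = 40L) {
  stopifnot(inherits(track, "binned_track"), flank >= track$bin_size)
  if (is.null(sites$strand)) sites$strand <- "+"
  offsets <- seq.int(-flank, flank)
  acc <- numeric(length(offsets))
  nacc <- integer(length(offsets))
  n_dropped <- 0L
  for (chrom in unique(sites$chrom)) {
    v <- track$values[[chrom]]
    if (is.null(v)) stop("sites on chromosome absent from track: ", chrom)
    centers <- (seq_along(v) - 0.5) * track$bin_size
    chrom_len <- if (!is.null(track$chrom_sizes)) track$chrom_sizes[[chrom]]
                 else length(v) * track$bin_size
    sel <- sites[sites$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(sel))) {
      pos <- sel$pos[i]
      if (pos - flank < 0 || pos + flank >= chrom_len) {
        n_dropped <- n_dropped + 1L
        next
      }
      at <- pos + offsets
      val <- stats::approx(centers, v, xout = at, rule = 2, ties = mean)$y
      if (sel$strand[i] == "-") val <- rev(val)
      ok <- !is.na(val)
      acc[ok] <- acc[ok] + val[ok]
      nacc[ok] <- nacc[ok] + 1L
    }
  }
  if (all(nacc == 0L)) stop("no usable sites (all dropped or empty set)")
  mean_raw <- ifelse(nacc > 0L, acc / nacc, NA_real_)
  smoothed <- if (smooth_window > 0L) running_mean(mean_raw, smooth_window)
              else mean_raw
  structure(list(offset = offsets, mean = smoothed, mean_raw = mean_raw,
                 n = nacc, n_dropped = n_dropped),
            class = "site_profile")
}

# centered running mean of width w points (bp on a 1-bp offset grid),
# truncated at the edges: each position averages the available points in
# [i - floor(w/2), i + floor(w/2)]
running_mean <- function(x, w) {
  half <- floor(w / 2)
  n <- length(x)
  xs <- ifelse(is.na(x), 0, x)
  cnt <- as.numeric(!is.na(x))
  cs <- cumsum(c(0, xs))
  cc <- cumsum(c(0, cnt))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  num <- cs[hi + 1L] - cs[lo]
  den <- cc[hi + 1L] - cc[lo]
  ifelse(den > 0, num / den, NA_real_)
}

#' @export
print.site_profile <- function(x, ...) {
  cat(sprintf("<site_profile> offsets %+d..%+d bp over %d site(s)%s\n",
              min(x$offset), max(x$offset), max(x$n),
              if (x$n_dropped) sprintf(" (%d dropped)", x$n_dropped) else ""))
  invisible(x)
}

#' TSS profiles for every titration point, split by expression
#'
#' Genes are split into expressed and silent sets at the stated expression
#' quantiles (default: upper vs lower third) and a TSS-anchored profile is
#' computed for each titration point plus the pooled occupancy track. Under
#' light digestion, fragile nucleosomes (e.g. the -1 nucleosome of expressed
#' genes) appear strongest and fade as MNase increases.
#'
#' @param series A [titration_series()].
#' @param genes data.frame with `chrom`, `start`, `end`, `strand` (TSS is
#'   taken strand-aware) and `gene_id`.
#' @param expression data.frame with `gene_id` and `value` (expression
#'   estimates).
#' @param expressed_above,silent_below Expression quantiles defining the two
#'   sets (defaults 2/3 and 1/3).
#' @param flank,smooth_window Passed to [site_profile()].
#' @return Nested list: `expressed` and `silent`, each a list of
#'   `site_profile`s named by concentration plus `"pooled"`.
#' @export
titration_tss_profiles <- function(series, genes, expression,
                                   expressed_above = 2 / 3,
                                   silent_below = 1 / 3,
                                   flank = 1000L, smooth_window = 40L) {
  stopifnot(inherits(series, "titration_series"),
            all(c("gene_id", "value") %in% names(expression)))
  expr <- expression$value[match(genes$gene_id, expression$gene_id)]
  if (all(is.na(expr))) stop("no genes matched the expression table")
  hi <- stats::quantile(expr, expressed_above, na.rm = TRUE, type = 7)
  lo <- stats::quantile(expr, silent_below, na.rm = TRUE, type = 7)
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  anchors <- data.frame(chrom = genes$chrom, pos = tss,
                        strand = genes$strand, stringsAsFactors = FALSE)
  sets <- list(expressed = anchors[!is.na(expr) & expr >= hi, , drop = FALSE],
               silent = anchors[!is.na(expr) & expr <= lo, , drop = FALSE])
  if (any(vapply(sets, nrow, integer(1L)) == 0L))
    stop("empty expressed or silent gene set at the given quantiles")
  pooled <- pool_occupancy(series)
  lapply(sets, function(s) {
    profs <- lapply(series$tracks, site_profile, sites = s, flank = flank,
                    smooth_window = smooth_window)
    names(profs) <- paste0(series$concentrations, "U")
    profs$pooled <- site_profile(pooled, s, flank = flank,
                                 smooth_window = smooth_window)
    profs
  })
}

#' Pearson correlation between two tracks within a region mask
#'
#' @param a,b Tracks on one grid.
#' @param mask Optional logical vector (parallel to [track_values()])
#'   restricting the bins considered.
#' @return Pearson r over jointly defined bins, or `NA` when fewer than 3
#'   joint bins remain. For heatmap export multiply by 100 and round.
#' @export
track_correlation <- function(a, b, mask = NULL) {
  stop_unless_same_grid(a, b)
  av <- track_values(a)
  bv <- track_values(b)
  keep <- !is.na(av) & !is.na(bv)
  if (!is.null(mask)) keep <- keep & mask
  if (sum(keep) < 3L) return(NA_real_)
  stats::cor(av[keep], bv[keep])
}

#' Pairwise track-correlation heatmap matrix
#'
#' @param tracks Named list of tracks on one grid.
#' @param mask Optional logical region mask.
#' @param cells Multiply by 100 and round (heatmap-cell convention)?
#' @return Symmetric matrix of Pearson correlations.
#' @export
correlation_matrix <- function(tracks, mask = NULL, cells = FALSE) {
  n <- length(tracks)
  out <- matrix(NA_real_, n, n, dimnames = list(names(tracks),
                                                names(tracks)))
  for (i in seq_len(n)) for (j in seq_len(i)) {
    r <- track_correlation(tracks[[i]], tracks[[j]], mask = mask)
    out[i, j] <- out[j, i] <- r
  }
  if (cells) out <- round(out * 100)
  out
}

#' UPGMA clustering of per-sample signal profiles
#'
#' Hierarchical clustering of the sample rows of a samples-by-sites signal
#' matrix using average linkage (UPGMA) on the distance
#' `1 - Pearson correlation`. Rows are ordered by label before clustering so
#' the leaf order is deterministic under ties.
#'
#' @param mat Numeric matrix, samples in rows (rownames = sample labels),
#'   sites in columns (>= 3).
#' @return An [stats::hclust] object.
#' @export
cluster_profiles <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2L, ncol(mat) >= 3L)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("sample", seq_len(nrow(mat)))
  zero_var <- apply(mat, 1L, stats::sd) == 0
  if (any(zero_var))
    stop("zero-variance profile for sample(s): ",
         paste(rownames(mat)[zero_var], collapse = ", "))
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  d <- stats::as.dist(1 - stats::cor(t(mat)))
  stats::hclust(d, method = "average")
}
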