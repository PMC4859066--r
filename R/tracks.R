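#' Binned genomic signal track
#'
#' A `binned_track` stores one value per fixed-width, non-overlapping genomic
#' bin, as a named list of per-chromosome numeric vectors. Bin `i` (0-based)
#' of a chromosome covers `[i * bin_size, (i + 1) * bin_size)` in 0-based
#' half-open coordinates; the last bin of a chromosome may be partial.
#' `NA` marks excluded (missing) bins.
#'
#' @param values Named list of numeric vectors, one per chromosome.
#' @param bin_size Bin width in bp.
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#'   When supplied, the number of bins per chromosome must equal
#'   `ceiling(size / bin_size)`.
#' @param normalized Logical; `TRUE` once library-size/genome-size scaling has
#'   been applied (see [normalize_track()]).
#' @param units Either `"raw"` (integer counts) or `"per_million_scaled"`.
#' @return An object of class `binned_track`.
#' @export
binned_track <- function(values, bin_size, chrom_sizes = NULL,
                         normalized = FALSE,
                         units = if (normalized) "per_million_scaled" else "raw") {
  stopifnot(is.list(values), length(values) >= 1L, !is.null(names(values)),
            bin_size >= 1)
  values <- lapply(values, as.numeric)
  if (!is.null(chrom_sizes)) {
    chrom_sizes <- chrom_sizes[names(values)]
    if (anyNA(chrom_sizes))
      stop("chrom_sizes missing for chromosome(s): ",
           paste(setdiff(names(values), names(chrom_sizes)), collapse = ", "))
    expected <- ceiling(chrom_sizes / bin_size)
    got <- lengths(values)
    if (!all(got == expected))
      stop("bin vector lengths do not match ceiling(chrom_sizes / bin_size)")
  }
  structure(list(values = values, bin_size = as.integer(bin_size),
                 chrom_sizes = chrom_sizes, normalized = isTRUE(normalized),
                 units = units),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  v <- unlist(x$values, use.names = FALSE)
  cat(sprintf("<%s> %d chromosome(s), %d bins of %d bp (%s%s)\n",
              class(x)[1L], length(x$values), length(v), x$bin_size,
              x$units, if (x$normalized) ", normalized" else ""))
  cat(sprintf("  defined bins: %d; value range: [%.4g, %.4g]\n",
              sum(!is.na(v)),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

#' Flattened values of a track
#'
#' @param t A `binned_track`.
#' @return Numeric vector of all per-bin values in chromosome order.
#' @export
track_values <- function(t) unlist(t$values, use.names = FALSE)

#' Per-bin chromosome labels of a track, parallel to [track_values()]
#' @param t A `binned_track`.
#' @return Character vector.
#' @export
track_chroms <- function(t) rep(names(t$values), lengths(t$values))

#' Replace the values of a track, preserving its grid
#' @param t A `binned_track`.
#' @param v Numeric vector, same total length as `track_values(t)`.
#' @return A track with the same shape and new values.
#' @export
track_replace <- function(t, v) {
  stopifnot(length(v) == sum(lengths(t$values)))
  t$values <- utils::relist(as.numeric(v), t$values)
  t
}

#' Logical mask of partial terminal bins
#'
#' Bins whose nominal extent runs past the chromosome end (possible only for
#' the last bin of a chromosome when its length is not a multiple of
#' `bin_size`). Such bins are retained in tracks but excluded from quantile
#' threshold computations.
#'
#' @param t A `binned_track`.
#' @return Logical vector parallel to [track_values()]; all `FALSE` when the
#'   track carries no `chrom_sizes`.
#' @export
partial_bins <- function(t) {
  n <- lengths(t$values)
  out <- logical(sum(n))
  if (is.null(t$chrom_sizes)) return(out)
  ends <- cumsum(n)
  partial <- (t$chrom_sizes[names(t$values)] %% t$bin_size) != 0
  out[ends[partial]] <- TRUE
  out
}

same_grid <- function(a, b) {
  identical(a$bin_size, b$bin_size) &&
    identical(names(a$values), names(b$values)) &&
    identical(lengths(a$values), lengths(b$values))
}

stop_unless_same_grid <- function(a, b) {
  if (!same_grid(a, b))
    stop("tracks are not on the same bin grid (bin size, chromosomes and ",
         "bin counts must match)")
  invisible(TRUE)
}

#' Set of paired-end digestion fragments from one titration point
#'
#' @param fragments A data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param concentration MNase amount in units (U); must be > 0.
#' @param label Sample name.
#' @param pool One of `"chromatin"`, `"histone_chip"`, `"chip_input"`.
#' @return An object of class `fragment_set` with `library_size` equal to the
#'   number of fragments.
#' @export
fragment_set <- function(fragments, concentration, label = "sample",
                         pool = c("chromatin", "histone_chip", "chip_input")) {
  pool <- match.arg(pool)
  stopifnot(is.data.frame(fragments),
            all(c("chrom", "start", "end") %in% names(fragments)))
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      concentration <= 0)
    stop("concentration must be a single positive MNase amount (U)")
  fragments <- data.frame(chrom = as.character(fragments$chrom),
                          start = as.integer(fragments$start),
                          end = as.integer(fragments$end),
                          stringsAsFactors = FALSE)
  if (nrow(fragments) && any(fragments$start >= fragments$end))
    stop("fragments must satisfy start < end (0-based half-open)")
  structure(list(fragments = fragments,
                 library_size = nrow(fragments),
                 concentration = as.numeric(concentration),
                 label = label, pool = pool),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("<fragment_set> '%s' (%s pool), %g U MNase, %d fragments\n",
              x$label, x$pool, x$concentration, x$library_size))
  invisible(x)
}

fragment_lengths <- function(fs) fs$fragments$end - fs$fragments$start

#' Aligned normalized tracks across an MNase titration
#'
#' @param tracks List of k >= 2 normalized `binned_track`s on one bin grid.
#' @param concentrations Strictly increasing positive MNase amounts (U),
#'   parallel to `tracks`.
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(tracks, concentrations) {
  if (length(tracks) < 2L)
    stop("a titration series needs k >= 2 titration points")
  if (length(concentrations) != length(tracks))
    stop("one concentration per track required")
  if (any(concentrations <= 0) || any(diff(concentrations) <= 0))
    stop("concentrations must be strictly increasing and positive")
  if (!all(vapply(tracks, function(t) isTRUE(t$normalized), logical(1L))))
    stop("all tracks in a titration series must be normalized")
  for (t in tracks[-1L]) stop_unless_same_grid(tracks[[1L]], t)
  structure(list(tracks = tracks, concentrations = as.numeric(concentrations)),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("<titration_series> k = %d points at %s U; %d bins of %d bp\n",
              length(x$tracks), paste(x$concentrations, collapse = "/"),
              sum(lengths(x$tracks[[1L]]$values)), x$tracks[[1L]]$bin_size))
  invisible(x)
}

series_matrix <- function(series) {
  vapply(series$tracks, track_values,
         numeric(sum(lengths(series$tracks[[1L]]$values))))
}

#' Convert a track to GRanges
#'
#' @param t A `binned_track` (or `macc_track`).
#' @param keep_missing Keep bins with `NA` values?
#' @return A [GenomicRanges::GRanges] with a `score` column.
#' @export
track_granges <- function(t, keep_missing = FALSE) {
  n <- lengths(t$values)
  chrom <- rep(names(t$values), n)
  idx <- unlist(lapply(n, seq_len), use.names = FALSE) - 1L
  start0 <- idx * t$bin_size
  end0 <- start0 + t$bin_size
  if (!is.null(t$chrom_sizes))
    end0 <- pmin(end0, t$chrom_sizes[chrom])
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start0 + 1L, end = end0),
                               score = track_values(t))
  if (!is.null(t$chrom_sizes)) {
    GenomeInfoDb::seqlengths(gr) <- t$chrom_sizes[GenomeInfoDb::seqlevels(gr)]
  }
  if (!keep_missing) gr <- gr[!is.na(S4Vectors::mcols(gr)$score)]
  gr
}

#' Write a track as bedGraph (optionally bigWig)
#'
#' @param t A `binned_track`.
#' @param path Output file; format chosen from the extension
#'   (`.bedGraph`/`.bg` or `.bw`/`.bigWig`).
#' @return `path`, invisibly.
#' @export
write_track <- function(t, path) {
  gr <- track_granges(t)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("bw", "bigwig")) {
    rtracklayer::export.bw(gr, path)
  } else {
    rtracklayer::export(gr, path, format = "bedGraph")
  }
  invisible(path)
}
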