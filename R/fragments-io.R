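#' Read paired-end digestion fragments from BAM, BEDPE or fragment BED
#'
#' One fragment is formed per properly paired read pair, spanning
#' `[leftmost mate start, rightmost mate end)`. Fragments with inferred length
#' outside `[min_len, max_len]` are discarded (the defaults drop insert sizes
#' below 50 bp or above 500 bp). For BAM input the file must be
#' coordinate-sorted and indexed; uniquely mapping pairs are selected through
#' a mapping-quality cutoff. Interval input (BEDPE / 3-column BED) carries no
#' mapping-quality information, so uniqueness filtering is skipped with a
#' warning.
#'
#' @param source Path to a `.bam` (sorted + indexed), `.bedpe`, or 3-column
#'   fragment `.bed` file.
#' @param min_len,max_len Inclusive fragment-length window in bp.
#' @param concentration MNase amount (U) of this titration point.
#' @param label Sample label.
#' @param pool Digestion pool the sample belongs to.
#' @param min_mapq Minimum mapping quality used as the uniqueness filter for
#'   BAM input (ignored, with a warning, for interval input).
#' @return A [fragment_set()].
#' @export
read_fragments <- function(source, min_len = 50L, max_len = 500L,
                           concentration = 1, label = basename(source),
                           pool = "chromatin", min_mapq = 10L) {
  if (min_len > max_len) stop("min_len must be <= max_len")
  ext <- tolower(tools::file_ext(source))
  if (ext == "bam") {
    frags <- read_fragments_bam(source, min_mapq)
  } else {
    warning("interval input carries no mapping-quality information; ",
            "uniqueness filtering skipped")
    frags <- read_fragments_intervals(source)
  }
  len <- frags$end - frags$start
  frags <- frags[len >= min_len & len <= max_len, , drop = FALSE]
  if (nrow(frags) == 0L)
    stop("no fragments retained after the [", min_len, ", ", max_len,
         "] bp length filter")
  fragment_set(frags, concentration = concentration, label = label,
               pool = pool)
}

read_fragments_bam <- function(path, min_mapq) {
  bai <- paste0(path, ".bai")
  if (!file.exists(bai) && !file.exists(sub("\\.bam$", ".bai", path)))
    stop("BAM input must be coordinate-sorted and indexed (missing .bai for ",
         path, "); run samtools sort/index first")
  flag <- Rsamtools::scanBamFlag(isProperPair = TRUE,
                                 isUnmappedQuery = FALSE,
                                 hasUnmappedMate = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag,
                                   what = c("rname", "pos", "isize"),
                                   mapqFilter = min_mapq)
  res <- Rsamtools::scanBam(path, param = param)[[1L]]
  # keep the leftmost mate of each pair (positive template length); the
  # fragment spans [pos - 1, pos - 1 + isize) in 0-based half-open coords
  keep <- !is.na(res$isize) & res$isize > 0L
  data.frame(chrom = as.character(res$rname[keep]),
             start = res$pos[keep] - 1L,
             end = res$pos[keep] - 1L + res$isize[keep],
             stringsAsFactors = FALSE)
}

read_fragments_intervals <- function(path) {
  dt <- data.table::fread(path, header = FALSE, data.table = TRUE)
  if (ncol(dt) >= 6L && is.numeric(dt[[5L]]) && is.numeric(dt[[6L]]) &&
      is.character(dt[[4L]])) {
    # BEDPE: chrom1 start1 end1 chrom2 start2 end2 [...]
    if (!all(dt[[1L]] == dt[[4L]]))
      stop("BEDPE mates on different chromosomes are not supported")
    data.frame(chrom = as.character(dt[[1L]]),
               start = pmin(dt[[2L]], dt[[5L]]),
               end = pmax(dt[[3L]], dt[[6L]]),
               stringsAsFactors = FALSE)
  } else if (ncol(dt) >= 3L) {
    data.frame(chrom = as.character(dt[[1L]]),
               start = dt[[2L]], end = dt[[3L]],
               stringsAsFactors = FALSE)
  } else {
    stop("unrecognized interval format (need BEDPE or >= 3-column BED): ",
         path)
  }
}

#' Discard fragments mapping to anomalous positions
#'
#' Each fragment contributes its two sequenced-tag positions (`start` and
#' `end - 1`). Per-position tag counts are computed over positions carrying at
#' least one tag; positions whose count exceeds `mean + z_threshold * sd` are
#' flagged as anomalous and every fragment with either endpoint at a flagged
#' position is removed. With zero variance across positions nothing is
#' flagged.
#'
#' @param fs A [fragment_set()].
#' @param z_threshold Z-score significance threshold (default 7).
#' @return A filtered `fragment_set`; the number of flagged positions is
#'   reported via `message()`.
#' @export
filter_anomalous_positions <- function(fs, z_threshold = 7) {
  stopifnot(inherits(fs, "fragment_set"))
  if (fs$library_size == 0L) stop("fragment set is empty")
  if (!is.numeric(z_threshold) || z_threshold <= 0)
    stop("z_threshold must be > 0")
  fr <- fs$fragments
  tags <- data.table::data.table(
    chrom = rep(fr$chrom, 2L),
    pos = c(fr$start, fr$end - 1L))
  counts <- tags[, .N, by = c("chrom", "pos")]
  mu <- mean(counts$N)
  sdev <- stats::sd(counts$N)
  if (is.na(sdev) || sdev == 0) {
    message("filter_anomalous_positions: 0 positions flagged")
    return(fs)
  }
  bad <- counts[(counts$N - mu) / sdev > z_threshold, ]
  message(sprintf("filter_anomalous_positions: %d position(s) flagged at Z > %g",
                  nrow(bad), z_threshold))
  if (nrow(bad) == 0L) return(fs)
  key <- function(chrom, pos) paste0(chrom, ":", pos)
  badset <- key(bad$chrom, bad$pos)
  drop <- key(fr$chrom, fr$start) %in% badset |
    key(fr$chrom, fr$end - 1L) %in% badset
  fragment_set(fr[!drop, , drop = FALSE], concentration = fs$concentration,
               label = fs$label, pool = fs$pool)
}

#' Count fragments in fixed-width bins by fragment midpoint
#'
#' Each fragment is assigned to exactly one bin by its midpoint
#' `floor((start + end) / 2)`. The sum of the raw counts equals the library
#' size.
#'
#' @param fs A [fragment_set()].
#' @param genome Named numeric vector of chromosome sizes (bp), or a
#'   two-column data.frame `(chrom, size)`.
#' @param bin_size Bin width in bp (300 for fly-scale genomes, 500 for human
#'   in the original analyses).
#' @return A raw-count [binned_track()].
#' @export
bin_counts <- function(fs, genome, bin_size = 300L) {
  stopifnot(inherits(fs, "fragment_set"), bin_size >= 1)
  sizes <- as_chrom_sizes(genome)
  fr <- fs$fragments
  missing_chrom <- setdiff(unique(fr$chrom), names(sizes))
  if (length(missing_chrom))
    stop("fragments on chromosome(s) absent from the genome table: ",
         paste(missing_chrom, collapse = ", "))
  mids <- (fr$start + fr$end) %/% 2L
  bin <- mids %/% as.integer(bin_size)
  values <- lapply(names(sizes), function(chrom) {
    nb <- ceiling(sizes[[chrom]] / bin_size)
    sel <- fr$chrom == chrom
    tabulate(bin[sel] + 1L, nbins = nb)
  })
  names(values) <- names(sizes)
  binned_track(values, bin_size = bin_size, chrom_sizes = sizes,
               normalized = FALSE, units = "raw")
}

as_chrom_sizes <- function(genome) {
  if (is.data.frame(genome)) {
    sizes <- as.numeric(genome[[2L]])
    names(sizes) <- as.character(genome[[1L]])
  } else {
    stopifnot(is.numeric(genome), !is.null(names(genome)))
    sizes <- genome
  }
  if (any(sizes <= 0)) stop("chromosome sizes must be positive")
  sizes
}

#' Read a two-column chromosome-sizes TSV
#' @param path TSV with columns chrom, size.
#' @return Named numeric vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "size"),
                          stringsAsFactors = FALSE)
  as_chrom_sizes(df)
}

#' Normalize a raw count track to per-million, genome-size-scaled frequency
#'
#' Values are scaled to counts per one million mapped fragments and
#' additionally by `genome_size / 100 Mb` so that profiles are comparable
#' between genomes: `value' = value * 1e6 / library_size * genome_size / 1e8`.
#'
#' @param t Raw-count [binned_track()].
#' @param library_size Retained fragment count of the sample.
#' @param genome_size Total length (bp) of the analyzed chromosomes; by
#'   default derived from the track's own chromosome sizes.
#' @return A normalized `binned_track`.
#' @export
normalize_track <- function(t, library_size,
                            genome_size = sum(t$chrom_sizes)) {
  stopifnot(inherits(t, "binned_track"))
  if (isTRUE(t$normalized)) stop("track is already normalized")
  if (is.null(genome_size) || !is.finite(genome_size) || genome_size <= 0)
    stop("genome_size must be a positive length in bp")
  if (!is.numeric(library_size) || library_size <= 0)
    stop("library_size must be > 0")
  f <- 1e6 / library_size * genome_size / 1e8
  t$values <- lapply(t$values, function(v) v * f)
  t$normalized <- TRUE
  t$units <- "per_million_scaled"
  t
}

#' Pooled occupancy: per-bin mean frequency over all titration points
#'
#' Averaging the normalized fragment frequencies over the full titration
#' approximates a conventional single-digest nucleosome occupancy map.
#'
#' @param series A [titration_series()].
#' @return A normalized `binned_track`; a bin is missing only when it is
#'   missing in every track.
#' @export
pool_occupancy <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  y <- series_matrix(series)
  pooled <- rowMeans(y, na.rm = TRUE)
  pooled[rowSums(!is.na(y)) == 0L] <- NA_real_
  out <- series$tracks[[1L]]
  track_replace(out, pooled)
}

#' Fragment-length distribution, optionally restricted to a region set
#'
#' @param fs A [fragment_set()].
#' @param sites Optional data.frame `(chrom, start, end)` (0-based half-open)
#'   or `GRanges`; only fragments whose midpoint falls inside a site are
#'   counted.
#' @param min_len,max_len Length-axis limits of the histogram.
#' @return A list with `counts` (named integer vector over each 1-bp length
#'   class), `mean` and `median`.
#' @export
fragment_length_distribution <- function(fs, sites = NULL,
                                         min_len = 50L, max_len = 500L) {
  stopifnot(inherits(fs, "fragment_set"))
  if (fs$library_size == 0L) stop("fragment set is empty")
  fr <- fs$fragments
  if (!is.null(sites)) {
    gr <- if (inherits(sites, "GRanges")) sites else
      GenomicRanges::GRanges(sites$chrom,
                             IRanges::IRanges(start = sites$start + 1L,
                                              end = sites$end))
    mids <- (fr$start + fr$end) %/% 2L
    midgr <- GenomicRanges::GRanges(fr$chrom,
                                    IRanges::IRanges(start = mids + 1L,
                                                     width = 1L))
    hit <- IRanges::overlapsAny(midgr, gr)
    fr <- fr[hit, , drop = FALSE]
  }
  lens <- fr$end - fr$start
  lens <- lens[lens >= min_len & lens <= max_len]
  counts <- tabulate(lens - min_len + 1L, nbins = max_len - min_len + 1L)
  names(counts) <- as.character(seq.int(min_len, max_len))
  if (sum(counts) == 0L) {
    warning("no fragments overlap the given sites")
    return(list(counts = counts, mean = NA_real_, median = NA_real_))
  }
  list(counts = counts, mean = mean(lens), median = stats::median(lens))
}

#' Combine replicate fragment sets by pooling fragments
#'
#' Replicates of one titration point are pooled before normalization; the
#' pooled library size is the sum of the retained counts.
#'
#' @param ... `fragment_set`s sharing concentration and pool.
#' @return One pooled `fragment_set`.
#' @export
pool_replicates <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) &&
      !inherits(sets[[1L]], "fragment_set")) sets <- sets[[1L]]
  stopifnot(length(sets) >= 1L,
            all(vapply(sets, inherits, logical(1L), "fragment_set")))
  conc <- unique(vapply(sets, `[[`, numeric(1L), "concentration"))
  pool <- unique(vapply(sets, `[[`, character(1L), "pool"))
  if (length(conc) != 1L || length(pool) != 1L)
    stop("replicates must share concentration and pool")
  fragment_set(do.call(rbind, lapply(sets, `[[`, "fragments")),
               concentration = conc,
               label = paste(vapply(sets, `[[`, character(1L), "label"),
                             collapse = "+"),
               pool = pool)
}
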