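#' Simulate a synthetic chromatin landscape with known per-bin truth
#'
#' Bins are organized into domains with geometric lengths (domain-scale
#' clustering of accessibility states); each domain is assigned a class —
#' accessible (signal rises as MNase decreases), inaccessible (the opposite)
#' or neutral — and every bin a response exponent beta whose sign follows the
#' class. A subset of accessible bins is flagged as NHP-protected
#' (non-histone protection: present in whole-chromatin digests, absent from
#' histone-ChIP pools) or as fragile-nucleosome loci; both carry the largest
#' response magnitudes, mirroring the strongest titration responders. Per-bin
#' G+C fraction follows a smooth random field in [0.25, 0.75].
#'
#' @param n_bins Total number of bins.
#' @param bin_size Bin width in bp (default 300).
#' @param n_chrom Number of chromosomes the bins are split over (default 2).
#' @param mean_domain_len Mean domain length in bins (geometric; 1 = iid).
#' @param class_fractions Named vector of class probabilities
#'   (`accessible`, `inaccessible`, `neutral`), summing to <= 1 (remainder
#'   goes to neutral).
#' @param beta_range Magnitude range of beta for bulk accessible/inaccessible
#'   bins (default `c(0.1, 0.3)`).
#' @param flagged_beta_range Magnitude range for NHP/fragile loci
#'   (default `c(0.3, 0.45)`).
#' @param nhp_fraction,fragile_fraction Fractions of all bins flagged as NHP
#'   or fragile-nucleosome loci (flags live on accessible bins only).
#' @param gc_smooth Smoothing window (bins) of the GC random field.
#' @param seed Integer seed; the truth is fully deterministic given it.
#' @return A `synthetic_truth` data.frame with one row per bin: `chrom`,
#'   `bin`, `class`, `beta`, `gc`, `nhp`, `fragile`, `domain`; attributes
#'   `bin_size` and `chrom_sizes`.
#' @export
simulate_genome <- function(n_bins, bin_size = 300L, n_chrom = 2L,
                            mean_domain_len = 20,
                            class_fractions = c(accessible = 0.2,
                                                inaccessible = 0.2,
                                                neutral = 0.6),
                            beta_range = c(0.1, 0.3),
                            flagged_beta_range = c(0.3, 0.45),
                            nhp_fraction = 0.02, fragile_fraction = 0.03,
                            gc_smooth = 50L, seed = 1L) {
  stopifnot(n_bins >= n_chrom, mean_domain_len >= 1)
  cf <- class_fractions[c("accessible", "inaccessible", "neutral")]
  cf[is.na(cf)] <- 0
  names(cf) <- c("accessible", "inaccessible", "neutral")
  if (sum(cf) > 1 + 1e-9 || any(cf < 0))
    stop("class fractions must be non-negative and sum to <= 1")
  cf["neutral"] <- cf["neutral"] + (1 - sum(cf))
  if (nhp_fraction + fragile_fraction > cf[["accessible"]])
    stop("nhp_fraction + fragile_fraction cannot exceed the accessible class fraction")
  local_seed(seed, {
    # domains with geometric lengths: P(len = l) = p (1-p)^(l-1), mean 1/p
    p <- 1 / mean_domain_len
    lens <- integer(0)
    while (sum(lens) < n_bins)
      lens <- c(lens, stats::rgeom(max(64L, ceiling(n_bins / mean_domain_len)),
                                   p) + 1L)
    lens <- lens[cumsum(lens) - lens < n_bins]
    lens[length(lens)] <- n_bins - sum(lens[-length(lens)])
    domain <- rep(seq_along(lens), lens)
    dom_class <- sample(names(cf), length(lens), replace = TRUE, prob = cf)
    class <- dom_class[domain]
    beta <- numeric(n_bins)
    acc <- class == "accessible"
    inac <- class == "inaccessible"
    beta[acc] <- stats::runif(sum(acc), beta_range[1L], beta_range[2L])
    beta[inac] <- -stats::runif(sum(inac), beta_range[1L], beta_range[2L])
    # NHP / fragile flags on accessible bins, disjoint, strongest responders
    nhp <- fragile <- logical(n_bins)
    n_nhp <- round(nhp_fraction * n_bins)
    n_frag <- round(fragile_fraction * n_bins)
    acc_idx <- which(acc)
    pick <- sample(acc_idx, min(n_nhp + n_frag, length(acc_idx)))
    nhp[pick[seq_len(min(n_nhp, length(pick)))]] <- TRUE
    fragile[setdiff(pick, which(nhp))] <- TRUE
    flagged <- nhp | fragile
    beta[flagged] <- stats::runif(sum(flagged), flagged_beta_range[1L],
                                  flagged_beta_range[2L])
    # smooth GC field in [0.25, 0.75]
    z <- stats::rnorm(n_bins)
    z <- running_mean(z, gc_smooth)
    z <- (z - mean(z)) / stats::sd(z)
    gc <- 0.25 + 0.5 * stats::pnorm(z)
    # split over chromosomes
    per <- diff(round(seq(0, n_bins, length.out = n_chrom + 1L)))
    chrom <- rep(paste0("chrS", seq_len(n_chrom)), per)
    bin <- unlist(lapply(per, seq_len), use.names = FALSE) - 1L
    truth <- data.frame(chrom = chrom, bin = bin, class = class,
                        beta = beta, gc = gc, nhp = nhp, fragile = fragile,
                        domain = domain, stringsAsFactors = FALSE)
    attr(truth, "bin_size") <- as.integer(bin_size)
    attr(truth, "chrom_sizes") <- stats::setNames(per * bin_size,
                                                  paste0("chrS", seq_len(n_chrom)))
    class(truth) <- c("synthetic_truth", "data.frame")
    truth
  })
}

#' Simulate an MNase titration from a synthetic truth
#'
#' Expected fragment yield per bin and titration point follows the log-linear
#' response `lambda_ij = depth * exp(beta_i * (x_j - xbar))` with
#' `x_j = -ln(c_j)`; counts are Poisson. Mean-centering the abscissa keeps
#' expected library sizes comparable across points for class-symmetric
#' truths. GC digestion bias is injected into the response exponent
#' (`beta_eff = beta + strength * 1.2 * (gc - 0.5)`): MNase sequence
#' preference modulates how yield responds to digestion depth, which is the
#' slope-level bias the LOWESS correction removes; at strength 0 yields are
#' unbiased. Fragment lengths are Normal(150, 20) truncated to [50, 500] bp —
#' Normal(110, 15) at NHP loci, whose protected footprints are
#' sub-nucleosomal — with midpoints uniform within the bin.
#'
#' Three pools are emitted per titration point: `chromatin` (everything),
#' `histone_chip` (yield at NHP loci dropped entirely by default — those
#' loci are protected by non-histone proteins and do not
#' immunoprecipitate; set `nhp_chip_background > 0` to add a flat
#' nucleosomal background there instead) and `chip_input` (mirrors
#' chromatin).
#'
#' @param truth A `synthetic_truth` from [simulate_genome()].
#' @param concentrations Strictly increasing MNase amounts in U (default
#'   1.5/6.25/25/100).
#' @param depth Expected fragments per bin per titration point (default 50).
#' @param gc_bias_strength GC bias strength (0 = none, 1 = strong).
#' @param pools Which pools to simulate.
#' @param nhp_chip_background Flat background fraction of `depth` emitted at
#'   NHP loci in the histone-ChIP pool (default 0: NHP loci absent from the
#'   ChIP pool, so their h-MACC is undefined and treated as 0 by
#'   [assign_groups()]).
#' @param seed Integer seed.
#' @return A `titration_simulation`: list with `fragments` (nested list
#'   `pool -> concentration -> fragment_set`), `truth`, `concentrations`,
#'   `chrom_sizes`, `bin_size`.
#' @export
simulate_titration <- function(truth,
                               concentrations = c(1.5, 6.25, 25, 100),
                               depth = 50, gc_bias_strength = 0,
                               pools = c("chromatin", "histone_chip",
                                         "chip_input"),
                               nhp_chip_background = 0, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (depth <= 0) stop("depth must be > 0")
  if (length(concentrations) < 2L || any(diff(concentrations) <= 0) ||
      any(concentrations <= 0))
    stop("concentrations must be >= 2 strictly increasing positive values")
  bin_size <- attr(truth, "bin_size")
  sizes <- attr(truth, "chrom_sizes")
  x <- -log(concentrations)
  xc <- x - mean(x)
  beta_eff <- truth$beta + gc_bias_strength * 1.2 * (truth$gc - 0.5)
  out <- local_seed(seed, {
    lapply(stats::setNames(pools, pools), function(pool) {
      res <- lapply(seq_along(concentrations), function(j) {
        lambda <- depth * exp(beta_eff * xc[j])
        if (pool == "histone_chip")
          lambda[truth$nhp] <- nhp_chip_background * depth
        counts <- stats::rpois(nrow(truth), lambda)
        idx <- rep.int(seq_len(nrow(truth)), counts)
        n <- length(idx)
        len_mu <- ifelse(truth$nhp[idx] & pool != "histone_chip", 110, 150)
        len_sd <- ifelse(truth$nhp[idx] & pool != "histone_chip", 15, 20)
        len <- round(stats::rnorm(n, len_mu, len_sd))
        len <- pmin(pmax(len, 50L), 500L)
        mid <- truth$bin[idx] * bin_size +
          floor(stats::runif(n, 0, bin_size))
        start <- mid - len %/% 2L
        chrom <- truth$chrom[idx]
        start <- pmax(start, 0L)
        end <- pmin(start + len, sizes[chrom])
        start <- pmax(end - len, 0L)
        fragment_set(data.frame(chrom = chrom, start = start, end = end,
                                stringsAsFactors = FALSE),
                     concentration = concentrations[j],
                     label = sprintf("%s_%gU", pool, concentrations[j]),
                     pool = pool)
      })
      names(res) <- paste0(concentrations, "U")
      res
    })
  })
  structure(list(fragments = out, truth = truth,
                 concentrations = concentrations,
                 chrom_sizes = sizes, bin_size = bin_size),
            class = "titration_simulation")
}

#' @export
print.titration_simulation <- function(x, ...) {
  cat(sprintf("<titration_simulation> %d bins x %d points x %d pool(s)\n",
              nrow(x$truth), length(x$concentrations), length(x$fragments)))
  invisible(x)
}

#' Build normalized titration series from simulated (or real) fragment sets
#'
#' Convenience wrapper: bins each fragment set, normalizes by its retained
#' library size and the genome size, and assembles a [titration_series()].
#'
#' @param fragment_sets List of `fragment_set`s ordered by concentration.
#' @param genome Chromosome sizes (named vector or data.frame).
#' @param bin_size Bin width in bp.
#' @return A `titration_series`.
#' @export
build_series <- function(fragment_sets, genome, bin_size = 300L) {
  sizes <- as_chrom_sizes(genome)
  conc <- vapply(fragment_sets, `[[`, numeric(1L), "concentration")
  ord <- order(conc)
  tracks <- lapply(fragment_sets[ord], function(fs)
    normalize_track(bin_counts(fs, sizes, bin_size), fs$library_size,
                    genome_size = sum(sizes)))
  titration_series(tracks, conc[ord])
}

#' Write a simulated titration to disk as a re-readable plain-text fixture
#'
#' Emits one BEDPE per pool and titration point (mates reconstructed as
#' 36-bp reads at the fragment ends), a chromosome-sizes TSV, a truth BED
#' (name = class with NHP/fragile flags appended), a synthetic reference
#' FASTA whose per-bin base composition matches the truth GC field, and a
#' samples YAML with per-sample metadata (file, concentration, pool, label,
#' library size). Reading a BEDPE back with [read_fragments()] reproduces the
#' fragment multiset exactly.
#'
#' @param sim A `titration_simulation`.
#' @param dir Output directory (created if needed).
#' @param read_len Reconstructed read length for the BEDPE mates.
#' @param seed Seed for the synthetic reference bases (fixed seed gives a
#'   byte-identical fixture).
#' @return Invisibly, the sample metadata data.frame.
#' @export
write_fixture <- function(sim, dir, read_len = 36L, seed = 1L) {
  stopifnot(inherits(sim, "titration_simulation"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  sizes <- sim$chrom_sizes
  utils::write.table(data.frame(names(sizes), as.integer(sizes)),
                     file.path(dir, "chrom.sizes"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  samples <- list()
  for (pool in names(sim$fragments)) {
    for (nm in names(sim$fragments[[pool]])) {
      fs <- sim$fragments[[pool]][[nm]]
      fr <- fs$fragments
      rl <- pmin(read_len, fr$end - fr$start)
      bedpe <- data.frame(fr$chrom, fr$start, fr$start + rl,
                          fr$chrom, fr$end - rl, fr$end,
                          paste0("frag", seq_len(nrow(fr))), 0L, "+", "-")
      fn <- sprintf("%s_%s.bedpe", pool, nm)
      data.table::fwrite(bedpe, file.path(dir, fn), sep = "\t",
                         quote = FALSE, col.names = FALSE)
      samples[[length(samples) + 1L]] <-
        list(file = fn, concentration = fs$concentration, pool = pool,
             label = fs$label, library_size = fs$library_size)
    }
  }
  yaml::write_yaml(list(bin_size = sim$bin_size, samples = samples),
                   file.path(dir, "samples.yaml"))
  truth <- sim$truth
  flags <- paste0(truth$class,
                  ifelse(truth$nhp, ";nhp", ""),
                  ifelse(truth$fragile, ";fragile", ""))
  bed <- data.frame(truth$chrom, truth$bin * sim$bin_size,
                    pmin((truth$bin + 1L) * sim$bin_size,
                         sizes[truth$chrom]),
                    flags, round(truth$beta, 6), ".")
  utils::write.table(bed, file.path(dir, "truth.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  local_seed(seed,
             write_synthetic_fasta(truth, sizes, sim$bin_size,
                                   file.path(dir, "synthetic_genome.fa")))
  invisible(do.call(rbind, lapply(samples, as.data.frame)))
}

# synthetic reference whose per-bin GC matches the truth GC field in
# expectation (bases drawn iid within each bin)
write_synthetic_fasta <- function(truth, sizes, bin_size, path) {
  seqs <- vapply(names(sizes), function(chrom) {
    tr <- truth[truth$chrom == chrom, , drop = FALSE]
    bases <- unlist(lapply(seq_len(nrow(tr)), function(i) {
      w <- min(bin_size, sizes[[chrom]] - tr$bin[i] * bin_size)
      p <- tr$gc[i]
      sample(c("G", "C", "A", "T"), w, replace = TRUE,
             prob = c(p / 2, p / 2, (1 - p) / 2, (1 - p) / 2))
    }), use.names = FALSE)
    paste(bases, collapse = "")
  }, character(1L))
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- names(sizes)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir Fixture directory.
#' @return List with `fragments` (pool -> concentration -> `fragment_set`),
#'   `chrom_sizes`, `bin_size`, `truth` (when `truth.bed` present).
#' @export
read_fixture <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "samples.yaml"))
  sizes <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  fragments <- list()
  for (s in meta$samples) {
    fs <- suppressWarnings(read_fragments(file.path(dir, s$file),
                                          min_len = 1L, max_len = 10000L,
                                          concentration = s$concentration,
                                          label = s$label, pool = s$pool))
    key <- paste0(s$concentration, "U")
    fragments[[s$pool]][[key]] <- fs
  }
  truth <- NULL
  tb <- file.path(dir, "truth.bed")
  if (file.exists(tb)) {
    df <- utils::read.table(tb, sep = "\t", stringsAsFactors = FALSE)
    truth <- data.frame(chrom = df[[1L]],
                        bin = df[[2L]] %/% meta$bin_size,
                        class = sub(";.*$", "", df[[4L]]),
                        beta = df[[5L]],
                        nhp = grepl(";nhp", df[[4L]]),
                        fragile = grepl(";fragile", df[[4L]]),
                        stringsAsFactors = FALSE)
  }
  list(fragments = fragments, chrom_sizes = sizes,
       bin_size = meta$bin_size, truth = truth)
}
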