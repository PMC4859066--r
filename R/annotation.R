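#' Build a per-bin genome annotation from gene models and enhancers
#'
#' Every bin receives exactly one class via the priority rule
#' enhancer > promoter > 5'-gene > TES-proximal > gene body > unannotated.
#' The promoter is the `window` bp upstream of the TSS and the 5'-gene region
#' the `window` bp downstream of the TSS (strand-aware; 1 kb for fly-scale
#' annotations, 2 kb for mammalian ones); TES-proximal covers +/- `window`
#' around the TES. TSS-proximal bins (promoter and 5'-gene) overlapping a
#' different gene are excluded from those classes; enhancer overlap wins
#' regardless per the priority rule.
#'
#' @param genes data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `strand` (`"+"`/`"-"`), and optionally `id`.
#' @param enhancers Optional data.frame `(chrom, start, end)` of enhancer
#'   regions.
#' @param genome Named chromosome sizes (bp) or two-column data.frame.
#' @param bin_size Bin width in bp.
#' @param window TSS/TES window in bp (default 1000).
#' @return A `genome_annotation`: list with `classes` (per-chromosome
#'   character vectors), `bin_size`, `chrom_sizes`, `window`.
#' @export
build_annotation <- function(genes, enhancers = NULL, genome,
                             bin_size = 300L, window = 1000L) {
  stopifnot(is.data.frame(genes),
            all(c("chrom", "start", "end", "strand") %in% names(genes)))
  if (any(!genes$strand %in% c("+", "-")))
    stop("strandless gene records are not allowed (strand must be '+' or '-')")
  sizes <- as_chrom_sizes(genome)
  if (is.null(genes$id)) genes$id <- seq_len(nrow(genes))

  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand, id = genes$id)
  plus <- genes$strand == "+"
  tss <- ifelse(plus, genes$start, genes$end - 1L)   # 0-based TSS position
  tes <- ifelse(plus, genes$end - 1L, genes$start)
  clamp_gr <- function(chrom, start0, end0, id) {
    start0 <- pmax(start0, 0L)
    end0 <- pmin(end0, sizes[chrom])
    keep <- end0 > start0
    GenomicRanges::GRanges(chrom[keep],
                           IRanges::IRanges(start = start0[keep] + 1L,
                                            end = end0[keep]),
                           id = id[keep])
  }
  promoter <- clamp_gr(genes$chrom,
                       ifelse(plus, tss - window, tss + 1L),
                       ifelse(plus, tss, tss + 1L + window),
                       genes$id)
  five_prime <- clamp_gr(genes$chrom,
                         ifelse(plus, tss, tss + 1L - window),
                         ifelse(plus, tss + window, tss + 1L),
                         genes$id)
  tes_prox <- clamp_gr(genes$chrom, tes - window, tes + 1L + window,
                       genes$id)

  nb <- ceiling(sizes / bin_size)
  bins_gr <- GenomicRanges::GRanges(
    rep(names(sizes), nb),
    IRanges::IRanges(
      start = unlist(lapply(nb, function(n) (seq_len(n) - 1L)), use.names = FALSE) *
        bin_size + 1L,
      end = pmin(unlist(lapply(nb, seq_len), use.names = FALSE) * bin_size,
                 rep(sizes, nb))))
  classes <- rep("unannotated", length(bins_gr))

  # exclusion of TSS-proximal regions that overlap a *different* gene
  tss_ok <- function(region_gr) {
    hits <- GenomicRanges::findOverlaps(region_gr, gene_gr,
                                        ignore.strand = TRUE)
    other <- S4Vectors::mcols(region_gr)$id[S4Vectors::queryHits(hits)] !=
      S4Vectors::mcols(gene_gr)$id[S4Vectors::subjectHits(hits)]
    bad <- unique(S4Vectors::queryHits(hits)[other])
    region_gr[setdiff(seq_along(region_gr), bad)]
  }
  promoter <- tss_ok(promoter)
  five_prime <- tss_ok(five_prime)

  assign_class <- function(classes, region_gr, label) {
    if (is.null(region_gr) || length(region_gr) == 0L) return(classes)
    hit <- IRanges::overlapsAny(bins_gr, region_gr, ignore.strand = TRUE)
    classes[hit & classes == "unannotated"] <- label
    classes
  }
  # priority order: later assignments never overwrite earlier ones
  if (!is.null(enhancers)) {
    enh_gr <- GenomicRanges::GRanges(
      enhancers$chrom,
      IRanges::IRanges(start = enhancers$start + 1L, end = enhancers$end))
    classes <- assign_class(classes, enh_gr, "enhancer")
  }
  classes <- assign_class(classes, promoter, "promoter")
  classes <- assign_class(classes, five_prime, "five_prime")
  classes <- assign_class(classes, tes_prox, "tes_prox")
  classes <- assign_class(classes, gene_gr, "gene_body")

  class_list <- split(classes, rep(names(sizes), nb))[names(sizes)]
  structure(list(classes = class_list, bin_size = as.integer(bin_size),
                 chrom_sizes = sizes, window = window),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  tab <- table(unlist(x$classes, use.names = FALSE))
  cat("<genome_annotation>", sum(tab), "bins:\n")
  print(tab)
  invisible(x)
}

#' Enrichment of a bin set in annotated region classes
#'
#' Per class, the ratio between the fraction of query bins in the class and
#' the fraction of the genome (all bins) covered by the class; 1 means no
#' enrichment.
#'
#' @param bins Logical vector on the annotation's bin grid marking the query
#'   bins (e.g. peak bins or group-labeled bins).
#' @param ann A `genome_annotation`.
#' @return data.frame with `class`, `query_fraction`, `genome_fraction`,
#'   `enrichment` (NA for classes with zero genome coverage).
#' @export
region_enrichment <- function(bins, ann) {
  stopifnot(inherits(ann, "genome_annotation"))
  classes <- unlist(ann$classes, use.names = FALSE)
  stopifnot(length(bins) == length(classes))
  lev <- c("enhancer", "promoter", "five_prime", "tes_prox", "gene_body",
           "unannotated")
  genome_frac <- as.numeric(table(factor(classes, levels = lev))) /
    length(classes)
  if (!any(bins)) stop("empty query bin set")
  query_frac <- as.numeric(table(factor(classes[bins], levels = lev))) /
    sum(bins)
  data.frame(class = lev,
             query_fraction = query_frac,
             genome_fraction = genome_frac,
             enrichment = ifelse(genome_frac > 0, query_frac / genome_frac,
                                 NA_real_),
             stringsAsFactors = FALSE)
}
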