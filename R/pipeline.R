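#' Default run parameters
#'
#' One place for every tunable constant of the pipeline: 300-bp bins (500 bp
#' recommended for human-scale genomes), 50-500 bp fragment-length window,
#' anomalous-position Z threshold 7, natural-log concentration scale, LOWESS
#' span 0.3, the 80/10/90 positive-score percentiles of the group
#' thresholds, occupancy/MACC quadrant quantiles 0.80/0.05/0.95, 10 overlap
#' randomizations, 40-bp profile smoothing, 1-kb TSS windows (2 kb for
#' mammalian annotations), 10 HMM restarts.
#'
#' @return Named list of defaults.
#' @export
default_parameters <- function() {
  list(bin_size = 300L,
       min_fragment_length = 50L,
       max_fragment_length = 500L,
       anomalous_z = 7,
       log_base = exp(1),
       lowess_span = 0.3,
       lowess_iterations = 0L,
       group_c_quantile = 0.80,
       group_h_low = 0.10,
       group_h_high = 0.90,
       occupancy_top = 0.80,
       macc_low = 0.05,
       macc_high = 0.95,
       n_randomizations = 10L,
       smooth_window = 40L,
       tss_window = 1000L,
       tss_window_mammal = 2000L,
       hmm_restarts = 10L,
       min_defined_bins = 100L,
       seed = 1L)
}

#' Read, validate and serialize a pipeline run configuration
#'
#' A run configuration is a YAML file with a `samples` table (file,
#' concentration, pool, replicate, label), `genome` paths (`sizes`, optional
#' `fasta`, `annotations`, `cpg_islands`) and a `parameters` block; every
#' parameter omitted from the file takes its default from
#' [default_parameters()].
#'
#' @param path YAML config path.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$base_dir <- dirname(normalizePath(path))
  validate_run_config(raw)
}

#' @rdname read_run_config
#' @param config A raw config list.
#' @export
validate_run_config <- function(config) {
  if (is.null(config$samples) || length(config$samples) == 0L)
    stop("config must list at least one sample")
  params <- utils::modifyList(default_parameters(),
                              config$parameters %||% list())
  samples <- do.call(rbind, lapply(config$samples, function(s) {
    data.frame(file = s$file, concentration = as.numeric(s$concentration),
               pool = s$pool %||% "chromatin",
               replicate = s$replicate %||% 1L,
               label = s$label %||% basename(s$file),
               stringsAsFactors = FALSE)
  }))
  for (pool in unique(samples$pool)) {
    k <- length(unique(samples$concentration[samples$pool == pool]))
    if (k < 2L)
      stop("pool '", pool, "' has ", k,
           " distinct concentration(s); a titration needs >= 2")
  }
  base <- config$base_dir %||% "."
  resolve <- function(p) if (is.null(p)) NULL else
    if (file.exists(p)) p else file.path(base, p)
  genome <- config$genome %||% list()
  genome$sizes <- resolve(genome$sizes)
  genome$fasta <- resolve(genome$fasta)
  genome$cpg_islands <- resolve(genome$cpg_islands)
  if (is.null(genome$sizes))
    stop("config must provide genome: sizes (chromosome-sizes TSV)")
  paths <- file.path(base, samples$file)
  paths[file.exists(samples$file)] <- samples$file[file.exists(samples$file)]
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("referenced sample file(s) do not exist: ",
         paste(missing, collapse = ", "))
  if (!file.exists(genome$sizes))
    stop("chromosome sizes file does not exist: ", genome$sizes)
  samples$path <- paths
  structure(list(samples = samples, genome = genome, parameters = params),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a run configuration back to YAML
#' @param config A `run_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  samples <- lapply(seq_len(nrow(config$samples)), function(i) {
    s <- config$samples[i, ]
    list(file = s$file, concentration = s$concentration, pool = s$pool,
         replicate = s$replicate, label = s$label)
  })
  yaml::write_yaml(list(samples = samples,
                        genome = config$genome[!vapply(config$genome,
                                                       is.null, logical(1L))],
                        parameters = config$parameters), path)
  invisible(path)
}

#' Run the MACC pipeline
#'
#' Executes the stages in dependency order: fragment reading and filtering,
#' binned track construction and normalization, MACC fitting (per pool), GC
#' correction (when a reference FASTA is configured), median shifting, HMM
#' segmentation, peak calling, and group assignment (when a histone-ChIP
#' pool is present). Every output carries a provenance header (config hash,
#' seed, package version); reruns with identical config and seed reproduce
#' all outputs.
#'
#' @param config A `run_config` ([read_run_config()]).
#' @param out_dir Artifact directory (created if needed).
#' @param stages Subset of
#'   `c("tracks", "macc", "segment", "peaks", "groups")`; stages are always
#'   executed in dependency order and earlier stages are run as needed.
#' @return Invisibly, a list of in-memory results (`series`, `macc`,
#'   `segmentation`, `peaks`, `groups`, ...).
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("tracks", "macc", "segment", "peaks",
                                    "groups")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- config$parameters
  sizes <- read_chrom_sizes(config$genome$sizes)
  provenance <- pipeline_provenance(config)
  logf <- file.path(out_dir, "run_log.jsonl")
  log_event <- function(...) {
    rec <- list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), ...)
    cat(mini_json(rec), "\n", sep = "", file = logf, append = TRUE)
  }
  log_event(event = "start", config_hash = provenance$config_hash,
            seed = p$seed)

  # --- fragments -> normalized titration series, per pool -----------------
  series_by_pool <- list()
  for (pool in unique(config$samples$pool)) {
    rows <- config$samples[config$samples$pool == pool, , drop = FALSE]
    sets <- lapply(split(rows, rows$concentration), function(grp) {
      reps <- lapply(seq_len(nrow(grp)), function(i)
        suppressWarnings(read_fragments(grp$path[i],
                                        min_len = p$min_fragment_length,
                                        max_len = p$max_fragment_length,
                                        concentration = grp$concentration[i],
                                        label = grp$label[i], pool = pool)))
      filter_anomalous_positions(pool_replicates(reps),
                                 z_threshold = p$anomalous_z)
    })
    series_by_pool[[pool]] <- build_series(sets, sizes,
                                           bin_size = p$bin_size)
    log_event(event = "tracks", pool = pool,
              libraries = unname(vapply(sets, `[[`, numeric(1L),
                                        "library_size")))
  }
  if ("tracks" %in% stages) {
    for (pool in names(series_by_pool)) {
      s <- series_by_pool[[pool]]
      for (j in seq_along(s$tracks))
        write_track_with_header(
          s$tracks[[j]],
          file.path(out_dir, sprintf("%s_%gU.bedGraph", pool,
                                     s$concentrations[j])),
          provenance)
    }
  }
  results <- list(series = series_by_pool)
  if (!any(c("macc", "segment", "peaks", "groups") %in% stages))
    return(invisible(results))

  # --- MACC ----------------------------------------------------------------
  gc <- NULL
  if (!is.null(config$genome$fasta)) {
    cpg <- NULL
    if (!is.null(config$genome$cpg_islands))
      cpg <- utils::read.table(config$genome$cpg_islands, sep = "\t",
                               col.names = c("chrom", "start", "end"),
                               stringsAsFactors = FALSE)
    gc <- gc_content(config$genome$fasta,
                     series_by_pool[[1L]]$tracks[[1L]], cpg_islands = cpg)
  }
  macc_by_pool <- list()
  for (pool in names(series_by_pool)) {
    prov <- if (pool == "histone_chip") "h-MACC" else "c-MACC"
    m <- fit_macc(series_by_pool[[pool]], log_base = p$log_base,
                  provenance = prov)
    if (!is.null(gc))
      m <- gc_correct(m, gc, stratify_cpg = !is.null(gc$cpg),
                      span = p$lowess_span,
                      iterations = p$lowess_iterations, seed = p$seed)
    m <- median_shift(m)
    macc_by_pool[[pool]] <- m
    write_track_with_header(m, file.path(out_dir,
                                         sprintf("macc_%s.bedGraph", pool)),
                            provenance)
    log_event(event = "macc", pool = pool,
              defined_bins = sum(!is.na(track_values(m))))
  }
  results$macc <- macc_by_pool
  c_macc <- macc_by_pool[["chromatin"]] %||% macc_by_pool[[1L]]

  # --- segmentation --------------------------------------------------------
  if ("segment" %in% stages) {
    model <- fit_two_state_hmm(c_macc, n_restarts = p$hmm_restarts,
                               seed = p$seed,
                               min_defined_bins = p$min_defined_bins)
    seg <- viterbi_segment(model, c_macc)
    write_hmm_model(model, file.path(out_dir, "hmm_model.yaml"))
    write_segmentation(seg, file.path(out_dir, "segmentation.bed"))
    st <- segment_stats(seg)
    log_event(event = "segment",
              accessible_coverage = st$coverage[["accessible"]])
    results$model <- model
    results$segmentation <- seg
  }

  # --- peaks ---------------------------------------------------------------
  if (any(c("peaks", "groups") %in% stages)) {
    peaks <- call_local_peaks(c_macc)
    write_peaks(peaks, file.path(out_dir, "peaks.bed"))
    log_event(event = "peaks", n_peaks = nrow(peaks))
    results$peaks <- peaks
  }

  # --- groups --------------------------------------------------------------
  if ("groups" %in% stages && "histone_chip" %in% names(macc_by_pool)) {
    groups <- assign_groups(c_macc, macc_by_pool[["histone_chip"]],
                            c_quantile = p$group_c_quantile,
                            h_low = p$group_h_low, h_high = p$group_h_high)
    for (g in c("group1", "group2")) {
      gp <- peaks_in_group(results$peaks, groups, g, c_macc)
      write_peaks(gp, file.path(out_dir, paste0(g, "_peaks.bed")), name = g)
    }
    tab <- table(factor(groups$labels, levels = c("group1", "group2",
                                                  "none")))
    summary_df <- data.frame(
      metric = c("group1_bins", "group2_bins",
                 names(groups$thresholds)),
      value = c(tab[["group1"]], tab[["group2"]],
                unname(groups$thresholds)))
    utils::write.table(summary_df, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_event(event = "groups", group1 = tab[["group1"]],
              group2 = tab[["group2"]],
              thresholds = as.list(groups$thresholds))
    results$groups <- groups
  }
  log_event(event = "done")
  invisible(results)
}

pipeline_provenance <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_run_config(config, tmp)
  list(config_hash = unname(tools::md5sum(tmp)),
       seed = config$parameters$seed,
       version = as.character(utils::packageVersion("maccr")))
}

write_track_with_header <- function(t, path, provenance) {
  header <- sprintf("# maccr v%s | config %s | seed %s",
                    provenance$version, provenance$config_hash,
                    provenance$seed)
  tmp <- tempfile(fileext = ".bedGraph")
  write_track(t, tmp)
  writeLines(c(header, readLines(tmp)), path)
  unlink(tmp)
  invisible(path)
}

# minimal JSON serializer for flat log records (numbers, strings, vectors)
mini_json <- function(x) {
  enc <- function(v) {
    if (is.list(v)) return(mini_json(v))
    if (length(v) > 1L)
      return(paste0("[", paste(vapply(v, enc, character(1L)),
                               collapse = ","), "]"))
    if (is.numeric(v)) return(format(v, digits = 10))
    paste0("\"", gsub("\"", "\\\\\"", as.character(v)), "\"")
  }
  paste0("{", paste(sprintf("\"%s\":%s", names(x),
                            vapply(x, enc, character(1L))),
                    collapse = ","), "}")
}
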