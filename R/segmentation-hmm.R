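#' Fit a two-state Gaussian HMM to a MACC track
#'
#' Chromatin accessibility states are modeled as a two-state hidden Markov
#' model with one Gaussian emission per state, fit by Baum-Welch EM over the
#' maximal gap-free runs of defined bins (runs are treated as independent
#' observation sequences; missing bins break sequences rather than being
#' imputed). EM is initialized from a 2-means split of the values; the best
#' of `n_restarts` runs by log-likelihood is kept, and states are relabeled
#' so that the state with the larger emission mean is "accessible".
#'
#' @param m A `macc_track` (or any `binned_track`).
#' @param n_restarts EM restarts (default 10).
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @param max_iter Maximum EM iterations per restart.
#' @param tol Convergence threshold on the log-likelihood gain (default 1e-6).
#' @param min_defined_bins Minimum number of defined bins required (default
#'   100).
#' @return An `hmm_model`: list with `init`, `trans` (2x2, rows sum to 1),
#'   `mu`, `sd` (accessible state first), `loglik`.
#' @export
fit_two_state_hmm <- function(m, n_restarts = 10L, seed = 1L,
                              max_iter = 500L, tol = 1e-6,
                              min_defined_bins = 100L) {
  seqs <- defined_runs(m)
  y_all <- unlist(seqs, use.names = FALSE)
  if (length(y_all) < min_defined_bins)
    stop("need at least ", min_defined_bins, " defined bins to fit the HMM")
  if (length(unique(y_all)) < 2L)
    stop("degenerate emissions: all defined values identical")
  fits <- local_seed(seed, {
    lapply(seq_len(n_restarts), function(r) {
      init_par <- hmm_init_params(y_all, perturb = r > 1L)
      tryCatch(baum_welch(seqs, init_par, max_iter = max_iter, tol = tol),
               error = function(e) NULL)
    })
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0L)
    stop("EM failed in all ", n_restarts, " restarts (check value range and ",
         "number of defined bins)")
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1L), "loglik"))]]
  # accessible = larger emission mean, stored first
  if (best$mu[1L] < best$mu[2L]) {
    ord <- c(2L, 1L)
    best$init <- best$init[ord]
    best$trans <- best$trans[ord, ord]
    best$mu <- best$mu[ord]
    best$sd <- best$sd[ord]
  }
  best$states <- c("accessible", "inaccessible")
  class(best) <- "hmm_model"
  best
}

#' @export
print.hmm_model <- function(x, ...) {
  cat("<hmm_model> two-state Gaussian HMM\n")
  cat(sprintf("  accessible:   mean %+.4f, sd %.4f, stay prob %.4f\n",
              x$mu[1L], x$sd[1L], x$trans[1L, 1L]))
  cat(sprintf("  inaccessible: mean %+.4f, sd %.4f, stay prob %.4f\n",
              x$mu[2L], x$sd[2L], x$trans[2L, 2L]))
  cat(sprintf("  log-likelihood: %.3f\n", x$loglik))
  invisible(x)
}

hmm_init_params <- function(y, perturb = FALSE) {
  km <- stats::kmeans(y, centers = 2L, nstart = 1L)
  mu <- as.numeric(km$centers)
  sd_ <- vapply(1:2, function(k) {
    s <- stats::sd(y[km$cluster == k])
    if (is.na(s) || s < 1e-8) s <- max(stats::sd(y) * 0.1, 1e-6)
    s
  }, numeric(1L))
  if (perturb) {
    mu <- mu + stats::rnorm(2L, 0, max(abs(diff(mu)), 1e-3) * 0.25)
    sd_ <- sd_ * exp(stats::rnorm(2L, 0, 0.2))
  }
  list(init = c(0.5, 0.5),
       trans = matrix(c(0.9, 0.1, 0.1, 0.9), 2L, 2L),
       mu = mu, sd = sd_)
}

baum_welch <- function(seqs, par, max_iter = 500L, tol = 1e-6) {
  prev_ll <- -Inf
  for (iter in seq_len(max_iter)) {
    est <- lapply(seqs, function(y)
      .hmm_estep(y, par$init, par$trans, par$mu, par$sd))
    ll <- sum(vapply(est, `[[`, numeric(1L), "loglik"))
    gamma <- do.call(rbind, lapply(est, `[[`, "gamma"))
    xi <- Reduce(`+`, lapply(est, `[[`, "xi_sum"))
    gamma_first <- Reduce(`+`, lapply(est, function(e) e$gamma[1L, ]))
    y_all <- unlist(seqs, use.names = FALSE)
    # M-step
    par$init <- gamma_first / sum(gamma_first)
    denom <- rowSums(xi)
    trans <- xi / ifelse(denom > 0, denom, 1)
    trans[denom == 0, ] <- c(0.5, 0.5)
    par$trans <- trans
    w <- colSums(gamma)
    par$mu <- as.numeric(crossprod(gamma, y_all)) / w
    par$sd <- sqrt(vapply(1:2, function(k)
      sum(gamma[, k] * (y_all - par$mu[k])^2), numeric(1L)) / w)
    par$sd <- pmax(par$sd, 1e-6)
    if (is.finite(ll) && ll - prev_ll < tol && iter > 1L) {
      prev_ll <- ll
      break
    }
    prev_ll <- ll
  }
  list(init = par$init, trans = par$trans, mu = par$mu, sd = par$sd,
       loglik = prev_ll, n_iter = iter)
}

# maximal gap-free runs of defined bins, as a flat list of numeric vectors;
# attributes record where each run sits on the track
defined_runs <- function(m) {
  seqs <- list()
  pos <- list()
  for (chrom in names(m$values)) {
    v <- m$values[[chrom]]
    r <- rle(!is.na(v))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      seqs[[length(seqs) + 1L]] <- v[starts[i]:ends[i]]
      pos[[length(pos) + 1L]] <- list(chrom = chrom, start = starts[i],
                                      end = ends[i])
    }
  }
  attr(seqs, "positions") <- pos
  seqs
}

#' Viterbi segmentation of a MACC track into accessibility states
#'
#' Decodes the most probable state path within each maximal gap-free run of
#' defined bins; missing bins are labeled `"missing"` and break runs.
#'
#' @param model An `hmm_model` from [fit_two_state_hmm()].
#' @param m The `macc_track` to segment.
#' @return A `state_segmentation`: list with `labels` (per-chromosome
#'   character vectors in accessible/inaccessible/missing) and `runs`
#'   (data.frame chrom, start_bin, end_bin (0-based, end exclusive), state,
#'   mean_value).
#' @export
viterbi_segment <- function(model, m) {
  stopifnot(inherits(model, "hmm_model"))
  validate_hmm_model(model)
  labels <- lapply(m$values, function(v) rep("missing", length(v)))
  seqs <- defined_runs(m)
  pos <- attr(seqs, "positions")
  for (i in seq_along(seqs)) {
    path <- .hmm_viterbi(seqs[[i]], model$init, model$trans, model$mu,
                         model$sd)
    p <- pos[[i]]
    labels[[p$chrom]][p$start:p$end] <- model$states[path]
  }
  runs <- segmentation_runs(labels, m)
  structure(list(labels = labels, runs = runs, bin_size = m$bin_size),
            class = "state_segmentation")
}

validate_hmm_model <- function(model) {
  stopifnot(length(model$mu) == 2L, length(model$sd) == 2L,
            all(model$sd > 0),
            all(abs(rowSums(model$trans) - 1) < 1e-9),
            all(model$trans >= 0), all(model$trans <= 1),
            all(model$init >= 0), abs(sum(model$init) - 1) < 1e-9)
  invisible(TRUE)
}

segmentation_runs <- function(labels, m) {
  out <- list()
  for (chrom in names(labels)) {
    lab <- labels[[chrom]]
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != "missing"
    if (!any(keep)) next
    mean_value <- vapply(which(keep), function(i)
      mean(m$values[[chrom]][starts[i]:ends[i]]), numeric(1L))
    out[[chrom]] <- data.frame(chrom = chrom,
                               start_bin = starts[keep] - 1L,
                               end_bin = ends[keep],
                               state = r$values[keep],
                               mean_value = mean_value,
                               stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(), start_bin = integer(),
                      end_bin = integer(), state = character(),
                      mean_value = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.state_segmentation <- function(x, ...) {
  st <- segment_stats(x)
  cat(sprintf("<state_segmentation> %d runs over %d chromosome(s)\n",
              nrow(x$runs), length(x$labels)))
  cat(sprintf("  accessible coverage: %.1f%%; median run lengths (bins): %s\n",
              100 * st$coverage[["accessible"]],
              paste(sprintf("%s=%g", names(st$median_run_length),
                            st$median_run_length), collapse = ", ")))
  invisible(x)
}

#' Shuffle a MACC track within each chromosome
#'
#' Defined values are permuted uniformly at random within their chromosome;
#' missing bins stay in place. Used to build the randomized null for run
#' statistics.
#'
#' @param m A `macc_track` or `binned_track`.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A track of the same class and grid.
#' @export
shuffle_track <- function(m, seed = 1L) {
  local_seed(seed, {
    m$values <- lapply(m$values, function(v) {
      idx <- which(!is.na(v))
      v[idx] <- v[idx[sample.int(length(idx))]]
      v
    })
  })
  m
}

#' Coverage and run-length statistics of a segmentation
#'
#' @param seg A `state_segmentation`.
#' @param shuffled_seg Optional segmentation of a shuffled track for
#'   comparison of median run lengths against the randomized null.
#' @return List with `coverage` (fraction of defined bins per state),
#'   `run_lengths` (list of integer vectors per state),
#'   `median_run_length`, and (when `shuffled_seg` is given)
#'   `shuffled_median_run_length`.
#' @export
segment_stats <- function(seg, shuffled_seg = NULL) {
  stopifnot(inherits(seg, "state_segmentation"))
  lab <- unlist(seg$labels, use.names = FALSE)
  def <- lab != "missing"
  if (!any(def)) stop("segmentation has no defined bins")
  states <- c("accessible", "inaccessible")
  coverage <- vapply(states, function(s) sum(lab[def] == s) / sum(def),
                     numeric(1L))
  run_lengths <- lapply(states, function(s)
    seg$runs$end_bin[seg$runs$state == s] -
      seg$runs$start_bin[seg$runs$state == s])
  names(run_lengths) <- states
  out <- list(coverage = coverage,
              run_lengths = run_lengths,
              median_run_length = vapply(run_lengths, function(x)
                if (length(x)) stats::median(as.numeric(x)) else NA_real_,
                numeric(1L)))
  if (!is.null(shuffled_seg)) {
    sstats <- segment_stats(shuffled_seg)
    out$shuffled_median_run_length <- sstats$median_run_length
  }
  out
}

#' Write a segmentation as BED
#'
#' @param seg A `state_segmentation`.
#' @param path Output BED path (name = state, score = mean MACC of the run).
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(seg, path) {
  runs <- seg$runs
  gr <- GenomicRanges::GRanges(
    runs$chrom,
    IRanges::IRanges(start = runs$start_bin * seg$bin_size + 1L,
                     end = runs$end_bin * seg$bin_size),
    name = runs$state,
    score = round(runs$mean_value, 6))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Save / load HMM parameters as a YAML sidecar
#' @param model An `hmm_model`.
#' @param path YAML path.
#' @return `path` invisibly (write) or an `hmm_model` (read).
#' @export
write_hmm_model <- function(model, path) {
  yaml::write_yaml(list(init = as.numeric(model$init),
                        trans = lapply(seq_len(2L), function(i)
                          as.numeric(model$trans[i, ])),
                        mu = as.numeric(model$mu),
                        sd = as.numeric(model$sd),
                        states = model$states,
                        loglik = as.numeric(model$loglik)), path,
                   precision = 12L)
  invisible(path)
}

#' @rdname write_hmm_model
#' @export
read_hmm_model <- function(path) {
  x <- yaml::read_yaml(path)
  model <- list(init = as.numeric(x$init),
                trans = do.call(rbind, lapply(x$trans, as.numeric)),
                mu = as.numeric(x$mu), sd = as.numeric(x$sd),
                states = x$states, loglik = x$loglik)
  class(model) <- "hmm_model"
  validate_hmm_model(model)
  model
}
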