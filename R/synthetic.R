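#' Simulation parameters for synthetic multi-caller peak sets
#'
#' Describes a ground-truth generative model for validating the cluster /
#' metacluster pipeline by parameter recovery: \code{n_sites} true binding
#' sites are placed on one chromosome far enough apart to stay resolvable,
#' and every (site, experiment, caller) triple emits a peak with probability
#' \code{detection_prob}, its center displaced from the site by rounded
#' Gaussian noise with a caller-specific SD. Each (experiment, caller) pair
#' additionally contributes Poisson-distributed spurious peaks placed
#' uniformly on the chromosome, independent across callers.
#'
#' Defaults emulate a well-studied TF: nine experiments (the typical corpus
#' depth per factor), caller center noise GEM 3 < PICS 5 < MACS 8 <
#' SISSRs 12 bp (consistent with the published caller-priority order), 80\%
#' detection probability and two spurious peaks per experiment and caller.
#'
#' @param genome_length Chromosome length in bp.
#' @param n_sites Number of true binding sites.
#' @param n_experiments Number of simulated ChIP-seq experiments.
#' @param callers Callers to simulate (subset of \code{callers()}).
#' @param center_noise_sd Named numeric vector, per-caller SD (bp) of the
#'   center localisation noise.
#' @param detection_prob Named numeric vector or scalar in [0, 1]: the
#'   probability a caller detects a given site in a given experiment.
#' @param fp_rate Named numeric vector or scalar >= 0: expected spurious
#'   peaks per experiment and caller.
#' @param peak_halfwidth Half-width (bp) of emitted peak intervals (GEM
#'   events are always unit length).
#' @param tf TF identifier attached to all simulated peaks.
#' @param seed Integer seed; the simulation is fully reproducible from it.
#' @return An object of class \code{sim_params}.
#' @export
sim_params <- function(genome_length = 1e6L, n_sites = 200L,
                       n_experiments = 9L, callers = metapeaks::callers(),
                       center_noise_sd = c(GEM = 3, PICS = 5, MACS = 8,
                                           SISSRS = 12),
                       detection_prob = 0.8, fp_rate = 2,
                       peak_halfwidth = 150L, tf = "TF1", seed = 1L) {
  callers <- normalize_callers(callers)
  center_noise_sd <- expand_by_caller(center_noise_sd, callers, "center_noise_sd")
  detection_prob <- expand_by_caller(detection_prob, callers, "detection_prob")
  fp_rate <- expand_by_caller(fp_rate, callers, "fp_rate")
  stopifnot(genome_length > 0, n_sites >= 0, n_experiments >= 1,
            all(center_noise_sd >= 0),
            all(detection_prob >= 0 & detection_prob <= 1),
            all(fp_rate >= 0), peak_halfwidth >= 1)
  structure(
    list(genome_length = as.integer(genome_length),
         n_sites = as.integer(n_sites),
         n_experiments = as.integer(n_experiments),
         callers = callers, center_noise_sd = center_noise_sd,
         detection_prob = detection_prob, fp_rate = fp_rate,
         peak_halfwidth = as.integer(peak_halfwidth),
         tf = as.character(tf), seed = as.integer(seed)),
    class = "sim_params"
  )
}

expand_by_caller <- function(x, callers, what) {
  if (is.null(names(x))) {
    if (length(x) == 1L) return(stats::setNames(rep(as.numeric(x), length(callers)), callers))
    stop(what, " must be a scalar or named by caller", call. = FALSE)
  }
  names(x) <- normalize_callers(names(x))
  missing <- setdiff(callers, names(x))
  if (length(missing))
    stop(what, " lacks value(s) for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  stats::setNames(as.numeric(x[callers]), callers)
}

# Run expr under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate multi-experiment, multi-caller peak sets with known truth
#'
#' Draws true site positions and per-(site, experiment, caller) peak calls
#' under the model described in \code{\link{sim_params}}. Sites are placed
#' with pairwise gaps strictly greater than
#' \code{2 * (4 * max(center_noise_sd) + 50)} bp so that neighbouring sites
#' cannot be chained into one cluster at the default merge distance. Peak
#' geometry follows each caller's reporting convention: GEM emits a
#' unit-length interval at the (noisy) center; MACS emits
#' \code{center +/- peak_halfwidth} with the summit offset pointing at the
#' center; PICS and SISSRs emit \code{center +/- peak_halfwidth} so their
#' geometric center is the noisy center.
#'
#' @param params A \code{\link{sim_params}} object.
#' @return A list of class \code{synthetic_peaks} with elements
#'   \code{truth} (class \code{synthetic_truth}: \code{site_positions},
#'   \code{params}) and \code{peaks} (a \code{peaks} table).
#' @examples
#' sim <- simulate_peaks(sim_params(n_sites = 5, seed = 42))
#' sim$truth$site_positions
#' nrow(sim$peaks)
#' @export
simulate_peaks <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, {
    hw <- params$peak_halfwidth
    max_sd <- if (length(params$center_noise_sd)) max(params$center_noise_sd) else 0
    min_gap <- floor(2 * (4 * max_sd + 50)) + 1L   # strictly > the resolvability bound
    margin <- hw + ceiling(4 * max_sd) + 1L
    sites <- place_sites(params$n_sites, params$genome_length, min_gap, margin)

    recs <- list()
    for (cl in params$callers) {
      sd_cl <- params$center_noise_sd[[cl]]
      p_det <- params$detection_prob[[cl]]
      fp <- params$fp_rate[[cl]]
      for (e in seq_len(params$n_experiments)) {
        eid <- sprintf("exp%02d", e)
        detected <- if (params$n_sites)
          which(stats::runif(params$n_sites) < p_det) else integer()
        ctr <- integer()
        if (length(detected))
          ctr <- sites[detected] +
            as.integer(round(stats::rnorm(length(detected), 0, sd_cl)))
        n_fp <- stats::rpois(1L, fp)
        if (n_fp > 0L)
          ctr <- c(ctr, as.integer(floor(stats::runif(
            n_fp, hw, params$genome_length - hw - 1L))))
        if (!length(ctr)) next
        ctr <- pmin(pmax(ctr, hw), params$genome_length - hw - 1L)
        recs[[length(recs) + 1L]] <- caller_peak_geometry(ctr, cl, hw, eid,
                                                          params$tf)
      }
    }
    pk <- if (length(recs)) do.call(rbind, recs) else as.data.frame(empty_peaks())
    rownames(pk) <- NULL
    truth <- structure(list(site_positions = sites, params = params),
                       class = "synthetic_truth")
    structure(list(truth = truth, peaks = validate_peaks(pk)),
              class = "synthetic_peaks")
  })
}

# Uniformly scatter n sites in [margin, genome_length - margin) with
# pairwise gaps >= min_gap (strictly increasing positions).
place_sites <- function(n, genome_length, min_gap, margin) {
  if (n == 0L) return(integer())
  span <- genome_length - 2 * margin - (n - 1) * min_gap
  if (span < n)
    stop(sprintf(paste("cannot place %d sites with required spacing %d bp on a",
                       "%d bp chromosome"), n, min_gap, genome_length),
         call. = FALSE)
  slack <- sort(floor(stats::runif(n, 0, span)))
  as.integer(margin + slack + (seq_len(n) - 1L) * min_gap)
}

caller_peak_geometry <- function(centers, caller, halfwidth, experiment_id, tf) {
  if (caller == "GEM") {
    start <- centers; end <- centers + 1L; summit <- NA_integer_
  } else {
    start <- centers - halfwidth; end <- centers + halfwidth
    summit <- if (caller == "MACS") centers - start else NA_integer_
  }
  data.frame(chrom = "chr1", start = as.integer(start), end = as.integer(end),
             summit_offset = as.integer(summit), caller = caller,
             experiment_id = experiment_id, tf = tf, stringsAsFactors = FALSE)
}

#' @export
print.synthetic_peaks <- function(x, ...) {
  cat(sprintf("Synthetic peak set: %d true site(s), %d peak(s), %d experiment(s), callers %s\n",
              length(x$truth$site_positions), nrow(x$peaks),
              x$truth$params$n_experiments,
              paste(x$truth$params$callers, collapse = ",")))
  invisible(x)
}

#' Write the ground-truth site table
#'
#' Two-column TSV: site index and 0-based position.
#'
#' @param truth A \code{synthetic_truth} object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  out <- data.frame(site = seq_along(truth$site_positions),
                    position = truth$site_positions)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a ground-truth site table written by \code{write_truth}
#'
#' @param path Path to the TSV.
#' @return A \code{synthetic_truth} object (without generation parameters).
#' @export
read_truth <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t")
  structure(list(site_positions = as.integer(df$position), params = NULL),
            class = "synthetic_truth")
}

#' Score recovered sites against the simulated truth
#'
#' Matches predicted site centers to true sites by greedy one-to-one
#' nearest-neighbour assignment among all pairs within
#' \code{match_distance} bp, then reports recall (fraction of true sites
#' matched), precision (fraction of predictions matched; \code{NA} and
#' flagged not-applicable when there are no predictions) and the RMSE of
#' the matched center errors.
#'
#' @param truth A \code{synthetic_truth} object.
#' @param predicted A \code{metaclusters} or \code{peak_clusters} object,
#'   or any data.frame with a \code{center} column, or a bare integer
#'   vector of predicted positions.
#' @param match_distance Maximum |prediction - site| (bp) for a match.
#'   Default 50, mirroring the merge threshold.
#' @return A list of class \code{recovery_report}: \code{n_sites},
#'   \code{n_predicted}, \code{n_matched}, \code{recall}, \code{precision},
#'   \code{precision_applicable}, \code{rmse}, \code{matched} (data.frame
#'   of site/prediction pairs and errors).
#' @examples
#' truth <- structure(list(site_positions = c(100L, 900L)),
#'                    class = "synthetic_truth")
#' evaluate_recovery(truth, c(102L, 905L))$recall  # 1
#' @export
evaluate_recovery <- function(truth, predicted, match_distance = 50) {
  stopifnot(inherits(truth, "synthetic_truth"))
  centers <- if (is.data.frame(predicted)) as.integer(predicted$center)
             else as.integer(predicted)
  sites <- truth$site_positions
  pairs <- greedy_match(sites, centers, match_distance)
  n_matched <- nrow(pairs)
  rmse <- if (n_matched) sqrt(mean(pairs$error^2)) else NA_real_
  structure(list(
    n_sites = length(sites), n_predicted = length(centers),
    n_matched = n_matched,
    recall = if (length(sites)) n_matched / length(sites) else NA_real_,
    precision = if (length(centers)) n_matched / length(centers) else NA_real_,
    precision_applicable = length(centers) > 0L,
    rmse = rmse, matched = pairs
  ), class = "recovery_report")
}

# Greedy one-to-one matching: repeatedly take the closest unmatched
# (site, prediction) pair within match_distance.
greedy_match <- function(sites, centers, match_distance) {
  empty <- data.frame(site = integer(), prediction = integer(),
                      error = integer())
  if (!length(sites) || !length(centers)) return(empty)
  d <- abs(outer(sites, centers, "-"))
  cand <- which(d <= match_distance, arr.ind = TRUE)
  if (!nrow(cand)) return(empty)
  cand <- cand[order(d[cand], cand[, 1L], cand[, 2L]), , drop = FALSE]
  used_s <- logical(length(sites)); used_c <- logical(length(centers))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1L]; j <- cand[k, 2L]
    if (!used_s[i] && !used_c[j]) {
      keep[k] <- TRUE; used_s[i] <- TRUE; used_c[j] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(site = cand[, 1L], prediction = cand[, 2L],
             error = centers[cand[, 2L]] - sites[cand[, 1L]])
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Site recovery:\n")
  cat(sprintf("  true sites:  %d\n  predicted:   %d\n  matched:     %d\n",
              x$n_sites, x$n_predicted, x$n_matched))
  cat(sprintf("  recall:      %s\n", format(x$recall, digits = 4)))
  cat(sprintf("  precision:   %s\n",
              if (x$precision_applicable) format(x$precision, digits = 4)
              else "n/a (no predictions)"))
  cat(sprintf("  center RMSE: %s bp\n",
              if (is.na(x$rmse)) "n/a" else format(x$rmse, digits = 4)))
  invisible(x)
}
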