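#' Recognised peak callers, in fallback priority order
#'
#' The four peak callers whose outputs can be merged: GEM, PICS, MACS and
#' SISSRs. The vector is ordered by the published caller priority (best
#' first), which doubles as the tie-break / fallback order wherever a
#' data-driven priority cannot decide.
#'
#' @return Character vector of caller names.
#' @export
callers <- function() c("GEM", "PICS", "MACS", "SISSRS")

#' Clustering parameters
#'
#' Bundles the tunable parameters of cluster and metacluster construction:
#' the single-linkage merge distance between peak (or cluster) centers, the
#' default motif length used when a TF has no known motif, and the multiplier
#' applied to the within-cluster SD when deriving cluster width.
#'
#' @param merge_distance Maximum center-to-center distance (bp) at which two
#'   peaks (or clusters) are chained into one group. Default 50.
#' @param default_motif_length Assumed protein-DNA contact length (bp) for
#'   TFs absent from the motif-length table. Default 20.
#' @param sd_multiplier Multiplier applied to the within-cluster SD of peak
#'   centers to obtain the positional-uncertainty term of cluster width.
#'   Default 4.
#' @return An object of class \code{cluster_params}.
#' @examples
#' cluster_params()
#' cluster_params(merge_distance = 100)
#' @export
cluster_params <- function(merge_distance = 50L,
                           default_motif_length = 20L,
                           sd_multiplier = 4) {
  merge_distance <- as.integer(merge_distance)
  default_motif_length <- as.integer(default_motif_length)
  sd_multiplier <- as.numeric(sd_multiplier)
  if (is.na(merge_distance) || merge_distance < 0L)
    stop("merge_distance must be a non-negative integer", call. = FALSE)
  if (is.na(default_motif_length) || default_motif_length < 1L)
    stop("default_motif_length must be a positive integer", call. = FALSE)
  if (is.na(sd_multiplier) || sd_multiplier < 0)
    stop("sd_multiplier must be non-negative", call. = FALSE)
  structure(
    list(merge_distance = merge_distance,
         default_motif_length = default_motif_length,
         sd_multiplier = sd_multiplier),
    class = "cluster_params"
  )
}

#' @export
print.cluster_params <- function(x, ...) {
  cat("Cluster parameters:\n")
  cat("  merge distance:      ", x$merge_distance, "bp\n")
  cat("  default motif length:", x$default_motif_length, "bp\n")
  cat("  SD multiplier:       ", x$sd_multiplier, "\n")
  invisible(x)
}

#' Fixed caller priority
#'
#' Constructs a caller-priority object from an explicit ordering (best
#' first). The default is the published order GEM > PICS > MACS > SISSRs,
#' obtained by ranking callers by the median within-cluster SD of their peak
#' centers. Use \code{\link{calibrate_priority}} to re-derive the order from
#' a given cluster set instead.
#'
#' @param order Character vector of caller names, best first. Must be a
#'   subset of \code{callers()} without duplicates.
#' @param median_sd Optional named numeric vector of per-caller median SDs
#'   backing the ordering (filled in by \code{calibrate_priority}).
#' @return An object of class \code{caller_priority}.
#' @examples
#' caller_priority()                      # published order
#' caller_priority(c("MACS", "GEM"))      # custom two-caller ranking
#' @seealso \code{\link{calibrate_priority}}
#' @export
caller_priority <- function(order = callers(), median_sd = NULL) {
  order <- normalize_callers(order)
  if (anyDuplicated(order))
    stop("duplicated caller in priority order", call. = FALSE)
  if (!is.null(median_sd)) {
    median_sd <- median_sd[order]
    names(median_sd) <- order
  }
  structure(list(order = order, median_sd = median_sd),
            class = "caller_priority")
}

#' @export
print.caller_priority <- function(x, ...) {
  cat("Caller priority:", paste(x$order, collapse = " > "), "\n")
  if (!is.null(x$median_sd)) {
    cat("Median within-cluster SD (bp):\n")
    for (cl in x$order)
      cat(sprintf("  %-7s %s\n", cl,
                  ifelse(is.na(x$median_sd[[cl]]), "n/a (no eligible clusters)",
                         format(x$median_sd[[cl]], digits = 4))))
  }
  invisible(x)
}

# Validate caller names case-insensitively against the enum; returns the
# canonical upper-case spellings ("SISSRs" dialects map to "SISSRS").
normalize_callers <- function(x) {
  up <- toupper(trimws(as.character(x)))
  ok <- up %in% callers()
  if (!all(ok)) {
    stop(sprintf("unknown peak caller(s): %s (accepted values: %s)",
                 paste(unique(x[!ok]), collapse = ", "),
                 paste(callers(), collapse = ", ")),
         call. = FALSE)
  }
  up
}
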