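#' Group peak centers by single-linkage chaining
#'
#' Partitions peak centers on one chromosome into groups such that, after
#' sorting, adjacent centers within a group are at most \code{merge_distance}
#' bp apart, while consecutive groups are separated by more than
#' \code{merge_distance} bp. This is single-linkage (transitive) chaining:
#' two centers share a group whenever a chain of within-threshold gaps
#' connects them. A distance of exactly \code{merge_distance} joins
#' ("50 bp from each other or closer").
#'
#' @param centers A data.frame of peak centers as produced by
#'   \code{\link{peak_centers}} (all rows must share one chromosome, one TF
#'   and one caller), or a bare integer vector of positions.
#' @param merge_distance Chaining threshold in bp.
#' @return A list of groups ordered by genomic position; each element is a
#'   subset of \code{centers} (rows sorted by position) or, for vector
#'   input, a sorted integer vector.
#' @examples
#' group_centers(c(100L, 150L), 50)   # one group: gap of exactly 50 joins
#' group_centers(c(100L, 151L), 50)   # two groups
#' @export
group_centers <- function(centers, merge_distance) {
  merge_distance <- as.numeric(merge_distance)
  if (is.na(merge_distance) || merge_distance < 0)
    stop("merge_distance must be non-negative", call. = FALSE)
  if (is.data.frame(centers)) {
    if (nrow(centers) == 0L) return(list())
    if (length(unique(centers$chrom)) > 1L)
      stop("group_centers() requires centers from a single chromosome",
           call. = FALSE)
    if (length(unique(centers$tf)) > 1L || length(unique(centers$caller)) > 1L)
      stop("group_centers() requires centers from a single TF and caller",
           call. = FALSE)
    ids <- chain_group_ids(centers$position, merge_distance)
    ord <- order(centers$position)
    split(centers[ord, , drop = FALSE], ids[ord])
  } else {
    pos <- as.integer(centers)
    if (!length(pos)) return(list())
    ids <- chain_group_ids(pos, merge_distance)
    ord <- order(pos)
    unname(split(pos[ord], ids[ord]))
  }
}

# Single-linkage chaining over positions: sort, start a new group wherever
# the gap to the previous position exceeds the threshold. Returns group ids
# aligned with the input order, numbered by genomic position.
chain_group_ids <- function(positions, merge_distance) {
  ord <- order(positions)
  sorted <- positions[ord]
  breaks <- c(1L, as.integer(diff(sorted) > merge_distance))
  ids_sorted <- cumsum(breaks)
  ids <- integer(length(positions))
  ids[ord] <- ids_sorted
  ids
}

#' Cluster center: median of member peak centers
#'
#' For an odd member count this is the middle value; for an even count, the
#' floor of the mean of the two middle values, keeping centers integral.
#'
#' @param member_centers Integer vector of peak-center positions (non-empty).
#' @return Integer center position.
#' @examples
#' cluster_center(c(100L, 110L, 120L))  # 110
#' cluster_center(c(100L, 111L))        # 105
#' @export
cluster_center <- function(member_centers) {
  n <- length(member_centers)
  if (n == 0L) stop("cluster_center() of an empty set", call. = FALSE)
  s <- sort(as.numeric(member_centers))
  if (n %% 2L == 1L) {
    as.integer(s[(n + 1L) / 2L])
  } else {
    as.integer(floor((s[n / 2L] + s[n / 2L + 1L]) / 2))
  }
}

#' Within-cluster SD of peak centers
#'
#' Sample standard deviation (n - 1 denominator) of the member peak-center
#' positions. A singleton cluster has no defined scatter; \code{NA} is
#' returned as the needs-imputation signal (see
#' \code{\link{impute_singleton_sd}}).
#'
#' @param member_centers Integer vector of peak-center positions (non-empty).
#' @return Non-negative numeric SD in bp, or \code{NA_real_} for a singleton.
#' @examples
#' cluster_sd(c(100L, 110L, 120L))  # 10
#' cluster_sd(42L)                  # NA: needs imputation
#' @export
cluster_sd <- function(member_centers) {
  n <- length(member_centers)
  if (n == 0L) stop("cluster_sd() of an empty set", call. = FALSE)
  if (n == 1L) return(NA_real_)
  stats::sd(member_centers)
}

#' Imputed SD for single-peak clusters
#'
#' A cluster supported by a single peak takes the median of the SD values of
#' all other clusters (those with at least two member peaks). When no such
#' cluster exists the imputed SD is 0, i.e. the width reduces to the motif
#' length.
#'
#' @param all_cluster_sds Numeric vector of SDs from clusters with >= 2
#'   members (may be empty).
#' @return Numeric imputed SD in bp.
#' @examples
#' impute_singleton_sd(c(2, 4, 10))  # 4
#' impute_singleton_sd(numeric())    # 0
#' @export
impute_singleton_sd <- function(all_cluster_sds) {
  all_cluster_sds <- all_cluster_sds[!is.na(all_cluster_sds)]
  if (!length(all_cluster_sds)) return(0)
  stats::median(all_cluster_sds)
}

#' Cluster width from motif length and center scatter
#'
#' Width = assumed protein-DNA contact length (the TF's motif length) plus
#' an uncertainty term, \code{sd_multiplier} times the within-cluster SD of
#' peak centers, rounded half-up to an integer number of bp.
#'
#' @param sd Non-negative SD of member peak centers (bp).
#' @param motif_length Motif length (bp, >= 1).
#' @param sd_multiplier Uncertainty multiplier (default 4).
#' @return Integer width in bp.
#' @examples
#' cluster_width(0, 20)    # 20: zero scatter, default footprint
#' cluster_width(10, 12)   # 52 = 12 + 4 * 10
#' @export
cluster_width <- function(sd, motif_length, sd_multiplier = 4) {
  stopifnot(all(sd >= 0), all(motif_length >= 1))
  as.integer(motif_length) + as.integer(floor(sd_multiplier * sd + 0.5))
}

#' Build peak clusters per (TF, caller)
#'
#' Implements the cluster-construction step: peaks for the same TF and the
#' same caller, typically from different experiments, are reduced to their
#' caller-specific centers and merged by single-linkage chaining at
#' \code{merge_distance} bp per chromosome. Each cluster records the median
#' of its member centers as its center, the sample SD of the member centers
#' (imputed for singletons from the median SD of the same TF/caller's other
#' clusters), and a width of motif length plus \code{sd_multiplier} * SD.
#' The cluster interval is placed symmetrically about the center:
#' \code{[center - floor(width/2), center - floor(width/2) + width)}.
#'
#' @param x A \code{peaks} table (may span TFs, callers and chromosomes).
#' @param motif_lengths A \code{\link{motif_length_table}}, or \code{NULL}
#'   to use the default length from \code{params} for every TF.
#' @param params A \code{\link{cluster_params}} object.
#' @return A \code{data.frame} of class \code{peak_clusters}, sorted by
#'   (tf, caller, chrom, start), with columns \code{tf}, \code{caller},
#'   \code{chrom}, \code{start}, \code{end}, \code{center}, \code{sd},
#'   \code{sd_imputed}, \code{peak_count}, \code{width} and a list-column
#'   \code{members} holding each cluster's member peak centers.
#' @examples
#' p <- peaks(chrom = "chr1", start = c(995L, 1003L), end = c(996L, 1004L),
#'            caller = "GEM", experiment_id = c("e1", "e2"), tf = "USF1")
#' cl <- build_clusters(p, motif_length_table(c(USF1 = 12L)))
#' cl$center  # 999, the floor-median of 995 and 1003
#' @export
build_clusters <- function(x, motif_lengths = NULL, params = cluster_params()) {
  stopifnot(inherits(params, "cluster_params"))
  if (is.null(motif_lengths))
    motif_lengths <- motif_length_table(default_length = params$default_motif_length)
  stopifnot(inherits(motif_lengths, "motif_length_table"))
  centers <- peak_centers(x)
  if (nrow(centers) == 0L) return(empty_clusters())

  rows <- list()
  for (key_tc in split(centers, list(centers$tf, centers$caller), drop = TRUE)) {
    tf <- key_tc$tf[1]; caller <- key_tc$caller[1]
    groups <- list()
    for (key_chr in split(key_tc, key_tc$chrom, drop = TRUE))
      groups <- c(groups, group_centers(key_chr, params$merge_distance))
    sds <- vapply(groups, function(g) cluster_sd(g$position), numeric(1))
    imputed_sd <- impute_singleton_sd(sds)
    for (i in seq_along(groups)) {
      g <- groups[[i]]
      center <- cluster_center(g$position)
      imputed <- is.na(sds[i])
      sd_i <- if (imputed) imputed_sd else sds[i]
      width <- cluster_width(sd_i, motif_length(motif_lengths, tf),
                             params$sd_multiplier)
      start <- center - width %/% 2L
      rows[[length(rows) + 1L]] <- list(
        tf = tf, caller = caller, chrom = g$chrom[1],
        start = start, end = start + width, center = center,
        sd = sd_i, sd_imputed = imputed,
        peak_count = nrow(g), width = width,
        members = g[, c("chrom", "position", "experiment_id", "peak_id")]
      )
    }
  }
  df <- data.frame(
    tf = vapply(rows, `[[`, character(1), "tf"),
    caller = vapply(rows, `[[`, character(1), "caller"),
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    start = vapply(rows, `[[`, integer(1), "start"),
    end = vapply(rows, `[[`, integer(1), "end"),
    center = vapply(rows, `[[`, integer(1), "center"),
    sd = vapply(rows, `[[`, numeric(1), "sd"),
    sd_imputed = vapply(rows, `[[`, logical(1), "sd_imputed"),
    peak_count = vapply(rows, `[[`, integer(1), "peak_count"),
    width = vapply(rows, `[[`, integer(1), "width"),
    stringsAsFactors = FALSE
  )
  df$members <- lapply(rows, `[[`, "members")
  ord <- order(df$tf, df$caller, df$chrom, df$start)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  as_peak_clusters(df)
}

as_peak_clusters <- function(df) {
  class(df) <- c("peak_clusters", "data.frame")
  df
}

empty_clusters <- function() {
  df <- data.frame(
    tf = character(), caller = character(), chrom = character(),
    start = integer(), end = integer(), center = integer(),
    sd = numeric(), sd_imputed = logical(), peak_count = integer(),
    width = integer(), stringsAsFactors = FALSE
  )
  df$members <- list()
  as_peak_clusters(df)
}

#' @export
print.peak_clusters <- function(x, n = 10L, ...) {
  cat(sprintf("Peak clusters: %d cluster(s), %d TF(s), %d caller(s)\n",
              nrow(x), length(unique(x$tf)), length(unique(x$caller))))
  if (nrow(x)) {
    shown <- utils::head(as.data.frame(x)[setdiff(names(x), "members")], n)
    print(shown, ...)
    if (nrow(x) > n) cat("... and", nrow(x) - n, "more\n")
  }
  invisible(x)
}

#' @method summary peak_clusters
#' @export
summary.peak_clusters <- function(object, ...) {
  if (!nrow(object)) {
    cat("Empty cluster set\n")
    return(invisible(object))
  }
  cat(sprintf("Peak clusters: %d total; %d member peaks\n",
              nrow(object), sum(object$peak_count)))
  by_caller <- split(object, object$caller)
  for (cl in names(by_caller)) {
    b <- by_caller[[cl]]
    eligible <- b$sd[!b$sd_imputed]
    cat(sprintf("  %-7s %5d clusters, median peak count %g, median SD %s bp\n",
                cl, nrow(b), stats::median(b$peak_count),
                if (length(eligible)) format(stats::median(eligible), digits = 3)
                else "n/a"))
  }
  invisible(object)
}
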