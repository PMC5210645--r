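#' Calibrate caller priority from cluster center scatter
#'
#' Ranks peak callers by the median of their within-cluster SDs of peak
#' centers: a caller whose clusters show less center scatter localises
#' binding positions more precisely and gets higher priority. Only
#' directly-computed SDs contribute (clusters with >= 2 member peaks;
#' imputed singleton SDs are excluded). Callers present in the input but
#' with no eligible cluster are ranked last; ties and the ordering among
#' such callers fall back to the fixed order GEM > PICS > MACS > SISSRs.
#'
#' @param clusters A \code{peak_clusters} table (non-empty).
#' @return A \code{\link{caller_priority}} object whose \code{median_sd}
#'   field records the per-caller medians used.
#' @examples
#' p <- simulate_peaks(sim_params(n_sites = 50, seed = 7))
#' cl <- build_clusters(p$peaks)
#' calibrate_priority(cl)
#' @export
calibrate_priority <- function(clusters) {
  stopifnot(inherits(clusters, "peak_clusters"))
  if (nrow(clusters) == 0L)
    stop("nothing to calibrate: no clusters supplied", call. = FALSE)
  present <- unique(clusters$caller)
  med <- vapply(present, function(cl) {
    sds <- clusters$sd[clusters$caller == cl & !clusters$sd_imputed]
    if (length(sds)) stats::median(sds) else NA_real_
  }, numeric(1))
  fallback_rank <- match(present, callers())
  # ascending median SD; NA (no eligible clusters) last; ties by fallback
  ord <- order(is.na(med), med, fallback_rank)
  caller_priority(order = present[ord],
                  median_sd = stats::setNames(med, present))
}

#' Group clusters of one TF across callers
#'
#' Single-linkage chaining of cluster centers at \code{merge_distance} bp,
#' per chromosome and across callers — the same semantics as
#' \code{\link{group_centers}}, one level up.
#'
#' @param clusters A \code{peak_clusters} table for a single TF.
#' @param merge_distance Chaining threshold in bp.
#' @return A list of \code{peak_clusters} subsets, ordered by chromosome
#'   then position; each subset's rows are sorted by center.
#' @export
group_clusters <- function(clusters, merge_distance) {
  stopifnot(inherits(clusters, "peak_clusters"))
  if (nrow(clusters) == 0L) return(list())
  if (length(unique(clusters$tf)) > 1L)
    stop("group_clusters() requires clusters of a single TF", call. = FALSE)
  out <- list()
  for (chrom in sort(unique(clusters$chrom))) {
    sub <- clusters[clusters$chrom == chrom, , drop = FALSE]
    ids <- chain_group_ids(sub$center, merge_distance)
    ord <- order(sub$center)
    out <- c(out, lapply(split(seq_len(nrow(sub))[ord], ids[ord]),
                         function(i) as_peak_clusters(sub[i, , drop = FALSE])))
  }
  unname(out)
}

#' Select the representative cluster of a group
#'
#' Picks the member produced by the highest-priority caller. When that
#' caller contributes several members (chaining can pull in more than one),
#' the member whose center is nearest the group's median center wins;
#' remaining ties go to the leftmost.
#'
#' @param group A \code{peak_clusters} subset (non-empty, one TF/chrom).
#' @param priority A \code{\link{caller_priority}} object.
#' @return A one-row \code{peak_clusters} table.
#' @export
select_representative <- function(group, priority) {
  stopifnot(inherits(priority, "caller_priority"), nrow(group) >= 1L)
  rank <- match(group$caller, priority$order)
  rank[is.na(rank)] <- length(priority$order) + 1L  # unranked callers last
  cand <- which(rank == min(rank))
  if (length(cand) > 1L) {
    med <- cluster_center(group$center)
    d <- abs(group$center[cand] - med)
    cand <- cand[order(d, group$center[cand], group$start[cand])][1L]
  }
  as_peak_clusters(group[cand[1L], , drop = FALSE])
}

#' Build metaclusters: cross-caller consensus binding sites
#'
#' Groups clusters of the same TF whose centers lie within
#' \code{merge_distance} bp of each other (single-linkage, per chromosome,
#' across callers), drops groups supported by only one distinct caller, and
#' represents each surviving group by its highest-priority member cluster,
#' whose interval and center the metacluster adopts verbatim. The result is
#' treated as a non-redundant set of TF binding sites.
#'
#' @param clusters A \code{peak_clusters} table (may span TFs and
#'   chromosomes).
#' @param priority A \code{\link{caller_priority}} object; defaults to the
#'   published fixed order GEM > PICS > MACS > SISSRs. Pass the result of
#'   \code{\link{calibrate_priority}} to use a data-driven ranking.
#' @param params A \code{\link{cluster_params}} object (only
#'   \code{merge_distance} is used here).
#' @return A \code{data.frame} of class \code{metaclusters}, sorted by
#'   (tf, chrom, start), with columns \code{tf}, \code{chrom}, \code{start},
#'   \code{end}, \code{center}, \code{representative_caller},
#'   \code{n_callers}, \code{n_clusters} and list-columns
#'   \code{supporting_callers} (distinct callers, sorted) and
#'   \code{member_clusters} (per-member provenance).
#' @export
build_metaclusters <- function(clusters, priority = caller_priority(),
                               params = cluster_params()) {
  stopifnot(inherits(clusters, "peak_clusters"),
            inherits(priority, "caller_priority"),
            inherits(params, "cluster_params"))
  if (nrow(clusters) == 0L) return(empty_metaclusters())
  rows <- list()
  for (sub in split(clusters, clusters$tf)) {
    groups <- group_clusters(as_peak_clusters(sub), params$merge_distance)
    for (g in groups) {
      support <- sort(unique(g$caller))
      if (length(support) < 2L) next  # one-caller metaclusters are filtered out
      rep <- select_representative(g, priority)
      rows[[length(rows) + 1L]] <- list(
        tf = rep$tf, chrom = rep$chrom, start = rep$start, end = rep$end,
        center = rep$center, representative_caller = rep$caller,
        n_callers = length(support), n_clusters = nrow(g),
        supporting_callers = support,
        member_clusters = as.data.frame(g)[, c("caller", "chrom", "start",
                                               "end", "center", "sd",
                                               "peak_count")]
      )
    }
  }
  if (!length(rows)) return(empty_metaclusters())
  df <- data.frame(
    tf = vapply(rows, `[[`, character(1), "tf"),
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    start = vapply(rows, `[[`, integer(1), "start"),
    end = vapply(rows, `[[`, integer(1), "end"),
    center = vapply(rows, `[[`, integer(1), "center"),
    representative_caller = vapply(rows, `[[`, character(1),
                                   "representative_caller"),
    n_callers = vapply(rows, `[[`, integer(1), "n_callers"),
    n_clusters = vapply(rows, `[[`, integer(1), "n_clusters"),
    stringsAsFactors = FALSE
  )
  df$supporting_callers <- lapply(rows, `[[`, "supporting_callers")
  df$member_clusters <- lapply(rows, `[[`, "member_clusters")
  ord <- order(df$tf, df$chrom, df$start)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  as_metaclusters(df)
}

as_metaclusters <- function(df) {
  class(df) <- c("metaclusters", "data.frame")
  df
}

empty_metaclusters <- function() {
  df <- data.frame(
    tf = character(), chrom = character(), start = integer(),
    end = integer(), center = integer(),
    representative_caller = character(), n_callers = integer(),
    n_clusters = integer(), stringsAsFactors = FALSE
  )
  df$supporting_callers <- list()
  df$member_clusters <- list()
  as_metaclusters(df)
}

#' @export
print.metaclusters <- function(x, n = 10L, ...) {
  cat(sprintf("Metaclusters: %d consensus site(s), %d TF(s)\n",
              nrow(x), length(unique(x$tf))))
  if (nrow(x)) {
    shown <- as.data.frame(x)[setdiff(names(x),
                                      c("supporting_callers", "member_clusters"))]
    shown$callers <- vapply(x$supporting_callers, paste, character(1),
                            collapse = ",")
    print(utils::head(shown, n), ...)
    if (nrow(x) > n) cat("... and", nrow(x) - n, "more\n")
  }
  invisible(x)
}

#' @method summary metaclusters
#' @export
summary.metaclusters <- function(object, ...) {
  if (!nrow(object)) {
    cat("Empty metacluster set\n")
    return(invisible(object))
  }
  cat(sprintf("Metaclusters: %d; supporting callers 2:%d 3:%d 4:%d\n",
              nrow(object), sum(object$n_callers == 2L),
              sum(object$n_callers == 3L), sum(object$n_callers == 4L)))
  cat("Representative caller usage:\n")
  print(table(object$representative_caller))
  invisible(object)
}

#' Write a caller-priority table
#'
#' Three-column TSV: caller, median within-cluster SD (empty when no
#' eligible cluster backed the caller), and rank (1 = highest priority).
#'
#' @param priority A \code{\link{caller_priority}} object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_priority <- function(priority, path) {
  stopifnot(inherits(priority, "caller_priority"))
  med <- priority$median_sd
  med_col <- if (is.null(med)) rep("", length(priority$order)) else {
    v <- med[priority$order]
    ifelse(is.na(v), "", formatC(v, format = "f", digits = 4))
  }
  out <- data.frame(caller = priority$order, median_sd = med_col,
                    rank = seq_along(priority$order),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
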