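#' Pipeline configuration
#'
#' Collects everything one end-to-end run needs: peak inputs, the optional
#' motif-length table, clustering parameters, the caller-priority mode and
#' the output directory. Validation happens here, before any I/O.
#'
#' @param peaks Character vector of interchange-TSV paths, and/or a
#'   \code{peaks} table supplied directly (narrowPeak inputs should be read
#'   with \code{\link{read_narrowpeak}} first, since they need an
#'   experiment id and TF).
#' @param motif_lengths Path to a motif-length TSV, a
#'   \code{\link{motif_length_table}}, or \code{NULL}.
#' @param params A \code{\link{cluster_params}} object.
#' @param priority \code{"fixed"} (published order GEM > PICS > MACS >
#'   SISSRs), \code{"auto"} (recalibrate from the clusters), a character
#'   vector of caller names (best first), or a
#'   \code{\link{caller_priority}} object.
#' @param out_dir Output directory (created if missing).
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(peaks, motif_lengths = NULL,
                            params = cluster_params(),
                            priority = "fixed", out_dir = ".") {
  stopifnot(inherits(params, "cluster_params"))
  if (is.character(peaks)) {
    missing <- peaks[!file.exists(peaks)]
    if (length(missing))
      stop("peak input file(s) not found: ", paste(missing, collapse = ", "),
           call. = FALSE)
  } else if (!inherits(peaks, "peaks")) {
    stop("peaks must be file path(s) or a peaks table", call. = FALSE)
  }
  if (is.character(motif_lengths)) {
    if (!file.exists(motif_lengths))
      stop("motif-length table not found: ", motif_lengths, call. = FALSE)
  } else if (!is.null(motif_lengths) &&
             !inherits(motif_lengths, "motif_length_table")) {
    stop("motif_lengths must be a path, a motif_length_table or NULL",
         call. = FALSE)
  }
  priority <- resolve_priority_spec(priority)
  structure(list(peaks = peaks, motif_lengths = motif_lengths,
                 params = params, priority = priority, out_dir = out_dir),
            class = "pipeline_config")
}

resolve_priority_spec <- function(priority) {
  if (inherits(priority, "caller_priority")) return(priority)
  if (is.character(priority) && length(priority) == 1L &&
      tolower(priority) %in% c("fixed", "auto"))
    return(tolower(priority))
  if (is.character(priority) && length(priority) == 1L && grepl(",", priority))
    priority <- strsplit(priority, ",", fixed = TRUE)[[1]]
  if (is.character(priority)) return(caller_priority(priority))
  stop("priority must be 'fixed', 'auto', a caller list or a caller_priority",
       call. = FALSE)
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised keys mirror the \code{\link{pipeline_config}} arguments:
#' \code{peaks} (list of interchange TSVs), \code{motif_lengths},
#' \code{merge_distance}, \code{default_motif_length}, \code{sd_multiplier},
#' \code{priority}, \code{out_dir}. Relative paths are resolved against the
#' YAML file's directory.
#'
#' @param path Path to the YAML file.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  params <- cluster_params(
    merge_distance = y$merge_distance %||% 50L,
    default_motif_length = y$default_motif_length %||% 20L,
    sd_multiplier = y$sd_multiplier %||% 4
  )
  pipeline_config(
    peaks = resolve(unlist(y$peaks)),
    motif_lengths = if (!is.null(y$motif_lengths)) resolve(y$motif_lengths),
    params = params,
    priority = y$priority %||% "fixed",
    out_dir = if (!is.null(y$out_dir)) resolve(y$out_dir) else base
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full cluster / metacluster pipeline
#'
#' Reads the peak inputs, builds per-(TF, caller) clusters, obtains the
#' caller priority (fixed, supplied or recalibrated), builds cross-caller
#' metaclusters and writes four artifacts into the output directory:
#' \code{clusters.bed}, \code{metaclusters.bed}, \code{priority.tsv} and a
#' \code{run_report.yaml} recording parameter values and per-stage counts.
#'
#' @param config A \code{\link{pipeline_config}}, or a path to a YAML
#'   configuration file.
#' @return Invisibly, a list with the computed \code{clusters},
#'   \code{metaclusters}, \code{priority}, the \code{report} list and the
#'   output \code{paths}.
#' @examples
#' sim <- simulate_peaks(sim_params(n_sites = 10, seed = 3))
#' tsv <- tempfile(fileext = ".tsv")
#' write_interchange(sim$peaks, tsv)
#' out <- tempfile()
#' res <- run_pipeline(pipeline_config(peaks = tsv, out_dir = out))
#' res$report$n_metaclusters
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)

  pk <- if (inherits(config$peaks, "peaks")) config$peaks else {
    parts <- lapply(config$peaks, read_interchange)
    validate_peaks(do.call(rbind, lapply(parts, as.data.frame)))
  }
  message(sprintf("[read] %d peak(s) from %s", nrow(pk),
                  if (is.character(config$peaks))
                    paste(config$peaks, collapse = ", ") else "in-memory table"))

  motif_tab <- config$motif_lengths
  if (is.character(motif_tab))
    motif_tab <- read_motif_lengths(motif_tab,
                                    config$params$default_motif_length)

  cl <- build_clusters(pk, motif_tab, config$params)
  message(sprintf("[cluster] %d cluster(s)", nrow(cl)))

  priority <- config$priority
  if (identical(priority, "fixed")) priority <- caller_priority()
  else if (identical(priority, "auto")) {
    priority <- if (nrow(cl)) calibrate_priority(cl) else caller_priority()
  }
  message(sprintf("[priority] %s", paste(priority$order, collapse = " > ")))

  mc <- build_metaclusters(cl, priority, config$params)
  message(sprintf("[metacluster] %d metacluster(s)", nrow(mc)))

  paths <- list(
    clusters = file.path(config$out_dir, "clusters.bed"),
    metaclusters = file.path(config$out_dir, "metaclusters.bed"),
    priority = file.path(config$out_dir, "priority.tsv"),
    report = file.path(config$out_dir, "run_report.yaml")
  )
  write_bed(cl, paths$clusters)
  write_bed(mc, paths$metaclusters)
  write_priority(priority, paths$priority)

  report <- list(
    tool = paste0("metapeaks ",
                  as.character(utils::packageVersion("metapeaks"))),
    parameters = list(
      merge_distance = config$params$merge_distance,
      default_motif_length = config$params$default_motif_length,
      sd_multiplier = config$params$sd_multiplier,
      priority = paste(priority$order, collapse = " > ")
    ),
    n_peaks = nrow(pk),
    n_clusters = nrow(cl),
    n_clustered_peaks = sum(cl$peak_count),
    n_metaclusters = nrow(mc),
    n_metacluster_member_clusters = if (nrow(mc)) sum(mc$n_clusters) else 0L
  )
  yaml::write_yaml(report, paths$report)

  invisible(list(clusters = cl, metaclusters = mc, priority = priority,
                 report = report, paths = paths))
}
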