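#' Construct a peak table
#'
#' Assembles and validates the package's uniform peak representation: one row
#' per peak call, carrying its genomic interval (0-based half-open, BED
#' convention), the caller that produced it, the experiment it came from and
#' the targeted TF. MACS peaks may additionally carry a summit offset
#' (distance from \code{start} to the reported summit).
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors; 0-based half-open interval per peak.
#' @param caller Character vector of caller names (case-insensitive; one of
#'   \code{callers()}).
#' @param experiment_id Character vector of experiment identifiers.
#' @param tf Character vector of TF identifiers.
#' @param summit_offset Integer vector of summit offsets from \code{start}
#'   (MACS), \code{NA} where absent.
#' @return A \code{data.frame} of class \code{peaks}.
#' @examples
#' peaks(chrom = "chr1", start = 1000L, end = 1300L, caller = "MACS",
#'       experiment_id = "e1", tf = "USF1", summit_offset = 150L)
#' @export
peaks <- function(chrom = character(), start = integer(), end = integer(),
                  caller = character(), experiment_id = character(),
                  tf = character(), summit_offset = NA_integer_) {
  n <- max(length(chrom), length(start), length(end), length(caller),
           length(experiment_id), length(tf))
  if (length(chrom) == 0L) n <- 0L
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.integer(start), n),
    end = rep_len(as.integer(end), n),
    summit_offset = rep_len(as.integer(summit_offset), n),
    caller = if (n) rep_len(normalize_callers(caller), n) else character(),
    experiment_id = rep_len(as.character(experiment_id), n),
    tf = rep_len(as.character(tf), n),
    stringsAsFactors = FALSE
  )
  validate_peaks(df)
}

validate_peaks <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("chrom", "start", "end", "summit_offset", "caller",
                "experiment_id", "tf")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("peak table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(df)) {
    bad <- which(df$start < 0L | df$start >= df$end)
    if (length(bad))
      stop(sprintf("invalid peak interval at row %d: start=%d end=%d (need 0 <= start < end)",
                   bad[1], df$start[bad[1]], df$end[bad[1]]), call. = FALSE)
    so <- df$summit_offset
    bad <- which(!is.na(so) & (so < 0L | so >= df$end - df$start))
    if (length(bad))
      stop(sprintf("summit offset out of range at row %d: offset=%d width=%d",
                   bad[1], so[bad[1]], df$end[bad[1]] - df$start[bad[1]]),
           call. = FALSE)
    bad <- which(df$caller == "GEM" & df$end - df$start != 1L)
    if (length(bad))
      stop(sprintf("GEM peak at row %d is not unit length (GEM reports point events)",
                   bad[1]), call. = FALSE)
  }
  class(df) <- c("peaks", "data.frame")
  df
}

empty_peaks <- function() {
  peaks()
}

#' Read MACS peaks from an ENCODE narrowPeak file
#'
#' Parses a narrowPeak (BED6+4) file into the uniform peak table. Column 10
#' is interpreted as the summit offset from the interval start, per the
#' ENCODE convention; a value of -1 marks an absent summit. Coordinates in
#' narrowPeak are already 0-based half-open and are kept as-is. Records are
#' returned in file order.
#'
#' @param path Path to a narrowPeak file.
#' @param experiment_id Experiment identifier to attach to every record.
#' @param tf TF identifier to attach to every record.
#' @return A \code{peaks} table with \code{caller = "MACS"}.
#' @examples
#' np <- tempfile(fileext = ".narrowPeak")
#' writeLines(paste(c("chr1", 1000, 1300, "p1", 0, ".", 5, 10, 8, 150),
#'                  collapse = "\t"), np)
#' read_narrowpeak(np, experiment_id = "e1", tf = "USF1")
#' @export
read_narrowpeak <- function(path, experiment_id, tf) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  if (!any(keep)) return(empty_peaks())
  # Pre-scan so parse/validation failures name the offending line.
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 10L)
      stop(sprintf("narrowPeak parse error at line %d: expected 10 columns, found %d",
                   lineno[i], length(f)), call. = FALSE)
    s <- suppressWarnings(as.integer(f[2])); e <- suppressWarnings(as.integer(f[3]))
    p <- suppressWarnings(as.integer(f[10]))
    if (is.na(s) || is.na(e) || is.na(p))
      stop(sprintf("narrowPeak parse error at line %d: non-integer coordinate or summit field",
                   lineno[i]), call. = FALSE)
    if (s < 0L || s >= e)
      stop(sprintf("narrowPeak validation error at line %d: start=%d end=%d (need 0 <= start < end)",
                   lineno[i], s, e), call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "narrowPeak")
  summit <- as.integer(gr$peak)
  summit[!is.na(summit) & summit < 0L] <- NA_integer_
  peaks(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # GRanges is 1-based
    end = GenomicRanges::end(gr),
    caller = "MACS",
    experiment_id = experiment_id,
    tf = tf,
    summit_offset = summit
  )
}

#' Read peaks from the interchange TSV format
#'
#' The interchange format is a tab-separated file with a header line and
#' columns \code{chrom}, \code{start}, \code{end}, \code{summit_offset}
#' (may be empty), \code{caller}, \code{experiment_id}, \code{tf}.
#' Coordinates are 0-based half-open. Caller names are validated
#' case-insensitively against \code{callers()}. It is the recommended
#' carrier for SISSRs and PICS calls, whose native formats vary by version.
#'
#' @param path Path to an interchange TSV.
#' @return A \code{peaks} table, rows in file order.
#' @seealso \code{\link{write_interchange}} for the inverse.
#' @export
read_interchange <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(empty_peaks())
  so <- df$summit_offset
  so[is.na(so) | !nzchar(trimws(so))] <- NA
  peaks(
    chrom = df$chrom,
    start = as.integer(df$start),
    end = as.integer(df$end),
    caller = df$caller,
    experiment_id = df$experiment_id,
    tf = df$tf,
    summit_offset = as.integer(so)
  )
}

#' Write peaks to the interchange TSV format
#'
#' @param x A \code{peaks} table.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_interchange <- function(x, path) {
  x <- validate_peaks(as.data.frame(x))
  out <- data.frame(
    chrom = x$chrom, start = x$start, end = x$end,
    summit_offset = ifelse(is.na(x$summit_offset), "", x$summit_offset),
    caller = x$caller, experiment_id = x$experiment_id, tf = x$tf,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Extract per-caller peak centers
#'
#' Reduces each peak to the point estimate of the binding position that its
#' caller reports: the summit for MACS (interval start plus summit offset),
#' the unit-length event coordinate for GEM, and the geometric center
#' (floor of the interval midpoint) for PICS and SISSRs. MACS peaks lacking
#' a summit fall back to the geometric center, with a warning.
#'
#' @param x A \code{peaks} table.
#' @return A \code{data.frame} with one row per peak: \code{chrom},
#'   \code{position} (0-based point), \code{caller}, \code{experiment_id},
#'   \code{tf} and \code{peak_id} (row index into \code{x}).
#' @examples
#' p <- peaks(chrom = "chr1", start = 100L, end = 131L, caller = "SISSRS",
#'            experiment_id = "e1", tf = "USF1")
#' peak_centers(p)$position  # 115, the geometric center
#' @export
peak_centers <- function(x) {
  x <- validate_peaks(as.data.frame(x))
  geometric <- as.integer(floor((as.numeric(x$start) + as.numeric(x$end)) / 2))
  position <- geometric
  position[x$caller == "GEM"] <- x$start[x$caller == "GEM"]
  is_macs <- x$caller == "MACS"
  has_summit <- is_macs & !is.na(x$summit_offset)
  position[has_summit] <- x$start[has_summit] + x$summit_offset[has_summit]
  n_fallback <- sum(is_macs & is.na(x$summit_offset))
  if (n_fallback > 0L)
    warning(sprintf("%d MACS peak(s) lack a summit; using the geometric center",
                    n_fallback), call. = FALSE)
  data.frame(
    chrom = x$chrom, position = position, caller = x$caller,
    experiment_id = x$experiment_id, tf = x$tf,
    peak_id = seq_len(nrow(x)), stringsAsFactors = FALSE
  )
}

#' Motif length table
#'
#' Maps TF identifiers to the length (bp) of their binding motif (e.g. the
#' PWM length from a motif database such as HOCOMOCO), used as the estimate
#' of the protein-DNA contact footprint when computing cluster widths. TFs
#' absent from the table fall back to \code{default_length}.
#'
#' @param lengths Named integer vector: names are TF identifiers, values
#'   motif lengths in bp (all >= 1).
#' @param default_length Length (bp) used for unlisted TFs. Default 20.
#' @return An object of class \code{motif_length_table}.
#' @examples
#' tab <- motif_length_table(c(USF1 = 12L))
#' motif_length(tab, c("USF1", "CTCF"))  # 12, 20
#' @export
motif_length_table <- function(lengths = integer(), default_length = 20L) {
  lengths <- stats::setNames(as.integer(lengths), names(lengths))
  default_length <- as.integer(default_length)
  if (length(lengths) && (is.null(names(lengths)) || any(!nzchar(names(lengths)))))
    stop("motif lengths must be named by TF identifier", call. = FALSE)
  if (any(is.na(lengths)) || any(lengths < 1L))
    stop("motif lengths must be positive integers", call. = FALSE)
  if (is.na(default_length) || default_length < 1L)
    stop("default_length must be a positive integer", call. = FALSE)
  structure(list(lengths = lengths, default_length = default_length),
            class = "motif_length_table")
}

#' @rdname motif_length_table
#' @param table A \code{motif_length_table}.
#' @param tf Character vector of TF identifiers to look up.
#' @export
motif_length <- function(table, tf) {
  stopifnot(inherits(table, "motif_length_table"))
  out <- unname(table$lengths[tf])
  out[is.na(out)] <- table$default_length
  as.integer(out)
}

#' Read a motif-length table from a two-column TSV
#'
#' Expects tab-separated columns \code{tf} and \code{length}; lines starting
#' with \code{#} are ignored; a header line is optional and detected by a
#' non-numeric second field.
#'
#' @param path Path to the TSV.
#' @param default_length Fallback length (bp) for unlisted TFs.
#' @return A \code{motif_length_table}.
#' @export
read_motif_lengths <- function(path, default_length = 20L) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) return(motif_length_table(default_length = default_length))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L))
    stop("motif-length table must have two tab-separated columns: tf, length",
         call. = FALSE)
  first_len <- suppressWarnings(as.integer(fields[[1]][2]))
  if (is.na(first_len)) fields <- fields[-1]  # header row
  tfs <- vapply(fields, `[`, character(1), 1L)
  lens <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 2L)))
  if (anyNA(lens))
    stop("non-integer motif length in ", path, call. = FALSE)
  motif_length_table(stats::setNames(lens, tfs), default_length = default_length)
}

#' Write clusters or metaclusters as a BED6+ track
#'
#' Serialises a \code{peak_clusters} or \code{metaclusters} object to a
#' BED-like file: the six standard BED columns (0-based half-open interval,
#' TF as the name, score 0, strand ".") followed by object-specific extra
#' columns, documented in a leading \code{#}-comment header line. For
#' clusters the extras are caller, peak count, SD of member peak centers,
#' whether the SD was imputed, and the cluster center. For metaclusters they
#' are the supporting callers (comma-joined, sorted lexicographically), the
#' number of member clusters, the representative caller and the center.
#'
#' @param x A \code{peak_clusters} or \code{metaclusters} object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(x, path) UseMethod("write_bed")

#' @export
write_bed.peak_clusters <- function(x, path) {
  header <- "#chrom\tstart\tend\tname\tscore\tstrand\tcaller\tpeak_count\tsd\tsd_imputed\tcenter"
  body <- if (nrow(x)) {
    paste(x$chrom, x$start, x$end, x$tf, 0L, ".",
          x$caller, x$peak_count, format_sd(x$sd),
          ifelse(x$sd_imputed, "1", "0"), x$center, sep = "\t")
  } else character()
  writeLines(c(header, body), path)
  invisible(path)
}

#' @export
write_bed.metaclusters <- function(x, path) {
  header <- "#chrom\tstart\tend\tname\tscore\tstrand\tcallers\tn_clusters\trepresentative_caller\tcenter"
  body <- if (nrow(x)) {
    callers_col <- vapply(x$supporting_callers,
                          function(s) paste(sort(s), collapse = ","),
                          character(1))
    paste(x$chrom, x$start, x$end, x$tf, 0L, ".",
          callers_col, x$n_clusters, x$representative_caller, x$center,
          sep = "\t")
  } else character()
  writeLines(c(header, body), path)
  invisible(path)
}

format_sd <- function(sd) formatC(sd, format = "f", digits = 4)

#' Read a cluster BED track written by \code{write_bed}
#'
#' Restores the cluster table (without member-peak provenance, which the BED
#' serialisation does not carry) so that metaclustering and priority
#' calibration can run on a previously written cluster track.
#'
#' @param path Path to a cluster BED file produced by
#'   \code{\link{write_bed}}.
#' @return A \code{peak_clusters} table with an empty \code{members} column.
#' @export
read_clusters_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) return(empty_clusters())
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 11L))
    stop("not a cluster BED written by write_bed(): expected 11 columns",
         call. = FALSE)
  col <- function(i) vapply(f, `[`, character(1), i)
  df <- data.frame(
    tf = col(4), caller = normalize_callers(col(7)), chrom = col(1),
    start = as.integer(col(2)), end = as.integer(col(3)),
    center = as.integer(col(11)), sd = as.numeric(col(9)),
    sd_imputed = col(10) == "1", peak_count = as.integer(col(8)),
    width = as.integer(col(3)) - as.integer(col(2)),
    stringsAsFactors = FALSE
  )
  df$members <- replicate(nrow(df), NULL, simplify = FALSE)
  as_peak_clusters(df)
}
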