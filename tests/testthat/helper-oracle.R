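# Brute-force single-linkage oracle: build the graph over all position pairs
# with |a - b| <= d and take connected components. O(n^2), independent of the
# package's sorted-chaining implementation.
oracle_group <- function(positions, d) {
  n <- length(positions)
  if (n == 0L) return(list())
  adj <- abs(outer(positions, positions, "-")) <= d
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  groups <- lapply(unname(split(positions, comp)), sort)
  groups[order(vapply(groups, min, numeric(1)))]
}

# Minimal peaks table with unit-length GEM records at the given centers.
gem_peaks_at <- function(centers, tf = "TF1", experiment_id = "e1",
                         chrom = "chr1") {
  peaks(chrom = chrom, start = as.integer(centers),
        end = as.integer(centers) + 1L, caller = "GEM",
        experiment_id = experiment_id, tf = tf)
}

# Hand-built cluster table (bypasses build_clusters) for unit tests of the
# metacluster stage.
make_clusters <- function(caller, center, sd = 1, peak_count = 2L,
                          tf = "TF1", chrom = "chr1", width = 20L,
                          sd_imputed = FALSE) {
  n <- max(length(caller), length(center))
  df <- data.frame(
    tf = rep_len(tf, n), caller = rep_len(caller, n),
    chrom = rep_len(chrom, n),
    start = as.integer(rep_len(center, n) - rep_len(width, n) %/% 2L),
    end = as.integer(rep_len(center, n) - rep_len(width, n) %/% 2L +
                     rep_len(width, n)),
    center = as.integer(rep_len(center, n)),
    sd = rep_len(as.numeric(sd), n),
    sd_imputed = rep_len(sd_imputed, n),
    peak_count = as.integer(rep_len(peak_count, n)),
    width = as.integer(rep_len(width, n)),
    stringsAsFactors = FALSE
  )
  df$members <- replicate(n, NULL, simplify = FALSE)
  metapeaks:::as_peak_clusters(df)
}
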