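test_that("center grouping joins at the threshold and splits beyond it", {
  expect_equal(group_centers(c(100L, 150L), 50), list(c(100L, 150L)))
  expect_equal(group_centers(c(100L, 151L), 50), list(100L, 151L))
  # transitive chaining: 0-50-100 despite 0 and 100 being 100 bp apart
  expect_equal(group_centers(c(0L, 50L, 100L), 50), list(c(0L, 50L, 100L)))
  expect_equal(group_centers(integer(), 50), list())
})

test_that("center grouping rejects mixed chromosomes, TFs or callers", {
  pc <- peak_centers(gem_peaks_at(c(10L, 20L), chrom = "chr1"))
  pc2 <- peak_centers(gem_peaks_at(30L, chrom = "chr2"))
  expect_error(group_centers(rbind(pc, pc2), 50), "single chromosome")
  pc3 <- peak_centers(gem_peaks_at(30L, tf = "OTHER"))
  expect_error(group_centers(rbind(pc, pc3), 50), "single TF")
  expect_error(group_centers(c(1L, 2L), -1), "non-negative")
})

test_that("cluster center is the median, floored for even counts", {
  expect_equal(cluster_center(c(100L, 110L, 120L)), 110L)
  expect_equal(cluster_center(c(100L, 111L)), 105L)  # floor(211/2)
  expect_equal(cluster_center(42L), 42L)
  expect_equal(cluster_center(c(120L, 100L, 110L)), 110L)  # order-free
  expect_error(cluster_center(integer()), "empty")
})

test_that("cluster SD is the sample SD, with singletons flagged for imputation", {
  expect_equal(cluster_sd(c(100L, 110L, 120L)), 10)
  expect_equal(cluster_sd(c(7L, 7L, 7L)), 0)
  expect_true(is.na(cluster_sd(42L)))
  expect_error(cluster_sd(integer()), "empty")
})

test_that("singleton SD imputation takes the median of the other clusters", {
  expect_equal(impute_singleton_sd(c(2, 4, 10)), 4)
  expect_equal(impute_singleton_sd(c(3, 5)), 4)
  expect_equal(impute_singleton_sd(numeric()), 0)
})

test_that("cluster width is motif length plus the SD multiple, rounded half-up", {
  expect_equal(cluster_width(0, 20), 20L)
  expect_equal(cluster_width(10, 12), 52L)
  expect_equal(cluster_width(2.6, 20), 30L)    # 20 + half-up(10.4)
  expect_equal(cluster_width(0.125, 20), 21L)  # 0.5 rounds up, not to even
})

test_that("a two-experiment MACS cluster reproduces the hand-computed summary", {
  p <- peaks(chrom = "chr1", start = c(900L, 908L), end = c(1200L, 1208L),
             caller = "MACS", experiment_id = c("e1", "e2"), tf = "USF1",
             summit_offset = c(100L, 100L))  # centers 1000 and 1008
  cl <- build_clusters(p, motif_length_table(c(USF1 = 12L)))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$center, 1004L)
  expect_equal(cl$sd, sqrt(32), tolerance = 1e-12)  # sample SD of 1000, 1008
  expect_equal(cl$width, 35L)                       # 12 + half-up(4 * 5.657)
  expect_equal(cl$peak_count, 2L)
  expect_equal(cl$start, 1004L - 35L %/% 2L)
  expect_equal(cl$end - cl$start, cl$width)
})

test_that("a lone singleton cluster gets SD 0 and motif-length width", {
  cl <- build_clusters(gem_peaks_at(500L, tf = "NOVEL"))
  expect_equal(nrow(cl), 1L)
  expect_true(cl$sd_imputed)
  expect_equal(cl$sd, 0)
  expect_equal(cl$width, 20L)
  expect_equal(cl$center, 500L)
})

test_that("peaks of different TFs or callers at one locus never merge", {
  p <- rbind(gem_peaks_at(1000L, tf = "A"), gem_peaks_at(1005L, tf = "B"))
  cl <- build_clusters(metapeaks:::validate_peaks(p))
  expect_equal(nrow(cl), 2L)
  p2 <- peaks(chrom = "chr1", start = c(1000L, 900L), end = c(1001L, 1101L),
              caller = c("GEM", "SISSRS"), experiment_id = "e1", tf = "A")
  expect_equal(nrow(build_clusters(p2)), 2L)
})

test_that("singleton SD imputation is scoped to the same TF and caller", {
  # GEM/TF1 has two multi-peak clusters (SDs 10 and 2) plus one singleton;
  # SISSRS/TF1 has a wildly scattered cluster that must not leak in.
  p <- rbind(
    gem_peaks_at(c(990L, 1010L)),                 # SD 14.14
    gem_peaks_at(c(4999L, 5001L)),                # SD 1.41
    gem_peaks_at(9000L),                          # singleton
    as.data.frame(peaks(chrom = "chr1", start = c(100L, 500L),
                        end = c(301L, 701L), caller = "SISSRS",
                        experiment_id = c("e1", "e2"), tf = "TF1"))
  )
  cl <- build_clusters(metapeaks:::validate_peaks(p))
  singleton <- cl[cl$caller == "GEM" & cl$peak_count == 1L, ]
  expect_true(singleton$sd_imputed)
  expect_equal(singleton$sd, stats::median(c(sd(c(990, 1010)), sd(c(4999, 5001)))))
})

test_that("clustering partitions the input and separates groups by > 50 bp", {
  set.seed(42)
  for (rep in 1:20) {
    centers <- sort(sample.int(20000L, sample(1:150, 1)))
    cl <- build_clusters(gem_peaks_at(centers))
    expect_equal(sum(cl$peak_count), length(centers))
    member_pos <- lapply(cl$members, function(m) m$position)
    expect_equal(sort(unlist(member_pos)), sort(centers))
    if (nrow(cl) > 1L) {
      gaps <- vapply(seq_len(nrow(cl) - 1L), function(i)
        min(member_pos[[i + 1L]]) - max(member_pos[[i]]), numeric(1))
      expect_true(all(gaps > 50))
    }
    expect_true(all(cl$center >= vapply(member_pos, min, numeric(1)) &
                    cl$center <= vapply(member_pos, max, numeric(1))))
  }
})

test_that("raising the merge distance never increases the cluster count", {
  set.seed(99)
  centers <- sample.int(5000L, 120)
  counts <- vapply(c(0, 10, 25, 50, 100, 200), function(d)
    nrow(build_clusters(gem_peaks_at(centers),
                        params = cluster_params(merge_distance = d))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("width never drops below the motif length and grows with SD", {
  set.seed(17)
  sim <- simulate_peaks(sim_params(n_sites = 40, seed = 17))
  cl <- build_clusters(sim$peaks, motif_length_table(c(TF1 = 15L)))
  expect_true(all(cl$width >= 15L))
  expect_true(all(cl$end - cl$start == cl$width))
  ord <- order(cl$sd)
  expect_true(all(diff(cl$width[ord]) >= 0))  # width non-decreasing in SD
})

test_that("cluster construction is deterministic and order-insensitive", {
  set.seed(5)
  sim <- simulate_peaks(sim_params(n_sites = 30, seed = 5))
  cl1 <- build_clusters(sim$peaks)
  shuffled <- sim$peaks[sample(nrow(sim$peaks)), ]
  cl2 <- build_clusters(metapeaks:::validate_peaks(shuffled))
  f1 <- tempfile(); f2 <- tempfile()
  write_bed(cl1, f1); write_bed(cl2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("grouping matches the brute-force connected-components oracle", {
  set.seed(2718)
  for (rep in 1:50) {
    n <- sample(0:200, 1)
    pos <- sample.int(4000L, n, replace = TRUE)
    d <- sample(0:120, 1)
    expect_equal(group_centers(pos, d), oracle_group(pos, d),
                 info = sprintf("rep %d (n=%d, d=%d)", rep, n, d))
  }
})
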