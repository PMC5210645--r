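write_np <- function(lines) {
  path <- tempfile(fileext = ".narrowPeak")
  writeLines(lines, path)
  path
}

np_line <- function(chrom = "chr1", start = 1000, end = 1300, name = "p1",
                    summit = 150) {
  paste(c(chrom, start, end, name, 0, ".", 5, 10, 8, summit), collapse = "\t")
}

test_that("narrowPeak records map to MACS peaks with summit offsets", {
  p <- read_narrowpeak(write_np(np_line()), experiment_id = "e1", tf = "USF1")
  expect_s3_class(p, "peaks")
  expect_equal(p$chrom, "chr1")
  expect_equal(p$start, 1000L)
  expect_equal(p$end, 1300L)
  expect_equal(p$summit_offset, 150L)
  expect_equal(p$caller, "MACS")
  expect_equal(p$experiment_id, "e1")
  expect_equal(p$tf, "USF1")
})

test_that("narrowPeak summit sentinel -1 yields an absent summit", {
  p <- read_narrowpeak(write_np(np_line(summit = -1)), "e1", "USF1")
  expect_true(is.na(p$summit_offset))
})

test_that("narrowPeak reader preserves file order and handles empty files", {
  lines <- c(np_line(start = 5000, end = 5200, name = "b", summit = 10),
             np_line(start = 100, end = 400, name = "a", summit = 20))
  p <- read_narrowpeak(write_np(lines), "e1", "USF1")
  expect_equal(p$start, c(5000L, 100L))
  expect_equal(nrow(read_narrowpeak(write_np(character()), "e1", "USF1")), 0L)
})

test_that("narrowPeak errors name the offending line", {
  bad_cols <- write_np(c(np_line(), "chr1\t10\t20\tp2\t0"))
  expect_error(read_narrowpeak(bad_cols, "e1", "USF1"), "line 2")
  bad_interval <- write_np(np_line(start = 500, end = 400))
  expect_error(read_narrowpeak(bad_interval, "e1", "USF1"),
               "line 1.*start=500 end=400")
})

test_that("interchange round-trip reproduces the peak table exactly", {
  set.seed(101)
  n <- 40L
  caller <- sample(callers(), n, replace = TRUE)
  start <- sample.int(100000L, n)
  width <- ifelse(caller == "GEM", 1L, sample(50:400, n, replace = TRUE))
  summit <- ifelse(caller == "MACS", pmin(10L, width - 1L), NA_integer_)
  p <- peaks(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
             start = start, end = start + width, caller = caller,
             experiment_id = sample(c("e1", "e2", "e3"), n, replace = TRUE),
             tf = sample(c("USF1", "CTCF"), n, replace = TRUE),
             summit_offset = summit)
  path <- tempfile(fileext = ".tsv")
  write_interchange(p, path)
  expect_equal(read_interchange(path), p)
})

test_that("interchange validation rejects bad callers and bad intervals", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tsummit_offset\tcaller\texperiment_id\ttf",
               "chr2\t10\t11\t\tGEM\te1\tUSF1"), path)
  p <- read_interchange(path)
  expect_equal(p$caller, "GEM")
  expect_equal(p$end - p$start, 1L)

  writeLines(c("chrom\tstart\tend\tsummit_offset\tcaller\texperiment_id\ttf",
               "chr1\t10\t300\t\tmacs2\te1\tUSF1"), path)
  expect_error(read_interchange(path), "macs2.*GEM, PICS, MACS, SISSRS")

  writeLines(c("chrom\tstart\tend\tsummit_offset\tcaller\texperiment_id\ttf",
               "chr1\t5\t4\t\tMACS\te1\tUSF1"), path)
  expect_error(read_interchange(path), "start.*end")
})

test_that("caller names are accepted case-insensitively", {
  p <- peaks(chrom = "chr1", start = 0L, end = 1L, caller = "gem",
             experiment_id = "e1", tf = "A")
  expect_equal(p$caller, "GEM")
  expect_equal(normalize_callers <- metapeaks:::normalize_callers("SISSRs"),
               "SISSRS")
})

test_that("peak centers follow each caller's reporting convention", {
  p <- peaks(chrom = "chr1",
             start = c(1000L, 500L, 100L, 100L),
             end = c(1300L, 501L, 131L, 131L),
             caller = c("MACS", "GEM", "SISSRS", "PICS"),
             experiment_id = "e1", tf = "USF1",
             summit_offset = c(150L, NA, NA, NA))
  pc <- peak_centers(p)
  expect_equal(pc$position, c(1150L, 500L, 115L, 115L))
  # pure function: recomputing gives the same result, always inside the peak
  expect_identical(peak_centers(p), pc)
  expect_true(all(pc$position >= p$start & pc$position < p$end))
})

test_that("MACS peaks without a summit fall back to the geometric center", {
  p <- peaks(chrom = "chr1", start = 100L, end = 301L, caller = "MACS",
             experiment_id = "e1", tf = "USF1")
  expect_warning(pc <- peak_centers(p), "geometric center")
  expect_equal(pc$position, 200L)
})

test_that("GEM peaks must be unit length and summits must lie inside peaks", {
  expect_error(peaks(chrom = "chr1", start = 10L, end = 20L, caller = "GEM",
                     experiment_id = "e1", tf = "A"), "unit length")
  expect_error(peaks(chrom = "chr1", start = 10L, end = 20L, caller = "MACS",
                     experiment_id = "e1", tf = "A", summit_offset = 10L),
               "summit offset")
})

test_that("motif-length table lookups fall back to the default of 20 bp", {
  tab <- motif_length_table(c(USF1 = 12L, CTCF = 19L))
  expect_equal(motif_length(tab, c("USF1", "CTCF", "NOVEL")),
               c(12L, 19L, 20L))
  path <- tempfile(fileext = ".tsv")
  writeLines(c("# comment", "tf\tlength", "USF1\t12", "CTCF\t19"), path)
  tab2 <- read_motif_lengths(path)
  expect_equal(motif_length(tab2, "CTCF"), 19L)
  # headerless variant
  writeLines("USF1\t12", path)
  expect_equal(motif_length(read_motif_lengths(path), "USF1"), 12L)
  expect_error(motif_length_table(c(USF1 = 0L)), "positive")
})

test_that("cluster BED serialisation carries geometry and provenance columns", {
  cl <- make_clusters(caller = "MACS", center = 1010L, sd = 3.2,
                      peak_count = 5L, tf = "USF1", width = 40L)
  path <- tempfile(fileext = ".bed")
  write_bed(cl, path)
  lines <- readLines(path)
  expect_match(lines[1], "^#chrom\t")
  expect_equal(strsplit(lines[2], "\t")[[1]],
               c("chr1", "990", "1030", "USF1", "0", ".", "MACS", "5",
                 "3.2000", "0", "1010"))
  # empty input -> header-only file
  write_bed(metapeaks:::empty_clusters(), path)
  expect_equal(length(readLines(path)), 1L)
})

test_that("metacluster BED lists supporting callers sorted lexicographically", {
  cl <- make_clusters(caller = c("MACS", "GEM"), center = c(100L, 120L))
  mc <- build_metaclusters(cl)
  path <- tempfile(fileext = ".bed")
  write_bed(mc, path)
  f <- strsplit(readLines(path)[2], "\t")[[1]]
  expect_equal(f[7], "GEM,MACS")
  write_bed(metapeaks:::empty_metaclusters(), path)
  expect_equal(length(readLines(path)), 1L)
})

test_that("cluster BED round-trip restores the fields metaclustering needs", {
  set.seed(7)
  sim <- simulate_peaks(sim_params(n_sites = 15, seed = 7))
  cl <- build_clusters(sim$peaks)
  path <- tempfile(fileext = ".bed")
  write_bed(cl, path)
  back <- read_clusters_bed(path)
  for (col in c("tf", "caller", "chrom", "start", "end", "center",
                "sd_imputed", "peak_count", "width"))
    expect_equal(back[[col]], cl[[col]], info = col)
  expect_equal(back$sd, cl$sd, tolerance = 1e-4)
})
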