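test_that("read_bed parses, sorts and validates BED3+", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=x", "# comment",
               "chr2\t50\t60", "chr1\t200\t300\tp1\t7", "chr1\t0\t100"), f)
  ps <- read_bed(f, name = "toy")
  expect_s3_class(ps, "PeakSet")
  expect_equal(nrow(ps$intervals), 3L)
  expect_equal(ps$intervals$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(ps$intervals$start, c(0, 200, 50))
  expect_equal(ps$intervals$score[2], 7)

  writeLines("chr1\t100\t100", f)
  expect_error(read_bed(f), "zero-length")
  writeLines("chr1\tten\t100", f)
  expect_error(read_bed(f), "line 1.*non-integer")
  writeLines("chr1\t-5\t100", f)
  expect_error(read_bed(f), "negative|non-integer")
  writeLines("chr1\t100", f)
  expect_error(read_bed(f), "fewer than 3")
})

test_that("merge_intervals unions overlaps but not half-open adjacency", {
  expect_equal(merge_intervals(make_ps("chr1", c(0, 50), c(100, 150)))$intervals$end,
               150)
  adj <- merge_intervals(make_ps("chr1", c(0, 10), c(10, 20)))
  expect_equal(nrow(adj$intervals), 2L)
  disj <- make_ps("chr1", c(0, 30), c(10, 40))
  expect_equal(merge_intervals(disj)$intervals, disj$intervals)
})

test_that("merge_intervals is idempotent and base-conserving", {
  set.seed(11)
  covered_bp <- function(ps) {
    m <- merge_intervals(ps)$intervals
    sum(m$end - m$start)
  }
  for (i in 1:20) {
    ps <- random_ps(sample(2:40, 1))
    m1 <- merge_intervals(ps)
    expect_identical(merge_intervals(m1)$intervals, m1$intervals)
    # base conservation vs per-position enumeration on small coordinates
    bases <- unique(unlist(lapply(seq_len(nrow(ps$intervals)), function(k)
      paste0(ps$intervals$chrom[k],
             ":", seq(ps$intervals$start[k], ps$intervals$end[k] - 1)))))
    expect_equal(covered_bp(m1), length(bases))
  }
})

test_that("intersect_sets keeps a's coordinates and half-open boundaries", {
  a <- make_ps("chr1", c(0, 200), c(100, 300), "a")
  b <- make_ps("chr1", 250, 260, "b")
  r <- intersect_sets(a, b)
  expect_equal(r$intervals$start, 200)
  expect_equal(r$intervals$end, 300)
  expect_equal(intersect_sets(a, a)$intervals[, 1:3], a$intervals[, 1:3])
  expect_equal(nrow(intersect_sets(make_ps("chr1", 0, 10),
                                   make_ps("chr1", 10, 20))$intervals), 0L)
  expect_error(intersect_sets(a, b, min_overlap = 0), "min_overlap")
})

test_that("intersect_sets honours min_overlap in shared bases", {
  a <- make_ps("chr1", 0, 100)
  b <- make_ps("chr1", 95, 200)   # 5 shared bases
  expect_equal(nrow(intersect_sets(a, b, 5)$intervals), 1L)
  expect_equal(nrow(intersect_sets(a, b, 6)$intervals), 0L)
})

test_that("intersect_sets subset property holds on random fixtures", {
  set.seed(21)
  for (i in 1:25) {
    a <- random_ps(sample(1:40, 1)); b <- random_ps(sample(1:40, 1))
    r <- intersect_sets(a, b)
    key <- function(iv) paste(iv$chrom, iv$start, iv$end)
    expect_true(all(key(r$intervals) %in% key(a$intervals)))
    expect_equal(sort(key(r$intervals)),
                 sort(unique(key(a$intervals)[
                   oracle_overlap_flags(a$intervals, b$intervals)])))
  }
})

test_that("consensus_peaks implements the two-caller rule", {
  c1 <- make_ps("chr1", c(100, 300), c(200, 400), "macs")
  c2 <- make_ps("chr1", 150, 250, "swembl")
  r <- consensus_peaks(c1, c2)
  expect_equal(r$name, "high_confidence")
  expect_equal(r$intervals$start, 100)
  expect_equal(consensus_peaks(c1, c1)$intervals[, 1:3], c1$intervals[, 1:3])
  # two caller1 peaks inside one caller2 peak are both retained
  c3 <- make_ps("chr1", c(10, 60), c(20, 70))
  c4 <- make_ps("chr1", 0, 100)
  expect_equal(nrow(consensus_peaks(c3, c4)$intervals), 2L)
  expect_warning(r0 <- consensus_peaks(make_ps(character(), numeric(),
                                               numeric()), c2), "empty")
  expect_equal(length(r0), 0L)
})

test_that("consensus_peaks equals intersect_sets at 1 bp (regression lock)", {
  set.seed(31)
  for (i in 1:10) {
    a <- random_ps(sample(1:30, 1)); b <- random_ps(sample(1:30, 1))
    expect_equal(consensus_peaks(a, b)$intervals,
                 intersect_sets(a, b, 1)$intervals)
  }
})

test_that("pairwise_overlap_matrix: counts, orientation, diagonal", {
  a <- make_ps("chr1", c(0, 200), c(100, 300), "a")
  b <- make_ps("chr1", 250, 260, "b")
  m <- pairwise_overlap_matrix(list(a, b))
  expect_equal(m$values["a", "b"], 50)
  expect_equal(m$values["b", "a"], 100)
  expect_equal(diag(m$values), c(a = 100, b = 100))
  expect_match(m$orientation, "row")

  d1 <- make_ps("chr1", 0, 10, "d1"); d2 <- make_ps("chr1", 20, 30, "d2")
  d3 <- make_ps("chr2", 0, 10, "d3")
  m0 <- pairwise_overlap_matrix(list(d1, d2, d3))
  expect_true(all(m0$values[upper.tri(m0$values)] == 0))
  expect_error(pairwise_overlap_matrix(list(a)), ">= 2")
  expect_error(
    pairwise_overlap_matrix(list(a, peak_set(data.frame(), "empty"))),
    "empty")
})

test_that("pairwise_overlap_matrix equals the brute-force oracle", {
  set.seed(41)
  for (i in 1:100) {
    sets <- suppressWarnings(lapply(1:3, function(k)
      random_ps(sample(1:50, 1), name = paste0("s", k))))
    got <- pairwise_overlap_matrix(sets)
    expect_equal(unname(got$values), oracle_overlap_matrix(sets),
                 tolerance = 1e-12)
  }
})

test_that("cluster_matrix merges identical rows first, deterministically", {
  m <- rbind(a = c(10, 20, 30, 5), b = c(1, 2, 1, 9),
             c = c(10, 20, 30, 5), d = c(9, 1, 4, 2))
  cl <- cluster_matrix(m)
  first <- sort(rownames(m)[-cl$hclust$merge[1, ]])
  expect_equal(first, c("a", "c"))
  # permutation invariance of topology and leaf label order
  base_labels <- cl$labels
  for (perm in list(c(2, 1, 3, 4), c(4, 3, 2, 1), c(3, 1, 4, 2))) {
    clp <- cluster_matrix(m[perm, ])
    expect_equal(clp$labels, base_labels)
  }
  # 2x2: single merge
  cl2 <- cluster_matrix(m[1:2, ])
  expect_equal(nrow(cl2$hclust$merge), 1L)
  # constant row warns and still clusters
  mc <- rbind(m, e = c(3, 3, 3, 3))
  expect_warning(cluster_matrix(mc), "constant")
})
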