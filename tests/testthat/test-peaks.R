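mk_pairs <- function(pos1, cigar1, pos2, cigar2, contig = "c1") {
  n <- length(pos1)
  structure(
    data.frame(qname = sprintf("p%d", seq_len(n)), class = NA, contig = contig,
               flag1 = 99L, pos1 = pos1, cigar1 = cigar1,
               seq1 = "A", qual1 = "I", flag2 = 147L, pos2 = pos2,
               cigar2 = cigar2, seq2 = "A", qual2 = "I", tlen = 0L),
    contig_lengths = c(c1 = 1000L))
}

track_from_depth <- function(depth, contig = "c1") {
  # build a coverage_track directly from a per-base vector
  r <- rle(depth)
  ends <- cumsum(r$lengths)
  keep <- r$values > 0
  structure(data.frame(contig = rep(contig, sum(keep)),
                       start = (ends - r$lengths)[keep],
                       end = ends[keep], depth = as.integer(r$values[keep]),
                       stringsAsFactors = FALSE),
            contig_lengths = stats::setNames(length(depth), contig),
            class = c("coverage_track", "data.frame"))
}

test_that("coverage counts reference-consuming spans of both mates", {
  tr <- coverage_track(mk_pairs(1L, "75M", 1L, "75M"))
  expect_equal(as.data.frame(tr),
               data.frame(contig = "c1", start = 0L, end = 75L, depth = 2L),
               ignore_attr = TRUE)
  # a deletion-containing CIGAR covers a contiguous 75-base reference span
  tr2 <- coverage_track(mk_pairs(11L, "30M5D40M", 500L, "10M"))
  expect_equal(as.data.frame(tr2)[1, ],
               data.frame(contig = "c1", start = 10L, end = 85L, depth = 1L),
               ignore_attr = TRUE)
  expect_error(coverage_track(mk_pairs(990L, "75M", 1L, "10M")), "contig end")
})

test_that("coverage conserves total reference-consumed bases", {
  for (seed in 1:5) {
    fx <- planted_fixture(40L + seed)
    sim <- simulate_reads(fx$genome, fx$sites, sim_params(seed = seed))
    kept <- filter_pairs(sim$pairs)$kept
    tr <- coverage_track(kept)
    consumed <- sum(vapply(c(kept$cigar1, kept$cigar2),
                           oracle_cigar_ref_width, numeric(1)))
    expect_identical(sum((tr$end - tr$start) * tr$depth), as.integer(consumed))
  }
})

test_that("call_peaks reproduces the hand-evaluated maximal-run rule", {
  tr <- track_from_depth(c(0L, 0L, 1L, 2L, 2L, 0L, 3L))
  pk <- call_peaks(tr, min_height = 1L)
  expect_equal(as.data.frame(pk),
               data.frame(contig = c("c1", "c1"), start = c(2L, 6L),
                          end = c(5L, 7L), height = c(2L, 3L)))
  # merge_gap = 1 bridges the single zero base
  pk2 <- call_peaks(tr, min_height = 1L, merge_gap = 1L)
  expect_equal(as.data.frame(pk2),
               data.frame(contig = "c1", start = 2L, end = 7L, height = 3L))
  expect_equal(nrow(call_peaks(track_from_depth(integer(10)))), 0L)
  expect_error(call_peaks(tr, min_height = 0L), "min_height")
})

test_that("RLE coverage and peaks match the naive per-base oracle", {
  withr::with_seed(101, {
    for (rep in 1:25) {
      glen <- sample(2000:8000, 1)
      n <- sample(5:80, 1)
      pos1 <- sample.int(glen - 200L, n, replace = TRUE)
      pos2 <- pmin(pos1 + sample.int(150L, n, replace = TRUE), glen - 80L)
      pairs <- mk_pairs(pos1, "75M", pos2, "75M")
      attr(pairs, "contig_lengths") <- c(c1 = glen)
      tr <- coverage_track(pairs)
      depth <- oracle_depth_array(pairs, "c1", glen)
      expect_identical(track_to_array(tr, "c1", glen), depth)
      mh <- sample(1:4, 1)
      gap <- sample(0:2, 1)
      pk <- call_peaks(tr, min_height = mh, merge_gap = gap)
      expect_equal(
        data.frame(start = pk$start, end = pk$end, height = pk$height),
        oracle_peaks(depth, mh, gap))
    }
  })
})

test_that("raising min_height never widens peaks or covers new bases", {
  fx <- planted_fixture(47L)
  sim <- simulate_reads(fx$genome, fx$sites, sim_params(seed = 47L))
  tr <- coverage_track(filter_pairs(sim$pairs)$kept)
  prev <- call_peaks(tr, 1L)
  for (mh in c(2L, 5L, 20L)) {
    cur <- call_peaks(tr, mh)
    # a taller threshold can split a peak but never extend one: every peak
    # is contained in a single lower-threshold peak, so the covered base
    # set only shrinks
    expect_lte(length(peak_base_set(cur)), length(peak_base_set(prev)))
    expect_true(all(peak_base_set(cur) %in% peak_base_set(prev)))
    for (i in seq_len(nrow(cur))) {
      parent <- prev[prev$contig == cur$contig[i] & prev$start <= cur$start[i] &
                       prev$end >= cur$end[i], ]
      expect_equal(nrow(parent), 1L)
    }
    prev <- cur
  }
})

test_that("subtract_control removes any-overlap peaks only", {
  pk <- function(s, e, h = 10L) structure(
    data.frame(contig = "c1", start = s, end = e, height = h),
    class = c("peaks", "data.frame"))
  expect_equal(nrow(subtract_control(pk(100L, 200L), pk(150L, 160L))), 0L)
  expect_equal(subtract_control(pk(100L, 200L), pk(300L, 400L)),
               pk(100L, 200L))
  expect_equal(nrow(subtract_control(pk(100L, 200L), pk(100L, 200L))), 0L)
  # abutting (half-open) intervals do not overlap
  expect_equal(nrow(subtract_control(pk(100L, 200L), pk(200L, 300L))), 1L)
})

test_that("intersect_replicates takes base-wise intersections with min height", {
  pk <- function(s, e, h) structure(
    data.frame(contig = "c1", start = s, end = e, height = h),
    class = c("peaks", "data.frame"))
  out <- intersect_replicates(pk(100L, 200L, 10L), pk(150L, 250L, 4L))
  expect_equal(as.data.frame(out),
               data.frame(contig = "c1", start = 150L, end = 200L,
                          height = 4L))
  expect_equal(nrow(intersect_replicates(pk(100L, 200L, 10L),
                                         pk(300L, 400L, 4L))), 0L)
})

test_that("intersection is commutative/idempotent and never extends bases", {
  withr::with_seed(202, {
    for (rep in 1:60) {
      a <- random_peak_set()
      b <- random_peak_set()
      ab <- intersect_replicates(a, b)
      ba <- intersect_replicates(b, a)
      expect_identical(as.data.frame(ab), as.data.frame(ba))
      expect_identical(as.data.frame(intersect_replicates(a, a)),
                       as.data.frame(a))
      # base-set equality with the brute-force intersection oracle
      expect_identical(peak_base_set(ab),
                       intersect(peak_base_set(a), peak_base_set(b)))
      # subtraction never emits a base outside the sample
      sub <- subtract_control(a, b)
      expect_true(all(peak_base_set(sub) %in% peak_base_set(a)))
      expect_identical(as.data.frame(subtract_control(a,
                                                      circlenom:::empty_peaks())),
                       as.data.frame(a))
    }
  })
})

test_that("rank_sites orders by height with coordinate tie-breaks", {
  pk <- structure(
    data.frame(contig = c("c2", "c1", "c1"), start = c(5L, 9L, 2L),
               end = c(8L, 12L, 5L), height = c(3L, 30L, 3L)),
    class = c("peaks", "data.frame"))
  r <- rank_sites(pk)
  expect_equal(r$height, c(30L, 3L, 3L))
  expect_equal(r$contig, c("c1", "c1", "c2"))  # ties by contig then start
  expect_equal(r$rank, 1:3)
  expect_equal(rank_sites(structure(
    data.frame(contig = "c1", start = 0L, end = 1L, height = 1L),
    class = c("peaks", "data.frame")))$log10_height, 0)
})
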