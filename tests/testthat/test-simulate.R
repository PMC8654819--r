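sim_fixture <- function(seed = 1L, ...) {
  p <- planted_fixture(seed)
  params <- sim_params(..., seed = seed,
                       artifact_exclude = data.frame(
                         contig = p$sites$contig, pos = p$sites$cut_pos))
  list(planted = p, params = params,
       sim = simulate_reads(p$genome, p$sites, params))
}

test_that("null input gives an empty library", {
  g <- make_genome(1, 1L, 20000L)
  s <- simulate_reads(g, circlenom:::empty_sites(),
                      sim_params(background_pairs = 0L, n_artifact_loci = 0L,
                                 seed = 1L))
  expect_equal(nrow(s$pairs), 0L)
  d <- withr::local_tempdir()
  files <- write_simulation(s, d)
  expect_true(all(file.exists(files)))
  expect_length(readLines(files["r1"]), 0L)
  reread <- read_sam_pairs(files["sam"])
  expect_equal(nrow(reread), 0L)
  expect_equal(attr(reread, "contig_lengths"), circlenom:::contig_lengths(g))
})

test_that("certain cleavage yields exactly depth_per_site accepted pairs", {
  p <- planted_fixture(2L, mismatch_counts = 0L)
  s <- simulate_reads(p$genome, p$sites,
                      sim_params(depth_per_site = 100L, background_pairs = 0L,
                                 n_artifact_loci = 0L, seed = 3L))
  expect_equal(nrow(s$pairs), 100L)
  expect_true(all(flag_pair_pass(s$pairs$flag1, s$pairs$flag2)))
  key <- paste(pmin(s$pairs$flag1, s$pairs$flag2),
               pmax(s$pairs$flag1, s$pairs$flag2))
  expect_true(all(key %in% c("99 147", "83 163")))
})

test_that("truth classes are sound against the filters and counts conserve", {
  fx <- sim_fixture(4L)
  pr <- fx$sim$pairs
  expect_equal(nrow(pr),
               sum(fx$sim$n_cut_drawn) + fx$params$background_pairs +
                 fx$params$n_artifact_loci * fx$params$artifact_depth)
  pass <- flag_pair_pass(pr$flag1, pr$flag2) &
    deleted_region_size(pr$cigar1, pr$cigar2) < 20 &
    mean_quality(pr$qual1) >= 20 & mean_quality(pr$qual2) >= 20
  expect_true(all(pass[pr$class %in% c("cut", "artifact")]))
  expect_true(all(!pass[pr$class == "background"]))
})

test_that("kept-pair depth is maximal near each planted cut position", {
  fx <- sim_fixture(5L)
  kept <- filter_pairs(fx$sim$pairs)$kept
  ctg <- fx$planted$sites$contig[1]
  depth <- oracle_depth_array(kept, ctg,
                              fx$sim$contig_lengths[[ctg]])
  # the globally deepest base lies within one fragment length of the
  # on-target cut (cleave_prob 1.0 emits the most pairs)
  on_cut <- fx$planted$sites$cut_pos[fx$planted$sites$mismatches == 0][1]
  expect_lte(abs(which.max(depth) - on_cut), 400)
  for (i in seq_len(nrow(fx$planted$sites))) {
    cut <- fx$planted$sites$cut_pos[i]
    # every kept cut-derived pair for this site aligns within +/- one
    # fragment length of the cut
    sel <- kept$class == "cut" &
      grepl(fx$planted$sites$site_id[i], kept$qname, fixed = TRUE)
    expect_true(all(abs(kept$pos1[sel] - cut) <= 480))
  }
})

test_that("negative control shares artifact loci but no cleavage sites", {
  p <- planted_fixture(6L)
  params <- sim_params(seed = 6L, n_artifact_loci = 2L,
                       artifact_exclude = data.frame(
                         contig = p$sites$contig, pos = p$sites$cut_pos))
  smp <- simulate_reads(p$genome, p$sites, params)
  ctl <- simulate_negative_control(p$genome, params)
  expect_identical(smp$artifact_loci, ctl$artifact_loci)
  expect_true(all(ctl$pairs$class != "cut"))

  # coverage oracle on both truth pair sets: artifact loci peak in both
  ctg <- names(smp$contig_lengths)[1]
  d_s <- oracle_depth_array(filter_pairs(smp$pairs)$kept, ctg,
                            smp$contig_lengths[[ctg]])
  d_c <- oracle_depth_array(filter_pairs(ctl$pairs)$kept, ctg,
                            smp$contig_lengths[[ctg]])
  for (j in seq_len(nrow(smp$artifact_loci))) {
    loc <- smp$artifact_loci$pos[j]
    win <- (loc - 300):(loc + 300)
    expect_gt(max(d_s[win]), 0)
    expect_gt(max(d_c[win]), 0)
  }
  # control has no coverage at planted cleavage sites
  for (i in seq_len(nrow(p$sites)))
    expect_equal(max(d_c[(p$sites$cut_pos[i] - 200):(p$sites$cut_pos[i] + 200)]),
                 0L)

  # with no artifact loci the control shares no covered base with sample peaks
  params0 <- sim_params(seed = 7L, n_artifact_loci = 0L)
  ctl0 <- simulate_negative_control(p$genome, params0)
  d0 <- oracle_depth_array(filter_pairs(ctl0$pairs)$kept, ctg,
                           smp$contig_lengths[[ctg]])
  expect_equal(sum(d0), 0L)
})

test_that("simulation outputs are byte-identical under a fixed seed", {
  fx1 <- sim_fixture(8L)
  fx2 <- sim_fixture(8L)
  expect_identical(fx1$sim$pairs, fx2$sim$pairs)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- write_simulation(fx1$sim, d1)
  f2 <- write_simulation(fx2$sim, d2)
  for (k in names(f1))
    expect_identical(unname(tools::md5sum(f1[k])),
                     unname(tools::md5sum(f2[k])))
})

test_that("FASTQ records are well-formed and mate sequences re-oriented", {
  fx <- sim_fixture(9L)
  d <- withr::local_tempdir()
  files <- write_simulation(fx$sim, d)
  r1 <- readLines(files["r1"])
  expect_equal(length(r1), 4L * nrow(fx$sim$pairs))
  seqs <- r1[seq(2, length(r1), by = 4)]
  expect_true(all(nchar(seqs) == fx$params$read_length))
  # a reverse-flagged mate is stored forward in SAM but read-oriented in FASTQ
  i <- which(bitwAnd(fx$sim$pairs$flag1, 16L) != 0L)[1]
  expect_identical(
    seqs[i],
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(fx$sim$pairs$seq1[i]))))
})
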