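#' Simulation parameters for the synthetic CIRCLE-seq assay
#'
#' Defaults follow the assay geometry the pipeline expects: genomic DNA
#' sheared to an average 300 bp, sequenced as 75 bp paired-end reads.
#'
#' @param fragment_length_mean Mean circularised-fragment length, bp.
#' @param fragment_length_sd SD of fragment length (truncated normal,
#'   minimum `read_length`).
#' @param read_length Read length, bp.
#' @param depth_per_site Read pairs attempted per planted site; each pair is
#'   emitted with probability `cleave_prob` (binomial thinning).
#' @param background_pairs Number of background pairs that must fail the
#'   read-pair filters (non-accepted flag pairs or deletions >= 20 bp).
#' @param n_artifact_loci Number of shared artifact loci emitted identically
#'   in sample and negative control; their pairs pass the filters and are
#'   only removable by control subtraction.
#' @param artifact_depth Read pairs per artifact locus.
#' @param low_quality_frac Fraction of background pairs given mean base
#'   quality < 20 (exercises the quality screen; cut-derived pairs always
#'   carry qualities >= Q30 so truth accounting stays exact).
#' @param artifact_exclude Optional data.frame with columns `contig` and
#'   `pos`: artifact loci are drawn so that their read footprints (up to
#'   one maximal fragment length, about mean + 5 sd, either side) cannot
#'   touch these positions' footprints. On a miniature genome, uniform
#'   placement would frequently
#'   collide with planted cleavage sites — a coincidence that is vanishingly
#'   rare at genome scale — so the planted cut positions are normally
#'   excluded here.
#' @param seed Integer seed; fixed seed + params give byte-identical outputs.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(fragment_length_mean = 300, fragment_length_sd = 30,
                       read_length = 75L, depth_per_site = 200L,
                       background_pairs = 100L, n_artifact_loci = 2L,
                       artifact_depth = 50L, low_quality_frac = 0.1,
                       artifact_exclude = NULL, seed = 1L) {
  if (read_length > fragment_length_mean)
    stopf("read_length (%s) must be <= fragment_length_mean (%s)",
          read_length, fragment_length_mean)
  counts <- c(depth_per_site, background_pairs, n_artifact_loci, artifact_depth)
  if (any(counts < 0)) stopf("all counts must be >= 0")
  if (low_quality_frac < 0 || low_quality_frac > 1)
    stopf("low_quality_frac must be in [0, 1]")
  structure(list(fragment_length_mean = fragment_length_mean,
                 fragment_length_sd = fragment_length_sd,
                 read_length = as.integer(read_length),
                 depth_per_site = as.integer(depth_per_site),
                 background_pairs = as.integer(background_pairs),
                 n_artifact_loci = as.integer(n_artifact_loci),
                 artifact_depth = as.integer(artifact_depth),
                 low_quality_frac = low_quality_frac,
                 artifact_exclude = artifact_exclude,
                 seed = as.integer(seed)),
            class = "sim_params")
}

# Accepted ("concordant opposite-orientation") flag pairs and the background
# flag pairs deliberately outside that set.
ACCEPTED_FLAG_PAIRS <- list(c(99L, 147L), c(83L, 163L))
BACKGROUND_FLAG_PAIRS <- list(c(97L, 145L), c(65L, 129L))

QUAL_HIGH <- 40L  # 'I'
QUAL_LOW <- 15L   # '0' -> mean 15 < 20, fails the quality screen

qual_string <- function(q, len) strrep(intToUtf8(q + 33L), len)

# Draw fragment lengths from a truncated normal (min = read_length).
draw_fragment_lengths <- function(n, params) {
  if (n == 0L) return(integer(0))
  out <- integer(n)
  todo <- seq_len(n)
  for (try in 1:50) {
    L <- as.integer(round(rnorm(length(todo), params$fragment_length_mean,
                                params$fragment_length_sd)))
    ok <- L >= params$read_length
    out[todo[ok]] <- L[ok]
    todo <- todo[!ok]
    if (length(todo) == 0L) break
  }
  if (length(todo) > 0L) stopf("failed to draw valid fragment lengths")
  out
}

# Emit one class of pairs centred on cut positions. Returns a pair table in
# the package's internal paired-record layout (one row per pair).
emit_cut_pairs <- function(genome, contig, cut_pos, qname, params) {
  n <- length(cut_pos)
  if (n == 0L) return(empty_pairs())
  lens <- contig_lengths(genome)
  rl <- params$read_length
  L <- draw_fragment_lengths(n, params)
  # fragment [f0, f0 + L) covering the inter-base cut coordinate
  u <- 1L + as.integer(floor(runif(n) * (L - 1L)))
  f0 <- cut_pos - u
  clen <- lens[contig]
  f0 <- pmax(0L, pmin(f0, clen - L))
  orient <- sample.int(2L, n, replace = TRUE)  # 1 -> (99,147), 2 -> (83,163)

  left_pos <- f0 + 1L                 # 1-based leftmost of forward read
  right_pos <- f0 + L - rl + 1L       # 1-based leftmost of reverse read
  left_seq <- substring(genome[contig], left_pos, left_pos + rl - 1L)
  right_seq <- substring(genome[contig], right_pos, right_pos + rl - 1L)
  cig <- paste0(rl, "M")
  q <- qual_string(QUAL_HIGH, rl)

  fwd_first <- orient == 1L
  data.frame(
    qname = qname, class = NA_character_, contig = contig,
    flag1 = ifelse(fwd_first, 99L, 83L),
    pos1 = ifelse(fwd_first, left_pos, right_pos),
    cigar1 = cig,
    seq1 = ifelse(fwd_first, left_seq, right_seq),
    qual1 = q,
    flag2 = ifelse(fwd_first, 147L, 163L),
    pos2 = ifelse(fwd_first, right_pos, left_pos),
    cigar2 = cig,
    seq2 = ifelse(fwd_first, right_seq, left_seq),
    qual2 = q,
    tlen = L,
    stringsAsFactors = FALSE)
}

# Background pairs designed to fail the pipeline's read-pair filters: half get flag
# pairs outside the accepted set, half get an accepted flag pair but a CIGAR
# containing a deletion of 20-40 bp. A low_quality_frac subset additionally
# gets mean base quality < 20.
emit_background_pairs <- function(genome, params) {
  n <- params$background_pairs
  if (n == 0L) return(empty_pairs())
  lens <- contig_lengths(genome)
  rl <- params$read_length
  ctg <- sample(names(lens), n, replace = TRUE, prob = as.numeric(lens))
  mode_del <- runif(n) < 0.5
  dsize <- 20L + as.integer(floor(runif(n) * 21L))     # 20..40 bp
  span <- ifelse(mode_del, rl + dsize, rl)
  maxref <- as.integer(max(span) + rl + 50L)
  pos1 <- 1L + as.integer(floor(runif(n) * (lens[ctg] - maxref)))

  a <- 30L                                              # M bases before the D
  cigar1 <- ifelse(mode_del,
                   paste0(a, "M", dsize, "D", rl - a, "M"),
                   paste0(rl, "M"))
  seq_plain <- substring(genome[ctg], pos1, pos1 + rl - 1L)
  seq_del <- paste0(
    substring(genome[ctg], pos1, pos1 + a - 1L),
    substring(genome[ctg], pos1 + a + dsize, pos1 + dsize + rl - 1L))
  seq1 <- ifelse(mode_del, seq_del, seq_plain)

  pos2 <- pos1 + span + 1L
  seq2 <- substring(genome[ctg], pos2, pos2 + rl - 1L)

  badflags <- BACKGROUND_FLAG_PAIRS[[1L]]
  altflags <- BACKGROUND_FLAG_PAIRS[[2L]]
  alt <- runif(n) < 0.5
  flag1 <- ifelse(mode_del, 99L, ifelse(alt, badflags[1], altflags[1]))
  flag2 <- ifelse(mode_del, 147L, ifelse(alt, badflags[2], altflags[2]))

  lowq <- runif(n) < params$low_quality_frac
  q <- ifelse(lowq, qual_string(QUAL_LOW, rl), qual_string(QUAL_HIGH, rl))

  data.frame(
    qname = sprintf("bg%05d", seq_len(n)), class = "background", contig = ctg,
    flag1 = flag1, pos1 = pos1, cigar1 = cigar1, seq1 = seq1, qual1 = q,
    flag2 = flag2, pos2 = pos2, cigar2 = paste0(rl, "M"), seq2 = seq2,
    qual2 = q, tlen = pos2 - pos1 + rl,
    stringsAsFactors = FALSE)
}

empty_pairs <- function() {
  data.frame(qname = character(0), class = character(0), contig = character(0),
             flag1 = integer(0), pos1 = integer(0), cigar1 = character(0),
             seq1 = character(0), qual1 = character(0),
             flag2 = integer(0), pos2 = integer(0), cigar2 = character(0),
             seq2 = character(0), qual2 = character(0), tlen = integer(0),
             stringsAsFactors = FALSE)
}

# Shared artifact loci: positions drawn from the seed alone, so sample and
# negative control (same params) place them identically.
artifact_loci <- function(genome, params) {
  k <- params$n_artifact_loci
  if (k == 0L)
    return(data.frame(contig = character(0), pos = integer(0)))
  lens <- contig_lengths(genome)
  # two loci's read footprints (each up to ~ mean + 5 sd either side of the
  # locus) must not touch, or an artifact could mask a genuine cleavage peak
  margin <- as.integer(2 * (params$fragment_length_mean +
                              5 * params$fragment_length_sd))
  excl <- params$artifact_exclude
  with_seed(params$seed, {
    out <- data.frame(contig = character(0), pos = integer(0))
    for (i in seq_len(k)) {
      for (try in seq_len(1000L)) {
        ctg <- sample(names(lens), 1L, prob = as.numeric(lens))
        pos <- margin + as.integer(floor(runif(1) * (lens[[ctg]] - 2L * margin)))
        near_excl <- !is.null(excl) && nrow(excl) > 0L &&
          any(excl$contig == ctg & abs(excl$pos - pos) < margin)
        near_prev <- nrow(out) > 0L &&
          any(out$contig == ctg & abs(out$pos - pos) < margin)
        if (!near_excl && !near_prev) break
        if (try == 1000L) stopf("could not place artifact loci disjointly")
      }
      out <- rbind(out, data.frame(contig = ctg, pos = pos,
                                   stringsAsFactors = FALSE))
    }
    out
  })
}

#' Simulate a CIRCLE-seq sample library
#'
#' Generates the read pairs of one Cas9-treated library over a genome with
#' planted sites. Three molecule classes are emitted:
#' \describe{
#'   \item{cut}{`Binomial(depth_per_site, cleave_prob)` pairs per planted
#'     site, centred on its cut position, with flag pairs drawn uniformly
#'     from \{(99,147), (83,163)\} — these pass every filter.}
#'   \item{background}{pairs placed uniformly that fail the filters, via
#'     non-accepted flag pairs or CIGAR deletions >= 20 bp.}
#'   \item{artifact}{filter-passing pairs at shared loci that also appear in
#'     the negative control, removable only by control subtraction.}
#' }
#'
#' @param genome A `ref_genome` (typically from [plant_sites()]).
#' @param sites Truth site table from [plant_sites()].
#' @param params A [sim_params()].
#' @return A list of class `circleseq_sim` with elements `pairs` (the truth
#'   pair table, one row per pair, with a `class` column), `sites`,
#'   `n_cut_drawn` (per-site emitted pair counts), `params`,
#'   `contig_lengths`.
#' @export
simulate_reads <- function(genome, sites, params = sim_params()) {
  stopifnot(inherits(genome, "ref_genome"), inherits(params, "sim_params"))
  arts <- artifact_loci(genome, params)
  with_seed(params$seed, {
    n_cut <- if (nrow(sites)) rbinom(nrow(sites), params$depth_per_site,
                                     sites$cleave_prob) else integer(0)
    cut <- if (sum(n_cut) > 0L) {
      idx <- rep(seq_len(nrow(sites)), n_cut)
      p <- emit_cut_pairs(genome, sites$contig[idx], sites$cut_pos[idx],
                          sprintf("cut_%s_%05d", sites$site_id[idx],
                                  seq_along(idx)),
                          params)
      p$class <- "cut"
      p
    } else empty_pairs()
    art <- emit_artifact_pairs(genome, arts, params, "s")
    bg <- emit_background_pairs(genome, params)
    pairs <- rbind(cut, art, bg)
  })
  attr(pairs, "contig_lengths") <- contig_lengths(genome)
  structure(list(pairs = pairs, sites = sites, n_cut_drawn = n_cut,
                 artifact_loci = arts, params = params,
                 contig_lengths = contig_lengths(genome)),
            class = "circleseq_sim")
}

emit_artifact_pairs <- function(genome, arts, params, tag) {
  if (nrow(arts) == 0L || params$artifact_depth == 0L) return(empty_pairs())
  idx <- rep(seq_len(nrow(arts)), each = params$artifact_depth)
  p <- emit_cut_pairs(genome, arts$contig[idx], arts$pos[idx],
                      sprintf("art%s_%02d_%04d", tag, idx, seq_along(idx)),
                      params)
  p$class <- "artifact"
  p
}

#' Simulate the negative control (Cas9/sgRNA untreated) library
#'
#' Emits no cut-derived pairs at any planted site; contains the same shared
#' artifact loci as the matched sample (same `params`) plus background.
#'
#' @inheritParams simulate_reads
#' @return A `circleseq_sim` whose `pairs` contain only artifact and
#'   background classes.
#' @export
simulate_negative_control <- function(genome, params = sim_params()) {
  stopifnot(inherits(genome, "ref_genome"), inherits(params, "sim_params"))
  arts <- artifact_loci(genome, params)
  with_seed(params$seed + 1L, {
    art <- emit_artifact_pairs(genome, arts, params, "c")
    bg <- emit_background_pairs(genome, params)
    pairs <- rbind(art, bg)
  })
  attr(pairs, "contig_lengths") <- contig_lengths(genome)
  structure(list(pairs = pairs, sites = empty_sites(),
                 n_cut_drawn = integer(0), artifact_loci = arts,
                 params = params, contig_lengths = contig_lengths(genome)),
            class = "circleseq_sim")
}

#' Write a simulated library to FASTQ (R1/R2), truth SAM and truth BED
#'
#' @param sim A `circleseq_sim`.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix.
#' @return Named character vector of the files written, invisibly.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  stopifnot(inherits(sim, "circleseq_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(r1 = file.path(dir, paste0(prefix, "_R1.fastq")),
             r2 = file.path(dir, paste0(prefix, "_R2.fastq")),
             sam = file.path(dir, paste0(prefix, ".sam")),
             bed = file.path(dir, paste0(prefix, "_truth.bed")))
  write_pair_fastq(sim$pairs, files["r1"], files["r2"])
  write_pair_sam(sim$pairs, sim$contig_lengths, files["sam"])
  write_truth_bed(sim$sites, files["bed"])
  invisible(files)
}

# FASTQ: mate sequences are emitted read-orientation (reverse-flagged mates
# are reverse-complemented back out of reference orientation).
write_pair_fastq <- function(pairs, r1_path, r2_path) {
  emit <- function(seqs, quals, flags, names, path) {
    rev <- bitwAnd(flags, 16L) != 0L
    s <- seqs
    q <- quals
    if (any(rev)) {
      s[rev] <- revcomp(s[rev])
      q[rev] <- vapply(q[rev], function(x)
        intToUtf8(rev(utf8ToInt(x))), character(1), USE.NAMES = FALSE)
    }
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(paste0("@", names, "\n", s, "\n+\n", q), con, sep = "\n")
  }
  if (nrow(pairs) == 0L) {
    file.create(r1_path, r2_path)
    return(invisible(NULL))
  }
  emit(pairs$seq1, pairs$qual1, pairs$flag1, pairs$qname, r1_path)
  emit(pairs$seq2, pairs$qual2, pairs$flag2, pairs$qname, r2_path)
  invisible(NULL)
}

# Truth SAM: header + two records per pair, mates adjacent (name-grouped).
write_pair_sam <- function(pairs, contig_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:queryname",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)))
  fmt <- function(qname, flag, ctg, pos, cigar, pnext, tlen, seq, qual) {
    paste(qname, flag, ctg, pos, 60L, cigar, "=", pnext, tlen, seq, qual,
          sep = "\t")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (nrow(pairs) > 0L) {
    l1 <- fmt(pairs$qname, pairs$flag1, pairs$contig, pairs$pos1, pairs$cigar1,
              pairs$pos2, ifelse(pairs$pos1 <= pairs$pos2,
                                 pairs$tlen, -pairs$tlen),
              pairs$seq1, pairs$qual1)
    l2 <- fmt(pairs$qname, pairs$flag2, pairs$contig, pairs$pos2, pairs$cigar2,
              pairs$pos1, ifelse(pairs$pos2 < pairs$pos1,
                                 pairs$tlen, -pairs$tlen),
              pairs$seq2, pairs$qual2)
    out <- character(2L * nrow(pairs))
    out[c(TRUE, FALSE)] <- l1
    out[c(FALSE, TRUE)] <- l2
    writeLines(out, con, sep = "\n")
  }
  invisible(path)
}
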