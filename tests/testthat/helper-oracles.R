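# Shared fixtures and independent brute-force oracles. The oracles
# deliberately avoid the package's IRanges/RLE code paths: they accumulate
# per-base integer arrays and scan them position by position.

TEST_SPACER <- "ACGTTGCAGATTACGGCTAA"

test_sgrna <- function() sgrna_spec(TEST_SPACER)

# The reference study conditions: 50 kb genome, one on-target at cleavage
# probability 1.0, eight off-targets with 1-6 mismatches and probabilities
# 0.85 down to 0.1, depth 200 pairs/site, 2 replicates, shared artifact loci
# in sample and control.
default_study_config <- function(seed) {
  run_config(test_sgrna(),
             simulate = list(n_contigs = 1L, contig_length = 50000L,
                             mismatch_counts = c(0L, 1:6, 2L, 3L),
                             depth_per_site = 200L, background_pairs = 100L,
                             n_artifact_loci = 2L, artifact_depth = 50L),
             seed = seed)
}

# Reference width of one CIGAR, parsed by hand (M/D/N/=/X consume reference).
oracle_cigar_ref_width <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  len <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  sum(len[op %in% c("M", "D", "N", "=", "X")])
}

# Per-base depth array for one contig, accumulated mate by mate.
oracle_depth_array <- function(pairs, contig, contig_length) {
  depth <- integer(contig_length)
  add <- function(pos, cigar) {
    w <- oracle_cigar_ref_width(cigar)
    if (w > 0) depth[pos:(pos + w - 1)] <<- depth[pos:(pos + w - 1)] + 1L
  }
  sel <- which(pairs$contig == contig)
  for (i in sel) {
    add(pairs$pos1[i], pairs$cigar1[i])
    add(pairs$pos2[i], pairs$cigar2[i])
  }
  depth
}

# Naive peak caller on a per-base depth array: linear scan with merge gap.
oracle_peaks <- function(depth, min_height, merge_gap = 0L) {
  qual <- which(depth >= min_height)     # 1-based positions
  if (length(qual) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      height = integer(0)))
  brk <- c(0, which(diff(qual) > merge_gap + 1), length(qual))
  out <- lapply(seq_len(length(brk) - 1), function(k) {
    seg <- qual[(brk[k] + 1):brk[k + 1]]
    s <- min(seg); e <- max(seg)
    data.frame(start = s - 1L, end = e,
               height = max(depth[s:e]))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Convert a coverage_track (one contig) back to a per-base depth array.
track_to_array <- function(track, contig, contig_length) {
  depth <- integer(contig_length)
  tr <- track[track$contig == contig, , drop = FALSE]
  for (i in seq_len(nrow(tr)))
    depth[(tr$start[i] + 1):tr$end[i]] <- tr$depth[i]
  depth
}

# Random disjoint per-contig peak set, shaped like call_peaks output.
random_peak_set <- function(n_max = 8L, contig = "c1", span = 10000L) {
  n <- sample.int(n_max + 1L, 1L) - 1L
  if (n == 0L) return(circlenom:::empty_peaks())
  starts <- sort(sample.int(span - 200L, n))
  ends <- starts + sample.int(150L, n)
  keep <- logical(n)                         # enforce strict disjointness
  last_end <- -1L
  for (i in seq_len(n)) {
    if (starts[i] > last_end) {
      keep[i] <- TRUE
      last_end <- ends[i]
    }
  }
  structure(data.frame(contig = rep(contig, sum(keep)),
                       start = starts[keep] - 1L,
                       end = ends[keep], height = sample.int(50L, sum(keep),
                                                             replace = TRUE),
                       stringsAsFactors = FALSE),
            class = c("peaks", "data.frame"))
}

# Set of genomic bases (1-based) covered by a peak table on one contig.
peak_base_set <- function(peaks) {
  if (nrow(peaks) == 0L) return(integer(0))
  sort(unique(unlist(Map(function(s, e) (s + 1L):e, peaks$start, peaks$end))))
}

# A small planted genome shared by annotation and filter tests.
planted_fixture <- function(seed = 11L, mismatch_counts = c(0L, 3L)) {
  g <- make_genome(seed, 1L, 20000L)
  plant_sites(g, test_sgrna(), mismatch_counts, seed = seed + 1L)
}
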