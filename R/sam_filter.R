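#' Mean base quality of a Phred+33 quality string
#'
#' A read pair is screened out when either mate's mean base quality is
#' strictly below 20 (the screen keeps a mean of exactly 20).
#'
#' @param qual Phred+33 encoded quality string(s).
#' @return Numeric vector of mean Phred scores.
#' @examples
#' mean_quality(strrep("I", 10))  # Q40
#' @export
mean_quality <- function(qual) {
  if (any(!nzchar(qual))) stopf("empty quality string")
  vapply(qual, function(q) mean(utf8ToInt(q)) - 33, numeric(1),
         USE.NAMES = FALSE)
}

#' Test whether a mate pair carries an accepted SAM flag pair
#'
#' CIRCLE-seq-specific concordant opposite-orientation pairs are recognised
#' by their exact SAM flag values: the unordered pair must be \{83, 163\} or
#' \{99, 147\}. No other combination passes — notably not merely
#' "properly paired" pairs such as \{97, 145\}.
#'
#' @param flag1,flag2 Integer SAM flags (vectorised).
#' @return Logical vector.
#' @examples
#' flag_pair_pass(99, 147)
#' flag_pair_pass(97, 145)
#' @export
flag_pair_pass <- function(flag1, flag2) {
  lo <- pmin(flag1, flag2)
  hi <- pmax(flag1, flag2)
  (lo == 83L & hi == 163L) | (lo == 99L & hi == 147L)
}

#' Size of the deleted region of a read pair
#'
#' Parses both mates' CIGAR strings and returns, under the default
#' `metric = "max"`, the largest single deletion (`D`) operation across the
#' pair; `metric = "sum"` returns the total deleted length instead. The
#' pair-level rule keeps a pair iff this size is `< 20` bp.
#'
#' @param cigar1,cigar2 CIGAR strings (vectorised, equal length).
#' @param metric `"max"` (largest single D op) or `"sum"` (total D length).
#' @return Integer vector of deletion sizes in bp.
#' @examples
#' deleted_region_size("30M5D40M", "75M")
#' @export
deleted_region_size <- function(cigar1, cigar2, metric = c("max", "sum")) {
  metric <- match.arg(metric)
  bad <- !grepl("^([0-9]+[MIDNSHP=X])+$", c(cigar1, cigar2))
  if (any(bad))
    stopf("malformed CIGAR: %s", c(cigar1, cigar2)[bad][1])
  d1 <- GenomicAlignments::explodeCigarOpLengths(cigar1, ops = "D")
  d2 <- GenomicAlignments::explodeCigarOpLengths(cigar2, ops = "D")
  f <- if (metric == "max") function(x) if (length(x)) max(x) else 0L else sum
  per_pair <- function(a, b) {
    if (metric == "max") max(f(a), f(b)) else f(a) + f(b)
  }
  as.integer(mapply(per_pair, d1, d2))
}

# Reference width consumed by a CIGAR (M/D/N/=/X ops).
cigar_ref_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

#' Read a plain-text SAM file into the package's pair table
#'
#' Reads the 11 mandatory columns, drops secondary/supplementary alignments
#' (flag bits 0x100/0x800), groups primary records by query name, and
#' returns one row per complete pair. Records whose mate is never seen are
#' counted but excluded from the pair table.
#'
#' @param path SAM file path.
#' @return A pair table (data.frame) with attributes `contig_lengths` (from
#'   the `@SQ` header lines) and `n_unpaired`.
#' @export
read_sam_pairs <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  if (length(sq) == 0L) stopf("SAM file %s has no @SQ header lines", path)
  sqf <- strsplit(sq, "\t", fixed = TRUE)
  pick <- function(fields, tag)
    sub(paste0("^", tag, ":"), "",
        vapply(fields, function(x) x[startsWith(x, paste0(tag, ":"))][1], ""))
  sn <- pick(sqf, "SN")
  ln <- as.integer(pick(sqf, "LN"))
  lens <- stats::setNames(ln, sn)
  if (length(body) == 0L) {
    out <- empty_pairs()
    attr(out, "contig_lengths") <- lens
    attr(out, "n_unpaired") <- 0L
    return(out)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  rec <- data.frame(
    qname = vapply(f, `[`, "", 1L),
    flag = as.integer(vapply(f, `[`, "", 2L)),
    rname = vapply(f, `[`, "", 3L),
    pos = as.integer(vapply(f, `[`, "", 4L)),
    cigar = vapply(f, `[`, "", 6L),
    tlen = as.integer(vapply(f, `[`, "", 9L)),
    seq = vapply(f, `[`, "", 10L),
    qual = vapply(f, `[`, "", 11L),
    stringsAsFactors = FALSE)
  rec <- rec[bitwAnd(rec$flag, 0x900L) == 0L, , drop = FALSE]
  cnt <- table(rec$qname)
  paired_names <- names(cnt)[cnt == 2L]
  n_unpaired <- sum(cnt != 2L)
  rec <- rec[rec$qname %in% paired_names, , drop = FALSE]
  rec <- rec[order(match(rec$qname, unique(rec$qname))), , drop = FALSE]
  i1 <- seq(1L, nrow(rec), by = 2L)
  i2 <- i1 + 1L
  if (any(rec$qname[i1] != rec$qname[i2]))
    stopf("internal pairing error reading %s", path)
  if (any(rec$rname[i1] != rec$rname[i2]))
    stopf("inter-contig pairs not supported (qname %s)",
          rec$qname[i1][rec$rname[i1] != rec$rname[i2]][1])
  out <- data.frame(
    qname = rec$qname[i1], class = NA_character_, contig = rec$rname[i1],
    flag1 = rec$flag[i1], pos1 = rec$pos[i1], cigar1 = rec$cigar[i1],
    seq1 = rec$seq[i1], qual1 = rec$qual[i1],
    flag2 = rec$flag[i2], pos2 = rec$pos[i2], cigar2 = rec$cigar[i2],
    seq2 = rec$seq[i2], qual2 = rec$qual[i2],
    tlen = abs(rec$tlen[i1]),
    stringsAsFactors = FALSE)
  attr(out, "contig_lengths") <- lens
  attr(out, "n_unpaired") <- n_unpaired
  out
}

#' Filter read pairs by quality, flag pair and deleted-region size
#'
#' Applies the three read-level rules in order — mean base quality, exact
#' flag-pair membership, deleted-region size — dropping each pair at its
#' first failing stage:
#' \enumerate{
#'   \item quality: drop if either mate's mean base quality < `min_mean_q`;
#'   \item flags: keep only unordered flag pairs \{83,163\} or \{99,147\};
#'   \item deletion: drop if the deleted-region size >= `max_deletion` bp.
#' }
#'
#' @param x A pair table (from [read_sam_pairs()] or a `circleseq_sim`'s
#'   `pairs`) or a path to a SAM file.
#' @param min_mean_q Quality threshold (strict `<` drops); default 20.
#' @param max_deletion Deleted-region threshold in bp; pairs are kept iff
#'   size `< max_deletion`; default 20.
#' @param deletion_metric `"max"` (default) or `"sum"`; see
#'   [deleted_region_size()].
#' @return A list of class `filter_result`: `kept` (pair table) and
#'   `report`, a one-row data.frame with counts `input`, `dropped_quality`,
#'   `dropped_flags`, `dropped_deletion`, `kept` satisfying
#'   `input = dropped_quality + dropped_flags + dropped_deletion + kept`.
#' @export
filter_pairs <- function(x, min_mean_q = 20, max_deletion = 20,
                         deletion_metric = c("max", "sum")) {
  deletion_metric <- match.arg(deletion_metric)
  pairs <- if (is.character(x) && length(x) == 1L) read_sam_pairs(x) else x
  n <- nrow(pairs)
  if (n == 0L) {
    report <- data.frame(input = 0L, dropped_quality = 0L, dropped_flags = 0L,
                         dropped_deletion = 0L, kept = 0L)
    return(structure(list(kept = pairs, report = report),
                     class = "filter_result"))
  }
  q_ok <- mean_quality(pairs$qual1) >= min_mean_q &
    mean_quality(pairs$qual2) >= min_mean_q
  f_ok <- flag_pair_pass(pairs$flag1, pairs$flag2)
  d_ok <- deleted_region_size(pairs$cigar1, pairs$cigar2,
                              metric = deletion_metric) < max_deletion
  dropped_quality <- sum(!q_ok)
  dropped_flags <- sum(q_ok & !f_ok)
  dropped_deletion <- sum(q_ok & f_ok & !d_ok)
  keep <- q_ok & f_ok & d_ok
  kept <- pairs[keep, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "contig_lengths") <- attr(pairs, "contig_lengths")
  report <- data.frame(input = n, dropped_quality = dropped_quality,
                       dropped_flags = dropped_flags,
                       dropped_deletion = dropped_deletion, kept = sum(keep))
  structure(list(kept = kept, report = report), class = "filter_result")
}
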