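#' Compute per-base read coverage as a run-length-encoded track
#'
#' Depth at a base is the number of mate alignments whose
#' reference-consuming CIGAR span (M/D/=/X/N) covers it; both mates of every
#' kept pair contribute. The track is the bedGraph-style run-length
#' encoding of the nonzero depth regions, 0-based half-open.
#'
#' @param pairs A kept pair table (e.g. `filter_pairs(...)$kept`).
#' @param contig_lengths Named integer vector of contig lengths; defaults to
#'   the table's `contig_lengths` attribute.
#' @return A data.frame of class `coverage_track` with columns `contig`,
#'   `start` (0-based), `end` (half-open), `depth` (> 0), carrying
#'   `contig_lengths` as an attribute.
#' @export
coverage_track <- function(pairs, contig_lengths = NULL) {
  if (is.null(contig_lengths)) contig_lengths <- attr(pairs, "contig_lengths")
  if (is.null(contig_lengths)) stopf("contig_lengths required")
  starts <- c(pairs$pos1, pairs$pos2)
  widths <- c(cigar_ref_width(pairs$cigar1), cigar_ref_width(pairs$cigar2))
  ctg <- rep(pairs$contig, 2L)
  over <- starts + widths - 1L > contig_lengths[ctg]
  if (any(over))
    stopf("alignment beyond contig end (qname %s)",
          rep(pairs$qname, 2L)[over][1])
  rows <- lapply(names(contig_lengths), function(cn) {
    sel <- ctg == cn
    cv <- IRanges::coverage(IRanges::IRanges(starts[sel], width = widths[sel]),
                            width = contig_lengths[[cn]])
    rl <- S4Vectors::runLength(cv)
    rv <- S4Vectors::runValue(cv)
    ends <- cumsum(rl)
    keep <- rv > 0L
    if (!any(keep)) return(NULL)
    data.frame(contig = cn, start = ends[keep] - rl[keep], end = ends[keep],
               depth = as.integer(rv[keep]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), depth = integer(0),
                      stringsAsFactors = FALSE)
  attr(out, "contig_lengths") <- contig_lengths
  class(out) <- c("coverage_track", "data.frame")
  out
}

empty_peaks <- function() {
  structure(data.frame(contig = character(0), start = integer(0),
                       end = integer(0), height = integer(0),
                       stringsAsFactors = FALSE),
            class = c("peaks", "data.frame"))
}

#' Call peaks from a coverage track
#'
#' A peak is a maximal interval in which depth >= `min_height`, with
#' intervals separated by at most `merge_gap` bases merged into one; its
#' height is the maximum depth inside.
#'
#' @param track A `coverage_track`.
#' @param min_height Minimum depth (>= 1) for a base to seed a peak.
#' @param merge_gap Merge qualifying intervals separated by <= this many
#'   bases (default 0: only directly adjacent runs merge).
#' @return A data.frame of class `peaks` with columns `contig`, `start`
#'   (0-based), `end` (half-open), `height`.
#' @export
call_peaks <- function(track, min_height = 1L, merge_gap = 0L) {
  if (min_height < 1L) stopf("min_height must be >= 1, got %s", min_height)
  if (merge_gap < 0L) stopf("merge_gap must be >= 0")
  rows <- lapply(split(as.data.frame(track), track$contig), function(tr) {
    tr <- tr[tr$depth >= min_height, , drop = FALSE]
    if (nrow(tr) == 0L) return(NULL)
    tr <- tr[order(tr$start), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(tr$start[-1L] - tr$end[-nrow(tr)] >
                                     merge_gap)))
    data.frame(contig = tr$contig[1L],
               start = as.integer(tapply(tr$start, grp, min)),
               end = as.integer(tapply(tr$end, grp, max)),
               height = as.integer(tapply(tr$depth, grp, max)),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty_peaks())
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peaks", "data.frame")
  out
}

peaks_by_contig_iranges <- function(peaks) {
  split(IRanges::IRanges(peaks$start + 1L, peaks$end), peaks$contig)
}

#' Subtract negative-control peaks from sample peaks
#'
#' Removes every sample peak that overlaps (by >= 1 bp) any peak of the
#' negative control; surviving peaks pass through unmodified. This is the
#' any-overlap exclusion semantics of `bedtools intersect -v`.
#'
#' @param sample,control `peaks` data.frames.
#' @return A `peaks` data.frame (subset of `sample`).
#' @export
subtract_control <- function(sample, control) {
  if (nrow(sample) == 0L || nrow(control) == 0L) return(sample)
  drop <- logical(nrow(sample))
  for (cn in unique(sample$contig)) {
    si <- which(sample$contig == cn)
    ci <- which(control$contig == cn)
    if (length(ci) == 0L) next
    ir_s <- IRanges::IRanges(sample$start[si] + 1L, sample$end[si])
    ir_c <- IRanges::IRanges(control$start[ci] + 1L, control$end[ci])
    drop[si] <- IRanges::overlapsAny(ir_s, ir_c)
  }
  out <- sample[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect peaks across replicate experiments
#'
#' Returns the base-wise intersections of overlapping peak pairs between two
#' replicates; each output interval's height is the minimum of the two
#' parent heights (conservative evidence). Commutative, and idempotent on a
#' disjoint peak set.
#'
#' @param rep_a,rep_b `peaks` data.frames (each already control-subtracted).
#' @return A `peaks` data.frame.
#' @export
intersect_replicates <- function(rep_a, rep_b) {
  if (nrow(rep_a) == 0L || nrow(rep_b) == 0L) return(empty_peaks())
  rows <- lapply(intersect(unique(rep_a$contig), unique(rep_b$contig)),
                 function(cn) {
    ai <- which(rep_a$contig == cn)
    bi <- which(rep_b$contig == cn)
    ir_a <- IRanges::IRanges(rep_a$start[ai] + 1L, rep_a$end[ai])
    ir_b <- IRanges::IRanges(rep_b$start[bi] + 1L, rep_b$end[bi])
    hits <- IRanges::findOverlaps(ir_a, ir_b)
    if (length(hits) == 0L) return(NULL)
    qa <- S4Vectors::queryHits(hits)
    qb <- S4Vectors::subjectHits(hits)
    inter <- IRanges::pintersect(ir_a[qa], ir_b[qb])
    data.frame(contig = cn, start = IRanges::start(inter) - 1L,
               end = IRanges::end(inter),
               height = pmin(rep_a$height[ai][qa], rep_b$height[bi][qb]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) return(empty_peaks())
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peaks", "data.frame")
  out
}

#' Rank peaks by height with log10 transform
#'
#' Orders peaks by height descending (ties broken by contig then start
#' ascending, so output is deterministic) and annotates `log10_height` and
#' `rank`.
#'
#' @param peaks A `peaks` data.frame with all heights >= 1.
#' @return A data.frame with columns `contig`, `start`, `end`, `height`,
#'   `log10_height`, `rank`.
#' @export
rank_sites <- function(peaks) {
  if (nrow(peaks) == 0L)
    return(cbind(as.data.frame(empty_peaks()),
                 log10_height = numeric(0), rank = integer(0)))
  if (any(peaks$height < 1L)) stopf("peak heights must be >= 1 for ranking")
  o <- order(-peaks$height, peaks$contig, peaks$start)
  out <- as.data.frame(peaks)[o, , drop = FALSE]
  out$log10_height <- log10(out$height)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Write a coverage track or peak set as bedGraph
#'
#' Four columns (chrom, start, end, value), 0-based half-open, per the UCSC
#' bedGraph convention. Peaks are written with their height as the value.
#'
#' @param x A `coverage_track` or `peaks` data.frame.
#' @param path Output path.
#' @param header Optional `# key=value` provenance lines to prepend.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path, header = character(0)) {
  val <- if ("depth" %in% names(x)) x$depth else x$height
  con <- file(path, "wb")
  on.exit(close(con))
  if (length(header)) writeLines(header, con, sep = "\n")
  if (nrow(x) > 0L)
    writeLines(paste(x$contig, x$start, x$end, val, sep = "\t"), con,
               sep = "\n")
  invisible(path)
}
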