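#' Find the best-matching protospacer under a peak
#'
#' Scans both strands of the peak interval, extended by `flank` bp on each
#' side, for 20-mers adjacent to a PAM-pattern match, and returns the hit
#' with the fewest mismatches to the spacer. Ties are broken by smaller
#' distance from the hit's inferred cut position to the peak's apex (its
#' depth-maximal base, or the midpoint when no track is given), then by
#' genomic coordinate, then by `+` strand.
#'
#' @param genome A `ref_genome`.
#' @param peak One-row `peaks` data.frame (or a list with `contig`, `start`,
#'   `end`).
#' @param sgrna An [sgrna_spec()].
#' @param flank Search window extension in bp (default 25).
#' @param apex Optional 0-based position of the peak's depth-maximal base.
#' @return A one-row data.frame with columns `matched_protospacer`,
#'   `match_strand`, `mismatches`, `pam_observed`, `cut_inferred` (0-based
#'   inter-base), or `NULL` when no PAM-adjacent 20-mer exists in the
#'   window.
#' @export
find_protospacer <- function(genome, peak, sgrna, flank = 25L, apex = NULL) {
  stopifnot(inherits(genome, "ref_genome"), inherits(sgrna, "sgrna_spec"))
  if (flank < 0L) stopf("flank must be >= 0")
  ctg <- as.character(peak$contig)
  clen <- nchar(genome[[ctg]])
  w0 <- max(0L, as.integer(peak$start) - as.integer(flank))
  w1 <- min(clen, as.integer(peak$end) + as.integer(flank))
  if (w0 > as.integer(peak$start) - flank || w1 < as.integer(peak$end) + flank)
    warning("search window clipped to contig bounds", call. = FALSE)
  win <- substr(genome[[ctg]], w0 + 1L, w1)
  if (is.null(apex)) apex <- (as.integer(peak$start) + as.integer(peak$end)) / 2
  hits <- rbind(scan_strand(win, sgrna, w0, w1, "+"),
                scan_strand(revcomp(win), sgrna, w0, w1, "-"))
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  hits$apex_dist <- abs(hits$cut_inferred - apex)
  hits <- hits[order(hits$mismatches, hits$apex_dist, hits$cut_inferred,
                     hits$match_strand), , drop = FALSE]
  out <- hits[1L, c("matched_protospacer", "match_strand", "mismatches",
                    "pam_observed", "cut_inferred"), drop = FALSE]
  rownames(out) <- NULL
  out
}

# Scan one strand of a window for PAM-adjacent 20-mers. `win` is given in
# scan orientation (reverse complement for "-"); coordinates are mapped back
# to forward-genome inter-base positions.
scan_strand <- function(win, sgrna, w0, w1, strand) {
  sl <- nchar(sgrna$spacer)
  pl <- nchar(sgrna$pam)
  n <- nchar(win)
  if (n < sl + pl) return(NULL)
  starts <- seq_len(n - sl - pl + 1L)          # 1-based in scan orientation
  pams <- substring(win, starts + sl, starts + sl + pl - 1L)
  ok <- vapply(pams, iupac_match, logical(1), pattern = sgrna$pam,
               USE.NAMES = FALSE)
  if (!any(ok)) return(NULL)
  starts <- starts[ok]
  prot <- substring(win, starts, starts + sl - 1L)
  mm <- hamming(sgrna$spacer, prot)
  cut_scan <- (starts - 1L) + sl - sgrna$cut_offset  # inter-base, scan coords
  cut_gen <- if (strand == "+") w0 + cut_scan else w1 - cut_scan
  data.frame(matched_protospacer = prot, match_strand = strand,
             mismatches = as.integer(mm), pam_observed = pams[ok],
             cut_inferred = as.integer(cut_gen), stringsAsFactors = FALSE)
}

#' Annotate ranked peaks with protospacer matches
#'
#' Applies [find_protospacer()] to every peak of a ranked table, using the
#' coverage track (when given) to locate each peak's apex.
#'
#' @param ranked Output of [rank_sites()].
#' @param genome A `ref_genome`.
#' @param sgrna An [sgrna_spec()].
#' @param flank Search window extension in bp.
#' @param track Optional `coverage_track` for apex localisation.
#' @return `ranked` with added columns `matched_protospacer`, `match_strand`,
#'   `mismatches`, `pam_observed`, `cut_inferred` (`NA` for no-hit peaks).
#'   Peak intervals and heights are never altered.
#' @export
annotate_peaks <- function(ranked, genome, sgrna, flank = 25L, track = NULL) {
  n <- nrow(ranked)
  ann <- data.frame(matched_protospacer = rep(NA_character_, n),
                    match_strand = rep(NA_character_, n),
                    mismatches = rep(NA_integer_, n),
                    pam_observed = rep(NA_character_, n),
                    cut_inferred = rep(NA_integer_, n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ranked))) {
    apex <- NULL
    if (!is.null(track)) apex <- peak_apex(track, ranked[i, ])
    hit <- find_protospacer(genome, ranked[i, ], sgrna, flank = flank,
                            apex = apex)
    if (!is.null(hit)) ann[i, ] <- hit
  }
  cbind(ranked, ann)
}

# 0-based position of the first depth-maximal base inside a peak.
peak_apex <- function(track, peak) {
  sel <- track$contig == peak$contig & track$end > peak$start &
    track$start < peak$end
  if (!any(sel)) return(NULL)
  tr <- track[sel, , drop = FALSE]
  top <- tr[which.max(tr$depth), , drop = FALSE]
  max(top$start, peak$start)
}

#' Label candidate sites as on-target
#'
#' A site is on-target iff its inferred cut position lies within
#' `tolerance` bp (inclusive) of the known on-target cut coordinate.
#'
#' @param sites Annotated table from [annotate_peaks()].
#' @param truth_contig,truth_cut_pos On-target contig and 0-based inter-base
#'   cut coordinate (from the truth BED or run configuration).
#' @param tolerance Inclusive distance tolerance in bp (default 5).
#' @return `sites` with a logical `is_on_target` column.
#' @export
label_on_target <- function(sites, truth_contig, truth_cut_pos,
                            tolerance = 5L) {
  sites$is_on_target <- !is.na(sites$cut_inferred) &
    sites$contig == truth_contig &
    abs(sites$cut_inferred - truth_cut_pos) <= tolerance
  sites
}
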