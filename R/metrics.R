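#' Exon-skipping efficiency
#'
#' Percentage of skipped product:
#' `100 * skipped / (skipped + unskipped)`. Scale-invariant, so skipped and
#' unskipped amounts may be in any shared unit (copies, molar, qPCR
#' quantity).
#'
#' @param skipped,unskipped Non-negative product amounts (vectorised).
#' @return Efficiency in percent, in `[0, 100]`.
#' @examples
#' skipping_efficiency(25, 75)
#' @export
skipping_efficiency <- function(skipped, unskipped) {
  if (any(skipped < 0) || any(unskipped < 0))
    stopf("amounts must be non-negative")
  tot <- skipped + unskipped
  if (any(tot == 0))
    stopf("undefined measurement: skipped + unskipped must be > 0")
  100 * skipped / tot
}

#' Reading-frame shift from exon removal
#'
#' Computes the reading-frame shift caused by removing a set of exons from
#' a transcript: the sum of removed exon lengths modulo 3. The frame is
#' restored iff the shift is 0 — the arithmetic behind therapeutic exon
#' skipping (e.g. removing the 176 bp dystrophin exon 45 from a transcript
#' already lacking the 148 bp exon 44 restores the frame, since
#' 148 + 176 = 324 is divisible by 3).
#'
#' @param exon_lengths Named integer vector of exon lengths in bp (names are
#'   exon labels), or unnamed (labels default to positions).
#' @param removed Character vector of exon labels to remove.
#' @return A list with `shift` (0, 1 or 2) and `frame_restored`
#'   (`shift == 0`).
#' @examples
#' frame_shift(c(ex44 = 148, ex45 = 176), c("ex44", "ex45"))
#' @export
frame_shift <- function(exon_lengths, removed = character(0)) {
  if (any(exon_lengths < 1)) stopf("exon lengths must be >= 1 bp")
  if (is.null(names(exon_lengths)))
    names(exon_lengths) <- as.character(seq_along(exon_lengths))
  if (anyDuplicated(names(exon_lengths)))
    stopf("exon labels must be unique")
  unknown <- setdiff(removed, names(exon_lengths))
  if (length(unknown))
    stopf("unknown exon label(s): %s", paste(unknown, collapse = ", "))
  shift <- sum(exon_lengths[removed]) %% 3
  list(shift = as.integer(shift), frame_restored = shift == 0)
}

#' ddPCR copy-number loss
#'
#' Percent of edited alleles at a cut site, from droplet digital PCR
#' concentrations of an amplicon spanning the target site and of an uncut
#' reference (non-target) amplicon: `100 * (1 - target / reference)`,
#' clamped to `[0, 100]` with a warning when target exceeds reference
#' (sampling noise).
#'
#' @param target_conc Target-amplicon concentration, copies/uL (>= 0).
#' @param reference_conc Reference-amplicon concentration, copies/uL (> 0).
#' @return Percent copy loss in `[0, 100]`.
#' @examples
#' ddpcr_copy_loss(50, 100)
#' @export
ddpcr_copy_loss <- function(target_conc, reference_conc) {
  if (any(reference_conc <= 0)) stopf("reference_conc must be > 0")
  if (any(target_conc < 0)) stopf("target_conc must be >= 0")
  loss <- 100 * (1 - target_conc / reference_conc)
  if (any(loss < 0)) {
    warning("target concentration exceeds reference; clamping to 0%",
            call. = FALSE)
    loss <- pmax(loss, 0)
  }
  pmin(loss, 100)
}
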