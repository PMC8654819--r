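#' Generate a random reference genome
#'
#' Builds a small synthetic reference of one or more contigs of uniform
#' i.i.d. A/C/G/T sequence. The result stands in for a real reference
#' (e.g. hg38) so that cleavage sites can be planted at known coordinates
#' and every downstream stage checked against ground truth.
#'
#' @param seed Integer seed; the same seed always yields the same genome.
#' @param n_contigs Number of contigs (>= 1).
#' @param contig_length Length of each contig in bp (>= 1000).
#' @return A named character vector of class `ref_genome`, one element per
#'   contig (`contig1`, `contig2`, ...).
#' @examples
#' g <- make_genome(1, n_contigs = 2, contig_length = 5000)
#' nchar(g)
#' @export
make_genome <- function(seed, n_contigs = 1L, contig_length = 50000L) {
  if (n_contigs < 1L) stopf("n_contigs must be >= 1, got %s", n_contigs)
  if (contig_length < 1000L)
    stopf("contig_length must be >= 1000, got %s", contig_length)
  contigs <- with_seed(seed, vapply(seq_len(n_contigs), function(i) {
    paste(sample(DNA_BASES, contig_length, replace = TRUE), collapse = "")
  }, character(1)))
  names(contigs) <- paste0("contig", seq_len(n_contigs))
  structure(contigs, class = "ref_genome")
}

contig_lengths <- function(genome) {
  stats::setNames(nchar(unclass(genome)), names(genome))
}

#' Specify an sgRNA
#'
#' @param spacer 20-nt guide sequence (A/C/G/T).
#' @param pam PAM pattern in IUPAC code; default `"NGG"` (SpCas9).
#' @param cut_offset Cut distance in bp from the PAM-proximal end of the
#'   protospacer; default 3 (blunt SpCas9 cut between positions 17 and 18).
#' @return A list of class `sgrna_spec`.
#' @examples
#' sgrna_spec("ACGTACGTACGTACGTACGT")
#' @export
sgrna_spec <- function(spacer, pam = "NGG", cut_offset = 3L) {
  spacer <- toupper(spacer)
  if (nchar(spacer) != 20L) stopf("spacer must be 20 nt, got %d", nchar(spacer))
  if (!grepl("^[ACGT]+$", spacer)) stopf("spacer must be A/C/G/T only")
  if (nchar(pam) < 2L) stopf("pam pattern must be >= 2 nt")
  if (cut_offset <= 0L || cut_offset >= 20L)
    stopf("cut_offset must be in (0, 20), got %s", cut_offset)
  structure(list(spacer = spacer, pam = toupper(pam),
                 cut_offset = as.integer(cut_offset)),
            class = "sgrna_spec")
}

# Mutate exactly k positions of a 20-mer to different random bases.
mutate_spacer <- function(spacer, k) {
  b <- strsplit(spacer, "")[[1]]
  if (k > 0L) {
    idx <- sample(length(b), k)
    for (i in idx) b[i] <- sample(setdiff(DNA_BASES, b[i]), 1L)
  }
  paste(b, collapse = "")
}

#' Plant on- and off-target sites into a genome
#'
#' Overwrites the genome at random, well-separated loci with a protospacer
#' carrying a requested number of mismatches to the spacer, followed (in
#' protospacer orientation) by a PAM matching the pattern. Sites are placed
#' on a random strand. The first entry is conventionally the on-target
#' (0 mismatches, maximal cleavage probability).
#'
#' @param genome A `ref_genome`.
#' @param sgrna An [sgrna_spec()].
#' @param mismatch_counts Integer vector, one entry per site.
#' @param cleave_probs Cleavage probabilities in `[0, 1]`, same length; if
#'   `NULL`, defaults to `max(0.05, 1 - 0.15 * mismatches)`.
#' @param seed Integer seed.
#' @param min_separation Minimum distance in bp between any two planted cut
#'   positions (default 600, i.e. twice a 300 bp mean fragment, so coverage
#'   footprints of neighbouring sites cannot overlap).
#' @return A list with `genome` (modified) and `sites`, a data.frame with
#'   columns `site_id`, `contig`, `cut_pos` (0-based inter-base), `strand`,
#'   `protospacer`, `pam`, `mismatches`, `cleave_prob`.
#' @export
plant_sites <- function(genome, sgrna, mismatch_counts, cleave_probs = NULL,
                        seed = 1L, min_separation = 600L) {
  stopifnot(inherits(genome, "ref_genome"), inherits(sgrna, "sgrna_spec"))
  n <- length(mismatch_counts)
  if (is.null(cleave_probs))
    cleave_probs <- pmax(0.05, 1 - 0.15 * mismatch_counts)
  if (length(cleave_probs) != n)
    stopf("mismatch_counts and cleave_probs must have equal length")
  if (n == 0L)
    return(list(genome = genome, sites = empty_sites()))
  if (any(cleave_probs < 0 | cleave_probs > 1))
    stopf("cleave_probs must lie in [0, 1]")

  lens <- contig_lengths(genome)
  elt <- nchar(sgrna$spacer) + nchar(sgrna$pam)   # planted element length
  seqs <- as.list(unclass(genome))

  with_seed(seed, {
    placed <- data.frame(contig = character(0), pos0 = integer(0))
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(1000L)) {
        ctg <- sample(names(lens), 1L, prob = as.numeric(lens))
        pos0 <- sample.int(lens[[ctg]] - elt - 2L * min_separation, 1L) +
          min_separation
        same <- placed$pos0[placed$contig == ctg]
        if (all(abs(same - pos0) >= min_separation + elt)) { ok <- TRUE; break }
      }
      if (!ok) stopf("could not place %d sites disjointly; genome too small", n)
      placed <- rbind(placed, data.frame(contig = ctg, pos0 = pos0))

      strand <- sample(c("+", "-"), 1L)
      proto <- mutate_spacer(sgrna$spacer, mismatch_counts[i])
      pam <- realize_iupac(sgrna$pam)
      if (strand == "+") {
        element <- paste0(proto, pam)
        cut_pos <- pos0 + nchar(sgrna$spacer) - sgrna$cut_offset
      } else {
        element <- revcomp(paste0(proto, pam))
        cut_pos <- pos0 + nchar(sgrna$pam) + sgrna$cut_offset
      }
      s <- seqs[[ctg]]
      seqs[[ctg]] <- paste0(substr(s, 1L, pos0),
                            element,
                            substr(s, pos0 + elt + 1L, nchar(s)))
      rows[[i]] <- data.frame(
        site_id = sprintf("site%02d_mm%d", i, mismatch_counts[i]),
        contig = ctg, cut_pos = as.integer(cut_pos), strand = strand,
        protospacer = proto, pam = pam,
        mismatches = as.integer(mismatch_counts[i]),
        cleave_prob = cleave_probs[i],
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
  })
  g2 <- structure(unlist(seqs), class = "ref_genome")
  names(g2) <- names(genome)
  list(genome = g2, sites = out)
}

empty_sites <- function() {
  data.frame(site_id = character(0), contig = character(0),
             cut_pos = integer(0), strand = character(0),
             protospacer = character(0), pam = character(0),
             mismatches = integer(0), cleave_prob = numeric(0),
             stringsAsFactors = FALSE)
}

#' Write a genome to FASTA
#'
#' 60-column wrapped FASTA via Biostrings.
#' @param genome A `ref_genome`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  dss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(dss, path, width = 60L)
  invisible(path)
}

#' Read a genome from FASTA
#' @param path FASTA file.
#' @return A `ref_genome`.
#' @export
read_genome_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  g <- as.character(dss)
  names(g) <- sub("\\s.*$", "", names(dss))
  structure(g, class = "ref_genome")
}

#' Write planted truth sites as BED6
#'
#' One record per site: the base immediately 3' of the cut (0-based
#' half-open), name = site id, score = `round(1000 * cleave_prob)`.
#' @param sites Truth site table from [plant_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(sites, path) {
  df <- data.frame(sites$contig, sites$cut_pos, sites$cut_pos + 1L,
                   sites$site_id, as.integer(round(1000 * sites$cleave_prob)),
                   sites$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
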