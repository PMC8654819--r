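#' @importFrom stats rbinom rnorm runif
#' @importFrom utils write.table read.delim
NULL

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC nucleotide codes used for PAM pattern matching ("N" matches anything).
IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All randomness in the package flows through this helper so
# that identical (seed, params) give byte-identical outputs.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distance between equal-length nucleotide strings (vectorised over b).
hamming <- function(a, b) {
  ai <- utf8ToInt(a)
  vapply(b, function(s) sum(utf8ToInt(s) != ai), integer(1), USE.NAMES = FALSE)
}

# Does `seq` match the IUPAC `pattern` position by position?
iupac_match <- function(seq, pattern) {
  if (nchar(seq) != nchar(pattern)) return(FALSE)
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  all(mapply(function(b, code) b %in% IUPAC[[code]], s, p))
}

# One concrete realisation of an IUPAC pattern (ambiguous codes sampled).
realize_iupac <- function(pattern) {
  p <- strsplit(pattern, "")[[1]]
  paste(vapply(p, function(code) {
    opts <- IUPAC[[code]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
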