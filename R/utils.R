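# Internal helpers shared across modules.
#
# Coordinate convention: all genomic intervals in this package are 0-based,
# half-open (BED style). R string functions are 1-based; conversions happen at
# the call site and nowhere else.

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream. All user-facing generators funnel their `seed` through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

DNA_BASES <- c("A", "C", "G", "T")

# transitions: A<->G, C<->T
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))

is_purine <- function(x) x == "A" | x == "G"

# character string -> single upper-case DNA string, validated lazily
as_dna_string <- function(x) {
  if (methods::is(x, "DNAString") || methods::is(x, "DNAStringSet")) {
    return(as.character(x))
  }
  toupper(as.character(x))
}

stopifnot_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
}

# half-open interval [a, b) utilities on 0-based coordinates
interval_ok <- function(iv) {
  is.numeric(iv) && length(iv) == 2L && !anyNA(iv) && iv[1] <= iv[2]
}

intervals_disjoint <- function(a, b) a[2] <= b[1] || b[2] <= a[1]

point_in_interval <- function(p, iv) p >= iv[1] & p < iv[2]

#' Write sequences to FASTA
#'
#' Thin wrapper around [Biostrings::writeXStringSet()] accepting a named
#' character vector.
#'
#' @param sequences named character vector (or `DNAStringSet`) of sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  x <- if (methods::is(sequences, "DNAStringSet")) sequences else
    Biostrings::DNAStringSet(unlist(sequences))
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write reads with qualities to FASTQ (Phred+33)
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  Biostrings::writeXStringSet(methods::as(reads, "DNAStringSet"),
                              filepath = path, format = "fastq",
                              qualities = Biostrings::quality(reads))
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ file path.
#' @return a [Biostrings::QualityScaledDNAStringSet].
#' @export
read_fastq <- function(path) {
  # the reader keeps qualities in mcols and warns when it moves them; the
  # quality-scaled container is what the QC and mapping stages expect
  suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
}
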