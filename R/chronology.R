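# TE activity dating: Kimura two-parameter divergence to the family
# consensus, CpG correction D_CpG = D / (1 + 9 * F_CpG), conversion to years
# through a per-generation substitution rate, and 0.01-bin divergence
# landscapes.

#' Kimura two-parameter distance between two aligned sequences
#'
#' `P` and `Q` are the transition (A<->G, C<->T) and transversion proportions
#' over comparable columns (both bases in ACGT; gaps and ambiguity codes are
#' excluded from the denominator), and
#' `D = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`.
#'
#' @param seq1,seq2 aligned sequences of equal length (may contain `-`/`N`).
#' @param exclude_sites optional 1-based column indices to drop (e.g. CpG
#'   columns of the consensus).
#' @return list with `P`, `Q`, `D` and `n_sites` (comparable columns).
#' @export
#' @examples
#' # 100 columns, 10 transitions: D = -log(0.8)/2
#' a <- strrep("A", 100)
#' b <- paste0(strrep("G", 10), strrep("A", 90))
#' kimura2p(a, b)$D
kimura2p <- function(seq1, seq2, exclude_sites = NULL) {
  s1 <- strsplit(as_dna_string(seq1), "")[[1]]
  s2 <- strsplit(as_dna_string(seq2), "")[[1]]
  if (length(s1) != length(s2)) {
    stop("sequences must be aligned to equal length", call. = FALSE)
  }
  use <- s1 %in% DNA_BASES & s2 %in% DNA_BASES
  if (!is.null(exclude_sites)) use[exclude_sites] <- FALSE
  n <- sum(use)
  if (n == 0L) stop("no comparable columns", call. = FALSE)
  a <- s1[use]; b <- s2[use]
  diff <- a != b
  ts <- diff & (is_purine(a) == is_purine(b))
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    stop("saturation: Kimura two-parameter distance undefined (1-2P-Q = ",
         signif(w1, 3), ", 1-2Q = ", signif(w2, 3), ")", call. = FALSE)
  }
  list(P = P, Q = Q, D = -0.5 * log(w1 * sqrt(w2)), n_sites = n)
}

#' CpG-site fraction of a consensus
#'
#' `F_CpG = 2 * (number of CG dinucleotides) / length`: both positions of
#' every CG count, once each.
#'
#' @param consensus consensus sequence.
#' @return fraction in `[0, 1]`.
#' @export
#' @examples
#' compute_fcpg("ACGT")  # 0.5
compute_fcpg <- function(consensus) {
  s <- as_dna_string(consensus)
  if (!nchar(s)) stop("empty consensus", call. = FALSE)
  cg <- gregexpr("CG", s, fixed = TRUE)[[1]]
  n_cg <- if (cg[1] == -1) 0L else length(cg)
  2 * n_cg / nchar(s)
}

#' CpG-corrected divergence
#'
#' `D_CpG = D / (1 + 9 * F_CpG)`: hypermutable CpG sites inflate raw
#' divergence roughly tenfold, so the correction divides out their excess
#' contribution in proportion to the consensus CpG content.
#'
#' @param D raw divergence (substitutions/site, >= 0).
#' @param F_CpG CpG-site fraction in `[0, 1]`.
#' @return corrected divergence.
#' @export
cpg_correct <- function(D, F_CpG) {
  if (any(D < 0)) stop("D must be >= 0", call. = FALSE)
  if (any(F_CpG < 0 | F_CpG > 1)) stop("F_CpG must be in [0, 1]",
                                       call. = FALSE)
  D / (1 + 9 * F_CpG)
}

#' Substitution-rate parameters
#'
#' @param r substitutions per site per generation (default 2.5e-8).
#' @param g generation time in years (default 5).
#' @return a `rate_params` list.
#' @export
rate_params <- function(r = 2.5e-8, g = 5) {
  if (r <= 0 || g <= 0) stop("r and g must be > 0", call. = FALSE)
  structure(list(r = r, g = g), class = "rate_params")
}

#' Convert divergence to an age in years
#'
#' `age = (D / r) * g`.
#'
#' @param D divergence in substitutions/site (>= 0).
#' @param params a [rate_params()].
#' @return age in years.
#' @export
#' @examples
#' divergence_to_age(0.025)  # 5e6 years
divergence_to_age <- function(D, params = rate_params()) {
  if (any(D < 0)) stop("D must be >= 0", call. = FALSE)
  D / params$r * params$g
}

#' Divergence landscape
#'
#' Histogram counts of divergence values in half-open bins
#' `[k * w, (k + 1) * w)`.
#'
#' @param d numeric vector of divergences (e.g. `D_CpG` per copy).
#' @param bin_width bin size (default 0.01).
#' @return data.frame with `bin_start` and `count`; counts sum to
#'   `length(d)`.
#' @export
divergence_landscape <- function(d, bin_width = 0.01) {
  if (!length(d)) stop("no records", call. = FALSE)
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  k <- floor(d / bin_width)
  tb <- table(factor(k, levels = seq(min(k), max(k))))
  data.frame(bin_start = as.numeric(names(tb)) * bin_width,
             count = as.integer(tb))
}

#' Date a set of TE copies against their consensus
#'
#' Per copy: Kimura two-parameter distance to the consensus, CpG correction
#' using the consensus CpG fraction, and conversion to years. Copies must be
#' aligned to the consensus (equal length).
#'
#' @param copies character vector of aligned copies.
#' @param consensus the family consensus.
#' @param params a [rate_params()].
#' @return data.frame with `copy_id`, `P`, `Q`, `D`, `F_CpG`, `D_CpG`,
#'   `age_years`.
#' @export
te_chronology <- function(copies, consensus, params = rate_params()) {
  if (is.null(names(copies))) {
    names(copies) <- sprintf("copy%04d", seq_along(copies))
  }
  fcpg <- compute_fcpg(consensus)
  rows <- lapply(names(copies), function(id) {
    k <- kimura2p(copies[[id]], consensus)
    dc <- cpg_correct(k$D, fcpg)
    data.frame(copy_id = id, P = k$P, Q = k$Q, D = k$D, F_CpG = fcpg,
               D_CpG = dc, age_years = divergence_to_age(dc, params))
  })
  do.call(rbind, rows)
}
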