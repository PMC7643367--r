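# Read-backed presence/absence genotyping: read QC, +/-200 bp local
# references with the R1..R5 region layout, an ungapped internal mapper, the
# four coverage criteria, and per-pattern concordance against pattern
# expectations.
#
# The decision rule consumes only per-base coverage of the local reference,
# which is why a simple exact/near-exact ungapped mapper suffices here.

#' Read QC parameters
#'
#' @param min_base_q bases with Phred quality <= this (or `N`) count as low
#'   quality (default 20).
#' @param max_lowq_frac reads whose low-quality fraction exceeds this are
#'   discarded (default 0.30).
#' @param adapters character vector of adapter sequences; reads containing
#'   one as an exact substring are removed.
#' @param trim_3prime_below trim the 3' run of bases with quality strictly
#'   below this (default 20).
#' @return a `qc_params` list.
#' @export
qc_params <- function(min_base_q = 20L, max_lowq_frac = 0.30,
                      adapters = character(0), trim_3prime_below = 20L) {
  if (max_lowq_frac < 0 || max_lowq_frac > 1) {
    stop("max_lowq_frac must be in [0, 1]", call. = FALSE)
  }
  structure(list(min_base_q = as.integer(min_base_q),
                 max_lowq_frac = max_lowq_frac,
                 adapters = toupper(adapters),
                 trim_3prime_below = as.integer(trim_3prime_below)),
            class = "qc_params")
}

#' Quality-control reads
#'
#' Applies, in order: (1) removal of reads containing an adapter as an exact
#' substring; (2) trimming of the longest 3' suffix whose bases are all below
#' `trim_3prime_below`; (3) removal of reads whose fraction of low-quality
#' bases (quality <= `min_base_q`, or `N`) exceeds `max_lowq_frac`; (4)
#' removal of reads left empty.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param params a [qc_params()].
#' @return the filtered, trimmed `QualityScaledDNAStringSet`.
#' @export
qc_reads <- function(reads, params = qc_params()) {
  if (!length(reads)) return(reads)
  seqs <- as.character(reads)
  quals <- methods::as(Biostrings::quality(reads), "IntegerList")
  if (any(lengths(quals) != nchar(seqs))) {
    stop("sequence/quality length mismatch", call. = FALSE)
  }
  keep <- rep(TRUE, length(reads))
  for (ad in params$adapters) {
    keep <- keep & !grepl(ad, seqs, fixed = TRUE)
  }
  seqs <- seqs[keep]
  qlist <- as.list(quals[keep])
  nm <- names(reads)[keep]
  # 3' trim: cut after the last base with quality >= threshold
  last_ok <- vapply(qlist, function(q) {
    ok <- which(q >= params$trim_3prime_below)
    if (length(ok)) max(ok) else 0L
  }, 0L)
  seqs <- substring(seqs, 1L, last_ok)
  qlist <- lapply(seq_along(qlist), function(i) qlist[[i]][seq_len(last_ok[i])])
  # low-quality / N fraction on the trimmed read
  n_lowq <- vapply(qlist, function(q) sum(q <= params$min_base_q), 0L)
  n_N <- as.integer(Biostrings::letterFrequency(
    Biostrings::DNAStringSet(seqs), "N"))
  # N bases already below the quality cut must not be double-counted
  dbl <- which(n_N > 0L & n_lowq > 0L)
  for (i in dbl) {
    at_N <- strsplit(seqs[i], "")[[1]] == "N"
    n_N[i] <- sum(at_N & qlist[[i]] > params$min_base_q)
  }
  lowq <- ifelse(last_ok == 0L, 1, (n_lowq + n_N) / pmax(last_ok, 1L))
  ok <- last_ok > 0L & lowq <= params$max_lowq_frac
  seqs <- seqs[ok]; qlist <- qlist[ok]; nm <- nm[ok]
  qual_strings <- vapply(qlist, function(q)
    rawToChar(as.raw(pmin(q, 93L) + 33L)), "")
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(stats::setNames(seqs, nm)),
    Biostrings::PhredQuality(qual_strings))
}

#' R1..R5 region layout of a local reference
#'
#' With the default 200 bp flank: R1 = left 195 bp, R2 = the 5 bp left of the
#' SV breakpoint, R3 = the SV span, R4 = the 5 bp right of it, R5 = the right
#' 195 bp; contiguous in that order, half-open 0-based.
#'
#' @param sv_length SV length in bp.
#' @param flank flank size in bp (breakpoint regions stay 5 bp).
#' @return a `region_set` list with intervals `r1`..`r5`, `flank` and the
#'   total local-reference `length`.
#' @export
region_set <- function(sv_length, flank = 200L) {
  if (flank <= 5L) stop("flank must exceed the 5 bp breakpoint region",
                        call. = FALSE)
  r1 <- c(0, flank - 5)
  r2 <- c(flank - 5, flank)
  r3 <- c(flank, flank + sv_length)
  r4 <- c(flank + sv_length, flank + sv_length + 5)
  r5 <- c(flank + sv_length + 5, 2 * flank + sv_length)
  structure(list(r1 = r1, r2 = r2, r3 = r3, r4 = r4, r5 = r5,
                 flank = flank, length = 2 * flank + sv_length),
            class = "region_set")
}

#' Build a local reference around an SV
#'
#' Extracts `flank` bp on both sides of the SV span `[sv_start, sv_end)` from
#' a genome that CARRIES the sequence: presence-type SVs use a carrier
#' genome, absence-type SVs the genome that still holds the segment (the
#' reference, for deletions called against it).
#'
#' @param carrier_genome genome sequence holding the SV sequence.
#' @param sv_start,sv_end 0-based half-open SV span on that genome.
#' @param flank flank size in bp; must fit inside the genome.
#' @return a `local_reference` list with `sequence` and `regions`.
#' @export
build_local_reference <- function(carrier_genome, sv_start, sv_end,
                                  flank = 200L) {
  carrier_genome <- as_dna_string(carrier_genome)
  L <- nchar(carrier_genome)
  if (sv_start < flank || sv_end + flank > L) {
    stop("flank does not fit inside the genome at this SV", call. = FALSE)
  }
  if (sv_end <= sv_start) stop("empty SV span", call. = FALSE)
  seq <- substring(carrier_genome, sv_start - flank + 1L, sv_end + flank)
  structure(list(sequence = seq,
                 regions = region_set(sv_end - sv_start, flank)),
            class = "local_reference")
}

#' Local reference straight from a catalog record
#'
#' For a deletion the segment lives on the reference and the local reference
#' is `ref[start - flank, end + flank)`. For an insertion the carried
#' sequence is `alt_seq`, and under intact flanks the carrier genome's local
#' context equals `ref-left-flank + alt_seq + ref-right-flank`, which is
#' assembled directly.
#'
#' @param reference the reference genome sequence.
#' @param record one SV record row (`ref_start`, `ref_end`, `type`,
#'   `alt_seq`).
#' @param flank flank size in bp.
#' @return a `local_reference`.
#' @export
local_reference_from_record <- function(reference, record, flank = 200L) {
  if (record$type == "deletion") {
    return(build_local_reference(reference, record$ref_start, record$ref_end,
                                 flank))
  }
  if (record$type != "insertion") {
    stop("local references are built for insertion/deletion records",
         call. = FALSE)
  }
  reference <- as_dna_string(reference)
  p <- record$ref_start
  if (p < flank || p + flank > nchar(reference)) {
    stop("flank does not fit inside the genome at this SV", call. = FALSE)
  }
  seq <- paste0(substring(reference, p - flank + 1L, p),
                record$alt_seq,
                substring(reference, p + 1L, p + flank))
  structure(list(sequence = seq,
                 regions = region_set(nchar(record$alt_seq), flank)),
            class = "local_reference")
}

#' Map reads to a local reference (ungapped, all placements)
#'
#' Reports every end-to-end ungapped placement of each read on the local
#' reference with at most `max_mismatches` mismatches. Candidate placements
#' are pre-screened with a pigeonhole k-mer filter (a read with <=
#' `max_mismatches` mismatches must share one of `max_mismatches + 1`
#' disjoint blocks exactly), then verified exhaustively. Reads longer than
#' the local reference are skipped. Deterministic output order: placement
#' start, then read name.
#'
#' @param reads a `QualityScaledDNAStringSet`, `DNAStringSet` or named
#'   character vector (QC'd).
#' @param local_ref a `local_reference` or plain sequence string.
#' @param max_mismatches maximum Hamming mismatches (default 2).
#' @return data.frame with `read`, `start` (0-based), `end` (half-open),
#'   `mismatches`.
#' @export
map_reads <- function(reads, local_ref, max_mismatches = 2L) {
  ref <- if (methods::is(local_ref, "local_reference")) local_ref$sequence
         else as_dna_string(local_ref)
  seqs <- if (is.character(reads)) reads else as.character(reads)
  if (is.null(names(seqs))) names(seqs) <- sprintf("read%06d", seq_along(seqs))
  Lr <- nchar(ref)
  w <- nchar(seqs)
  skip <- w > Lr
  seqs <- seqs[!skip]; w <- w[!skip]
  empty <- data.frame(read = character(0), start = integer(0),
                      end = integer(0), mismatches = integer(0))
  if (!length(seqs)) return(empty)
  # propose placements by pigeonhole: a placement with <= max_mismatches
  # mismatches leaves at least one of the max_mismatches + 1 disjoint read
  # blocks intact, so indexing the reference at every block length and
  # looking up each block proposes every valid placement
  nblk <- max_mismatches + 1L
  blk <- pmax(1L, w %/% nblk)
  rr <- charToRaw(ref)
  proposals <- vector("list", length(seqs))
  for (b in unique(blk)) {
    if (Lr < b) next
    starts <- 1:(Lr - b + 1L)
    refk <- substring(ref, starts, starts + b - 1L)
    tab <- split(starts, refk)
    sel <- which(blk == b)
    for (k in seq_len(nblk)) {
      off <- (k - 1L) * b
      seeds <- substring(seqs[sel], off + 1L, off + b)
      idx <- match(seeds, names(tab))
      for (j in which(!is.na(idx))) {
        i <- sel[j]
        proposals[[i]] <- c(proposals[[i]], tab[[idx[j]]] - off)
      }
    }
  }
  h_read <- character(0); h_start <- integer(0)
  h_end <- integer(0); h_mm <- integer(0)
  for (i in which(lengths(proposals) > 0L)) {
    pr <- unique(proposals[[i]])
    pr <- pr[pr >= 1L & pr + w[i] - 1L <= Lr]
    if (!length(pr)) next
    read_raw <- charToRaw(seqs[[i]])
    for (p in sort(pr)) {
      mm <- sum(rr[p:(p + w[i] - 1L)] != read_raw)
      if (mm <= max_mismatches) {
        h_read <- c(h_read, names(seqs)[i])
        h_start <- c(h_start, p - 1L)
        h_end <- c(h_end, p - 1L + w[i])
        h_mm <- c(h_mm, mm)
      }
    }
  }
  if (!length(h_read)) return(empty)
  out <- data.frame(read = h_read, start = h_start, end = h_end,
                    mismatches = h_mm)
  out[order(out$start, out$read), , drop = FALSE]
}

#' Genotype one SV from read placements
#'
#' Computes the per-base coverage union of the placements and applies the
#' four coverage criteria (all inclusive): R3 covered >= 60%, R2 and R4
#' covered completely, R1 and R5 covered >= 50%. The call is `present` iff
#' all four hold, else `absent`; there is no no-call state. A low-coverage
#' warning flag (not part of the decision) is attached when fewer than
#' `warn_below` placements support the locus.
#'
#' @param placements data.frame from [map_reads()].
#' @param regions a `region_set` (or a `local_reference`).
#' @param r3_min,r15_min fractional thresholds for R3 and R1/R5.
#' @param warn_below placement count below which `low_coverage` is flagged.
#' @return a `genotype_call` list: `call`, `fractions` (named r1..r5),
#'   `n_placements`, `low_coverage`.
#' @export
genotype <- function(placements, regions, r3_min = 0.60, r15_min = 0.50,
                     warn_below = 5L) {
  if (methods::is(regions, "local_reference")) regions <- regions$regions
  L <- regions$length
  cov <- integer(L + 1L)
  if (nrow(placements)) {
    s <- pmax(placements$start, 0L)
    e <- pmin(placements$end, L)
    d <- integer(L + 1L)
    for (i in seq_along(s)) {
      d[s[i] + 1L] <- d[s[i] + 1L] + 1L
      d[e[i] + 1L] <- d[e[i] + 1L] - 1L
    }
    cov <- cumsum(d)
  }
  covered <- cov[seq_len(L)] > 0
  frac <- vapply(c("r1", "r2", "r3", "r4", "r5"), function(r) {
    iv <- regions[[r]]
    if (iv[2] <= iv[1]) return(1)
    mean(covered[(iv[1] + 1L):iv[2]])
  }, 0)
  call <- if (frac["r3"] >= r3_min && frac["r2"] == 1 && frac["r4"] == 1 &&
              frac["r1"] >= r15_min && frac["r5"] >= r15_min) "present"
          else "absent"
  structure(list(call = call, fractions = frac,
                 n_placements = nrow(placements),
                 low_coverage = nrow(placements) < warn_below),
            class = "genotype_call")
}

#' Genotype a cohort over a panel of local references
#'
#' Maps each individual's (QC'd) reads to every SV's local reference
#' independently and applies [genotype()].
#'
#' @param reads_by_individual named list of read sets.
#' @param local_refs named list of `local_reference` objects (one per SV).
#' @param max_mismatches passed to [map_reads()].
#' @return 0/1 integer matrix, individuals x SVs (1 = present).
#' @export
genotype_cohort <- function(reads_by_individual, local_refs,
                            max_mismatches = 2L) {
  inds <- names(reads_by_individual)
  svs <- names(local_refs)
  calls <- matrix(0L, nrow = length(inds), ncol = length(svs),
                  dimnames = list(inds, svs))
  for (ind in inds) {
    rd <- reads_by_individual[[ind]]
    if (!is.character(rd)) rd <- as.character(rd)
    for (sv in svs) {
      pl <- map_reads(rd, local_refs[[sv]], max_mismatches)
      g <- genotype(pl, local_refs[[sv]])
      calls[ind, sv] <- as.integer(g$call == "present")
    }
  }
  calls
}

#' Expected presence of an SV's sequence for a population group
#'
#' Derived from the pattern definitions: e.g. an `A-p` local reference (the
#' Asian-presence sequence) is expected covered in Asian individuals and not
#' in European ones. `NA` for groups the pattern says nothing about
#' (outgroups).
#'
#' @param pattern one of `"A-a"`, `"A-p"`, `"SA-a"`, `"SA-p"`.
#' @param group one of `EUR`, `ASIA_N`, `ASIA_S`, `TIBET`, `CROSS`,
#'   `OUTGROUP`.
#' @param cross_with_south,cross_as_asian see [group_assignment()].
#' @return logical (`TRUE` = expected present) or `NA`.
#' @export
expected_presence <- function(pattern, group, cross_with_south = TRUE,
                              cross_as_asian = TRUE) {
  if (group == "OUTGROUP") return(NA)
  asian <- group %in% c("ASIA_N", "ASIA_S", "TIBET") ||
    (group == "CROSS" && cross_as_asian)
  south <- group == "ASIA_S" || (group == "CROSS" && cross_with_south)
  switch(pattern,
         "A-a" = !asian,
         "A-p" = asian,
         "SA-a" = !south,
         "SA-p" = south,
         NA)
}

#' Concordance of genotype calls with pattern expectations
#'
#' Compares each call to the presence the SV's pattern predicts for the
#' individual's population group and reports matching rates overall, per
#' pattern, and per group. Pairs with no expectation (outgroups, `none`
#' patterns) are excluded.
#'
#' @param calls 0/1 matrix (individuals x SVs) from [genotype_cohort()].
#' @param sv_patterns named character vector: SV id -> pattern.
#' @param individual_groups named character vector: individual -> group.
#' @return list with `overall`, `per_pattern`, `per_group` and `n_pairs`.
#' @export
concordance <- function(calls, sv_patterns, individual_groups) {
  if (!length(calls)) stop("empty call matrix", call. = FALSE)
  missing <- setdiff(rownames(calls), names(individual_groups))
  if (length(missing)) {
    stop("individuals without a group: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  inds <- rownames(calls); svs <- colnames(calls)
  exp_mat <- matrix(NA, nrow = length(inds), ncol = length(svs),
                    dimnames = dimnames(calls))
  for (i in inds) {
    for (s in svs) {
      pat <- sv_patterns[[s]]
      if (is.null(pat) || is.na(pat)) next
      exp_mat[i, s] <- expected_presence(pat, individual_groups[[i]])
    }
  }
  ok <- !is.na(exp_mat)
  if (!any(ok)) stop("no call has a pattern expectation", call. = FALSE)
  match_mat <- (calls == 1) == exp_mat
  per_pattern <- vapply(split(seq_along(svs),
                              unlist(sv_patterns[svs])), function(j) {
    m <- match_mat[, j, drop = FALSE]; o <- ok[, j, drop = FALSE]
    if (!any(o)) NA_real_ else mean(m[o])
  }, 0)
  per_group <- vapply(split(seq_along(inds),
                            unlist(individual_groups[inds])), function(i) {
    m <- match_mat[i, , drop = FALSE]; o <- ok[i, , drop = FALSE]
    if (!any(o)) NA_real_ else mean(m[o])
  }, 0)
  list(overall = mean(match_mat[ok]),
       per_pattern = per_pattern,
       per_group = per_group,
       n_pairs = sum(ok))
}
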