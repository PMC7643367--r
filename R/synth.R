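# Synthetic study generator: reference and derived genomes with planted,
# population-patterned SVs, TE copies diverged under a CpG-elevated
# substitution process, and error-bearing single-end short reads.
#
# The generator is the ground-truth side of the pipeline: everything it plants
# is recorded, so downstream stages (SV discovery, pattern classification,
# genotyping, TE attribution, dating) can be scored exactly.

#' Simulation configuration
#'
#' Bundles the study-design parameters of the synthetic cohort: one reference
#' genome, several populations each contributing one or more derived genomes,
#' and two disjoint chromosomal windows in which the two population patterns
#' (south-Asia-specific "SA" and Asia/Europe "A") are planted. The window
#' layout mirrors the two adjacent low-recombination X-chromosome regions the
#' patterns occupy in real pig data, scaled down to the synthetic genome.
#'
#' @param seed integer seed controlling every random draw downstream.
#' @param genome_length reference length in bp.
#' @param gc_fraction target GC content of the reference, in `[0, 1]`.
#' @param populations data.frame with columns `name`, `group` (one of
#'   `EUR`, `ASIA_N`, `ASIA_S`, `TIBET`, `OUTGROUP`) and `n_genomes`.
#' @param pattern_window_SA,pattern_window_A half-open `[start, end)` bp
#'   intervals (0-based) on the reference; must be disjoint and within the
#'   genome. Defaults scale the relative extents of the real 44-58 Mb and
#'   58-92 Mb X windows onto the synthetic genome.
#' @param read_length,depth,error_rate single-end read simulation parameters:
#'   read length (bp), fold coverage and per-base substitution error
#'   probability.
#' @param polya_len length of the 3' poly-A tail appended to TE-derived
#'   insertion sequences.
#' @param cpg_multiplier fold elevation of the substitution rate at CpG sites
#'   when evolving TE copies (default 10).
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, genome_length = 50000)
#' cfg$populations
sim_config <- function(seed = 1L,
                       genome_length = 200000L,
                       gc_fraction = 0.42,
                       populations = default_populations(),
                       pattern_window_SA = NULL,
                       pattern_window_A = NULL,
                       read_length = 100L,
                       depth = 20,
                       error_rate = 0.001,
                       polya_len = 12L,
                       cpg_multiplier = 10) {
  if (genome_length < 0) stop("genome_length must be >= 0", call. = FALSE)
  if (gc_fraction < 0 || gc_fraction > 1) {
    stop("gc_fraction must be in [0, 1]", call. = FALSE)
  }
  if (error_rate < 0 || error_rate > 1) {
    stop("error_rate must be in [0, 1]", call. = FALSE)
  }
  stopifnot(is.data.frame(populations),
            all(c("name", "group", "n_genomes") %in% names(populations)))
  if (any(populations$n_genomes < 1)) {
    stop("each population needs n_genomes >= 1", call. = FALSE)
  }
  bad <- setdiff(populations$group,
                 c("EUR", "ASIA_N", "ASIA_S", "TIBET", "CROSS", "OUTGROUP"))
  if (length(bad)) stop("unknown population group(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  # default windows: two adjacent blocks (SA then A, as on the real X
  # chromosome), sized generously so the default panel fits with intact
  # unique flanks on a desk-scale chromosome
  if (is.null(pattern_window_SA)) {
    pattern_window_SA <- round(c(0.05, 0.35) * genome_length)
  }
  if (is.null(pattern_window_A)) {
    pattern_window_A <- round(c(0.35, 0.95) * genome_length)
  }
  for (iv in list(pattern_window_SA, pattern_window_A)) {
    if (!interval_ok(iv) || iv[1] < 0 || iv[2] > genome_length) {
      stop("pattern windows must be half-open intervals within the genome",
           call. = FALSE)
    }
  }
  if (!intervals_disjoint(pattern_window_SA, pattern_window_A)) {
    stop("pattern windows must be disjoint", call. = FALSE)
  }
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 gc_fraction = gc_fraction,
                 populations = populations,
                 pattern_window_SA = as.numeric(pattern_window_SA),
                 pattern_window_A = as.numeric(pattern_window_A),
                 read_length = as.integer(read_length),
                 depth = depth,
                 error_rate = error_rate,
                 polya_len = as.integer(polya_len),
                 cpg_multiplier = cpg_multiplier),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_populations <- function() {
  data.frame(name = c("EUR", "ASIA_N", "ASIA_S", "TIBET"),
             group = c("EUR", "ASIA_N", "ASIA_S", "TIBET"),
             n_genomes = c(3L, 3L, 2L, 2L))
}

#' Read / write a simulation configuration as YAML
#'
#' @param config a [sim_config()] object.
#' @param path YAML file path.
#' @return `read_sim_config()` returns a `sim_config`; `write_sim_config()`
#'   returns `path` invisibly.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$populations <- lapply(seq_len(nrow(config$populations)), function(i)
    as.list(config$populations[i, ]))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$populations <- do.call(rbind, lapply(x$populations, as.data.frame))
  do.call(sim_config, x)
}

#' Generate a random reference sequence
#'
#' Bases are drawn i.i.d. with `P(G) + P(C) = gc`; the draw is deterministic
#' given `seed` and does not disturb the caller's RNG state.
#'
#' @param length sequence length in bp (>= 0).
#' @param gc GC fraction in `[0, 1]`.
#' @param seed integer seed.
#' @return a single character string.
#' @export
generate_reference <- function(length, gc = 0.42, seed = 1L) {
  if (length < 0) stop("length must be >= 0", call. = FALSE)
  if (length == 0) return("")
  with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  })
}

#' Synthetic TE consensus library
#'
#' Builds a small SYNTHETIC stand-in for a pig repeat library: random consensus
#' sequences labelled with SINE/LINE family names in the field's
#' `name#class/family` header style. The PRE0-like consensus is derived from
#' the PRE1-like one at ~8% divergence so that family attribution has a
#' realistic near-miss competitor. These are random sequences, not Repbase
#' entries.
#'
#' @param seed integer seed.
#' @return data.frame with columns `name`, `te_class`, `family`, `consensus`.
#' @export
make_te_library <- function(seed = 42L) {
  with_seed(seed, {
    pre1 <- paste(sample(DNA_BASES, 290, replace = TRUE,
                         prob = c(0.28, 0.24, 0.24, 0.24)), collapse = "")
    pre0 <- evolve_te_copies(pre1, n = 1, target_divergence = 0.08,
                             cpg_multiplier = 1,
                             seed = sample.int(2^31 - 1, 1))$copies
    l1 <- paste(sample(DNA_BASES, 1200, replace = TRUE), collapse = "")
    dnax <- paste(sample(DNA_BASES, 500, replace = TRUE), collapse = "")
    data.frame(name = c("PRE1-SS", "PRE0-SS", "L1-SS", "hAT-1_SS"),
               te_class = c("SINE", "SINE", "LINE", "other"),
               family = c("PRE1", "PRE0", "L1", "hAT"),
               consensus = c(pre1, pre0, l1, dnax))
  })
}

#' Build a pattern-structured SV panel
#'
#' Draws a panel of ground-truth SVs whose carrier sets realise the four
#' population patterns: Asia-absence / Asia-presence SVs inside the A window
#' and south-Asia-absence / -presence SVs inside the SA window, plus a
#' fraction of single-population private SVs that match no pattern. SVs are
#' spaced so that every breakpoint has >= `min_gap` bp of unique flank.
#'
#' Relative to the European-breed reference, "absence" patterns are planted as
#' deletions carried by the sequence-lacking populations and "presence"
#' patterns as insertions carried by the sequence-holding populations.
#'
#' @param reference reference sequence (character).
#' @param config a [sim_config()].
#' @param n_sv total number of SVs to plant.
#' @param size_range `c(min, max)` SV length in bp (ignored for TE-derived
#'   insertions, whose length is the evolved copy plus poly-A tail).
#' @param te_library optional [make_te_library()] data.frame; when supplied,
#'   `te_fraction` of insertions are evolved TE copies with a 3' poly-A tail.
#' @param te_fraction fraction of insertions drawn from the TE library.
#' @param pattern_mix named numeric weights for
#'   `c("A-a", "A-p", "SA-a", "SA-p", "none")`.
#' @param min_gap minimum bp between consecutive SV breakpoints (flank
#'   uniqueness for discovery and genotyping).
#' @param seed integer seed; defaults to `config$seed`.
#' @return data.frame with columns `name`, `ref_position`, `type`, `length`,
#'   `sequence`, `carriers` (comma-separated population names), `te_source`,
#'   `pattern`.
#' @export
make_sv_panel <- function(reference, config, n_sv = 60,
                          size_range = c(50, 5000),
                          te_library = NULL, te_fraction = 0.5,
                          pattern_mix = c("A-a" = 0.3, "A-p" = 0.3,
                                          "SA-a" = 0.15, "SA-p" = 0.15,
                                          "none" = 0.1),
                          min_gap = 600, seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  pops <- config$populations
  asian <- pops$name[pops$group %in% c("ASIA_N", "ASIA_S", "TIBET", "CROSS")]
  south <- pops$name[pops$group %in% c("ASIA_S", "CROSS")]
  non_south <- setdiff(pops$name[pops$group != "OUTGROUP"], south)
  private_pool <- pops$name[pops$group %in% c("ASIA_N", "TIBET")]
  if (!length(asian) || !length(south) || !length(private_pool)) {
    stop("config must include EUR, ASIA_N/TIBET and ASIA_S populations",
         call. = FALSE)
  }
  with_seed(seed, {
    pattern <- sample(names(pattern_mix), n_sv, replace = TRUE,
                      prob = pattern_mix)
    # carrier sets and variant types per pattern (relative to EUR reference)
    type <- ifelse(pattern %in% c("A-p", "SA-p", "none"),
                   "insertion", "deletion")
    carriers <- lapply(seq_len(n_sv), function(i) {
      switch(pattern[i],
             "A-a" = asian, "A-p" = asian,
             "SA-a" = south, "SA-p" = south,
             "none" = sample(private_pool, 1))
    })
    len <- round(stats::runif(n_sv, size_range[1], size_range[2]))
    sequence <- character(n_sv)
    te_source <- rep(NA_character_, n_sv)
    for (i in which(type == "insertion")) {
      use_te <- !is.null(te_library) && stats::runif(1) < te_fraction
      if (use_te) {
        ent <- te_library[sample.int(nrow(te_library), 1), ]
        ev <- evolve_te_copies(ent$consensus, n = 1,
                               target_divergence = stats::runif(1, 0.01, 0.08),
                               cpg_multiplier = config$cpg_multiplier,
                               seed = sample.int(2^31 - 1, 1))
        sequence[i] <- paste0(ev$copies, strrep("A", config$polya_len))
        te_source[i] <- ent$name
        len[i] <- nchar(sequence[i])
      } else {
        sequence[i] <- paste(sample(DNA_BASES, len[i], replace = TRUE),
                             collapse = "")
      }
    }
    # place SVs: pattern SVs in their window, private SVs outside both;
    # patterns sharing a window are laid out jointly so they cannot collide
    lo <- min(config$pattern_window_SA[1], config$pattern_window_A[1])
    hi <- max(config$pattern_window_SA[2], config$pattern_window_A[2])
    outside <- if (lo > min_gap * 2) c(0, lo) else c(hi, config$genome_length)
    win_of <- c("A-a" = "A", "A-p" = "A", "SA-a" = "SA", "SA-p" = "SA",
                "none" = "none")
    position <- numeric(n_sv)
    for (w in c("A", "SA", "none")) {
      idx <- which(win_of[pattern] == w)
      if (!length(idx)) next
      iv <- switch(w, A = config$pattern_window_A,
                   SA = config$pattern_window_SA, none = outside)
      idx <- idx[sample.int(length(idx))]  # interleave patterns in the window
      span <- ifelse(type[idx] == "deletion", len[idx], 0)
      need <- sum(span) + (length(idx) + 1) * min_gap
      if (need > iv[2] - iv[1]) {
        stop("window too small for requested SVs (", w, ")", call. = FALSE)
      }
      slack <- (iv[2] - iv[1]) - sum(span) - length(idx) * min_gap
      gaps <- min_gap + diff(c(0, sort(stats::runif(length(idx), 0, slack))))
      position[idx] <- iv[1] + cumsum(gaps) + cumsum(c(0, span[-length(span)]))
    }
    ord <- order(position)
    panel <- data.frame(name = sprintf("sv%03d", seq_len(n_sv)),
                        ref_position = round(position[ord]),
                        type = type[ord],
                        length = len[ord],
                        sequence = sequence[ord],
                        carriers = vapply(carriers[ord], paste, "",
                                          collapse = ","),
                        te_source = te_source[ord],
                        pattern = pattern[ord])
    # deletions take their sequence from the reference
    del <- panel$type == "deletion"
    panel$sequence[del] <- substring(reference, panel$ref_position[del] + 1,
                                     panel$ref_position[del] + panel$length[del])
    panel
  })
}

#' Plant SVs into derived genomes
#'
#' Applies each panel SV to every genome of its carrier populations,
#' left-to-right with cumulative coordinate offsets: carriers of an insertion
#' gain the inserted sequence at `ref_position`; carriers of a deletion lose
#' `[ref_position, ref_position + length)`. Non-carriers keep the reference
#' allele. Returns the derived genomes together with the full ground truth.
#'
#' @param reference reference sequence (character).
#' @param panel SV panel, as from [make_sv_panel()]: columns `name`,
#'   `ref_position` (0-based, strictly increasing), `type`, `length`,
#'   `sequence`, `carriers`.
#' @param config a [sim_config()]; supplies the population layout.
#' @return list with `genomes` (named character vector, one derived genome per
#'   population member, named `<pop>_<i>`), `truth` (logical genome x SV
#'   carrier matrix) and `panel`.
#' @export
plant_svs <- function(reference, panel, config) {
  if (nrow(panel) == 0) {
    genomes <- character(0)
  }
  pops <- config$populations
  if (nrow(panel) > 0) {
    pos <- panel$ref_position
    if (any(diff(pos) <= 0)) {
      stop("panel positions must be strictly increasing", call. = FALSE)
    }
    span_end <- pos + ifelse(panel$type == "deletion", panel$length, 0)
    if (any(pos[-1] < span_end[-length(span_end)])) {
      stop("panel entries overlap on the reference", call. = FALSE)
    }
    if (any(span_end > nchar(reference))) {
      stop("panel extends past the reference end", call. = FALSE)
    }
    if (any(panel$length != nchar(panel$sequence)) || any(panel$length < 1)) {
      stop("each SV needs length == nchar(sequence) >= 1", call. = FALSE)
    }
    carrier_sets <- strsplit(panel$carriers, ",", fixed = TRUE)
    if (any(lengths(carrier_sets) == 0)) {
      stop("every SV needs a non-empty carrier set", call. = FALSE)
    }
  } else {
    carrier_sets <- list()
  }

  genome_names <- unlist(lapply(seq_len(nrow(pops)), function(i)
    paste0(pops$name[i], "_", seq_len(pops$n_genomes[i]))))
  genome_pop <- rep(pops$name, pops$n_genomes)

  derive <- function(pop) {
    carried <- which(vapply(carrier_sets, function(s) pop %in% s, TRUE))
    if (!length(carried)) return(reference)
    parts <- character(0)
    cursor <- 0  # 0-based ref position consumed so far
    for (i in carried) {
      p <- panel$ref_position[i]
      parts <- c(parts, substring(reference, cursor + 1, p))
      if (panel$type[i] == "insertion") {
        parts <- c(parts, panel$sequence[i])
        cursor <- p
      } else {
        cursor <- p + panel$length[i]
      }
    }
    parts <- c(parts, substring(reference, cursor + 1, nchar(reference)))
    paste(parts, collapse = "")
  }

  per_pop <- stats::setNames(lapply(pops$name, derive), pops$name)
  genomes <- stats::setNames(unlist(per_pop[genome_pop], use.names = FALSE),
                             genome_names)
  truth <- matrix(FALSE, nrow = length(genome_names), ncol = nrow(panel),
                  dimnames = list(genome_names, panel$name))
  for (j in seq_len(nrow(panel))) {
    truth[, j] <- genome_pop %in% carrier_sets[[j]]
  }
  list(genomes = genomes, truth = truth, panel = panel)
}

#' Evolve diverged TE copies from a consensus
#'
#' Simulates `n` copies of `consensus` under a Kimura-style two-parameter
#' substitution process: each site accrues a Poisson(`target_divergence`)
#' number of substitution events (so multiple hits and back mutations occur,
#' and the Kimura two-parameter estimator is consistent for the planted
#' value); each event is a transition with probability 2/3, otherwise a random
#' transversion (transition:transversion 2:1). Sites inside CpG dinucleotides
#' of the consensus mutate at `cpg_multiplier` times the base rate.
#'
#' @param consensus consensus sequence (character).
#' @param n number of copies.
#' @param target_divergence expected substitutions per site, in `[0, 0.75)`.
#' @param cpg_multiplier CpG rate elevation (>= 1).
#' @param seed integer seed.
#' @return list with `copies` (character vector), `true_divergence`
#'   (substitution events per site actually applied, per copy) and
#'   `cpg_sites` (0-based consensus positions inside CpG dinucleotides).
#' @export
evolve_te_copies <- function(consensus, n, target_divergence,
                             cpg_multiplier = 1, seed = 1L) {
  if (target_divergence < 0 || target_divergence >= 0.75) {
    stop("target_divergence must be in [0, 0.75)", call. = FALSE)
  }
  if (cpg_multiplier < 1) stop("cpg_multiplier must be >= 1", call. = FALSE)
  consensus <- as_dna_string(consensus)
  L <- nchar(consensus)
  cons <- strsplit(consensus, "")[[1]]
  cg <- gregexpr("CG", consensus, fixed = TRUE)[[1]]
  cpg_sites <- if (cg[1] == -1) integer(0) else sort(unique(c(cg, cg + 1)))
  rate <- rep(target_divergence, L)
  rate[cpg_sites] <- rate[cpg_sites] * cpg_multiplier
  with_seed(seed, {
    copies <- character(n)
    true_div <- numeric(n)
    for (i in seq_len(n)) {
      nev <- stats::rpois(L, rate)
      x <- cons
      hit <- which(nev > 0)
      for (s in hit) {
        for (k in seq_len(nev[s])) {
          b <- x[s]
          if (!b %in% DNA_BASES) break
          x[s] <- if (stats::runif(1) < 2 / 3) TRANSITION[[b]] else
            sample(TRANSVERSIONS[[b]], 1)
        }
      }
      copies[i] <- paste(x, collapse = "")
      true_div[i] <- sum(nev) / L
    }
    list(copies = copies, true_divergence = true_div, cpg_sites = cpg_sites - 1)
  })
}

#' Simulate single-end reads
#'
#' Places `round(depth * |genome| / read_length)` reads uniformly on the
#' genome and applies i.i.d. base substitution errors at `error_rate`. Base
#' qualities are constant and encode the error model
#' (`Q = round(-10 log10(error_rate))`, capped at 40; Q40 when error-free).
#' Read names carry the 0-based origin (`<prefix><i>_<pos>`) for debugging.
#'
#' @param genome genome sequence (character).
#' @param read_length read length in bp (must not exceed the genome length).
#' @param depth fold coverage (0 gives no reads).
#' @param error_rate per-base substitution probability.
#' @param seed integer seed.
#' @param prefix read-name prefix.
#' @return a [Biostrings::QualityScaledDNAStringSet].
#' @export
simulate_reads <- function(genome, read_length, depth, error_rate = 0,
                           seed = 1L, prefix = "read") {
  genome <- as_dna_string(genome)
  L <- nchar(genome)
  if (read_length > L) stop("read_length exceeds genome length", call. = FALSE)
  n <- round(depth * L / read_length)
  q <- if (error_rate <= 0) 40L else
    min(40L, as.integer(round(-10 * log10(error_rate))))
  if (n == 0) {
    return(Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(character(0)),
      Biostrings::PhredQuality(character(0))))
  }
  with_seed(seed, {
    starts <- sample.int(L - read_length + 1L, n, replace = TRUE) - 1L
    seqs <- substring(genome, starts + 1L, starts + read_length)
    if (error_rate > 0) {
      nerr <- stats::rbinom(n, read_length, error_rate)
      for (i in which(nerr > 0)) {
        pos <- sample.int(read_length, nerr[i])
        x <- strsplit(seqs[i], "")[[1]]
        for (p in pos) {
          x[p] <- sample(setdiff(DNA_BASES, x[p]), 1)
        }
        seqs[i] <- paste(x, collapse = "")
      }
    }
    names(seqs) <- sprintf("%s%06d_%d", prefix, seq_len(n), starts)
    qual <- strrep(rawToChar(as.raw(q + 33L)), read_length)
    Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(seqs),
      Biostrings::PhredQuality(rep(qual, n)))
  })
}

#' Simulate a complete synthetic study
#'
#' Orchestrates the generator end to end: reference, TE library, patterned SV
#' panel, derived genomes with ground truth, and (optionally) reads per
#' derived genome.
#'
#' @param config a [sim_config()].
#' @param n_sv,size_range,te_fraction passed to [make_sv_panel()].
#' @param te_library TE library (default [make_te_library()] seeded from the
#'   config).
#' @param reads if `TRUE`, simulate a read set per derived genome.
#' @return list with `reference`, `te_library`, `panel`, `genomes`, `truth`,
#'   `reads` (named list or `NULL`) and `config`.
#' @export
simulate_study <- function(config, n_sv = 60, size_range = c(50, 5000),
                           te_fraction = 0.5, te_library = NULL,
                           reads = FALSE) {
  if (is.null(te_library)) te_library <- make_te_library(config$seed + 1000L)
  reference <- generate_reference(config$genome_length, config$gc_fraction,
                                  seed = config$seed)
  panel <- make_sv_panel(reference, config, n_sv = n_sv,
                         size_range = size_range, te_library = te_library,
                         te_fraction = te_fraction, seed = config$seed + 1L)
  planted <- plant_svs(reference, panel, config)
  read_sets <- NULL
  if (isTRUE(reads)) {
    read_sets <- lapply(seq_along(planted$genomes), function(i)
      simulate_reads(planted$genomes[[i]], config$read_length, config$depth,
                     config$error_rate, seed = config$seed + 100L + i,
                     prefix = paste0(names(planted$genomes)[i], "_")))
    names(read_sets) <- names(planted$genomes)
  }
  list(reference = reference, te_library = te_library, panel = panel,
       genomes = planted$genomes, truth = planted$truth, reads = read_sets,
       config = config)
}

#' Write / read a ground-truth SV table as TSV
#'
#' Coordinates are 0-based half-open.
#'
#' @param panel SV panel data.frame.
#' @param path TSV path.
#' @return `read_truth_table()` returns the data.frame; the writer returns
#'   `path` invisibly.
#' @export
write_truth_table <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
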