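# Assembly-versus-assembly SV discovery: unique-k-mer anchoring, collinear
# chaining, gap-arithmetic SV calling, and the cross-genome merge into a
# nonoverlapping catalog with a genome x SV presence matrix.
#
# The anchoring stage approximates maximal-unique-match seeding: a k-mer that
# occurs exactly once in both sequences seeds a maximal exact match, found by
# comparing whole diagonals at once. Anchors are then chained by a
# longest-increasing-subsequence dynamic programme and consecutive-anchor gaps
# are turned into insertion/deletion/indel records.

#' Anchoring parameters
#'
#' `min_match_len` and `min_cluster_len` play the roles of the classical
#' whole-genome-aligner `-l` (minimum maximal-match length, default 100) and
#' `-c` (minimum cluster length, default 500) knobs.
#'
#' @param min_match_len minimum anchor length in bp.
#' @param min_cluster_len minimum total anchored length of a retained chain.
#' @param seed_k k-mer size used for unique seeding.
#' @param allow_reverse also search the reverse-complement strand of the
#'   query (off by default; the synthetic data is forward-strand).
#' @param max_anchor_overlap maximum bp by which consecutive chained anchors
#'   may overlap before trimming (maximal matches around an indel over-extend
#'   by the length of coincidental boundary agreement; trimming restores
#'   non-overlap without losing exactness). Must stay below `min_match_len`.
#' @return an `anchor_params` list.
#' @export
anchor_params <- function(min_match_len = 100L, min_cluster_len = 500L,
                          seed_k = 21L, allow_reverse = FALSE,
                          max_anchor_overlap = min_match_len - 1L) {
  if (seed_k < 11L) stop("seed_k must be >= 11", call. = FALSE)
  if (min_match_len < seed_k) {
    stop("min_match_len must be >= seed_k", call. = FALSE)
  }
  if (max_anchor_overlap >= min_match_len) {
    stop("max_anchor_overlap must be < min_match_len", call. = FALSE)
  }
  structure(list(min_match_len = as.integer(min_match_len),
                 min_cluster_len = as.integer(min_cluster_len),
                 seed_k = as.integer(seed_k),
                 allow_reverse = isTRUE(allow_reverse),
                 max_anchor_overlap = as.integer(max_anchor_overlap)),
            class = "anchor_params")
}

#' Assembly N50
#'
#' The largest length `L` such that contigs of length >= `L` jointly cover at
#' least half of the assembly.
#'
#' @param contig_lengths numeric vector of contig lengths (all > 0).
#' @return the N50 in bp.
#' @export
#' @examples
#' compute_n50(c(5, 4, 3, 2, 1))  # 4
compute_n50 <- function(contig_lengths) {
  if (length(contig_lengths) == 0) {
    stop("contig_lengths must be non-empty", call. = FALSE)
  }
  if (any(contig_lengths <= 0)) {
    stop("contig lengths must be > 0", call. = FALSE)
  }
  s <- sort(contig_lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

# positions (0-based) of k-mers occurring exactly once in seq
.unique_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(list(kmer = character(0), pos = integer(0)))
  km <- substring(seq, 1:(n - k + 1), k:n)
  dup <- duplicated(km) | duplicated(km, fromLast = TRUE)
  list(kmer = km[!dup], pos = which(!dup) - 1L)
}

#' Find maximal exact-match anchors between two sequences
#'
#' Seeds at k-mers that are unique in both `ref` and `qry`, then extends each
#' seed to the maximal exact match on its alignment diagonal. Anchors shorter
#' than `min_match_len` are dropped. Forward strand only unless
#' `params$allow_reverse` is set, in which case reverse-complement matches of
#' the query are reported with `strand == "-"` (query coordinates on the
#' reverse-complemented sequence).
#'
#' @param ref,qry sequences (character).
#' @param params an [anchor_params()].
#' @return data.frame with 0-based half-open `ref_start`, `ref_end`,
#'   `qry_start`, `qry_end`, `length`, `strand`.
#' @export
find_anchors <- function(ref, qry, params = anchor_params()) {
  ref <- as_dna_string(ref); qry <- as_dna_string(qry)
  if (nchar(ref) == 0 || nchar(qry) == 0) {
    stop("ref and qry must be non-empty", call. = FALSE)
  }
  fwd <- .find_anchors_fwd(ref, qry, params)
  fwd$strand <- rep("+", nrow(fwd))
  if (params$allow_reverse) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(qry)))
    rev <- .find_anchors_fwd(ref, rc, params)
    if (nrow(rev)) {
      rev$strand <- "-"
      fwd <- rbind(fwd, rev)
    }
  }
  fwd[order(fwd$ref_start, fwd$qry_start), , drop = FALSE]
}

.find_anchors_fwd <- function(ref, qry, params) {
  k <- params$seed_k
  ur <- .unique_kmers(ref, k)
  uq <- .unique_kmers(qry, k)
  hit <- match(ur$kmer, uq$kmer)
  keep <- !is.na(hit)
  empty <- data.frame(ref_start = integer(0), ref_end = integer(0),
                      qry_start = integer(0), qry_end = integer(0),
                      length = integer(0))
  if (!any(keep)) return(empty)
  rpos <- ur$pos[keep]
  qpos <- uq$pos[hit[keep]]
  diag <- qpos - rpos
  rr <- charToRaw(ref); qq <- charToRaw(qry)
  Lr <- length(rr); Lq <- length(qq)
  out <- vector("list", length(unique(diag)))
  oi <- 0L
  for (d in unique(diag)) {
    seeds <- sort(rpos[diag == d])
    lo <- max(0L, -d)               # smallest valid ref pos (0-based)
    hi <- min(Lr, Lq - d) - 1L      # largest valid ref pos
    eq <- rr[(lo + 1L):(hi + 1L)] == qq[(lo + d + 1L):(hi + d + 1L)]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values & r$lengths >= params$min_match_len)
    for (j in runs) {
      a <- lo + starts[j] - 1L   # 0-based ref start of run
      b <- lo + ends[j]          # 0-based half-open ref end
      if (!any(seeds >= a & seeds + k <= b)) next  # unseeded repeat region
      oi <- oi + 1L
      out[[oi]] <- c(a, b, a + d, b + d, b - a)
    }
  }
  if (oi == 0L) return(empty)
  m <- do.call(rbind, out[seq_len(oi)])
  data.frame(ref_start = m[, 1], ref_end = m[, 2], qry_start = m[, 3],
             qry_end = m[, 4], length = m[, 5])
}

#' Chain anchors into collinear clusters
#'
#' Repeatedly extracts the maximal-weight collinear chain (weight = total
#' anchor length; a longest-increasing-subsequence dynamic programme on both
#' coordinate axes) from the remaining anchors. Consecutive anchors in a
#' chain must advance on both reference and query; bounded overlap up to
#' `params$max_anchor_overlap` is tolerated and resolved later by
#' [call_svs()]. Chains whose total anchor length falls below
#' `params$min_cluster_len` are discarded.
#'
#' @param anchors anchor data.frame from [find_anchors()] (one ref/qry pair,
#'   forward strand).
#' @param params an [anchor_params()].
#' @return list of chains, each an anchor data.frame ordered by `ref_start`.
#' @export
chain_anchors <- function(anchors, params = anchor_params()) {
  if (!nrow(anchors)) return(list())
  if ("strand" %in% names(anchors) && any(anchors$strand != "+")) {
    anchors <- anchors[anchors$strand == "+", , drop = FALSE]
  }
  a <- anchors[order(anchors$ref_start, anchors$qry_start), , drop = FALSE]
  remaining <- rep(TRUE, nrow(a))
  ov <- params$max_anchor_overlap
  chains <- list()
  while (any(remaining)) {
    idx <- which(remaining)
    n <- length(idx)
    best <- a$length[idx]      # best chain weight ending at idx[i]
    prev <- rep(0L, n)
    for (i in seq_len(n)) {
      ri <- idx[i]
      for (j in seq_len(i - 1L)) {
        rj <- idx[j]
        if (a$ref_start[ri] > a$ref_start[rj] &&
            a$qry_start[ri] > a$qry_start[rj] &&
            a$ref_end[ri] > a$ref_end[rj] &&
            a$qry_end[ri] > a$qry_end[rj] &&
            a$ref_start[ri] >= a$ref_end[rj] - ov &&
            a$qry_start[ri] >= a$qry_end[rj] - ov) {
          w <- best[j] + a$length[ri]
          if (w > best[i]) {
            best[i] <- w
            prev[i] <- j
          }
        }
      }
    }
    tail_i <- which.max(best)
    members <- integer(0)
    i <- tail_i
    while (i != 0L) {
      members <- c(idx[i], members)
      i <- prev[i]
    }
    remaining[members] <- FALSE
    if (sum(a$length[members]) >= params$min_cluster_len) {
      chains[[length(chains) + 1L]] <- a[members, , drop = FALSE]
    }
  }
  chains
}

#' Call SVs from the gaps of a collinear chain
#'
#' For each pair of consecutive anchors the reference gap `g_r` and query gap
#' `g_q` are computed after trimming any bounded anchor overlap (the
#' downstream anchor is shortened equally on both coordinates, which keeps it
#' an exact match). Then: `g_r == 0, g_q > 0` is an insertion of `g_q` bp
#' (with `alt_sequence`); `g_q == 0, g_r > 0` a deletion of `g_r` bp; both
#' positive an `indel` of `|g_q - g_r|` bp (reported only when >= 1). Records
#' outside `[min_len, max_len]` bp are dropped. A chain whose anchors overlap
#' beyond repair (an anchor consumed entirely) is rejected with a warning.
#'
#' @param chain one chain from [chain_anchors()].
#' @param ref,qry the sequences the chain was built on.
#' @param source_genome genome label stored on the records.
#' @param chrom chromosome/contig name.
#' @param min_len,max_len retained SV length bounds in bp (1 and 10000).
#' @return data.frame of SV records: `chrom`, `ref_start`, `ref_end`
#'   (0-based half-open; insertions have `ref_end == ref_start`), `type`,
#'   `length`, `alt_seq`, `source_genome`.
#' @export
call_svs <- function(chain, ref, qry, source_genome = "query",
                     chrom = "chr1", min_len = 1L, max_len = 10000L) {
  empty <- data.frame(chrom = character(0), ref_start = integer(0),
                      ref_end = integer(0), type = character(0),
                      length = integer(0), alt_seq = character(0),
                      source_genome = character(0))
  n <- nrow(chain)
  if (n < 2L) return(empty)
  recs <- list()
  for (i in seq_len(n - 1L)) {
    re <- chain$ref_end[i];  qe <- chain$qry_end[i]
    rs <- chain$ref_start[i + 1L]; qs <- chain$qry_start[i + 1L]
    trim <- max(0L, re - rs, qe - qs)
    rs <- rs + trim; qs <- qs + trim
    if (rs >= chain$ref_end[i + 1L] || qs >= chain$qry_end[i + 1L]) {
      warning("chain rejected: anchors overlap beyond repair")
      return(empty)
    }
    g_r <- rs - re
    g_q <- qs - qe
    if (g_r == 0L && g_q == 0L) next
    if (g_r == 0L && g_q > 0L) {
      recs[[length(recs) + 1L]] <- data.frame(
        chrom = chrom, ref_start = re, ref_end = re, type = "insertion",
        length = g_q, alt_seq = substring(qry, qe + 1L, qs),
        source_genome = source_genome)
    } else if (g_q == 0L && g_r > 0L) {
      recs[[length(recs) + 1L]] <- data.frame(
        chrom = chrom, ref_start = re, ref_end = rs, type = "deletion",
        length = g_r, alt_seq = "", source_genome = source_genome)
    } else {
      len <- abs(g_q - g_r)
      if (len >= 1L) {
        recs[[length(recs) + 1L]] <- data.frame(
          chrom = chrom, ref_start = re, ref_end = rs, type = "indel",
          length = len, alt_seq = substring(qry, qe + 1L, qs),
          source_genome = source_genome)
      }
    }
  }
  if (!length(recs)) return(empty)
  out <- do.call(rbind, recs)
  out[out$length >= min_len & out$length <= max_len, , drop = FALSE]
}

#' Discover SVs between a reference and one query genome
#'
#' Convenience pipeline: [find_anchors()], [chain_anchors()], then
#' [call_svs()] on every retained chain.
#'
#' @inheritParams find_anchors
#' @inheritParams call_svs
#' @return combined SV record data.frame.
#' @export
discover_svs <- function(ref, qry, params = anchor_params(),
                         source_genome = "query", chrom = "chr1") {
  anchors <- find_anchors(ref, qry, params)
  chains <- chain_anchors(anchors, params)
  recs <- lapply(chains, call_svs, ref = ref, qry = qry,
                 source_genome = source_genome, chrom = chrom)
  out <- do.call(rbind, recs)
  if (is.null(out)) return(call_svs(data.frame(), ref, qry))
  out[order(out$ref_start, out$type), , drop = FALSE]
}

# union-find with path compression
.uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Merge per-genome SV calls into a nonoverlapping catalog
#'
#' Same-type records are collapsed when they satisfy the merge rule:
#' deletions and indels at reciprocal overlap >= `recip_overlap`; insertions
#' with breakpoints within `ins_bp_tol` bp and lengths within
#' `ins_len_tol` (ratio of shorter to longer >= 1 - tolerance). Merging is
#' transitive (connected components), the representative is the longest and
#' then leftmost record, and the result does not depend on the order of the
#' input genomes. The presence matrix marks which genomes contributed a
#' record to each merged SV.
#'
#' @param per_genome_svs named list of SV record data.frames (one per
#'   genome), all on the same reference.
#' @param recip_overlap minimum reciprocal overlap for deletion/indel merging.
#' @param ins_bp_tol insertion breakpoint tolerance in bp.
#' @param ins_len_tol insertion length tolerance (fraction).
#' @return an `sv_catalog`: list with `records` (data.frame with `sv_id`) and
#'   `presence` (genome x SV logical matrix).
#' @export
merge_catalog <- function(per_genome_svs, recip_overlap = 0.5,
                          ins_bp_tol = 10L, ins_len_tol = 0.2) {
  if (is.null(names(per_genome_svs)) || any(names(per_genome_svs) == "")) {
    stop("per_genome_svs must be a named list (one entry per genome)",
         call. = FALSE)
  }
  genomes <- sort(names(per_genome_svs))
  all <- do.call(rbind, lapply(genomes, function(g) {
    df <- per_genome_svs[[g]]
    if (is.null(df) || !nrow(df)) return(NULL)
    df$source_genome <- g
    df
  }))
  if (is.null(all) || !nrow(all)) {
    cat_records <- data.frame(sv_id = character(0), chrom = character(0),
                              ref_start = integer(0), ref_end = integer(0),
                              type = character(0), length = integer(0),
                              alt_seq = character(0))
    presence <- matrix(FALSE, nrow = length(genomes), ncol = 0,
                       dimnames = list(genomes, character(0)))
    return(structure(list(records = cat_records, presence = presence),
                     class = "sv_catalog"))
  }
  # deterministic canonical order regardless of input genome order
  ord <- order(all$chrom, all$type, all$ref_start, all$length,
               all$source_genome)
  all <- all[ord, , drop = FALSE]
  n <- nrow(all)
  parent <- seq_len(n)
  for (grp in split(seq_len(n), paste(all$chrom, all$type))) {
    if (length(grp) < 2L) next
    type <- all$type[grp[1]]
    for (ii in seq_along(grp)[-1]) {
      i <- grp[ii]
      for (jj in seq_len(ii - 1L)) {
        j <- grp[jj]
        if (type == "insertion") {
          hit <- abs(all$ref_start[i] - all$ref_start[j]) <= ins_bp_tol &&
            min(all$length[i], all$length[j]) /
              max(all$length[i], all$length[j]) >= 1 - ins_len_tol
        } else {
          ovl <- min(all$ref_end[i], all$ref_end[j]) -
            max(all$ref_start[i], all$ref_start[j])
          hit <- ovl > 0 &&
            ovl / (all$ref_end[i] - all$ref_start[i]) >= recip_overlap &&
            ovl / (all$ref_end[j] - all$ref_start[j]) >= recip_overlap
        }
        if (hit) {
          pi <- .uf_find(parent, i); pj <- .uf_find(parent, j)
          if (pi != pj) parent[max(pi, pj)] <- min(pi, pj)
        }
      }
    }
  }
  comp <- vapply(seq_len(n), function(i) .uf_find(parent, i), 1L)
  groups <- split(seq_len(n), comp)
  reps <- vapply(groups, function(g) {
    g[order(-all$length[g], all$ref_start[g])][1]
  }, 1L)
  o <- order(all$chrom[reps], all$ref_start[reps], all$type[reps])
  groups <- groups[o]; reps <- reps[o]
  records <- all[reps, c("chrom", "ref_start", "ref_end", "type", "length",
                         "alt_seq"), drop = FALSE]
  records$sv_id <- sprintf("%s:%d-%d:%s", records$chrom, records$ref_start,
                           records$ref_end, records$type)
  if (anyDuplicated(records$sv_id)) {
    records$sv_id <- make.unique(records$sv_id, sep = "#")
  }
  rownames(records) <- NULL
  records <- records[, c("sv_id", "chrom", "ref_start", "ref_end", "type",
                         "length", "alt_seq")]
  presence <- matrix(FALSE, nrow = length(genomes), ncol = nrow(records),
                     dimnames = list(genomes, records$sv_id))
  for (k in seq_along(groups)) {
    presence[unique(all$source_genome[groups[[k]]]), k] <- TRUE
  }
  structure(list(records = records, presence = presence),
            class = "sv_catalog")
}

#' @export
print.sv_catalog <- function(x, ...) {
  cat("sv_catalog:", nrow(x$records), "merged SVs across",
      nrow(x$presence), "genomes\n")
  if (nrow(x$records)) print(table(x$records$type))
  invisible(x)
}

#' Write / read SV tables and catalogs as TSV
#'
#' SV record tables use columns `chrom`, `ref_start`, `ref_end`, `type`,
#' `length`, `alt_seq`, `source_genome` (0-based half-open), so externally
#' produced assembly-diff calls in the same shape can be read back.
#'
#' @param svs SV record data.frame.
#' @param catalog an `sv_catalog`.
#' @param path,records_path,presence_path file paths.
#' @return readers return the object; writers return the path(s) invisibly.
#' @export
write_sv_table <- function(svs, path) {
  utils::write.table(svs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sv_table
#' @export
read_sv_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname write_sv_table
#' @export
write_catalog <- function(catalog, records_path, presence_path) {
  utils::write.table(catalog$records, records_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pm <- data.frame(genome = rownames(catalog$presence),
                   catalog$presence * 1L, check.names = FALSE)
  utils::write.table(pm, presence_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(records_path, presence_path))
}

#' @rdname write_sv_table
#' @export
read_catalog <- function(records_path, presence_path) {
  records <- utils::read.delim(records_path, stringsAsFactors = FALSE)
  pm <- utils::read.delim(presence_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  presence <- as.matrix(pm[, -1, drop = FALSE]) == 1
  rownames(presence) <- pm$genome
  structure(list(records = records, presence = presence),
            class = "sv_catalog")
}
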