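# TE attribution and subfamily structure: optimal local alignment against a
# consensus library, the complete/partial/unassigned status rule, 3' poly-A
# detection, greedy identity clustering of consensi, and recursive subfamily
# splitting on significant cosegregating mutations.

.substitution_matrix <- function(match = 1, mismatch = -1) {
  Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                           baseOnly = FALSE, type = "DNA")
}

#' Optimal local alignment of a query against a target
#'
#' Smith-Waterman alignment under the scheme match +1, mismatch -1, gap -2
#' per gapped column. Identity is matches over aligned columns (gaps
#' included); coverage is aligned query bases over query length.
#'
#' @param query,target sequences (character).
#' @param match,mismatch,gap scoring parameters.
#' @return list with `score`, `identity`, `coverage`, `query_range` and
#'   `target_range` (1-based closed ranges on the input sequences).
#' @export
local_align <- function(query, target, match = 1, mismatch = -1, gap = -2) {
  query <- as_dna_string(query); target <- as_dna_string(target)
  if (!nchar(query) || !nchar(target)) {
    stop("query and target must be non-empty", call. = FALSE)
  }
  al <- Biostrings::pairwiseAlignment(
    query, target, type = "local",
    substitutionMatrix = .substitution_matrix(match, mismatch),
    gapOpening = 0, gapExtension = abs(gap))
  ncol_al <- Biostrings::nchar(al)
  qr <- c(Biostrings::start(Biostrings::pattern(al)),
          Biostrings::end(Biostrings::pattern(al)))
  tr <- c(Biostrings::start(Biostrings::subject(al)),
          Biostrings::end(Biostrings::subject(al)))
  list(score = Biostrings::score(al),
       identity = Biostrings::nmatch(al) / ncol_al,
       coverage = (qr[2] - qr[1] + 1) / nchar(query),
       columns = ncol_al, query_range = qr, target_range = tr)
}

#' Attribute an SV sequence to a TE family
#'
#' Aligns the query locally against every library consensus and keeps the
#' best hit by score (ties broken by higher identity, then library order).
#' Status: `complete` iff identity > 0.90 and query coverage > 0.80;
#' otherwise `partial` iff identity > 0.80; otherwise `unassigned`. A
#' detected 3' poly-A tail is soft-trimmed before alignment by default (tail
#' length varies between copies and would depress coverage); coverage is
#' reported relative to the trimmed query.
#'
#' @param sv_sequence query sequence.
#' @param library TE library data.frame (`name`, `te_class`, `family`,
#'   `consensus`), e.g. [make_te_library()] or [read_te_library()].
#' @param mask_polya soft-trim a detected 3' poly-A tail before aligning.
#' @param both_strands also align the reverse complement and keep the better
#'   strand.
#' @param min_align_len minimum alignment columns for any family call; the
#'   optimal local alignment of unrelated sequences is a short near-perfect
#'   match, so identity is only meaningful over a qualified alignment length.
#' @return one-row data.frame: `family` (library entry name), `te_class`,
#'   `identity`, `coverage`, `score`, `te_status`.
#' @export
assign_family <- function(sv_sequence, library, mask_polya = TRUE,
                          both_strands = FALSE, min_align_len = 30L) {
  if (!nrow(library)) stop("library is empty", call. = FALSE)
  q <- as_dna_string(sv_sequence)
  if (mask_polya) {
    pa <- detect_polya(q)
    if (pa$has_tail && pa$tail_length < nchar(q)) {
      q <- substring(q, 1L, nchar(q) - pa$tail_length)
    }
  }
  queries <- q
  if (both_strands) {
    queries <- c(q, as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(q))))
  }
  best <- NULL
  for (qq in queries) {
    for (i in seq_len(nrow(library))) {
      h <- local_align(qq, library$consensus[i])
      if (is.null(best) || h$score > best$score ||
          (h$score == best$score && h$identity > best$identity)) {
        best <- h
        best$entry <- i
      }
    }
  }
  status <- if (best$columns < min_align_len) "unassigned"
            else if (best$identity > 0.90 && best$coverage > 0.80) "complete"
            else if (best$identity > 0.80) "partial"
            else "unassigned"
  data.frame(family = library$name[best$entry],
             te_class = library$te_class[best$entry],
             identity = best$identity, coverage = best$coverage,
             score = best$score, te_status = status)
}

#' Detect a 3' poly-A tail
#'
#' `has_tail` is `TRUE` iff the 3'-terminal `window` bases contain at least
#' `min_a` adenines (strand-specific: poly-T does not count). The tail length
#' is the longest terminal run allowing one non-A per 10 bases.
#'
#' @param sequence sequence (character).
#' @param window terminal window size.
#' @param min_a minimum adenine count within the window.
#' @return list with `has_tail` and `tail_length`.
#' @export
detect_polya <- function(sequence, window = 15L, min_a = 12L) {
  s <- as_dna_string(sequence)
  n <- nchar(s)
  if (!n) stop("empty sequence", call. = FALSE)
  x <- rev(strsplit(s, "")[[1]])   # 3' -> 5'
  w <- min(window, n)
  has_tail <- sum(x[seq_len(w)] == "A") >= min_a
  non_a <- cumsum(x != "A")
  ok <- which(non_a <= floor(seq_len(n) / 10))
  tail_length <- if (length(ok)) max(ok) else 0L
  list(has_tail = has_tail, tail_length = tail_length)
}

# global identity between two sequences (matches / alignment columns)
.global_identity <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = .substitution_matrix(),
    gapOpening = 0, gapExtension = 2)
  Biostrings::nmatch(al) / Biostrings::nchar(al)
}

#' Greedy identity clustering of consensus sequences
#'
#' CD-HIT-style greedy incremental clustering: sequences are sorted by length
#' (descending; ties by name) and each joins the first existing
#' representative with global identity >= `identity_threshold`, otherwise it
#' founds a new cluster. Deterministic and independent of input order.
#'
#' @param consensi named character vector of sequences.
#' @param identity_threshold global-identity threshold (default 0.95).
#' @return data.frame with `name`, `cluster` (integer) and `representative`.
#' @export
greedy_cluster <- function(consensi, identity_threshold = 0.95) {
  if (!length(consensi)) stop("no sequences to cluster", call. = FALSE)
  if (is.null(names(consensi))) {
    names(consensi) <- sprintf("seq%03d", seq_along(consensi))
  }
  ord <- order(-nchar(consensi), names(consensi))
  x <- consensi[ord]
  cluster <- integer(length(x))
  reps <- integer(0)   # indices into x
  for (i in seq_along(x)) {
    placed <- FALSE
    for (r in reps) {
      if (.global_identity(x[[i]], x[[r]]) >= identity_threshold) {
        cluster[i] <- cluster[r]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      cluster[i] <- length(reps)
    }
  }
  out <- data.frame(name = names(x), cluster = cluster,
                    representative = names(x)[reps[cluster]])
  out[match(names(consensi), out$name), , drop = FALSE]
}

#' Cosegregation parameters
#'
#' @param min_subfamily_size minimum copies per subfamily (default 30).
#' @param p_threshold binomial-tail significance threshold for a split
#'   (default 1e-4).
#' @param max_depth recursion limit.
#' @return a `coseg_params` list.
#' @export
coseg_params <- function(min_subfamily_size = 30L, p_threshold = 1e-4,
                         max_depth = 10L) {
  if (min_subfamily_size < 2L) {
    stop("min_subfamily_size must be >= 2", call. = FALSE)
  }
  structure(list(min_subfamily_size = as.integer(min_subfamily_size),
                 p_threshold = p_threshold,
                 max_depth = as.integer(max_depth)),
            class = "coseg_params")
}

#' Split a TE family into subfamilies by cosegregating mutations
#'
#' Recursive two-site test: over all pairs of (consensus position,
#' non-consensus state), the number of copies carrying both states is
#' compared to the binomial tail expected if the two single-site frequencies
#' were independent. If the most significant pair has p below
#' `params$p_threshold` and both the carrier group and the remainder reach
#' `params$min_subfamily_size`, the family splits on that pair, consensi are
#' recomputed, and both halves recurse. Copies must be aligned to the
#' consensus (equal length, substitution-only; columns index consensus
#' positions).
#'
#' @param copies character vector of aligned copies (equal lengths).
#' @param consensus optional consensus; the per-column majority when `NULL`.
#' @param params a [coseg_params()].
#' @return a `subfamily_partition` list: `assignment` (integer subfamily per
#'   copy), `consensi` (per-subfamily majority consensus), `splits`
#'   (data.frame with the diagnostic `pos1`, `state1`, `pos2`, `state2`
#'   (1-based consensus columns), `p`, `n_carriers`) and `n_subfamilies`.
#' @export
split_subfamilies <- function(copies, consensus = NULL,
                              params = coseg_params()) {
  n <- length(copies)
  if (!n) stop("no copies", call. = FALSE)
  L <- unique(nchar(copies))
  if (length(L) != 1L) {
    stop("copies must be aligned to equal length", call. = FALSE)
  }
  M <- do.call(rbind, strsplit(copies, ""))
  majority <- function(rows) {
    apply(M[rows, , drop = FALSE], 2, function(col) {
      t <- sort(table(col), decreasing = TRUE)
      names(t)[1]
    })
  }
  cons <- if (is.null(consensus)) majority(seq_len(n)) else
    strsplit(as_dna_string(consensus), "")[[1]]
  if (length(cons) != L) {
    stop("consensus length must match the alignment", call. = FALSE)
  }
  assignment <- integer(n)
  splits <- list()
  next_id <- 0L

  recurse <- function(rows, cons_here, depth) {
    m <- length(rows)
    if (m < 2L * params$min_subfamily_size || depth <= 0L) {
      next_id <<- next_id + 1L
      assignment[rows] <<- next_id
      return(invisible(NULL))
    }
    sub <- M[rows, , drop = FALSE]
    # candidate (position, state): non-consensus states with enough carriers
    cand <- list()
    for (j in seq_len(L)) {
      tb <- table(sub[, j])
      tb <- tb[names(tb) != cons_here[j] & names(tb) %in% DNA_BASES]
      tb <- tb[tb >= params$min_subfamily_size]
      for (s in names(tb)) cand[[length(cand) + 1L]] <- list(pos = j, state = s)
    }
    best <- NULL
    if (length(cand) >= 2L) {
      for (a in seq_len(length(cand) - 1L)) {
        va <- sub[, cand[[a]]$pos] == cand[[a]]$state
        fa <- mean(va)
        for (b in (a + 1L):length(cand)) {
          if (cand[[b]]$pos == cand[[a]]$pos) next
          vb <- sub[, cand[[b]]$pos] == cand[[b]]$state
          n12 <- sum(va & vb)
          if (n12 < params$min_subfamily_size ||
              m - n12 < params$min_subfamily_size) next
          p <- stats::pbinom(n12 - 1L, m, fa * mean(vb), lower.tail = FALSE)
          if (is.null(best) || p < best$p) {
            best <- list(p = p, a = cand[[a]], b = cand[[b]], n12 = n12,
                         carriers = va & vb)
          }
        }
      }
    }
    if (is.null(best) || best$p >= params$p_threshold) {
      next_id <<- next_id + 1L
      assignment[rows] <<- next_id
      return(invisible(NULL))
    }
    splits[[length(splits) + 1L]] <<- data.frame(
      pos1 = best$a$pos, state1 = best$a$state,
      pos2 = best$b$pos, state2 = best$b$state,
      p = best$p, n_carriers = best$n12)
    in_rows <- rows[best$carriers]
    out_rows <- rows[!best$carriers]
    recurse(out_rows, majority(out_rows), depth - 1L)
    recurse(in_rows, majority(in_rows), depth - 1L)
    invisible(NULL)
  }

  recurse(seq_len(n), cons, params$max_depth)
  consensi <- vapply(seq_len(next_id), function(k)
    paste(majority(which(assignment == k)), collapse = ""), "")
  structure(list(assignment = assignment, consensi = consensi,
                 splits = if (length(splits)) do.call(rbind, splits) else
                   data.frame(pos1 = integer(0), state1 = character(0),
                              pos2 = integer(0), state2 = character(0),
                              p = numeric(0), n_carriers = integer(0)),
                 n_subfamilies = next_id),
            class = "subfamily_partition")
}

#' Read a TE library FASTA
#'
#' Headers follow the `name#class/family` convention; class and family are
#' parsed from the header, with `other`/`NA` fallbacks.
#'
#' @param path FASTA file.
#' @return data.frame with `name`, `te_class`, `family`, `consensus`.
#' @export
read_te_library <- function(path) {
  x <- read_fasta(path)
  hdr <- names(x)
  name <- sub("#.*$", "", hdr)
  rest <- ifelse(grepl("#", hdr, fixed = TRUE), sub("^[^#]*#", "", hdr), "")
  te_class <- ifelse(rest == "", "other", sub("/.*$", "", rest))
  family <- ifelse(grepl("/", rest, fixed = TRUE), sub("^[^/]*/", "", rest),
                   NA_character_)
  data.frame(name = name, te_class = te_class, family = family,
             consensus = unname(x))
}

#' Write a TE library FASTA
#'
#' @param library TE library data.frame.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_te_library <- function(library, path) {
  hdr <- paste0(library$name, "#", library$te_class,
                ifelse(is.na(library$family), "", paste0("/", library$family)))
  write_fasta(stats::setNames(library$consensus, hdr), path)
}
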