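# Pattern classification of catalog SVs: the four population-specific
# presence/absence classes (A-a, A-p, SA-a, SA-p), panel selection within the
# pattern windows, chromosomal enrichment, and a lightweight gene-model
# annotator.
#
# The classes are defined on SEQUENCE presence: A-a = the sequence occurs in
# every European genome and no Asian genome, A-p the reverse; SA-a = in every
# non-south genome and no south-Asian genome, SA-p the reverse. The merged
# catalog instead records VARIANT presence (which genomes deviate from the
# reference), so deletion rows are inverted before classification
# (`sequence_presence()`).

#' Population group assignment
#'
#' Maps each catalog genome to one of `EUR`, `ASIA_N`, `ASIA_S`, `TIBET`,
#' `CROSS`, `OUTGROUP` and derives the group sets the classifier uses. The
#' crossbreed is counted with the south-Asian set by default (it clusters
#' with south-Asian breeds) and with the Asian set for the A patterns; both
#' choices are flags.
#'
#' @param groups named character vector: genome -> group.
#' @param cross_with_south count `CROSS` genomes in the south-Asian set.
#' @param cross_as_asian count `CROSS` genomes in the Asian set.
#' @return a `group_assignment` list with `groups`, `european_set`,
#'   `asian_set`, `south_set`, `non_south_set`.
#' @export
group_assignment <- function(groups, cross_with_south = TRUE,
                             cross_as_asian = TRUE) {
  valid <- c("EUR", "ASIA_N", "ASIA_S", "TIBET", "CROSS", "OUTGROUP")
  bad <- setdiff(unique(groups), valid)
  if (length(bad)) stop("unknown group(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("groups must be named by genome", call. = FALSE)
  }
  g <- names(groups)
  asian_groups <- c("ASIA_N", "ASIA_S", "TIBET", if (cross_as_asian) "CROSS")
  south_groups <- c("ASIA_S", if (cross_with_south) "CROSS")
  asian <- g[groups %in% asian_groups]
  south <- g[groups %in% south_groups]
  structure(list(groups = groups,
                 european_set = g[groups == "EUR"],
                 asian_set = asian,
                 south_set = south,
                 non_south_set = setdiff(g[groups != "OUTGROUP"], south)),
            class = "group_assignment")
}

#' Convert a catalog's variant-presence matrix to sequence presence
#'
#' Insertion columns are kept as-is (the variant carrier holds the sequence);
#' deletion columns are inverted (the variant carrier lacks it). Indel
#' columns are set to `NA`: they are excluded from pattern classification.
#'
#' @param catalog an `sv_catalog`.
#' @param include_reference optional `c(name = group)` single-element named
#'   vector adding a row for the reference genome itself (which holds every
#'   deleted segment and no insertion).
#' @return logical genome x SV matrix (with `NA` for indel columns).
#' @export
sequence_presence <- function(catalog, include_reference = NULL) {
  m <- catalog$presence
  type <- catalog$records$type[match(colnames(m), catalog$records$sv_id)]
  m[, type == "deletion"] <- !m[, type == "deletion", drop = FALSE]
  m[, type == "indel"] <- NA
  if (!is.null(include_reference)) {
    ref_row <- ifelse(type == "deletion", TRUE,
                      ifelse(type == "insertion", FALSE, NA))
    m <- rbind(m, matrix(ref_row, nrow = 1,
                         dimnames = list(names(include_reference), NULL)))
  }
  m
}

#' Classify one SV into a population pattern
#'
#' Applies the strict all-or-none rule on sequence presence: `A-a` iff
#' present in all European and no Asian genomes; `A-p` iff the reverse;
#' `SA-a` iff present in all non-south and no south genomes; `SA-p` iff the
#' reverse; otherwise `none`. When both an SA and an A rule match, SA takes
#' precedence (configurable). Outgroup genomes are ignored.
#'
#' @param presence_row named logical vector of sequence presence per genome.
#' @param groups a [group_assignment()].
#' @param sa_precedence prefer SA over A when both match.
#' @return one of `"A-a"`, `"A-p"`, `"SA-a"`, `"SA-p"`, `"none"`.
#' @export
classify_sv <- function(presence_row, groups, sa_precedence = TRUE) {
  needed <- unique(c(groups$european_set, groups$asian_set,
                     groups$south_set, groups$non_south_set))
  missing <- setdiff(needed, names(presence_row))
  if (length(missing)) {
    stop("genomes missing from presence row: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyNA(presence_row[needed])) return("none")
  all_in <- function(s) length(s) > 0 && all(presence_row[s])
  none_in <- function(s) !any(presence_row[s])
  sa_a <- all_in(groups$non_south_set) && none_in(groups$south_set)
  sa_p <- all_in(groups$south_set) && none_in(groups$non_south_set)
  a_a <- all_in(groups$european_set) && none_in(groups$asian_set)
  a_p <- all_in(groups$asian_set) && none_in(groups$european_set)
  pats <- c("SA-a" = sa_a, "SA-p" = sa_p, "A-a" = a_a, "A-p" = a_p)
  if (!sa_precedence) pats <- pats[c("A-a", "A-p", "SA-a", "SA-p")]
  hit <- names(pats)[pats]
  if (length(hit)) hit[1] else "none"
}

#' Classify every SV in a catalog
#'
#' @param catalog an `sv_catalog`.
#' @param groups a [group_assignment()] covering all catalog genomes.
#' @param include_reference passed to [sequence_presence()]; if the reference
#'   genome itself belongs to a group (it is a European breed in the study
#'   design), include it here so its alleles count.
#' @param sa_precedence see [classify_sv()].
#' @return data.frame with `sv_id` and `pattern`.
#' @export
classify_catalog <- function(catalog, groups, include_reference = NULL,
                             sa_precedence = TRUE) {
  grp <- groups
  if (!is.null(include_reference)) {
    gg <- c(grp$groups, include_reference)
    grp <- group_assignment(gg)
  }
  m <- sequence_presence(catalog, include_reference)
  missing <- setdiff(names(grp$groups), rownames(m))
  if (length(missing)) {
    stop("grouped genomes absent from catalog: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pattern <- vapply(seq_len(ncol(m)), function(j)
    classify_sv(m[, j], grp, sa_precedence), "")
  data.frame(sv_id = colnames(m), pattern = pattern)
}

#' Pattern window regions
#'
#' The half-open windows the two patterns occupy, plus the minimum panel SV
#' length. Presets encode the real X-chromosome windows: `"methods"`
#' (44-58 Mb SA, 58-92 Mb A) and `"results"` (45-57 Mb SA, 57-87 Mb A); the
#' two presets differ in the source text and `"methods"` is the default.
#' Synthetic studies pass their own windows.
#'
#' @param window_SA,window_A half-open bp intervals.
#' @param min_panel_len minimum SV length for the panel (strict `>`).
#' @param preset `"methods"` or `"results"` (ignored when explicit windows
#'   are given).
#' @return a `pattern_regions` list.
#' @export
pattern_regions <- function(window_SA = NULL, window_A = NULL,
                            min_panel_len = 100, preset = "methods") {
  if (is.null(window_SA) || is.null(window_A)) {
    p <- match.arg(preset, c("methods", "results"))
    if (p == "methods") {
      window_SA <- c(44e6, 58e6); window_A <- c(58e6, 92e6)
    } else {
      window_SA <- c(45e6, 57e6); window_A <- c(57e6, 87e6)
    }
  }
  if (!interval_ok(window_SA) || !interval_ok(window_A) ||
      !intervals_disjoint(window_SA, window_A)) {
    stop("windows must be disjoint half-open intervals", call. = FALSE)
  }
  structure(list(window_SA = window_SA, window_A = window_A,
                 min_panel_len = min_panel_len),
            class = "pattern_regions")
}

#' Select the pattern SV panel
#'
#' Keeps SVs with a pattern other than `none` and length strictly greater
#' than `regions$min_panel_len`; with `apply_windows = TRUE` the SV start
#' must additionally lie inside the window matching its pattern (SA patterns
#' in `window_SA`, A patterns in `window_A`).
#'
#' @param calls output of [classify_catalog()].
#' @param catalog the `sv_catalog` the calls refer to.
#' @param regions a [pattern_regions()].
#' @param apply_windows filter on window location.
#' @param chrom restrict to this chromosome (default: no restriction).
#' @return data.frame of panel records with `sv_id` and `pattern` merged in.
#' @export
select_panel <- function(calls, catalog, regions, apply_windows = TRUE,
                         chrom = NULL) {
  rec <- merge(catalog$records, calls, by = "sv_id", sort = FALSE)
  keep <- rec$pattern != "none" & rec$length > regions$min_panel_len
  if (!is.null(chrom)) keep <- keep & rec$chrom == chrom
  if (apply_windows) {
    win <- ifelse(startsWith(rec$pattern, "SA"),
                  list(regions$window_SA), list(regions$window_A))
    inwin <- vapply(seq_len(nrow(rec)), function(i)
      point_in_interval(rec$ref_start[i], win[[i]]), TRUE)
    keep <- keep & inwin
  }
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$ref_start), , drop = FALSE]
}

#' Chromosomal enrichment of pattern SVs
#'
#' One-degree-of-freedom goodness-of-fit chi-squared test of the number of
#' pattern SVs on `chrom` against an expectation proportional to that
#' chromosome's share of the whole catalog (all SVs, patterned or not).
#'
#' @param calls output of [classify_catalog()].
#' @param catalog the `sv_catalog`.
#' @param chrom chromosome to test.
#' @return list with `chrom`, `observed`, `expected`, `chi2`, `p`.
#' @export
enrichment <- function(calls, catalog, chrom) {
  rec <- catalog$records
  if (!nrow(rec)) stop("catalog is empty", call. = FALSE)
  pat <- calls$pattern[match(rec$sv_id, calls$sv_id)] != "none"
  n_pat <- sum(pat)
  share <- mean(rec$chrom == chrom)
  expected <- n_pat * share
  if (expected <= 0 || expected >= n_pat) {
    stop("degenerate expectation: chromosome share is ", share, call. = FALSE)
  }
  observed <- sum(pat & rec$chrom == chrom)
  chi2 <- (observed - expected)^2 / expected +
    ((n_pat - observed) - (n_pat - expected))^2 / (n_pat - expected)
  list(chrom = chrom, observed = observed, expected = expected,
       chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Annotate panel SVs against gene models
#'
#' Labels each SV `exonic` (interval intersects an exon), `intronic`
#' (otherwise inside a gene span) or `intergenic`. Insertions are treated as
#' 1-bp intervals at their breakpoint. Also reports genes hit by at least
#' `min_hits` SVs.
#'
#' @param panel panel data.frame (from [select_panel()]), with `ref_start`,
#'   `ref_end`, `type`, `sv_id` and optionally `chrom`.
#' @param gene_models exon table: data.frame with `gene`, `transcript`,
#'   `start`, `end` (0-based half-open) and optionally `chrom`; or a GFF3
#'   file path (read via the rtracklayer package).
#' @param min_hits threshold for the multi-hit gene report.
#' @return list with `labels` (data.frame `sv_id`, `label`, `gene`) and
#'   `multi_hit` (data.frame `gene`, `n_svs`).
#' @export
region_annotate <- function(panel, gene_models, min_hits = 2L) {
  if (is.character(gene_models) && length(gene_models) == 1L) {
    gene_models <- read_gene_models(gene_models)
  }
  ex <- gene_models
  if (any(ex$end < ex$start)) stop("malformed exon intervals", call. = FALSE)
  if (!"chrom" %in% names(ex)) ex$chrom <- "chr1"
  pan <- panel
  if (!"chrom" %in% names(pan)) pan$chrom <- "chr1"
  gene_span <- do.call(rbind, lapply(split(ex, ex$gene), function(d)
    data.frame(gene = d$gene[1], chrom = d$chrom[1],
               start = min(d$start), end = max(d$end))))
  lab <- character(nrow(pan))
  gene <- rep(NA_character_, nrow(pan))
  for (i in seq_len(nrow(pan))) {
    s <- pan$ref_start[i]
    e <- if (pan$type[i] == "insertion") s + 1 else pan$ref_end[i]
    hit_ex <- ex$chrom == pan$chrom[i] & ex$start < e & ex$end > s
    hit_gene <- gene_span$chrom == pan$chrom[i] &
      gene_span$start < e & gene_span$end > s
    if (any(hit_ex)) {
      lab[i] <- "exonic"; gene[i] <- ex$gene[which(hit_ex)[1]]
    } else if (any(hit_gene)) {
      lab[i] <- "intronic"; gene[i] <- gene_span$gene[which(hit_gene)[1]]
    } else {
      lab[i] <- "intergenic"
    }
  }
  counts <- table(gene[!is.na(gene)])
  multi <- data.frame(gene = names(counts), n_svs = as.integer(counts))
  multi <- multi[multi$n_svs >= min_hits, , drop = FALSE]
  rownames(multi) <- NULL
  list(labels = data.frame(sv_id = pan$sv_id, label = lab, gene = gene),
       multi_hit = multi[order(-multi$n_svs), , drop = FALSE])
}

#' Read gene models from a GFF3 file
#'
#' Imports `exon` features and returns the 0-based half-open exon table
#' [region_annotate()] consumes. Requires the rtracklayer package.
#'
#' @param path GFF3 file.
#' @return data.frame with `gene`, `transcript`, `chrom`, `start`, `end`.
#' @export
read_gene_models <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GFF3 requires the rtracklayer package", call. = FALSE)
  }
  gr <- rtracklayer::import(path)
  ex <- as.data.frame(gr[gr$type == "exon"])
  gene <- if (!is.null(ex$gene_id)) ex$gene_id else
    as.character(unlist(ex$Parent))
  tx <- if (!is.null(ex$transcript_id)) ex$transcript_id else
    as.character(unlist(ex$Parent))
  data.frame(gene = as.character(gene), transcript = as.character(tx),
             chrom = as.character(ex$seqnames),
             start = ex$start - 1L, end = ex$end)
}
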