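# Dated-tree inference: origination intervals for single-origin markers,
# gains-only (Fitch-style) minimum-origins counting that flags
# tree-incompatible carrier profiles as candidate introgression, and a
# deterministic set-algebra simulator for multi-phase admixture/selection
# haplogroup scenarios.

#' Dated population tree
#'
#' Wraps an `ape` phylo object with node ages in Ma. Ages come from numeric
#' internal node labels when present, otherwise from branching times
#' (requires an ultrametric tree); leaves have age 0. Ages must strictly
#' decrease from root to tip.
#'
#' @param tree an `ape::phylo` object, a newick string, or a file path.
#' @return a `dated_tree` list with `tree` and `ages` (indexed by ape node
#'   number, tips first).
#' @export
dated_tree <- function(tree) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree) else
      ape::read.tree(text = tree)
  }
  if (!inherits(tree, "phylo")) stop("need a phylo object", call. = FALSE)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  ages <- numeric(ntip + nnode)
  lab_ages <- suppressWarnings(as.numeric(tree$node.label))
  if (!is.null(tree$node.label) && !anyNA(lab_ages)) {
    ages[ntip + seq_len(nnode)] <- lab_ages
  } else {
    bt <- ape::branching.times(tree)
    ages[as.integer(names(bt))] <- unname(bt)
  }
  parent <- tree$edge[, 1]; child <- tree$edge[, 2]
  if (any(ages[parent] <= ages[child] & child > ntip) ||
      any(ages[parent] <= 0 & child <= ntip)) {
    stop("node ages must strictly decrease from root to tips", call. = FALSE)
  }
  structure(list(tree = tree, ages = ages), class = "dated_tree")
}

#' @export
print.dated_tree <- function(x, ...) {
  cat("dated_tree:", length(x$tree$tip.label), "leaves, root age",
      max(x$ages), "Ma\n")
  invisible(x)
}

#' Read a dated tree from a newick file
#'
#' Internal node labels carry the node ages in Ma.
#'
#' @param path newick file.
#' @return a [dated_tree()].
#' @export
read_dated_tree <- function(path) dated_tree(path)

#' The packaged dated Sus phylogeny
#'
#' The 13-leaf species/population tree used throughout: the warthog outgroup
#' (divergence 11 Ma), the clade of four other Sus species (3.5 Ma), the
#' Sumatran S. scrofa subspecies (2 Ma), and the seven Eurasian populations
#' with the Europe/Asia split at 1 Ma, the south/north Asia split at 0.6 Ma
#' and the Tibet/north-China split at 0.2 Ma. Ages not fixed by those printed
#' divergences (inside the outgroup Sus clade; the domestic/wild splits at
#' 0.01 Ma) are synthetic placeholders that sit strictly inside the printed
#' bounds and carry no inferential weight.
#'
#' @return a [dated_tree()].
#' @export
sus_dated_tree <- function() {
  path <- system.file("extdata", "sus_dated.nwk", package = "introscan")
  read_dated_tree(path)
}

.tip_index <- function(dt, leaves) {
  idx <- match(leaves, dt$tree$tip.label)
  if (anyNA(idx)) {
    stop("unknown leaves: ", paste(leaves[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  idx
}

# tips (indices) descending from each node, as a list indexed by node number
.tips_under <- function(tree) {
  tree <- stats::reorder(tree, "cladewise")
  ntip <- length(tree$tip.label)
  res <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) res[[i]] <- i
  # edges in ape are in preorder for rooted trees; fill bottom-up
  for (e in rev(seq_len(nrow(tree$edge)))) {
    p <- tree$edge[e, 1]; c <- tree$edge[e, 2]
    res[[p]] <- c(res[[p]], res[[c]])
  }
  res
}

#' Extract a dated subtree
#'
#' Restricts a [dated_tree()] to the given leaves; node ages of retained
#' splits are preserved.
#'
#' @param dt a `dated_tree`.
#' @param leaves leaf names to keep.
#' @return a `dated_tree` on those leaves.
#' @export
extract_dated_clade <- function(dt, leaves) {
  .tip_index(dt, leaves)
  sub <- ape::keep.tip(dt$tree, leaves)
  dated_tree(sub)
}

#' Origination interval of a single-origin marker
#'
#' Assuming the marker arose once and was never lost, its origin lies on the
#' stem branch of the carrier clade: the interval runs from the age of the
#' carrier clade's parent node (older bound) down to the carrier crown age
#' (younger bound; 0 for a single carrier leaf). Leaves with unknown state
#' are ignored. Carriers that are not monophyletic have no single-origin
#' branch; use [min_origins()] instead.
#'
#' @param dt a [dated_tree()].
#' @param carriers leaf names carrying the marker.
#' @param unknown leaf names with unknown state (ignored).
#' @return list with `older` and `younger` bounds in Ma (`older = Inf` when
#'   every non-unknown leaf is a carrier).
#' @export
origination_interval <- function(dt, carriers, unknown = character(0)) {
  tree <- dt$tree
  ntip <- length(tree$tip.label)
  car <- .tip_index(dt, carriers)
  unk <- if (length(unknown)) .tip_index(dt, unknown) else integer(0)
  if (!length(car)) stop("need at least one carrier", call. = FALSE)
  if (length(car) == 1L) {
    mrca <- car
  } else {
    mrca <- ape::getMRCA(tree, car)
  }
  tips <- .tips_under(tree)
  inside <- setdiff(tips[[mrca]], unk)
  if (!all(inside %in% car)) {
    stop("carriers are not monophyletic on this tree; ",
         "use min_origins() to count independent gains", call. = FALSE)
  }
  root <- ntip + 1L
  younger <- dt$ages[mrca]
  if (mrca == root) {
    return(list(older = Inf, younger = younger))
  }
  parent <- tree$edge[tree$edge[, 2] == mrca, 1]
  list(older = dt$ages[parent], younger = younger)
}

#' Minimum number of independent origins of a marker
#'
#' Gains-only small parsimony: losses are disallowed, so every gain edge must
#' subtend only carrier (or unknown) leaves, and the minimal solution is one
#' gain on the stem of each maximal all-carrier subtree. More than one origin
#' flags the profile as tree-incompatible - candidate introgression or
#' homoplasy.
#'
#' @inheritParams origination_interval
#' @return list with `n_origins`, `gain_nodes` (tip or node labels/numbers
#'   of the maximal carrier subtrees' crowns) and `introgression_flag`
#'   (`n_origins > 1`).
#' @export
min_origins <- function(dt, carriers, unknown = character(0)) {
  tree <- dt$tree
  ntip <- length(tree$tip.label)
  car <- .tip_index(dt, carriers)
  if (!length(car)) stop("need at least one carrier", call. = FALSE)
  unk <- if (length(unknown)) .tip_index(dt, unknown) else integer(0)
  tips <- .tips_under(tree)
  n_all <- ntip + tree$Nnode
  pure <- logical(n_all)       # subtree contains no non-carrier known leaf
  has_car <- logical(n_all)
  for (v in seq_len(n_all)) {
    known <- setdiff(tips[[v]], unk)
    pure[v] <- all(known %in% car)
    has_car[v] <- any(tips[[v]] %in% car)
  }
  parent_of <- integer(n_all)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1L
  gain <- vapply(seq_len(n_all), function(v) {
    if (!pure[v] || !has_car[v]) return(FALSE)
    v == root || !(pure[parent_of[v]] && has_car[parent_of[v]])
  }, TRUE)
  nodes <- which(gain)
  labels <- vapply(nodes, function(v) {
    if (v <= ntip) tree$tip.label[v] else paste0("node", v)
  }, "")
  list(n_origins = length(nodes), gain_nodes = labels,
       introgression_flag = length(nodes) > 1L)
}

#' All recombinant haplotypes of two loci
#'
#' Cartesian product of the allele sets at the two pattern loci.
#'
#' @param alleles_a,alleles_b non-empty character vectors, e.g.
#'   `c("A1", "A2")` and `c("B1", "B2")`.
#' @return sorted character vector of haplotypes (`"A1B1"`, ...).
#' @export
enumerate_recombinants <- function(alleles_a, alleles_b) {
  if (!length(alleles_a) || !length(alleles_b)) {
    stop("both allele sets must be non-empty", call. = FALSE)
  }
  sort(as.vector(outer(alleles_a, alleles_b, paste0)))
}

.hap_allele <- function(hap, locus) {
  m <- regmatches(hap, gregexpr("[A-Z][0-9]+", hap))
  vapply(m, function(parts) {
    hit <- parts[startsWith(parts, locus)]
    if (!length(hit)) NA_character_ else hit[1]
  }, "")
}

#' Scenario events
#'
#' Constructors for the four deterministic event types a phase may contain:
#' `ev_split` replaces a population by two daughters (each inheriting a copy
#' of its haplotype set) at a given time; `ev_fix` replaces a population's
#' set outright; `ev_admix` pours a source population into a target - with
#' recombination the target becomes every recombinant of the union's
#' alleles, without it the plain union; `ev_select` keeps only haplotypes
#' carrying the favoured allele at a locus.
#'
#' @param pop,source,target population names.
#' @param daughters two daughter population names.
#' @param time event time in Ma (must not increase across phases).
#' @param haplotypes character vector of haplotypes.
#' @param recombination logical.
#' @param locus locus prefix (`"A"` or `"B"`).
#' @param allele favoured allele (e.g. `"A1"`).
#' @return an event list.
#' @export
ev_split <- function(pop, daughters, time) {
  stopifnot(length(daughters) == 2L)
  list(type = "split", pop = pop, daughters = daughters, time = time)
}

#' @rdname ev_split
#' @export
ev_fix <- function(pop, haplotypes) {
  list(type = "fix", pop = pop, haplotypes = haplotypes)
}

#' @rdname ev_split
#' @export
ev_admix <- function(source, target, recombination = TRUE) {
  list(type = "admix", source = source, target = target,
       recombination = isTRUE(recombination))
}

#' @rdname ev_split
#' @export
ev_select <- function(pop, locus, allele) {
  list(type = "select", pop = pop, locus = locus, allele = allele)
}

#' Build a scenario from ordered phases
#'
#' @param ... phases, each a list of events (possibly empty).
#' @param names optional phase names.
#' @return a `scenario` object.
#' @export
scenario <- function(..., names = NULL) {
  phases <- list(...)
  if (is.null(names)) names <- paste0("phase", seq_along(phases))
  times <- unlist(lapply(phases, function(ph)
    vapply(Filter(function(e) e$type == "split", ph),
           function(e) e$time, 0)))
  if (length(times) > 1L && any(diff(times) > 0)) {
    stop("event times must be non-increasing across phases", call. = FALSE)
  }
  structure(list(phases = stats::setNames(phases, names)),
            class = "scenario")
}

#' The four-phase Eurasian haplogroup scenario
#'
#' The canonical admixture/selection history of the two X-linked pattern
#' loci: (1) an undifferentiated ancestral Eurasian population; (2) the
#' Europe/Asia split at 1 Ma with the patterns fixing A1B1 in Europe and
#' A2B2 in Asia; (3) the south/north Asia split at 0.6 Ma, European
#' migration into north Asia with recombination (producing all four
#' recombinant haplotypes) followed by cold-adaptation selection for A1
#' there; (4) the Tibetan split at 0.2 Ma fixing A1B2 in Tibet.
#'
#' @return list with `scenario` and the `initial` state.
#' @export
fig_scenario_eurasia <- function() {
  scn <- scenario(
    list(),
    list(ev_split("Eurasia", c("Europe", "Asia"), 1.0),
         ev_fix("Europe", "A1B1"),
         ev_fix("Asia", "A2B2")),
    list(ev_split("Asia", c("SouthAsia", "NorthAsia"), 0.6),
         ev_admix("Europe", "NorthAsia", recombination = TRUE),
         ev_select("NorthAsia", "A", "A1")),
    list(ev_split("NorthAsia", c("NorthAsia", "Tibet"), 0.2),
         ev_fix("Tibet", "A1B2")),
    names = c("phase1_ancestral", "phase2_divergence",
              "phase3_admixture_selection", "phase4_tibet"))
  list(scenario = scn, initial = list(Eurasia = "A2B2"))
}

#' Simulate a haplogroup scenario
#'
#' Deterministic set algebra over populations' haplotype sets, phase by
#' phase and event by event. The trace records the full population state
#' after every event, so intermediate states (e.g. the post-admixture,
#' pre-selection recombinant pool) can be inspected. Selection that empties
#' a population is an error, not a silent state.
#'
#' @param scn a [scenario()].
#' @param initial named list: population -> character vector of haplotypes.
#' @return list with `final` (named list of sorted haplotype sets),
#'   `census` (distinct haplotypes across extant populations),
#'   `n_haplogroups`, and `trace` (per phase, per event: event type and the
#'   state after it).
#' @export
simulate_phases <- function(scn, initial) {
  state <- lapply(initial, function(h) sort(unique(h)))
  trace <- list()
  for (ph in names(scn$phases)) {
    ev_states <- list()
    for (e in scn$phases[[ph]]) {
      state <- switch(
        e$type,
        split = {
          if (is.null(state[[e$pop]])) {
            stop("split of unknown population: ", e$pop, call. = FALSE)
          }
          s <- state
          h <- s[[e$pop]]
          s[[e$pop]] <- NULL
          s[[e$daughters[1]]] <- h
          s[[e$daughters[2]]] <- h
          s
        },
        fix = {
          if (is.null(state[[e$pop]])) {
            stop("fix of unknown population: ", e$pop, call. = FALSE)
          }
          s <- state
          s[[e$pop]] <- sort(unique(e$haplotypes))
          s
        },
        admix = {
          if (is.null(state[[e$source]]) || is.null(state[[e$target]])) {
            stop("admix with unknown population", call. = FALSE)
          }
          s <- state
          pool <- union(s[[e$source]], s[[e$target]])
          s[[e$target]] <- if (e$recombination) {
            enumerate_recombinants(unique(.hap_allele(pool, "A")),
                                   unique(.hap_allele(pool, "B")))
          } else sort(pool)
          s
        },
        select = {
          if (is.null(state[[e$pop]])) {
            stop("select on unknown population: ", e$pop, call. = FALSE)
          }
          s <- state
          keep <- .hap_allele(s[[e$pop]], e$locus) == e$allele
          if (!any(keep)) {
            stop("selection for ", e$allele, " eliminates every haplotype ",
                 "in ", e$pop, call. = FALSE)
          }
          s[[e$pop]] <- s[[e$pop]][keep]
          s
        },
        stop("unknown event type: ", e$type, call. = FALSE))
      ev_states[[length(ev_states) + 1L]] <- list(event = e$type,
                                                  state = state)
    }
    trace[[ph]] <- ev_states
  }
  census <- sort(unique(unlist(state)))
  list(final = state, census = census, n_haplogroups = length(census),
       trace = trace)
}

#' Read / write carrier profiles as TSV
#'
#' Two columns: `leaf` and `state` in `carrier` / `non-carrier` / `unknown`.
#'
#' @param path TSV file.
#' @param profile named character vector: leaf -> state.
#' @return `read_profile()` returns the named vector; the writer returns
#'   `path` invisibly.
#' @export
read_profile <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(d$state, d$leaf)
}

#' @rdname read_profile
#' @export
write_profile <- function(profile, path) {
  utils::write.table(data.frame(leaf = names(profile),
                                state = unname(profile)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a scenario from YAML
#'
#' Schema: `initial: {pop: [haplotypes]}` and `phases: [{name, events:
#' [{type, ...}]}]` with event fields matching the [ev_split()] family.
#'
#' @param path YAML file.
#' @return list with `scenario` and `initial`, as for
#'   [fig_scenario_eurasia()].
#' @export
scenario_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  phases <- lapply(y$phases, function(ph) {
    lapply(ph$events, function(e) {
      switch(e$type,
             split = ev_split(e$pop, unlist(e$daughters), e$time),
             fix = ev_fix(e$pop, unlist(e$haplotypes)),
             admix = ev_admix(e$source, e$target,
                              isTRUE(e$recombination)),
             select = ev_select(e$pop, e$locus, e$allele),
             stop("unknown event type in YAML: ", e$type, call. = FALSE))
    })
  })
  nm <- vapply(y$phases, function(ph)
    if (is.null(ph$name)) NA_character_ else ph$name, "")
  if (anyNA(nm)) nm <- paste0("phase", seq_along(phases))
  scn <- do.call(scenario, c(phases, list(names = nm)))
  list(scenario = scn, initial = lapply(y$initial, unlist))
}
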