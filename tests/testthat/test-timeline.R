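asian5 <- c("SouthChina_wild", "SouthChina_domestic", "Tibetan_wild",
            "NorthChina_wild", "NorthChina_domestic")
north3 <- c("Tibetan_wild", "NorthChina_wild", "NorthChina_domestic")

test_that("the packaged dated tree loads with the printed divergence ages", {
  dt <- sus_dated_tree()
  expect_s3_class(dt, "dated_tree")
  expect_length(dt$tree$tip.label, 13)
  expect_equal(max(dt$ages), 11)
  expect_true(all(c(3.5, 2, 1, 0.6, 0.2) %in% dt$ages))
})

test_that("dated_tree validates age ordering", {
  expect_error(dated_tree(ape::read.tree(text = "(A:1,(B:2,C:2)2:-1)1;")),
               "decrease")
  # a tree without labels falls back to branching times
  dt <- dated_tree(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
  expect_equal(sort(unique(dt$ages)), c(0, 1, 2))
})

test_that("origination intervals bracket the carrier clade stem", {
  dt <- sus_dated_tree()
  # the Asia-wide derived allele arose between the Europe/Asia split and
  # the south/north Asia split
  iv <- origination_interval(dt, asian5)
  expect_equal(iv$older, 1.0)
  expect_equal(iv$younger, 0.6)

  # within the Asian subtree, the north-Asian allele arose between the
  # south/north split and the Tibet/north-China split
  sub <- extract_dated_clade(dt, asian5)
  iv2 <- origination_interval(sub, north3)
  expect_equal(iv2$older, 0.6)
  expect_equal(iv2$younger, 0.2)

  # a single-leaf carrier clade has crown age 0
  iv3 <- origination_interval(sub, "Tibetan_wild")
  expect_equal(iv3$older, 0.2)
  expect_equal(iv3$younger, 0)

  # every leaf a carrier: the stem is unbounded above
  iv4 <- origination_interval(sub, sub$tree$tip.label)
  expect_equal(iv4$older, Inf)
  expect_equal(iv4$younger, 0.6)

  # non-monophyletic carriers are rejected with guidance
  expect_error(origination_interval(dt, c("Europe_wild", "Tibetan_wild")),
               "min_origins")
  # unknown-state leaves are ignored for monophyly
  iv5 <- origination_interval(dt, c("Tibetan_wild", "NorthChina_wild"),
                              unknown = "NorthChina_domestic")
  expect_equal(iv5$older, 0.6)
  expect_equal(iv5$younger, 0.2)
})

test_that("origination interval equals the brute-force feasible-edge scan", {
  dt <- sus_dated_tree()
  tree <- dt$tree
  ntip <- length(tree$tip.label)
  tips_below <- function(v) {
    if (v <= ntip) return(v)
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    unlist(lapply(kids, tips_below))
  }
  carriers <- asian5
  car_idx <- match(carriers, tree$tip.label)
  feasible <- which(vapply(seq_len(ntip + tree$Nnode), function(v) {
    setequal(tips_below(v), car_idx)
  }, TRUE))
  expect_length(feasible, 1)   # exactly the carrier-clade crown
  parent <- tree$edge[tree$edge[, 2] == feasible, 1]
  iv <- origination_interval(dt, carriers)
  expect_equal(iv$older, dt$ages[parent])
  expect_equal(iv$younger, dt$ages[feasible])
})

test_that("min_origins counts gains and agrees with exhaustive search", {
  dt <- sus_dated_tree()
  # a clean clade needs one gain
  expect_equal(min_origins(dt, asian5)$n_origins, 1)
  expect_false(min_origins(dt, asian5)$introgression_flag)
  # European breeds plus a north-China wild boar: two gains, flagged
  mo <- min_origins(dt, c("Europe_domestic", "Europe_wild",
                          "NorthChina_wild"))
  expect_equal(mo$n_origins, 2)
  expect_true(mo$introgression_flag)
  # all leaves: a single root gain
  expect_equal(min_origins(dt, dt$tree$tip.label)$n_origins, 1)

  # exhaustive oracle: smallest set of gain nodes whose subtended leaves
  # are exactly the carriers
  tree <- dt$tree
  ntip <- length(tree$tip.label)
  tips_below <- function(v) {
    if (v <= ntip) return(v)
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    unlist(lapply(kids, tips_below))
  }
  below <- lapply(seq_len(ntip + tree$Nnode), tips_below)
  brute <- function(car_idx) {
    for (k in 1:4) {
      for (s in utils::combn(length(below), k, simplify = FALSE)) {
        covered <- sort(unique(unlist(below[s])))
        if (identical(covered, sort(car_idx))) return(k)
      }
    }
    Inf
  }
  set.seed(17)
  for (rep in 1:6) {
    car_idx <- sort(sample(ntip, sample(2:6, 1)))
    got <- min_origins(dt, tree$tip.label[car_idx])$n_origins
    want <- brute(car_idx)
    if (is.finite(want)) expect_equal(got, want, info = paste("rep", rep))
  }
})

test_that("enumerate_recombinants is the Cartesian product of alleles", {
  expect_setequal(enumerate_recombinants(c("A1", "A2"), c("B1", "B2")),
                  c("A1B1", "A1B2", "A2B1", "A2B2"))
  expect_equal(enumerate_recombinants("A1", "B1"), "A1B1")
  expect_setequal(enumerate_recombinants("A1", c("B1", "B2")),
                  c("A1B1", "A1B2"))
  expect_error(enumerate_recombinants(character(0), "B1"), "non-empty")
})

test_that("the four-phase scenario reproduces the three modern haplogroups", {
  fs <- fig_scenario_eurasia()
  res <- simulate_phases(fs$scenario, fs$initial)
  expect_equal(res$final$Europe, "A1B1")
  expect_equal(res$final$SouthAsia, "A2B2")
  expect_equal(res$final$NorthAsia, c("A1B1", "A1B2"))
  expect_equal(res$final$Tibet, "A1B2")
  expect_equal(res$n_haplogroups, 3)
  expect_setequal(res$census, c("A1B1", "A1B2", "A2B2"))
  # the admixture intermediate holds all four recombinant haplotypes
  post_admix <- res$trace$phase3_admixture_selection[[2]]$state$NorthAsia
  expect_length(post_admix, 4)
  expect_setequal(post_admix, c("A1B1", "A1B2", "A2B1", "A2B2"))
})

test_that("scenario algebra is deterministic and order-insensitive within reason", {
  # without admixture or selection only the two parental haplogroups remain
  scn <- scenario(
    list(ev_split("Eurasia", c("Europe", "Asia"), 1.0),
         ev_fix("Europe", "A1B1"),
         ev_fix("Asia", "A2B2")))
  res <- simulate_phases(scn, list(Eurasia = "A2B2"))
  expect_equal(res$n_haplogroups, 2)

  # events on disjoint populations commute within a phase
  scn_a <- scenario(
    list(ev_split("Eurasia", c("Europe", "Asia"), 1.0)),
    list(ev_fix("Europe", "A1B1"), ev_fix("Asia", "A2B2")))
  scn_b <- scenario(
    list(ev_split("Eurasia", c("Europe", "Asia"), 1.0)),
    list(ev_fix("Asia", "A2B2"), ev_fix("Europe", "A1B1")))
  ra <- simulate_phases(scn_a, list(Eurasia = "A0B0"))
  rb <- simulate_phases(scn_b, list(Eurasia = "A0B0"))
  expect_equal(ra$final[order(names(ra$final))],
               rb$final[order(names(rb$final))])

  # selection that empties a population is an error
  bad <- scenario(list(ev_select("Eurasia", "A", "A9")))
  expect_error(simulate_phases(bad, list(Eurasia = "A2B2")), "eliminates")

  # event times must not increase across phases
  expect_error(scenario(list(ev_split("X", c("a", "b"), 0.5)),
                        list(ev_split("a", c("c", "d"), 0.9))),
               "non-increasing")
})

test_that("the packaged scenario YAML matches the built-in scenario", {
  path <- system.file("extdata", "eurasia_phases.yaml",
                      package = "introscan")
  ys <- scenario_from_yaml(path)
  res_yaml <- simulate_phases(ys$scenario, ys$initial)
  res_builtin <- simulate_phases(fig_scenario_eurasia()$scenario,
                                 fig_scenario_eurasia()$initial)
  expect_equal(res_yaml$final[order(names(res_yaml$final))],
               res_builtin$final[order(names(res_builtin$final))])
  expect_equal(res_yaml$n_haplogroups, 3)
})

test_that("carrier profiles round-trip through TSV", {
  prof <- c(Europe_wild = "carrier", Tibetan_wild = "non-carrier",
            Sumatra = "unknown")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_profile(prof, p)
  expect_equal(read_profile(p), prof)
})
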