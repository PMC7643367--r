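test_that("compute_n50 follows the sort-and-accumulate definition", {
  expect_equal(compute_n50(c(5, 4, 3, 2, 1)), 4)
  expect_equal(compute_n50(10), 10)
  expect_equal(compute_n50(c(1, 1, 1, 1)), 1)
  expect_error(compute_n50(numeric(0)), "non-empty")
  expect_error(compute_n50(c(5, 0)), "> 0")
})

test_that("find_anchors recovers identity and flanking matches around an insertion", {
  ref <- random_dna(1000, 101)
  p <- anchor_params()

  a <- find_anchors(ref, ref, p)
  expect_equal(nrow(a), 1)
  expect_equal(unlist(a[1, c("ref_start", "ref_end", "qry_start", "qry_end")],
                      use.names = FALSE), c(0, 1000, 0, 1000))

  # 300-bp novel insertion at position 500; force mismatching junction bases
  # so the maximal matches stop exactly at the breakpoint
  ins <- strsplit(random_dna(300, 102), "")[[1]]
  nxt <- substring(ref, 501, 501)
  prv <- substring(ref, 500, 500)
  ins[1] <- setdiff(c("A", "C", "G", "T"), nxt)[1]
  ins[300] <- setdiff(c("A", "C", "G", "T"), prv)[1]
  qry <- paste0(substring(ref, 1, 500), paste(ins, collapse = ""),
                substring(ref, 501, 1000))
  a <- find_anchors(ref, qry, p)
  expect_equal(nrow(a), 2)
  expect_equal(a$ref_start, c(0, 500))
  expect_equal(a$ref_end, c(500, 1000))
  expect_equal(a$qry_start, c(0, 800))
  expect_equal(a$qry_end, c(500, 1300))

  # unrelated sequences share no unique 21-mer
  expect_equal(nrow(find_anchors(random_dna(1000, 103),
                                 random_dna(1000, 104), p)), 0)
  expect_error(find_anchors("", ref, p), "non-empty")
})

test_that("chain_anchors matches a brute-force maximal-weight collinear chain", {
  p <- anchor_params(min_match_len = 30, min_cluster_len = 50, seed_k = 11,
                     max_anchor_overlap = 0)
  # brute force over all subsets of <= 10 anchors
  brute_best <- function(a, ov = 0) {
    n <- nrow(a)
    best <- 0
    for (size in seq_len(n)) {
      for (s in utils::combn(n, size, simplify = FALSE)) {
        s <- s[order(a$ref_start[s])]
        ok <- TRUE
        if (length(s) > 1) {
          for (k in seq_len(length(s) - 1)) {
            i <- s[k]; j <- s[k + 1]
            if (!(a$ref_start[j] > a$ref_start[i] &&
                  a$qry_start[j] > a$qry_start[i] &&
                  a$ref_end[j] > a$ref_end[i] &&
                  a$qry_end[j] > a$qry_end[i] &&
                  a$ref_start[j] >= a$ref_end[i] - ov &&
                  a$qry_start[j] >= a$qry_end[i] - ov)) { ok <- FALSE; break }
          }
        }
        if (ok) best <- max(best, sum(a$length[s]))
      }
    }
    best
  }
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(4:8, 1)
    rs <- sort(sample(0:2000, n))
    len <- sample(30:120, n, replace = TRUE)
    a <- data.frame(ref_start = rs, ref_end = rs + len,
                    qry_start = sample(0:2000, n),
                    length = len)
    a$qry_end <- a$qry_start + a$length
    chains <- chain_anchors(a, p)
    got <- if (length(chains)) max(vapply(chains, function(ch)
      sum(ch$length), 0)) else 0
    want <- brute_best(a)
    if (want < p$min_cluster_len) want <- 0
    expect_equal(got, want, info = paste("rep", rep))
  }

  # two collinear anchors form one chain
  a <- data.frame(ref_start = c(0, 300), ref_end = c(200, 500),
                  qry_start = c(0, 350), qry_end = c(200, 550),
                  length = c(200, 200))
  ch <- chain_anchors(a, p)
  expect_length(ch, 1)
  expect_equal(nrow(ch[[1]]), 2)

  # a lone 400-bp anchor dies below a 500-bp cluster threshold
  p500 <- anchor_params(min_match_len = 100, min_cluster_len = 500)
  a <- data.frame(ref_start = 0, ref_end = 400, qry_start = 0,
                  qry_end = 400, length = 400)
  expect_length(chain_anchors(a, p500), 0)
})

test_that("call_svs performs exact gap arithmetic and honours length bounds", {
  ref <- random_dna(3000, 201)
  p <- anchor_params()

  mk_qry_ins <- function(ref, pos, insert) {
    paste0(substring(ref, 1, pos), insert,
           substring(ref, pos + 1, nchar(ref)))
  }
  ins <- random_dna(300, 202)
  qry <- mk_qry_ins(ref, 1500, ins)
  chains <- chain_anchors(find_anchors(ref, qry, p), p)
  recs <- call_svs(chains[[1]], ref, qry, source_genome = "g1")
  expect_equal(nrow(recs), 1)
  expect_equal(recs$type, "insertion")
  expect_equal(recs$length, 300)
  expect_equal(recs$ref_start, recs$ref_end)
  # the called alt sequence reconstructs the derived genome
  expect_identical(mk_qry_ins(ref, recs$ref_start, recs$alt_seq), qry)

  # deletion
  qry_del <- paste0(substring(ref, 1, 1200), substring(ref, 1401, 3000))
  chains <- chain_anchors(find_anchors(ref, qry_del, p), p)
  recs <- call_svs(chains[[1]], ref, qry_del)
  expect_equal(recs$type, "deletion")
  expect_equal(recs$length, 200)
  expect_identical(paste0(substring(ref, 1, recs$ref_start),
                          substring(ref, recs$ref_end + 1, 3000)), qry_del)

  # perfectly adjacent anchors yield no record
  chain0 <- data.frame(ref_start = c(0, 500), ref_end = c(500, 1000),
                       qry_start = c(0, 500), qry_end = c(500, 1000),
                       length = c(500, 500))
  expect_equal(nrow(call_svs(chain0, ref, ref)), 0)

  # a 12-kb insertion exceeds the 10-kb bound and is dropped
  big <- random_dna(12000, 203)
  qry_big <- mk_qry_ins(ref, 1500, big)
  chains <- chain_anchors(find_anchors(ref, qry_big, p), p)
  expect_equal(nrow(do.call(rbind, lapply(chains, call_svs, ref = ref,
                                          qry = qry_big))), 0)
})

test_that("merge_catalog collapses duplicates and keeps presence bookkeeping", {
  recs <- function(starts, ends, types, genome) {
    data.frame(chrom = "chr1", ref_start = starts, ref_end = ends,
               type = types,
               length = ifelse(types == "insertion", 150, ends - starts),
               alt_seq = "", source_genome = genome)
  }
  a <- recs(c(100, 1000), c(300, 1000), c("deletion", "insertion"), "gA")

  # single genome: identical records, all-true presence
  cat1 <- merge_catalog(list(gA = a))
  expect_equal(nrow(cat1$records), 2)
  expect_true(all(cat1$presence["gA", ]))

  # two genomes with identical lists: same records, both present
  cat2 <- merge_catalog(list(gA = a, gB = recs(c(100, 1000), c(300, 1000),
                                               c("deletion", "insertion"),
                                               "gB")))
  expect_equal(nrow(cat2$records), 2)
  expect_true(all(cat2$presence))

  # disjoint records: union with diagonal presence
  b <- recs(c(5000, 8000), c(5200, 8000), c("deletion", "insertion"), "gB")
  cat3 <- merge_catalog(list(gA = a, gB = b))
  expect_equal(nrow(cat3$records), 4)
  expect_equal(sum(cat3$presence), 4)
  expect_equal(unname(rowSums(cat3$presence)), c(2, 2))
})

test_that("merge_catalog is permutation-invariant and idempotent", {
  set.seed(77)
  mk <- function(genome, starts) {
    data.frame(chrom = "chr1", ref_start = starts,
               ref_end = starts + sample(100:400, length(starts),
                                         replace = TRUE),
               type = "deletion", length = 0, alt_seq = "",
               source_genome = genome)
  }
  g1 <- mk("g1", c(100, 2000, 5000)); g1$length <- g1$ref_end - g1$ref_start
  g2 <- mk("g2", c(120, 2050, 9000)); g2$length <- g2$ref_end - g2$ref_start
  g3 <- mk("g3", c(5010, 9005));      g3$length <- g3$ref_end - g3$ref_start
  cat_a <- merge_catalog(list(g1 = g1, g2 = g2, g3 = g3))
  cat_b <- merge_catalog(list(g3 = g3, g1 = g1, g2 = g2))
  expect_identical(cat_a$records, cat_b$records)
  expect_identical(cat_a$presence, cat_b$presence)

  # idempotence: re-merging the merged representatives changes nothing
  again <- merge_catalog(list(all = transform(cat_a$records,
                                              source_genome = "all")))
  expect_equal(again$records$ref_start, cat_a$records$ref_start)
  expect_equal(again$records$length, cat_a$records$length)
})

test_that("every discovered record respects the 1-10000 bp length bound", {
  st <- cached("roundtrip_small", function() {
    cfg <- sim_config(seed = 31, genome_length = 80000)
    sim <- simulate_study(cfg, n_sv = 20, size_range = c(50, 5000),
                          te_fraction = 0.2)
    per <- lapply(names(sim$genomes)[c(1, 4, 7)], function(g)
      discover_svs(sim$reference, sim$genomes[[g]], source_genome = g))
    names(per) <- names(sim$genomes)[c(1, 4, 7)]
    list(sim = sim, per = per)
  })
  all_recs <- do.call(rbind, st$per)
  expect_true(all(all_recs$length >= 1 & all_recs$length <= 10000))
  expect_true(all(all_recs$ref_end >= all_recs$ref_start))
  ins <- all_recs[all_recs$type == "insertion", ]
  expect_true(all(ins$ref_end == ins$ref_start))
  expect_true(all(nchar(ins$alt_seq) == ins$length))
})
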