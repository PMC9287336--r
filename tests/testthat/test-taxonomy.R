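test_that("genome QC uses strict inequalities at the printed thresholds", {
  rec <- data.frame(genome = c("at45", "clean", "at70_5", "contam10"),
                    completeness = c(45, 98, 80, 90),
                    contamination = c(5, 0, 5, 10))
  kept <- filter_genomes(rec, 45, 10)
  expect_setequal(kept$genome, c("clean", "at70_5"))  # 45% completeness is out
  hq <- filter_genomes(rec, 70, 5)
  expect_setequal(hq$genome, "clean")                 # 5% contamination is out
})

test_that("AAI is exactly 100 for identical proteomes and flags undefined pairs", {
  pp <- simulate_divergent_proteomes(12, 120, 0.95, seed = 5)
  self <- compute_aai(pp$a, pp$a)
  expect_true(self$defined)
  expect_equal(self$aai, 100)
  expect_equal(self$n_pairs, 12L)

  # unalignable proteomes: no local alignment clears the score floor
  a <- Biostrings::AAStringSet(c(x = "PPPPPPPP"))
  b <- Biostrings::AAStringSet(c(y = "GGGGGGGG"))
  und <- compute_aai(a, b)
  expect_false(und$defined)
  expect_true(is.na(und$aai))
})

test_that("AAI recovers the simulated proteome divergence", {
  pp <- simulate_divergent_proteomes(25, 200, 0.9, seed = 6)
  r <- compute_aai(pp$a, pp$b)
  expect_true(r$defined)
  expect_lt(abs(r$aai - 90), 2)
})

test_that("AAI clustering separates blocks and splits polyphyletic clusters", {
  ids <- c("a1", "a2", "a3", "b1", "b2", "b3")
  m <- matrix(60, 6, 6, dimnames = list(ids, ids))
  m[1:3, 1:3] <- 96
  m[4:6, 4:6] <- 96
  diag(m) <- 100
  tree <- parse_newick("((a1:1,(a2:1,a3:1):1):1,(b1:1,(b2:1,b3:1):1):1);")
  genera <- cluster_taxa(m, 70, tree, rank = "genus")
  expect_true(same_partition(genera, list(c("a1", "a2", "a3"), c("b1", "b2", "b3"))))
  species <- cluster_taxa(m, 95, tree, rank = "species")
  expect_true(same_partition(species, list(c("a1", "a2", "a3"), c("b1", "b2", "b3"))))

  # same AAI blocks, but the tree strands a3 away from the other 'a' genomes:
  # the cohesive 'a' cluster splits into its two monophyletic components
  tree2 <- parse_newick("((a1:1,a2:1):1,(a3:1,(b1:1,(b2:1,b3:1):1):1):1);")
  split <- cluster_taxa(m, 70, tree2, rank = "genus")
  expect_true(same_partition(split, list(c("a1", "a2"), "a3",
                                         c("b1", "b2", "b3"))))

  # thresholds coarsen monotonically: everything merges at threshold 0
  one <- cluster_taxa(m, 0, tree, rank = "phylum")
  expect_equal(length(one), 1L)
  # and near-perfect thresholds isolate non-identical genomes
  singletons <- cluster_taxa(m, 99.5, tree)
  expect_equal(length(singletons), 6L)
})

test_that("completeness adjustment is linear and homogeneous", {
  expect_equal(adjust_for_completeness(1.0e6, 50), 2.0e6)
  expect_equal(adjust_for_completeness(1234, 100), 1234)
  expect_equal(round_half_up(adjust_for_completeness(1900, 97)), 1959)
  expect_error(adjust_for_completeness(100, 0), "\\(0, 100\\]")
  expect_equal(adjust_for_completeness(3 * 7, 60), 3 * adjust_for_completeness(7, 60))
})

test_that("proteome novelty applies each arCOG filter row by row", {
  hits <- data.frame(
    query = c("p1", "p2", "p3"),
    pid = c(40, 90, 30),
    alen = c(100, 200, 200),
    evalue = c(1e-10, 1e-3, 1e-10),
    bitscore = c(150, 300, 300)
  )
  # p1 keeps its hit; p2 fails on e-value; p3 fails on %ID; p4 has no hits
  expect_equal(proteome_novelty(hits, 4), 75)
  expect_equal(proteome_novelty(hits[0, ], 100), 100)
  all_good <- data.frame(query = sprintf("p%d", 1:10), pid = 90, alen = 200,
                         evalue = 1e-10, bitscore = 300)
  expect_equal(proteome_novelty(all_good, 10), 0)
  expect_error(proteome_novelty(hits, 0), "positive")
  # relaxing any threshold never increases novelty
  strict <- proteome_novelty(hits, 4)
  expect_lte(proteome_novelty(hits, 4, min_pid = 25), strict)
  expect_lte(proteome_novelty(hits, 4, max_evalue = 1e-2), strict)
  expect_lte(proteome_novelty(hits, 4, min_bitscore = 50), strict)
})

test_that("marker selection is single-copy with inclusive occupancy", {
  m <- rbind(
    half   = c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
    dup    = c(2, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    allone = rep(1, 10),
    sparse = c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0)
  )
  got <- select_markers(m, 0.5)
  expect_setequal(got, c("half", "allone"))  # 5/10 occupancy is inclusive
  expect_setequal(select_markers(m, 0.2), c("half", "allone", "sparse"))
  expect_false("dup" %in% select_markers(m, 0.1))
})

test_that("family filtering removes short sequences before small families", {
  long <- strrep("M", 30)
  short <- strrep("M", 29)
  fams <- list(
    trio = rep(long, 3),
    edge = c(rep(long, 3), short),   # drops to 3 after the length filter
    keep = rep(long, 4)
  )
  out <- filter_families(fams)
  expect_equal(names(out), "keep")
  expect_equal(length(out$keep), 4L)
})

test_that("genome summaries report means, ranges and 16S recovery", {
  rec <- data.frame(completeness = c(60, 70, 80, 90),
                    contamination = c(1, 2, 3, 4),
                    size = c(1e6, 2e6, 3e6, 4e6),
                    cds = c(1000, 2000, 3000, 4000),
                    rrna_16s = c(1, 0, 2, 0))
  s <- summarize_genomes(rec)
  expect_equal(s$n, 4L)
  expect_equal(unname(s$stats$completeness), c(75, 60, 90))
  expect_equal(unname(s$stats$size), c(2.5e6, 1e6, 4e6))
  expect_equal(s$p16s_recovery, 50)

  single <- summarize_genomes(rec[2L, ])
  expect_equal(unname(single$stats$completeness), c(70, 70, 70))

  recovery <- summarize_genomes(data.frame(
    completeness = 78, contamination = 3,
    rrna_16s = c(rep(1, 15), rep(0, 22))
  ))
  expect_equal(recovery$p16s_recovery, 41)
})
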