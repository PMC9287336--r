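tree4 <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")  # N1,(N2:A,B),(N3:C,D)

test_that("a perfect vertical family needs one origination and nothing else", {
  r <- reconcile_parsimony(c(A = 1, B = 1), tree4)
  expect_equal(r$origination, "N2")
  expect_equal(r$cost, 0)
  expect_equal(sum(r$events[, c("duplication", "transfer", "loss")]), 0)
  expect_equal(unname(r$copies[c("N2", "A", "B")]), c(1, 1, 1))
  expect_equal(unname(r$copies[c("N1", "N3", "C", "D")]), c(0, 0, 0, 0))
})

test_that("loss beats origination-plus-transfer for a three-of-four profile", {
  r <- reconcile_parsimony(c(A = 1, B = 1, C = 1), tree4,
                           costs = dtl_costs(2, 3, 1))
  expect_equal(r$origination, "N1")
  expect_equal(r$cost, 1)
  expect_equal(unname(r$events["D", "loss"]), 1)
  expect_equal(sum(r$events[, "transfer"]), 0)
  # history consistency: presence tracks the event path
  pres <- ancestral_presence(r)
  expect_true(all(pres[c("N1", "N2", "A", "B", "N3", "C")]))
  expect_false(pres[["D"]])
})

test_that("degenerate profiles are rejected with informative errors", {
  expect_error(reconcile_parsimony(c(A = 0, B = 0), tree4), "all-zero")
  expect_error(reconcile_parsimony(c(A = 9), tree4, c_max = 8), "c_max")
  expect_error(reconcile_parsimony(c(Z = 1), tree4), "not in tree")
})

test_that("the DP equals exhaustive enumeration on every 4- and 5-tip profile", {
  expect_equal(count_dp_mismatches("((A:1,B:1):1,(C:1,D:1):1);"), 0L)
  expect_equal(count_dp_mismatches("(((A:1,B:1):1,C:1):1,(D:1,E:1):1);"), 0L)
})

test_that("prohibitive transfer cost yields transfer-free reconciliations", {
  set.seed(8)
  tr <- simulate_species_tree(8, 1, seed = 44)
  tips <- tip_labels(tr)
  for (rep in 1:25) {
    p <- stats::setNames(rbinom(length(tips), 2, 0.5), tips)
    if (all(p == 0)) next
    r <- reconcile_parsimony(p, tr, costs = dtl_costs(2, 999, 1))
    expect_equal(sum(r$events[, "transfer"]), 0)
  }
})

test_that("raising the loss cost never increases the inferred loss count", {
  set.seed(15)
  tr <- simulate_species_tree(7, 1, seed = 21)
  tips <- tip_labels(tr)
  for (rep in 1:20) {
    p <- stats::setNames(rbinom(length(tips), 1, 0.6), tips)
    if (all(p == 0)) next
    l1 <- sum(reconcile_parsimony(p, tr, dtl_costs(2, 3, 1))$events[, "loss"])
    l2 <- sum(reconcile_parsimony(p, tr, dtl_costs(2, 3, 2))$events[, "loss"])
    expect_lte(l2, l1)
  }
})

test_that("event counts account exactly for copy-number changes on each branch", {
  set.seed(6)
  tr <- simulate_species_tree(9, 1, seed = 61)
  tips <- tip_labels(tr)
  for (rep in 1:15) {
    p <- stats::setNames(rbinom(length(tips), 2, 0.5), tips)
    if (all(p == 0)) next
    r <- reconcile_parsimony(p, tr)
    orig_i <- match(r$origination, tree_labels(tr))
    for (v in seq_along(tr$parent)[-1L]) {
      a <- r$copies[tr$parent[v]] + as.integer(v == orig_i)
      gains <- r$events[v, "duplication"] + r$events[v, "transfer"]
      expect_equal(unname(r$copies[v]), unname(a + gains - r$events[v, "loss"]))
    }
  }
})

test_that("completeness lets absences be explained as unobserved copies", {
  # D absent, completeness 0.7 everywhere: -log2(0.7) ~ 0.51 < loss cost 1,
  # so the cheapest history keeps D's copy and calls it unobserved
  r <- reconcile_parsimony(c(A = 1, B = 1, C = 1), tree4, completeness = 0.7)
  expect_equal(r$origination, "N1")
  expect_equal(sum(r$events[, "loss"]), 0)
  expect_equal(unname(r$copies["D"]), 1)
  expect_equal(r$cost, -log2(0.7), tolerance = 1e-12)
  # with complete genomes the unobserved explanation is unavailable
  r2 <- reconcile_parsimony(c(A = 1, B = 1, C = 1), tree4, completeness = 1)
  expect_equal(unname(r2$events["D", "loss"]), 1)
})

test_that("ancestral presence thresholds behave at the boundary", {
  fam <- list(copies = c(X = 1.0, Y = 0.49, Z = 0.5))
  pres <- ancestral_presence(fam, 0.5)
  expect_true(pres[["X"]])
  expect_false(pres[["Y"]])
  expect_true(pres[["Z"]])
  expect_error(ancestral_presence(fam, 0), "\\(0, 1\\]")
})

test_that("reconciliation tables round-trip and fractional counts survive", {
  tr <- simulate_species_tree(6, 1, seed = 10)
  fams <- lapply(1:3, function(i) {
    p <- stats::setNames(rbinom(n_tips(tr), 1, 0.7), tip_labels(tr))
    p[1L] <- 1L
    reconcile_parsimony(p, tr, family_id = paste0("f", i))
  })
  path <- tempfile(fileext = ".tsv")
  write_rec_table(fams, path)
  back <- read_rec_table(path)
  expect_setequal(names(back), c("f1", "f2", "f3"))
  for (f in fams) {
    b <- back[[f$family]]
    expect_equal(b$events[rownames(f$events), colnames(f$events)],
                 f$events, ignore_attr = TRUE)
    expect_equal(unname(b$copies[names(f$copies)]), unname(f$copies))
  }

  # hand-built fixture with fractional posterior-mean counts
  frac <- tempfile(fileext = ".tsv")
  writeLines(c(
    "family\tbranch\tduplications\ttransfers\tlosses\toriginations\tcopies",
    "famA\tN1\t0\t0.25\t0\t0.75\t0.8",
    "famA\tX\t0.5\t0\t0.1\t0\t1.2",
    "famB\tN1\t0\t0\t0\t1\t1"
  ), frac)
  got <- read_rec_table(frac)
  expect_equal(unname(got$famA$events["N1", "transfer"]), 0.25)
  expect_equal(unname(got$famA$copies["X"]), 1.2)

  # missing mandatory column
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("family\tbranch\tduplications\ttransfers\toriginations\tcopies",
               "f\tN1\t0\t0\t1\t1"), bad)
  expect_error(read_rec_table(bad), "losses")

  # branch mapping: unmappable ids fail loudly
  map <- data.frame(branch_id = c("N1", "X"), tree_label = c("root", "nodeX"))
  got2 <- read_rec_table(frac, branch_map = rbind(map,
    data.frame(branch_id = "N1b", tree_label = "zz")))
  expect_true("root" %in% rownames(got2$famA$events))
  expect_error(read_rec_table(frac, branch_map = map[2L, , drop = FALSE]),
               "unmappable")
})
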