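# Robinson-Foulds distances: split enumeration against an independent
# oracle, metric behavior, normalization, and the evaluation harness.

test_that("bipartition counts follow tree shape", {
  t4 <- read_newick(text = "((a:1,b:1):1,c:1,d:1);")
  expect_length(bipartitions(t4), 1L)
  star <- read_newick(text = "(a:1,b:1,c:1,d:1,e:1);")
  expect_length(bipartitions(star), 0L)
  set.seed(41)
  for (n in 5:8) {
    tr <- random_phylogeny(n, c(1))
    expect_length(bipartitions(tr), n - 3L)
  }
})

test_that("splits and RF agree with the brute-force oracle", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(4:7, 1)
    t1 <- random_phylogeny(n, c(1, 2))
    t2 <- random_phylogeny(n, c(1, 2))
    b1 <- bipartitions(t1); o1 <- oracle_splits(t1)
    expect_setequal(b1, o1)
    # symmetric difference computed from the oracle's split sets
    o2 <- oracle_splits(t2)
    expect_equal(rf_distance(t1, t2),
                 length(setdiff(o1, o2)) + length(setdiff(o2, o1)))
    # cross-check against the independent phangorn implementation
    expect_equal(rf_distance(t1, t2), as.integer(phangorn::RF.dist(t1, t2)))
  }
})

test_that("RF is a metric on fully resolved trees", {
  expect_equal(rf_distance(read_newick(text = "((a:1,b:1):1,c:1,d:1);"),
                           read_newick(text = "((a:1,b:1):1,c:1,d:1);")), 0L)
  set.seed(43)
  for (i in 1:10) {
    n <- sample(5:7, 1)
    trees <- replicate(3, random_phylogeny(n, c(1)), simplify = FALSE)
    d12 <- rf_distance(trees[[1]], trees[[2]])
    d13 <- rf_distance(trees[[1]], trees[[3]])
    d23 <- rf_distance(trees[[2]], trees[[3]])
    expect_identical(d12, rf_distance(trees[[2]], trees[[1]]))
    expect_lte(d13, d12 + d23)
    expect_gte(d12, 0L)
  }
  expect_error(
    rf_distance(read_newick(text = "(a:1,b:1,c:1,d:1);"),
                read_newick(text = "(a:1,b:1,c:1,e:1);")),
    "leaf sets differ")
})

test_that("normalization divides by 2n - 6 and spans [0, 1]", {
  ta <- read_newick(text = "((a:1,b:1):1,c:1,d:1);")
  tb <- read_newick(text = "((a:1,c:1):1,b:1,d:1);")
  expect_equal(normalized_rf(ta, ta), 0)
  expect_equal(normalized_rf(ta, tb), 1)   # 2 / (2*4 - 6)
  # n = 5 trees sharing exactly one of their two splits each
  t5a <- read_newick(text = "(((a:1,b:1):1,c:1):1,d:1,e:1);")
  t5b <- read_newick(text = "(((a:1,b:1):1,d:1):1,c:1,e:1);")
  expect_equal(normalized_rf(t5a, t5b), 0.5)
  set.seed(44)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    v <- normalized_rf(random_phylogeny(n, c(1)), random_phylogeny(n, c(1)))
    expect_gte(v, 0); expect_lte(v, 1)
  }
  expect_warning(
    normalized_rf(read_newick(text = "(a:1,b:1,c:1);"),
                  read_newick(text = "(a:1,b:1,c:1);")),
    "vacuous")
})

test_that("evaluation prunes the extra leaf and sums per-group scores", {
  set.seed(45)
  truth <- list()
  fitlike_trees <- list()
  rows <- list()
  for (j in 1:3) {
    key <- sprintf("rep%d", j)
    members <- sprintf("g%d_%d", j, 1:6)
    # constructed tree carries the representative as an extra leaf; the
    # truth tree is its representative-free restriction (groups 1, 2) or
    # an unrelated topology (group 3)
    full <- random_phylogeny(7, c(0.1, 0.2), labels = c(members, key))
    truth[[key]] <- if (j < 3) ape::drop.tip(full, key)
                    else random_phylogeny(6, c(0.1), labels = members)
    fitlike_trees[[sprintf("L1_%s", key)]] <- full
    rows[[j]] <- list(level = 1L, group_id = sprintf("L1_%s", key),
                      representative = key, members = c(members, key),
                      status = "ok")
  }
  manifest <- data.frame(
    level = 1L, group_id = vapply(rows, `[[`, "", "group_id"),
    representative = vapply(rows, `[[`, "", "representative"),
    status = "ok", stringsAsFactors = FALSE)
  manifest$members <- I(lapply(rows, `[[`, "members"))
  fit <- structure(list(manifest = manifest, trees = fitlike_trees,
                        partitions = list()), class = "hpc")
  ev <- evaluate_hierarchy(truth, fit)
  expect_equal(unname(ev$per_group[c("rep1", "rep2")]), c(0, 0))
  expect_gt(ev$per_group[["rep3"]], 0)
  expect_equal(ev$total, sum(ev$per_group))
  expect_true(all(ev$n_leaves == 6L))
})
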