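# Per-group construction: alpha defaults, identity-column trimming, column
# subsampling, the branch-ratio check, and the adaptive doubling loop.

test_that("initial alpha follows the group-size schedule", {
  expect_equal(initial_alpha(36), 5000L)
  expect_equal(initial_alpha(40), 5000L)
  expect_equal(initial_alpha(41), 15000L)
  expect_equal(initial_alpha(51), 15000L)
  expect_equal(initial_alpha(60), 15000L)
  expect_equal(initial_alpha(61), 25000L)
})

test_that("identity columns are capped at beta * d_S, variable kept", {
  # 2 variable (positions 1 and 13) + 11 identity columns
  aln2 <- toy_aln(a = "ACCCCCGGGGGAT", b = "TCCCCCGGGGGAA")
  expect_equal(n_variable_columns(aln2), 2L)
  expect_identical(trim_identity_columns(aln2, "unlimited"), aln2)
  t0 <- trim_identity_columns(aln2, 0)
  expect_equal(ncol(t0), 2L)
  expect_equal(alignment_matrix(t0)[, 1], c(a = "A", b = "T"))
  # ceiling(1.5 * 2) = 3 identity columns kept, earliest positions first
  t15 <- trim_identity_columns(aln2, 1.5)
  expect_equal(ncol(t15), 5L)
  expect_equal(unname(alignment_matrix(t15)["a", ]), c("A", "C", "C", "C", "T"))

  # a variable column is never removed, at any beta
  set.seed(21)
  sim <- evolve_alignment(random_phylogeny(5, c(0.05, 0.2)), 300)
  for (beta in c(0, 0.5, 2)) {
    tr <- trim_identity_columns(sim, beta)
    expect_equal(n_variable_columns(tr), n_variable_columns(sim))
  }
  # all-identical rows with beta = 0 retain one column
  expect_equal(ncol(trim_identity_columns(toy_aln(a = "AAAA", b = "AAAA"), 0)),
               1L)
})

test_that("column sampling is uniform-without-replacement and seeded", {
  # columns with unique 3-row signatures so sampled positions are traceable
  bases <- c("A", "C", "G", "T")
  combos <- expand.grid(r1 = bases, r2 = bases, r3 = bases,
                        stringsAsFactors = FALSE)
  set.seed(22)
  pick <- combos[sample(64, 40), ]
  aln <- toy_aln(r1 = paste(pick$r1, collapse = ""),
                 r2 = paste(pick$r2, collapse = ""),
                 r3 = paste(pick$r3, collapse = ""))
  expect_identical(sample_columns(aln, 40), aln)
  expect_identical(sample_columns(aln, 100), aln)
  s1 <- sample_columns(aln, 39, seed = 7)
  expect_equal(ncol(s1), 39L)
  expect_identical(unclass(sample_columns(aln, 39, seed = 7)), unclass(s1))

  s2 <- sample_columns(aln, 10, seed = 8)
  sig_full <- apply(alignment_matrix(aln), 2, paste, collapse = "")
  sig_sub <- apply(alignment_matrix(s2), 2, paste, collapse = "")
  idx <- match(sig_sub, sig_full)
  expect_false(anyNA(idx))
  expect_equal(anyDuplicated(idx), 0L)     # without replacement
  expect_true(all(diff(idx) > 0))          # ascending positional order
})

test_that("offending branches are counted with the epsilon guard", {
  t_eq <- read_newick(text = "(a:1,b:1,(c:1,d:1):1);")
  expect_equal(offending_branch_count(t_eq, 100), 0L)
  t_mix <- read_newick(text = "(a:1,b:0.001,c:1);")
  expect_equal(offending_branch_count(t_mix, 100), 1L)
  expect_equal(offending_branch_count(t_mix, 1001), 0L)
  t_zero <- read_newick(text = "(a:1,b:0,c:1);")
  expect_equal(offending_branch_count(t_zero, 100, epsilon = 1e-9), 1L)
})

test_that("adaptive loop terminates, tracks rounds, and keeps leaf sets", {
  set.seed(23)
  tr <- random_phylogeny(8, c(0.05, 0.1, 0.2))
  aln <- evolve_alignment(tr, 900)

  # alpha covering the whole alignment: single round
  rep1 <- adaptive_construct(aln, alpha = 2000, seed = 1)
  expect_equal(rep1$rounds, 1L)
  expect_setequal(rep1$tree$tip.label, rownames(aln))

  # small alpha: doubling happens, rounds bounded, counts recorded
  rep2 <- adaptive_construct(aln, alpha = 16, seed = 2, delta = 20,
                             max_doublings = 10)
  expect_lte(rep2$rounds, 11L)
  expect_length(rep2$offending_branches_per_round, rep2$rounds)
  expect_lte(rep2$alpha_used, rep2$columns_available)
  # accepted round achieves the minimum offending count
  expect_equal(min(rep2$offending_branches_per_round),
               offending_branch_count(rep2$tree, 20))

  # beta = 0 with alpha >= d_S: engine sees exactly the variable columns
  dS <- n_variable_columns(aln)
  rep3 <- adaptive_construct(aln, alpha = 1e6, beta = 0, seed = 3)
  expect_equal(rep3$columns_available, dS)
  expect_equal(rep3$alpha_used, dS)
})

test_that("a short internal edge resolves as alpha grows", {
  # alignment long enough that the full data resolve the short edge
  set.seed(24)
  base <- read_newick(text =
    "((a:0.05,b:0.05):0.004,(c:0.05,d:0.05):0.004,e:0.05);")
  aln <- evolve_alignment(base, 20000)
  full <- run_engine(engine_spec("builtin_nj"), aln)
  expect_equal(rf_distance(full, base), 0L)   # resolvable at full length
  rep <- adaptive_construct(aln, alpha = 100, seed = 4, delta = 1e6,
                            max_doublings = 12)
  offs <- rep$offending_branches_per_round
  expect_equal(offs[length(offs)], 0L)
  expect_true(all(diff(offs) < 0))            # strictly decreasing to 0
  expect_equal(rf_distance(rep$tree, base), 0L)
})
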