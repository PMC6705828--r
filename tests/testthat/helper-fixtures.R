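# Shared fixtures and independent oracles. Everything is generated in code;
# no data files.

# Small named alignment from sequence strings.
toy_aln <- function(...) as_alignment(c(...))

# Random additive distance matrix: path lengths on a random binary tree.
random_additive_matrix <- function(n, seed = NULL) {
  tr <- random_phylogeny(n, c(0.13, 0.29, 0.41, 0.57, 0.73), seed = seed)
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

# Independent split-enumeration oracle. A side A (containing the
# lexicographically smallest leaf) is a split of the tree iff every quartet
# (a1, a2 | b1, b2) straddling A is resolved that way under topological
# (unit-branch) path lengths: D(a1,a2) + D(b1,b2) strictly smaller than both
# cross pairings. Exhaustive over all subsets; practical up to ~8 leaves.
oracle_splits <- function(tree) {
  tips <- sort(tree$tip.label)
  n <- length(tips)
  if (n < 4L) return(character(0))
  t1 <- ape::unroot(tree)
  t1$edge.length <- rep(1, nrow(t1$edge))
  D <- ape::cophenetic.phylo(t1)[tips, tips]
  rest <- tips[-1L]
  out <- character(0)
  for (mask in seq_len(2^(n - 1L) - 1L)) {
    inside <- as.logical(intToBits(mask)[seq_len(n - 1L)])
    A <- c(tips[1L], rest[inside])
    if (length(A) < 2L || length(A) > n - 2L) next
    B <- setdiff(tips, A)
    ok <- TRUE
    for (a1 in seq_along(A)) for (a2 in seq_len(a1 - 1L))
      for (b1 in seq_along(B)) for (b2 in seq_len(b1 - 1L)) {
        s0 <- D[A[a1], A[a2]] + D[B[b1], B[b2]]
        s1 <- D[A[a1], B[b1]] + D[A[a2], B[b2]]
        s2 <- D[A[a1], B[b2]] + D[A[a2], B[b1]]
        if (!(s0 < s1 && s0 < s2)) { ok <- FALSE; break }
      }
    if (ok) out <- c(out, paste(A, collapse = "|"))
  }
  out
}

# Alignment with k planted clusters: large between-cluster divergence,
# `within_mism` mismatches within clusters, plus optional spread-out
# singleton isolates. Used for partition recovery.
make_clustered_alignment <- function(k = 3, per = 4, L = 4000,
                                     within_mism = 1, seed = 1,
                                     singletons = 0) {
  bases <- c("A", "C", "G", "T")
  mutate_at <- function(row, idx) {
    row[idx] <- vapply(row[idx],
                       function(x) sample(setdiff(bases, x), 1L), "")
    row
  }
  set.seed(seed)
  base <- sample(bases, L, replace = TRUE)
  rows <- character(0)
  for (i in seq_len(k)) {
    cbase <- mutate_at(base, sample.int(L, round(0.2 * L)))
    for (j in seq_len(per)) {
      r <- cbase
      if (j > 1L) r <- mutate_at(r, sample.int(L, within_mism))
      rows[sprintf("c%d_%d", i, j)] <- paste(r, collapse = "")
    }
  }
  for (s in seq_len(singletons)) {
    r <- mutate_at(base, sample.int(L, round(0.2 * L)))
    rows[sprintf("m%d", s)] <- paste(r, collapse = "")
  }
  as_alignment(rows)
}

# Signal-rich benchmark configuration: same construction as the standard
# Narrow bundle but with subgroup branch lengths and simulated column
# counts chosen so each subgroup branch carries several expected
# substitutions while the moderate/subgroup similarity contrast stays
# above 100. Used to validate topology recovery of the whole pipeline.
signal_rich_bundle <- function(seed) {
  simulate_dataset("narrow", columns = 4e4, seed = seed,
                   subgroup_menu = c(0.002, 0.004, 0.008),
                   min_subgroup_columns = 2000)
}
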