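# Benchmark dataset generator: random true phylogenies with discrete
# branch-length menus, GTR sequence evolution, identity-column padding of
# the subgroup alignments, and adjustment of identity columns to the
# representative isolate's letters.

#' GTR substitution model parameters
#'
#' Exchangeabilities in the order AC, AG, AT, CG, CT, GT and stationary
#' base frequencies in the order A, C, G, T. The default (all
#' exchangeabilities 1, equal frequencies) is the JC69 special case. The
#' rate matrix is scaled by the simulator so branch lengths are expected
#' substitutions per site at stationarity.
#'
#' @param rates six non-negative exchangeabilities.
#' @param freq four base frequencies summing to 1.
#' @return list with `rates` and `freq`.
#' @export
gtr_params <- function(rates = rep(1, 6), freq = rep(0.25, 4)) {
  stopifnot(length(rates) == 6, all(rates >= 0),
            length(freq) == 4, all(freq > 0))
  if (abs(sum(freq) - 1) > 1e-12)
    .stop_fmt("base frequencies must sum to 1 (got %.15g)", sum(freq))
  list(rates = as.numeric(rates), freq = as.numeric(freq))
}

#' Branch-length menus for the benchmark datasets
#'
#' The moderate menu is the arithmetic sequence 0.05, 0.10, ..., 0.95
#' substitutions per site (19 values); it is used for the group of
#' moderately similar isolates in both dataset types and for the subgroups
#' of the Wide type. The narrow subgroup menu holds the nine values
#' 1e-4 down to 1e-6 used for subgroups of the Narrow type.
#'
#' @name branch_menus
#' @export
moderate_branch_menu <- function() seq(0.05, 0.95, by = 0.05)

#' @rdname branch_menus
#' @export
narrow_subgroup_menu <- function()
  c(1e-4, 9e-5, 7e-5, 5e-5, 3e-5, 1e-5, 5e-6, 3e-6, 1e-6)

# Pre-padding alignment length for each subgroup size, at the reference
# alignment length of one million columns.
.SUBGROUP_COLUMNS <- c(`10` = 2500, `15` = 3500, `20` = 5000,
                       `25` = 6500, `30` = 8000, `35` = 9500)

#' Random unrooted binary phylogeny with menu branch lengths
#'
#' The topology is drawn uniformly over unrooted binary topologies by
#' sequential attachment: starting from the 3-leaf star, each further leaf
#' is attached to an edge chosen uniformly at random. Every branch length
#' is drawn uniformly (with replacement) from `branch_menu`.
#'
#' @param n leaf count, `>= 2`.
#' @param branch_menu positive branch-length values to draw from.
#' @param labels optional tip labels (default `t1 ... tn`).
#' @param seed optional seed.
#' @return a `phylo`.
#' @export
random_phylogeny <- function(n, branch_menu, labels = NULL, seed = NULL) {
  stopifnot(n >= 2, length(branch_menu) >= 1, all(branch_menu > 0))
  labels <- labels %||% paste0("t", seq_len(n))
  stopifnot(length(labels) == n)
  with_seed(seed, {
    if (n == 2L) {
      len <- sample(branch_menu, 2L, replace = TRUE)
      return(ape::read.tree(text = sprintf("(%s:%.12g,%s:%.12g);",
                                           labels[1L], len[1L],
                                           labels[2L], len[2L])))
    }
    parent <- rep(n + 1L, 3L)
    child <- 1:3
    next_int <- n + 2L
    if (n > 3L) for (k in 4:n) {
      e <- sample.int(length(parent), 1L)
      m <- next_int; next_int <- next_int + 1L
      old_child <- child[e]
      child[e] <- m
      parent <- c(parent, m, m)
      child <- c(child, old_child, k)
    }
    tr <- structure(list(edge = cbind(parent, child, deparse.level = 0),
                         edge.length = sample(branch_menu, length(parent),
                                              replace = TRUE),
                         tip.label = labels, Nnode = n - 2L),
                    class = "phylo")
    ape::reorder.phylo(tr, "cladewise")
  })
}

#' Simulate sequence evolution along a phylogeny
#'
#' Generates an ungapped nucleotide alignment by evolving a root sequence
#' (drawn from the stationary base frequencies) along the tree under the
#' GTR model, with branch lengths interpreted as expected substitutions
#' per site. The per-site evolution is delegated to
#' [phangorn::simSeq()], which applies the standard rate normalization.
#'
#' @param tree a `phylo` with branch lengths.
#' @param L number of columns.
#' @param gtr a [gtr_params()] list.
#' @param seed optional seed.
#' @return a `DNAbin` alignment with one row per tip, in tip-label order.
#' @export
evolve_alignment <- function(tree, L, gtr = gtr_params(), seed = NULL) {
  stopifnot(inherits(tree, "phylo"), L >= 1)
  with_seed(seed, {
    s <- phangorn::simSeq(tree, l = as.integer(L), Q = gtr$rates,
                          bf = gtr$freq, type = "DNA")
    x <- as.matrix(ape::as.DNAbin(s))
    as_alignment(x[tree$tip.label, , drop = FALSE])
  })
}

#' Pad a subgroup alignment with identity columns and adjust to the
#' representative
#'
#' The subgroup's simulated columns are placed at a seeded random set of
#' positions within the target length; every other position is an identity
#' column filled with the representative isolate's letter. Simulated
#' columns that happen to be invariant are likewise overwritten with the
#' representative's letter, so after padding the subgroup rows differ from
#' the representative row only at the variable simulated columns.
#'
#' @param sub_aln the condensed subgroup alignment.
#' @param representative_row the representative's full-length row (raw
#'   `DNAbin` vector, a 1-row alignment, or a character string).
#' @param target_L full alignment length, `>=` the condensed length.
#' @param seed optional seed for the placement draw.
#' @return a `DNAbin` alignment of width `target_L`; the chosen positions
#'   of the simulated columns are attached as attribute
#'   `"simulated_positions"`.
#' @export
pad_and_adjust <- function(sub_aln, representative_row, target_L,
                           seed = NULL) {
  sub_aln <- as_alignment(sub_aln)
  rep_row <- .as_row(representative_row)
  target_L <- as.integer(target_L)
  cL <- ncol(sub_aln)
  if (cL > target_L)
    .stop_fmt("condensed alignment (%d columns) exceeds target length %d",
              cL, target_L)
  if (length(rep_row) != target_L)
    .stop_fmt("representative row has length %d, target is %d",
              length(rep_row), target_L)
  n <- nrow(sub_aln)
  positions <- with_seed(seed, sort(sample.int(target_L, cL)))
  out <- matrix(rep_row, nrow = n, ncol = target_L, byrow = TRUE)
  var <- variable_columns(sub_aln)
  if (length(var))
    out[, positions[var]] <- unclass(sub_aln)[, var]
  rownames(out) <- rownames(sub_aln)
  out <- structure(out, class = "DNAbin")
  attr(out, "simulated_positions") <- positions
  out
}

#' Generate a Narrow or Wide benchmark dataset
#'
#' Builds a random true phylogeny for the moderately similar group and
#' evolves its alignment over the full length; then, for each planned
#' subgroup, builds a true subgroup phylogeny (Narrow menu or, for Wide
#' datasets, the moderate menu), evolves a condensed alignment at the
#' size-mapped pre-padding column count, draws a distinct representative
#' from the moderate group, and pads/adjusts the subgroup rows to full
#' length against the representative's row. At the reference length of
#' one million columns the pre-padding counts are 2500, 3500, 5000, 6500,
#' 8000 and 9500 columns for subgroup sizes 10 through 35; at reduced
#' lengths they scale proportionally with a floor of
#' `min_subgroup_columns`. The generated bundle is checked for the
#' similarity-contrast guarantee (moderate percent differences at least
#' `contrast_min` times every within-subgroup percent difference); if the
#' check fails, the subgroup alignments are regenerated with half as many
#' simulated columns (more padding), up to `max_retries` times.
#'
#' @param type `"narrow"` or `"wide"`.
#' @param columns full alignment length (reference value 1e6).
#' @param seed master seed for the whole dataset.
#' @param n_moderate size of the moderately similar group.
#' @param subgroup_sizes integer vector, one entry per subgroup; defaults
#'   to 12 subgroups of 10 plus 12 of 15 (Narrow) or 4 subgroups of each
#'   size 10, 15, 20, 25, 30, 35 (Wide). Sizes must appear in the
#'   size-to-columns map.
#' @param gtr a [gtr_params()] list.
#' @param moderate_menu,subgroup_menu branch-length menus (defaults per
#'   dataset type).
#' @param contrast_min required moderate/within-subgroup percent-difference
#'   ratio.
#' @param max_retries padding retries before giving up on the contrast.
#' @param min_subgroup_columns floor for the scaled pre-padding counts.
#' @return an object of class `hpc_dataset`: list with `alignment` (all
#'   isolates), `truth_moderate` (`phylo`), `truth_subgroups` (named list
#'   of `phylo` keyed by representative; leaf sets are the subgroup
#'   members), `membership` (named vector isolate -> representative or
#'   `"H"`), and `config`.
#' @export
simulate_dataset <- function(type = c("narrow", "wide"), columns = 1e6,
                             seed = NULL, n_moderate = 50L,
                             subgroup_sizes = NULL, gtr = gtr_params(),
                             moderate_menu = NULL, subgroup_menu = NULL,
                             contrast_min = 100, max_retries = 5L,
                             min_subgroup_columns = 50L) {
  type <- match.arg(type)
  L <- as.integer(columns)
  stopifnot(L >= 10L, n_moderate >= 2L)
  moderate_menu <- moderate_menu %||% moderate_branch_menu()
  subgroup_menu <- subgroup_menu %||%
    (if (type == "narrow") narrow_subgroup_menu() else moderate_branch_menu())
  subgroup_sizes <- subgroup_sizes %||%
    (if (type == "narrow") rep(c(10L, 15L), each = 12L)
     else rep(c(10L, 15L, 20L, 25L, 30L, 35L), times = 4L))
  bad <- setdiff(as.character(subgroup_sizes), names(.SUBGROUP_COLUMNS))
  if (length(bad))
    .stop_fmt("no pre-padding column count is defined for subgroup size(s) %s",
              paste(unique(bad), collapse = ", "))
  if (length(subgroup_sizes) > n_moderate)
    .stop_fmt("more subgroups (%d) than potential representatives (%d)",
              length(subgroup_sizes), n_moderate)

  with_seed(seed, {
    mod_labels <- sprintf("t%02d", seq_len(n_moderate))
    truth_moderate <- random_phylogeny(n_moderate, moderate_menu,
                                       labels = mod_labels)
    mod_aln <- evolve_alignment(truth_moderate, L, gtr)

    # Representatives drawn without replacement from the moderate group.
    reps <- sample(mod_labels, length(subgroup_sizes))

    truth_subgroups <- list()
    c_base <- pmin(L, pmax(min_subgroup_columns,
                           round(.SUBGROUP_COLUMNS[as.character(subgroup_sizes)] *
                                 L / 1e6)))
    for (j in seq_along(subgroup_sizes)) {
      labels <- sprintf("s%02d_%02d", j, seq_len(subgroup_sizes[j]))
      truth_subgroups[[reps[j]]] <- random_phylogeny(subgroup_sizes[j],
                                                     subgroup_menu,
                                                     labels = labels)
    }

    gen_subgroups <- function(c_use) {
      blocks <- vector("list", length(subgroup_sizes))
      for (j in seq_along(subgroup_sizes)) {
        tt <- truth_subgroups[[reps[j]]]
        cond <- evolve_alignment(tt, c_use[j], gtr)
        blocks[[j]] <- pad_and_adjust(cond, unclass(mod_aln)[reps[j], ], L)
      }
      blocks
    }

    c_use <- as.numeric(c_base)
    blocks <- gen_subgroups(c_use)
    min_mod_p <- .min_offdiag_p(mod_aln)
    for (try in seq_len(max_retries + 1L)) {
      max_sub_p <- max(vapply(blocks, .max_offdiag_p, numeric(1)))
      ratio <- if (max_sub_p == 0) Inf else min_mod_p / max_sub_p
      if (ratio >= contrast_min) break
      if (try > max_retries)
        .stop_fmt(paste0("similarity contrast %.3g below required %.3g after %d ",
                         "padding retries; increase the alignment length"),
                  ratio, contrast_min, max_retries)
      c_use <- pmax(4, floor(c_use / 2))
      blocks <- gen_subgroups(c_use)
    }

    aln <- do.call(rbind, c(list(mod_aln), blocks))
    membership <- c(stats::setNames(rep("H", n_moderate), mod_labels),
                    stats::setNames(
                      rep(reps, times = subgroup_sizes),
                      unlist(lapply(truth_subgroups[reps], function(t) t$tip.label),
                             use.names = FALSE)))
    structure(
      list(alignment = as_alignment(aln), truth_moderate = truth_moderate,
           truth_subgroups = truth_subgroups, membership = membership,
           config = list(type = type, columns = L, seed = seed,
                         n_moderate = n_moderate,
                         subgroup_sizes = as.integer(subgroup_sizes),
                         representatives = reps,
                         subgroup_columns = as.integer(c_use),
                         moderate_menu = moderate_menu,
                         subgroup_menu = subgroup_menu, gtr = gtr,
                         contrast_min = contrast_min)),
      class = "hpc_dataset")
  })
}

# Smallest off-diagonal percent difference within an alignment block.
.min_offdiag_p <- function(x) {
  P <- as.matrix(ape::dist.dna(x, model = "raw", pairwise.deletion = TRUE))
  min(P[upper.tri(P)])
}

.max_offdiag_p <- function(x) {
  P <- as.matrix(ape::dist.dna(x, model = "raw", pairwise.deletion = TRUE))
  max(P[upper.tri(P)], 0)
}

#' @export
print.hpc_dataset <- function(x, ...) {
  cfg <- x$config
  cat("Simulated ", cfg$type, " dataset: ", nrow(x$alignment), " isolates x ",
      ncol(x$alignment), " columns\n", sep = "")
  cat("  moderate group: ", cfg$n_moderate, "; subgroups: ",
      length(cfg$subgroup_sizes), " (sizes ",
      paste(sort(unique(cfg$subgroup_sizes)), collapse = ", "), ")\n", sep = "")
  cat("  pre-padding subgroup columns: ",
      paste(sort(unique(cfg$subgroup_columns)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Similarity contrast of a generated dataset
#'
#' The minimum percent difference over all pairs of moderately similar
#' isolates divided by the maximum percent difference over all pairs
#' within any subgroup. Generated bundles are constructed to keep this
#' ratio at or above the configured contrast (default 100).
#'
#' @param bundle an `hpc_dataset`.
#' @return list with `min_moderate_p`, `max_subgroup_p`, `ratio`.
#' @export
similarity_contrast <- function(bundle) {
  stopifnot(inherits(bundle, "hpc_dataset"))
  aln <- bundle$alignment
  moderates <- names(bundle$membership)[bundle$membership == "H"]
  min_mod <- .min_offdiag_p(form_subalignment(aln, moderates))
  max_sub <- 0
  for (r in names(bundle$truth_subgroups)) {
    members <- bundle$truth_subgroups[[r]]$tip.label
    max_sub <- max(max_sub, .max_offdiag_p(form_subalignment(aln, members)))
  }
  list(min_moderate_p = min_mod, max_subgroup_p = max_sub,
       ratio = if (max_sub == 0) Inf else min_mod / max_sub)
}

#' Write a simulated dataset to a directory
#'
#' Emits `alignment.fasta`, `truth/moderate.nwk`, one `truth/<rep>.nwk`
#' per subgroup, `membership.tsv` (isolate, representative-or-H) and
#' `simconfig.tsv` (key/value pairs).
#'
#' @param bundle an `hpc_dataset`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(bundle, dir) {
  stopifnot(inherits(bundle, "hpc_dataset"))
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  write_alignment(bundle$alignment, file.path(dir, "alignment.fasta"), "fasta")
  write_newick(bundle$truth_moderate, file.path(dir, "truth", "moderate.nwk"))
  for (r in names(bundle$truth_subgroups))
    write_newick(bundle$truth_subgroups[[r]],
                 file.path(dir, "truth", paste0(r, ".nwk")))
  utils::write.table(
    data.frame(isolate = names(bundle$membership),
               representative = unname(bundle$membership)),
    file.path(dir, "membership.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  cfg <- bundle$config
  keys <- c("type", "columns", "seed", "n_moderate", "contrast_min")
  vals <- vapply(keys, function(k) paste(format(cfg[[k]] %||% "NULL"),
                                         collapse = ","), character(1))
  extra <- c(subgroup_sizes = paste(cfg$subgroup_sizes, collapse = ","),
             subgroup_columns = paste(cfg$subgroup_columns, collapse = ","),
             representatives = paste(cfg$representatives, collapse = ","))
  utils::write.table(
    data.frame(key = c(keys, names(extra)), value = c(vals, unname(extra))),
    file.path(dir, "simconfig.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
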