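# The recursive driver: partition the isolates, build the group tree,
# recurse into each non-empty subgroup together with its representative.

#' Row-subset an alignment to a group of isolates
#'
#' @param x an alignment.
#' @param members character vector of isolate names, a subset of the
#'   alignment's row names; order is preserved in the result.
#' @return the sub-alignment (column count unchanged).
#' @export
form_subalignment <- function(x, members) {
  x <- as_alignment(x)
  unknown <- setdiff(members, rownames(x))
  if (length(unknown))
    .stop_fmt("unknown isolate(s): %s", paste(unknown, collapse = ", "))
  x[members, , drop = FALSE]
}

#' Hierarchical phylogeny construction
#'
#' The main driver. At each level the isolates are partitioned into a
#' group H of moderately similar isolates and subgroups of highly similar
#' isolates (one per representative in H); a tree is built for H from a
#' column-subsampled alignment with the adaptive doubling loop; and the
#' procedure recurses into every non-empty subgroup, with the
#' representative added to the subgroup's sub-alignment. The identity
#' column cap beta is unlimited at the top level and 0 at deeper levels,
#' so subgroup trees are built from variable columns only. Groups with
#' fewer than 4 members get degenerate trees (a star for 3 taxa, a single
#' edge for 2) directly from pairwise distances. At the deepest permitted
#' level no further partitioning is attempted and the group tree covers
#' all of the group's members.
#'
#' @param x an alignment (or a file read with [read_alignment()]).
#' @param engine an [engine_spec()]; default is the built-in
#'   neighbor-joining engine.
#' @param delta distance ratio cutoff (default 100; 50 is the conservative
#'   option for when the anchor estimate may sit near half the true
#'   maximum distance).
#' @param alpha initial column sample size, or `"auto"` for the
#'   size-dependent default of [initial_alpha()].
#' @param mode distance mode used by the partition step
#'   (`"p_distance"` or `"jc_ml"`).
#' @param seed master seed; every stochastic step (anchor draw, pass
#'   order, column samples) consumes the single stream this seed starts.
#' @param max_levels maximum number of tree levels (level 0 is the top).
#' @param max_doublings per-group cap on alpha doublings.
#' @param workdir scratch directory for external engine runs.
#' @return an object of class `hpc`: list with `manifest` (one row per
#'   group: level, group_id, representative, members, children, audit
#'   counters), `trees` (named list of `phylo` by group id), `partitions`
#'   (named list of [partition_isolates()] results by group id), plus the
#'   call parameters.
#' @seealso [representative_naming()], [write_hpc()],
#'   [evaluate_hierarchy()]
#' @export
hpc <- function(x, engine = engine_spec("builtin_nj"), delta = 100,
                alpha = "auto", mode = c("p_distance", "jc_ml"),
                seed = NULL, max_levels = 5L, max_doublings = 10L,
                workdir = tempfile("hpc")) {
  mode <- match.arg(mode)
  x <- as_alignment(x)
  if (nrow(x) < 2L) .stop_fmt("need at least 2 isolates")
  stopifnot(max_levels >= 1L)

  state <- new.env(parent = emptyenv())
  state$rows <- list()
  state$trees <- list()
  state$partitions <- list()

  record <- function(level, group_id, representative, members, children,
                     tree = NULL, report = NULL, status = "ok") {
    state$rows[[length(state$rows) + 1L]] <- list(
      level = level, group_id = group_id,
      representative = representative %||% NA_character_,
      n_members = length(members), members = members, children = children,
      alpha_used = if (!is.null(report)) report$alpha_used else NA_integer_,
      rounds = if (!is.null(report)) report$rounds else NA_integer_,
      offending = if (!is.null(report))
        paste(report$offending_branches_per_round, collapse = ",") else "",
      status = status)
    if (!is.null(tree)) state$trees[[group_id]] <- tree
  }

  trivial_tree <- function(aln) {
    D <- pairwise_distances(aln, mode = "jc_ml", clamp = TRUE)
    nj_tree(D)
  }

  build <- function(aln, level, group_id, representative) {
    n <- nrow(aln)
    beta <- if (level == 0L) "unlimited" else 0
    members <- rownames(aln)
    if (n < 4L) {
      record(level, group_id, representative, members, character(0),
             tree = trivial_tree(aln))
      return(invisible())
    }
    if (level >= max_levels - 1L) {
      rep_ <- adaptive_construct(aln, engine, delta = delta, alpha = alpha,
                                 beta = beta, max_doublings = max_doublings,
                                 workdir = file.path(workdir, group_id))
      record(level, group_id, representative, members, character(0),
             tree = rep_$tree, report = rep_)
      return(invisible())
    }
    part <- partition_isolates(aln, delta = delta, mode = mode)
    state$partitions[[group_id]] <- part
    nonempty <- names(part$subgroups)[lengths(part$subgroups) > 0L]
    if (level >= 1L && length(nonempty))
      message(sprintf(
        "note: level-%d group '%s' still contains highly similar isolates; recursing with unchanged delta = %g",
        level, group_id, delta))
    H_aln <- form_subalignment(aln, part$group_H)
    rep_ <- adaptive_construct(H_aln, engine, delta = delta, alpha = alpha,
                               beta = beta, max_doublings = max_doublings,
                               workdir = file.path(workdir, group_id))
    child_ids <- sprintf("L%d_%s", level + 1L, nonempty)
    record(level, group_id, representative, part$group_H, child_ids,
           tree = rep_$tree, report = rep_)
    for (r in nonempty) {
      cid <- sprintf("L%d_%s", level + 1L, r)
      sub_aln <- form_subalignment(aln, c(part$subgroups[[r]], r))
      tryCatch(build(sub_aln, level + 1L, cid, r),
               error = function(e)
                 record(level + 1L, cid, r, rownames(sub_aln), character(0),
                        status = paste0("failed: ", conditionMessage(e))))
    }
    invisible()
  }

  with_seed(seed, build(x, 0L, "L0_H", NULL))

  rows <- state$rows
  manifest <- data.frame(
    level = vapply(rows, `[[`, integer(1), "level"),
    group_id = vapply(rows, `[[`, character(1), "group_id"),
    representative = vapply(rows, `[[`, character(1), "representative"),
    n_members = vapply(rows, `[[`, integer(1), "n_members"),
    alpha_used = vapply(rows, `[[`, integer(1), "alpha_used"),
    rounds = vapply(rows, `[[`, integer(1), "rounds"),
    offending = vapply(rows, `[[`, character(1), "offending"),
    status = vapply(rows, `[[`, character(1), "status"),
    stringsAsFactors = FALSE)
  manifest$members <- I(lapply(rows, `[[`, "members"))
  manifest$children <- I(lapply(rows, `[[`, "children"))

  structure(
    list(manifest = manifest, trees = state$trees,
         partitions = state$partitions, delta = delta, mode = mode,
         engine = engine$name, alpha = alpha, seed = seed,
         max_levels = max_levels, call = match.call()),
    class = "hpc")
}

#' @export
print.hpc <- function(x, ...) {
  cat("Hierarchical phylogeny (engine '", x$engine, "', delta = ",
      format(x$delta), ")\n", sep = "")
  lv <- sort(unique(x$manifest$level))
  for (l in lv) {
    sel <- x$manifest$level == l
    cat("  level ", l, ": ", sum(sel), " tree(s), ",
        sum(x$manifest$n_members[sel]), " leaves total\n", sep = "")
  }
  failed <- x$manifest$status != "ok"
  if (any(failed))
    cat("  failed groups:", paste(x$manifest$group_id[failed], collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
summary.hpc <- function(object, ...) {
  m <- object$manifest
  structure(list(manifest = m[, c("level", "group_id", "representative",
                                  "n_members", "alpha_used", "rounds",
                                  "offending", "status")],
                 engine = object$engine, delta = object$delta),
            class = "summary.hpc")
}

#' @export
print.summary.hpc <- function(x, ...) {
  cat("Hierarchical phylogeny; engine '", x$engine, "', delta = ",
      format(x$delta), "\n\n", sep = "")
  print(x$manifest, row.names = FALSE)
  invisible(x)
}

#' Plot one tree from a hierarchical result
#'
#' @param x an `hpc` object.
#' @param group_id which tree to draw (default the top-level tree).
#' @param relabel apply the Group/Taxon display names of
#'   [representative_naming()] when drawing the top-level tree.
#' @param ... passed to [ape::plot.phylo()].
#' @export
plot.hpc <- function(x, group_id = "L0_H", relabel = TRUE, ...) {
  tr <- x$trees[[group_id]]
  if (is.null(tr)) .stop_fmt("no tree for group '%s'", group_id)
  if (relabel && identical(group_id, "L0_H"))
    tr <- representative_naming(x)$tree
  ape::plot.phylo(tr, ...)
  invisible(x)
}

#' Display names for the top-level tree
#'
#' Leaves of the top-level tree that represent non-empty subgroups are
#' renamed `Group1, Group2, ...`, the remaining leaves `Taxon1, ...`, in
#' the order they appear in group H. The mapping back to the original
#' isolate names is returned alongside the relabeled tree.
#'
#' @param fit an `hpc` object.
#' @return list with `tree` (relabeled `phylo`) and `map` (data frame
#'   `original` / `display`).
#' @export
representative_naming <- function(fit) {
  stopifnot(inherits(fit, "hpc"))
  tr <- fit$trees[["L0_H"]]
  part <- fit$partitions[["L0_H"]]
  if (is.null(tr)) .stop_fmt("result has no top-level tree")
  H <- if (!is.null(part)) part$group_H else tr$tip.label
  reps <- if (!is.null(part)) names(part$subgroups)[lengths(part$subgroups) > 0L]
          else character(0)
  display <- character(length(H))
  display[H %in% reps] <- sprintf("Group%d", seq_len(sum(H %in% reps)))
  display[!(H %in% reps)] <- sprintf("Taxon%d", seq_len(sum(!(H %in% reps))))
  map <- data.frame(original = H, display = display, stringsAsFactors = FALSE)
  tr$tip.label <- map$display[match(tr$tip.label, map$original)]
  list(tree = tr, map = map)
}

#' Write a hierarchical result to a directory
#'
#' Lays out `level0/group_H.nwk`, `level1/<representative>.nwk`, ... plus a
#' tab-separated manifest `hierarchy.tsv` with columns level, group_id,
#' representative, tree_path, members, children, alpha_used, rounds,
#' offending, status.
#'
#' @param fit an `hpc` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_hpc <- function(fit, dir) {
  stopifnot(inherits(fit, "hpc"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- fit$manifest
  paths <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    gid <- m$group_id[i]
    tr <- fit$trees[[gid]]
    if (is.null(tr)) { paths[i] <- ""; next }
    lvl_dir <- file.path(dir, sprintf("level%d", m$level[i]))
    dir.create(lvl_dir, showWarnings = FALSE)
    base <- if (m$level[i] == 0L) "group_H" else m$representative[i]
    paths[i] <- file.path(sprintf("level%d", m$level[i]), paste0(base, ".nwk"))
    write_newick(tr, file.path(dir, paths[i]))
  }
  out <- data.frame(
    level = m$level, group_id = m$group_id, representative = m$representative,
    tree_path = paths,
    members = vapply(m$members, paste, character(1), collapse = ","),
    children = vapply(m$children, paste, character(1), collapse = ","),
    alpha_used = m$alpha_used, rounds = m$rounds, offending = m$offending,
    status = m$status, stringsAsFactors = FALSE)
  utils::write.table(out, file.path(dir, "hierarchy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a hierarchical result back from a directory
#'
#' Reconstructs the manifest and trees written by [write_hpc()]; partition
#' details are not persisted and come back empty.
#'
#' @param dir directory containing `hierarchy.tsv`.
#' @return an `hpc` object.
#' @export
read_hpc_result <- function(dir) {
  path <- file.path(dir, "hierarchy.tsv")
  if (!file.exists(path)) .stop_fmt("no hierarchy.tsv in %s", dir)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, na.strings = "NA")
  trees <- list()
  for (i in seq_len(nrow(tab))) {
    p <- tab$tree_path[i]
    if (!is.na(p) && nzchar(p))
      trees[[tab$group_id[i]]] <- read_newick(file.path(dir, p))
  }
  manifest <- tab
  manifest$members <- I(strsplit(tab$members, ",", fixed = TRUE))
  manifest$children <- I(lapply(strsplit(tab$children, ",", fixed = TRUE),
                                function(v) v[nzchar(v)]))
  structure(list(manifest = manifest, trees = trees, partitions = list(),
                 delta = NA_real_, mode = NA_character_,
                 engine = NA_character_, alpha = NA, seed = NULL,
                 max_levels = NA_integer_, call = NULL),
            class = "hpc")
}
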