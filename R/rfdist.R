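# Robinson-Foulds distances on unrooted trees and the per-subgroup
# evaluation harness used to score a hierarchical result against the true
# subgroup phylogenies.

#' Non-trivial bipartitions of an unrooted tree
#'
#' One split per internal edge, as a canonical string key: the side of the
#' split containing the lexicographically smallest leaf, with its members
#' sorted and joined by `"|"`. Trivial splits (single leaves) are excluded,
#' so a fully resolved n-leaf tree yields n - 3 splits and a star yields
#' none. Multifurcating trees simply yield fewer splits.
#'
#' @param tree a `phylo`.
#' @return character vector of canonical split keys (possibly empty).
#' @export
bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  n <- length(tips)
  if (n < 4L) return(character(0))
  tree <- ape::unroot(tree)
  smallest <- sort(tips)[1L]
  edges <- tree$edge
  nnode <- tree$Nnode
  # Tip sets below each internal node, by postorder accumulation.
  below <- vector("list", n + nnode)
  for (i in seq_len(n)) below[[i]] <- tips[i]
  for (e in ape::postorder(tree)) {
    p <- edges[e, 1L]; ch <- edges[e, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  out <- character(0)
  for (e in seq_len(nrow(edges))) {
    ch <- edges[e, 2L]
    if (ch <= n) next                    # terminal edge: trivial split
    side <- below[[ch]]
    if (length(side) <= 1L || length(side) >= n - 1L) next
    if (!(smallest %in% side)) side <- setdiff(tips, side)
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

#' Robinson-Foulds distance between two unrooted trees
#'
#' The number of non-trivial bipartitions present in exactly one of the
#' two trees (symmetric difference of their split sets). Both trees must
#' have identical leaf sets.
#'
#' @param t1,t2 `phylo` objects on the same leaves.
#' @return non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    .stop_fmt("leaf sets differ (only in t1: %s; only in t2: %s)",
              paste(setdiff(t1$tip.label, t2$tip.label), collapse = ","),
              paste(setdiff(t2$tip.label, t1$tip.label), collapse = ","))
  b1 <- bipartitions(t1)
  b2 <- bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Normalized Robinson-Foulds distance
#'
#' The Robinson-Foulds distance divided by 2n - 6, the total number of
#' internal branches in two fully resolved unrooted n-leaf trees; the
#' result lies in `[0, 1]`. Comparisons with fewer than 4 leaves carry no
#' internal branches and score 0 with a warning.
#'
#' @param t1,t2 `phylo` objects on the same leaves.
#' @return numeric in `[0, 1]`.
#' @export
normalized_rf <- function(t1, t2) {
  n <- length(t1$tip.label)
  if (n < 4L) {
    if (!setequal(t1$tip.label, t2$tip.label))
      .stop_fmt("leaf sets differ")
    warning("fewer than 4 leaves: Robinson-Foulds comparison is vacuous, scoring 0")
    return(0)
  }
  rf_distance(t1, t2) / (2 * n - 6)
}

#' Score a hierarchical result against true subgroup phylogenies
#'
#' For each true subgroup tree, the corresponding constructed subgroup
#' tree is located in the result (by its group id when the planted
#' representative was recovered as such, otherwise by maximal leaf-set
#' overlap). Constructed subgroup trees carry the representative as an
#' extra leaf; every leaf absent from the truth tree is pruned before
#' comparison, so in the canonical two-level case this prunes exactly the
#' representative. Per-group normalized Robinson-Foulds distances and
#' their sum are returned.
#'
#' @param truth named list of `phylo` truth trees, keyed by subgroup
#'   representative (leaf sets = subgroup members only), or a directory
#'   containing `<representative>.nwk` files.
#' @param result an `hpc` object (or a directory written by
#'   [write_hpc()]).
#' @param level which result level holds the subgroup trees (default 1).
#' @return an object of class `hpc_eval`: list with `per_group` (named
#'   numeric), `total`, `n_leaves` (named integer), `matched_group`
#'   (named character: truth key -> result group id).
#' @export
evaluate_hierarchy <- function(truth, result, level = 1L) {
  if (is.character(truth) && length(truth) == 1L) {
    files <- list.files(truth, pattern = "\\.nwk$", full.names = TRUE)
    keys <- sub("\\.nwk$", "", basename(files))
    truth <- stats::setNames(lapply(files, read_newick), keys)
  }
  if (is.character(result) && length(result) == 1L)
    result <- read_hpc_result(result)
  stopifnot(inherits(result, "hpc"))
  m <- result$manifest
  cand <- m[m$level == level & m$status == "ok", , drop = FALSE]
  if (nrow(cand) == 0L) .stop_fmt("result has no level-%d groups", level)

  per <- numeric(0); nl <- integer(0); matched <- character(0)
  for (key in names(truth)) {
    tt <- truth[[key]]
    want <- tt$tip.label
    gid <- sprintf("L%d_%s", level, key)
    if (!gid %in% cand$group_id) {
      overlap <- vapply(cand$members, function(mm) length(intersect(mm, want)),
                        integer(1))
      if (max(overlap) == 0L)
        .stop_fmt("no constructed group matches truth group '%s'", key)
      gid <- cand$group_id[which.max(overlap)]
    }
    ct <- result$trees[[gid]]
    if (is.null(ct)) .stop_fmt("no tree for matched group '%s'", gid)
    extra <- setdiff(ct$tip.label, want)
    if (length(extra))
      ct <- ape::drop.tip(ct, extra)
    missing <- setdiff(want, ct$tip.label)
    if (length(missing))
      .stop_fmt("constructed group '%s' lacks truth members: %s",
                gid, paste(missing, collapse = ", "))
    val <- if (length(want) < 4L)
      suppressWarnings(normalized_rf(tt, ct)) else normalized_rf(tt, ct)
    per[key] <- val
    nl[key] <- length(want)
    matched[key] <- gid
  }
  structure(list(per_group = per, total = sum(per), n_leaves = nl,
                 matched_group = matched),
            class = "hpc_eval")
}

#' @export
print.hpc_eval <- function(x, ...) {
  cat("Subgroup evaluation over", length(x$per_group), "groups\n")
  cat("  total normalized RF:", format(x$total, digits = 6), "\n")
  cat("  per-group range: [", format(min(x$per_group), digits = 4), ", ",
      format(max(x$per_group), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Write an evaluation report as tab-separated text
#'
#' Per-group rows (group, leaves, normalized RF) followed by a `total` row.
#'
#' @param eval_result an `hpc_eval`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(eval_result, path) {
  df <- data.frame(group = names(eval_result$per_group),
                   n_leaves = eval_result$n_leaves,
                   normalized_rf = eval_result$per_group,
                   stringsAsFactors = FALSE)
  df <- rbind(df, data.frame(group = "total", n_leaves = NA,
                             normalized_rf = eval_result$total))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
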