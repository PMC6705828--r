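# Tree-construction engines: a built-in neighbor-joining engine (always
# available, deterministic) and adapters for the external maximum-likelihood
# programs RAxML, IQ-TREE and FastTree.

#' Describe a tree-construction engine
#'
#' @param name `"builtin_nj"`, `"raxml"`, `"iqtree"` or `"fasttree"`.
#' @param executable_path path to the external binary; when `NULL` the
#'   engine name itself is looked up on the PATH. Ignored for the built-in
#'   engine.
#' @param threads thread count passed to engines that accept one.
#' @param extra_args additional command-line tokens appended verbatim.
#' @param distance distance mode for the built-in engine: `"jc_ml"`
#'   (JC69-corrected, saturation clamped) or `"p_distance"`. The default
#'   `"auto"` applies the JC correction to ordinary alignments but falls
#'   back to raw percent differences when the alignment reaching the
#'   engine has had its identity columns stripped (beta = 0), since the
#'   JC map assumes unconditioned site sampling and over-corrects
#'   ascertainment-inflated proportions.
#' @return an object of class `engine_spec`.
#' @export
engine_spec <- function(name = c("builtin_nj", "raxml", "iqtree", "fasttree"),
                        executable_path = NULL, threads = 1L,
                        extra_args = character(),
                        distance = c("auto", "jc_ml", "p_distance")) {
  name <- match.arg(name)
  distance <- match.arg(distance)
  stopifnot(threads >= 1L)
  structure(list(name = name, executable_path = executable_path,
                 threads = as.integer(threads), extra_args = extra_args,
                 distance = distance),
            class = "engine_spec")
}

#' @export
print.engine_spec <- function(x, ...) {
  cat("Tree engine '", x$name, "'", sep = "")
  if (!is.null(x$executable_path)) cat(" (", x$executable_path, ")", sep = "")
  cat(", threads =", x$threads, "\n")
  invisible(x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Wraps the ape neighbor-joining implementation: the result is unrooted,
#' and the small negative branch lengths NJ can produce on noisy input are
#' clamped to zero. On an additive (tree-realizable) matrix the source tree
#' is recovered exactly.
#'
#' @param D symmetric distance matrix with zero diagonal and taxon dimnames.
#' @return an unrooted `phylo`.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || !isTRUE(all.equal(D, t(D), tolerance = 1e-12)))
    .stop_fmt("distance matrix must be symmetric")
  if (is.null(rownames(D))) .stop_fmt("distance matrix must carry taxon names")
  n <- nrow(D)
  if (n < 2L) .stop_fmt("need at least 2 taxa")
  if (n == 2L) {
    tr <- ape::read.tree(text = sprintf("(%s:%.12g,%s:%.12g);",
                                        rownames(D)[1L], D[1L, 2L] / 2,
                                        rownames(D)[2L], D[1L, 2L] / 2))
    return(tr)
  }
  if (n == 3L) {
    # Three-point closed form: a = (D_ab + D_ac - D_bc) / 2, etc.
    a <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    b <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    c3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    tr <- ape::read.tree(text = sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                                        rownames(D)[1L], max(a, 0),
                                        rownames(D)[2L], max(b, 0),
                                        rownames(D)[3L], max(c3, 0)))
    return(tr)
  }
  tr <- ape::nj(D)
  tr$edge.length[tr$edge.length < 0] <- 0
  ape::unroot(tr)
}

#' Command line for an external engine invocation
#'
#' Returns the binary, argument vector and expected output tree file for
#' running an external engine on `aln_file` inside `workdir`, without
#' executing anything.
#'
#' @param spec an [engine_spec()] for an external engine.
#' @param aln_file alignment file path handed to the engine.
#' @param workdir working directory of the invocation.
#' @return list with `bin`, `args`, `tree_file` (and, for RAxML,
#'   `fallback_tree_file`).
#' @export
engine_command <- function(spec, aln_file, workdir) {
  bin <- spec$executable_path %||% spec$name
  switch(spec$name,
    fasttree = list(
      bin = bin,
      args = c("-nt", "-gtr", "-quiet", spec$extra_args, aln_file),
      tree_file = file.path(workdir, "fasttree.nwk"),
      stdout_is_tree = TRUE),
    iqtree = list(
      bin = bin,
      args = c("-s", aln_file, "-m", "GTR", "-nt", spec$threads,
               "-seed", 44701L, spec$extra_args),
      tree_file = paste0(aln_file, ".treefile"),
      stdout_is_tree = FALSE),
    raxml = list(
      # Full analysis with the settings used when the engine runs inside
      # the hierarchical driver: 40 alternative runs, fixed parsimony and
      # bootstrap seeds.
      bin = bin,
      args = c("-f", "a", "-s", aln_file, "-n", "run", "-m", "GTRGAMMA",
               "-p", 44701L, "-x", 65701L, "-N", 40L, "-T", spec$threads,
               "-w", workdir, spec$extra_args),
      tree_file = file.path(workdir, "RAxML_bipartitions.run"),
      fallback_tree_file = file.path(workdir, "RAxML_bestTree.run"),
      stdout_is_tree = FALSE),
    .stop_fmt("engine '%s' has no external command", spec$name))
}

#' Run a tree-construction engine on an alignment
#'
#' The built-in engine computes JC69-corrected distances (saturation
#' clamped) and applies neighbor joining. External engines get the
#' alignment written in their preferred format inside `workdir`, are
#' invoked under the GTR substitution model, and their best-tree Newick
#' output is parsed back; the leaf set must equal the alignment's names.
#'
#' @param spec an [engine_spec()].
#' @param x an alignment (`>= 2` rows for the built-in engine, `>= 3` for
#'   external ones).
#' @param workdir working directory for external engines; created if
#'   needed, log files are retained there.
#' @return a `phylo` whose tip labels equal the alignment's row names.
#' @export
run_engine <- function(spec, x, workdir = tempfile("engine")) {
  stopifnot(inherits(spec, "engine_spec"))
  x <- as_alignment(x)
  if (spec$name == "builtin_nj") {
    mode <- spec$distance %||% "auto"
    if (mode == "auto") mode <- "jc_ml"
    D <- pairwise_distances(x, mode = mode, clamp = TRUE)
    return(nj_tree(D))
  }
  if (nrow(x) < 3L) .stop_fmt("external engines need at least 3 taxa")
  bin <- spec$executable_path %||% spec$name
  resolved <- if (file.exists(bin)) bin else Sys.which(bin)
  if (!nzchar(resolved) || !file.exists(resolved))
    .stop_fmt("engine configuration error: executable '%s' not found", bin)
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  fmt <- if (spec$name == "fasttree") "fasta" else "phylip"
  aln_file <- file.path(workdir,
                        paste0("alignment.", if (fmt == "fasta") "fasta" else "phy"))
  write_alignment(x, aln_file, format = fmt)
  cmd <- engine_command(spec, aln_file, workdir)
  log_file <- file.path(workdir, paste0(spec$name, ".log"))
  out_target <- if (isTRUE(cmd$stdout_is_tree)) cmd$tree_file else log_file
  status <- system2(resolved, cmd$args, stdout = out_target, stderr = log_file)
  if (!identical(status, 0L))
    .stop_fmt("engine '%s' exited with status %d; log: %s",
              spec$name, status, log_file)
  tree_file <- cmd$tree_file
  if (!file.exists(tree_file) && !is.null(cmd$fallback_tree_file))
    tree_file <- cmd$fallback_tree_file
  if (!file.exists(tree_file))
    .stop_fmt("engine '%s' produced no tree file (expected %s)",
              spec$name, cmd$tree_file)
  tr <- read_newick(tree_file)
  if (!setequal(tr$tip.label, rownames(x)))
    .stop_fmt("engine '%s' returned a tree whose leaves differ from the alignment (missing: %s; extra: %s)",
              spec$name,
              paste(setdiff(rownames(x), tr$tip.label), collapse = ","),
              paste(setdiff(tr$tip.label, rownames(x)), collapse = ","))
  ape::unroot(tr)
}
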