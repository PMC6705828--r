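# Phylogeny construction for one group: identity-column trimming by beta,
# random column subsampling of alpha columns, an engine run, the
# branch-length ratio check against delta, and the alpha doubling loop.

#' Initial column-sample size as a function of group size
#'
#' 5000 columns for up to 40 isolates, 15000 for 41-60, and 25000 beyond;
#' these sample sizes were calibrated so that a tree built from the sample
#' has nearly the topology obtained from a full-length alignment.
#'
#' @param n number of isolates, `>= 2`.
#' @return positive integer.
#' @export
initial_alpha <- function(n) {
  stopifnot(n >= 2)
  if (n <= 40) 5000L else if (n <= 60) 15000L else 25000L
}

#' Cap the number of identity columns at beta * d_S
#'
#' All variable columns are kept in their original order. When the number
#' of identity columns (columns without two distinct unambiguous bases)
#' exceeds `ceiling(beta * d_S)`, the surplus is dropped; the earliest
#' identity columns by position are the ones retained. `beta = "unlimited"`
#' keeps everything, `beta = 0` keeps only the variable columns. When the
#' result would be empty (an alignment of identical rows with `beta = 0`)
#' the first column is retained so downstream distance computations stay
#' defined.
#'
#' @param x an alignment.
#' @param beta non-negative real or `"unlimited"`.
#' @return the trimmed alignment.
#' @export
trim_identity_columns <- function(x, beta = "unlimited") {
  x <- as_alignment(x)
  if (identical(beta, "unlimited") || is.infinite(beta)) return(x)
  stopifnot(is.numeric(beta), beta >= 0)
  var_idx <- variable_columns(x)
  d_S <- length(var_idx)
  id_idx <- setdiff(seq_len(ncol(x)), var_idx)
  cap <- ceiling(beta * d_S)
  keep_id <- id_idx[seq_len(min(cap, length(id_idx)))]
  keep <- sort(c(var_idx, keep_id))
  if (length(keep) == 0L) keep <- 1L
  x[, keep, drop = FALSE]
}

#' Randomly subsample alignment columns without replacement
#'
#' Chooses exactly `alpha` distinct column indices uniformly at random and
#' returns them in ascending positional order; when `alpha` is at least the
#' alignment length the input is returned unchanged.
#'
#' @param x an alignment.
#' @param alpha positive integer sample size.
#' @param seed optional seed for the draw.
#' @return the subsampled alignment.
#' @export
sample_columns <- function(x, alpha, seed = NULL) {
  x <- as_alignment(x)
  stopifnot(alpha >= 1)
  L <- ncol(x)
  if (alpha >= L) return(x)
  idx <- with_seed(seed, sort(sample.int(L, alpha)))
  x[, idx, drop = FALSE]
}

#' Count branches failing the branch-length ratio check
#'
#' Let m be the maximum branch length in the tree. A branch e is offending
#' when `m / max(len(e), epsilon) >= delta`, i.e. the ratio check "every
#' ratio below delta" fails on it; epsilon guards zero-length branches.
#' Terminal and internal branches both participate.
#'
#' @param tree a `phylo` with branch lengths.
#' @param delta distance ratio cutoff.
#' @param epsilon lower clamp for branch lengths in the ratio.
#' @return integer count of offending branches.
#' @export
offending_branch_count <- function(tree, delta, epsilon = 1e-9) {
  stopifnot(inherits(tree, "phylo"), delta > 0, epsilon > 0)
  len <- tree$edge.length
  if (is.null(len) || length(len) == 0L) .stop_fmt("tree has no branch lengths")
  m <- max(len)
  sum(m / pmax(len, epsilon) >= delta)
}

#' Build one group's phylogeny with the adaptive column-doubling loop
#'
#' Applies identity-column trimming, samples `alpha` columns, runs the
#' engine and counts offending branches; on failure `alpha` is doubled and
#' the round repeated with a fresh sample. The loop stops when the count
#' reaches zero, stops decreasing, the sample already covers the whole
#' trimmed alignment, or `max_doublings` is exhausted. The tree of the
#' round with the fewest offending branches is returned (ties resolved in
#' favor of the larger sample).
#'
#' @param x an alignment with at least 2 rows.
#' @param engine an [engine_spec()].
#' @param delta distance ratio cutoff for the branch check.
#' @param alpha initial sample size; `"auto"` applies [initial_alpha()].
#' @param beta identity-column cap (see [trim_identity_columns()]).
#' @param seed optional seed for the column draws.
#' @param max_doublings maximum number of alpha doublings.
#' @param epsilon zero-branch guard for the ratio check.
#' @param workdir scratch directory for external engines.
#' @return an object of class `hpc_construct`: list with `tree`,
#'   `alpha_used`, `columns_available`, `rounds`,
#'   `offending_branches_per_round`, `alpha_per_round`.
#' @export
adaptive_construct <- function(x, engine = engine_spec("builtin_nj"),
                               delta = 100, alpha = "auto",
                               beta = "unlimited", seed = NULL,
                               max_doublings = 10L, epsilon = 1e-9,
                               workdir = tempfile("construct")) {
  x <- as_alignment(x)
  if (nrow(x) < 2L) .stop_fmt("need at least 2 isolates")
  trimmed <- trim_identity_columns(x, beta)
  L <- ncol(trimmed)
  # Resolve the built-in engine's "auto" distance mode: identity-stripped
  # alignments (beta = 0) get raw percent differences, everything else the
  # JC correction.
  if (identical(engine$name, "builtin_nj") &&
      identical(engine$distance %||% "auto", "auto"))
    engine$distance <- if (is.numeric(beta) && beta == 0) "p_distance" else "jc_ml"
  a0 <- if (identical(alpha, "auto")) initial_alpha(nrow(x)) else as.integer(alpha)
  stopifnot(a0 >= 1L)

  with_seed(seed, {
    offs <- integer(0)
    alphas <- integer(0)
    best_tree <- NULL
    best_off <- Inf
    a <- a0
    round <- 0L
    repeat {
      round <- round + 1L
      sub <- sample_columns(trimmed, a)
      tr <- tryCatch(
        run_engine(engine, sub, workdir = file.path(workdir, paste0("round", round))),
        error = function(e)
          .stop_fmt("engine failure in round %d (alpha = %d): %s",
                    round, a, conditionMessage(e)))
      off <- offending_branch_count(tr, delta, epsilon)
      offs <- c(offs, off)
      alphas <- c(alphas, min(a, L))
      if (off <= best_off) {   # ties resolved toward the larger sample
        best_off <- off
        best_tree <- tr
      }
      whole <- ncol(sub) == L
      no_progress <- round > 1L && off >= offs[round - 1L]
      if (off == 0L || whole || no_progress || round > max_doublings) break
      a <- a * 2L
    }
    best_idx <- max(which(offs == min(offs)))
    structure(
      list(tree = best_tree, alpha_used = alphas[best_idx],
           columns_available = L, rounds = round,
           offending_branches_per_round = offs, alpha_per_round = alphas,
           delta = delta, engine = engine$name),
      class = "hpc_construct")
  })
}

#' @export
print.hpc_construct <- function(x, ...) {
  cat("Group phylogeny (", x$engine, "), ", length(x$tree$tip.label),
      " leaves\n", sep = "")
  cat("  rounds: ", x$rounds, "; offending branches per round: ",
      paste(x$offending_branches_per_round, collapse = ", "), "\n", sep = "")
  cat("  alpha used: ", x$alpha_used, " of ", x$columns_available,
      " available columns\n", sep = "")
  invisible(x)
}
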