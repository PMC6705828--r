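# Pairwise evolutionary distances: percent difference (p-distance), the
# JC69 maximum-likelihood correction, full matrices, and the anchor-based
# estimate of the maximum pairwise distance.

#' Percent difference between two aligned rows
#'
#' Proportion of mismatching columns among the columns where both rows
#' carry an unambiguous base (A, C, G or T). Columns with N, gaps or other
#' ambiguity codes in either row are excluded from both numerator and
#' denominator.
#'
#' @param a,b aligned rows: equal-length character strings, character
#'   vectors, or raw `DNAbin` vectors.
#' @return proportion in `[0, 1]`.
#' @export
p_distance <- function(a, b) {
  a <- .as_row(a); b <- .as_row(b)
  if (length(a) != length(b))
    .stop_fmt("rows have different lengths (%d vs %d)", length(a), length(b))
  ok <- .acgt_mask(a) & .acgt_mask(b)
  n_ok <- sum(ok)
  if (n_ok == 0L)
    .stop_fmt("undefined distance: no column with unambiguous bases in both rows")
  sum(a[ok] != b[ok]) / n_ok
}

.as_row <- function(x) {
  if (is.raw(x)) return(x)
  if (is.character(x) && length(x) == 1L) x <- strsplit(x, "")[[1L]]
  if (is.character(x)) {
    m <- matrix(toupper(x), nrow = 1L, dimnames = list("x", NULL))
    return(as.vector(unclass(ape::as.DNAbin(m))))
  }
  if (inherits(x, "DNAbin")) return(as.vector(unclass(x)))
  .stop_fmt("cannot interpret object of class '%s' as an alignment row",
            class(x)[1L])
}

#' Jukes-Cantor distance from a percent difference
#'
#' The maximum-likelihood evolutionary distance under the JC69 model,
#' `-(3/4) * log(1 - (4/3) * p)`, in substitutions per site. Proportions at
#' or beyond the saturation point 0.75 are an error by default; with
#' `clamp = TRUE` they are mapped to `ceiling` instead, which keeps tree
#' building usable on near-saturated rows.
#'
#' @param p proportion(s) of differing sites, each in `[0, 0.75)`.
#' @param clamp replace saturated values by `ceiling` instead of stopping.
#' @param ceiling distance assigned to saturated pairs when clamping.
#' @return numeric vector of distances (substitutions per site).
#' @export
jc_distance <- function(p, clamp = FALSE, ceiling = 5) {
  if (any(p < 0, na.rm = TRUE)) .stop_fmt("negative proportion")
  sat <- !is.na(p) & p >= 0.75
  if (any(sat) && !clamp)
    .stop_fmt("p = %.4g is at or beyond JC69 saturation (0.75)", max(p[sat]))
  d <- suppressWarnings(-0.75 * log(1 - (4 / 3) * p))
  d[sat] <- ceiling
  d
}

#' Full pairwise distance matrix
#'
#' Computes all n(n-1)/2 pairwise distances, with pairwise exclusion of
#' ambiguous columns. Mode `"p_distance"` is the raw percent difference;
#' `"jc_ml"` applies the JC69 ML correction.
#'
#' @param x an alignment with at least two rows.
#' @param mode `"jc_ml"` or `"p_distance"`.
#' @param clamp,ceiling saturation handling for `"jc_ml"` (see
#'   [jc_distance()]).
#' @return symmetric numeric matrix with zero diagonal and isolate dimnames.
#' @export
pairwise_distances <- function(x, mode = c("jc_ml", "p_distance"),
                               clamp = FALSE, ceiling = 5) {
  mode <- match.arg(mode)
  x <- as_alignment(x)
  if (nrow(x) < 2L) .stop_fmt("need at least 2 isolates")
  P <- as.matrix(ape::dist.dna(x, model = "raw", pairwise.deletion = TRUE))
  if (anyNA(P)) {
    bad <- which(is.na(P), arr.ind = TRUE)[1L, ]
    .stop_fmt("undefined distance between '%s' and '%s': no shared unambiguous column",
              rownames(P)[bad[1L]], colnames(P)[bad[2L]])
  }
  D <- if (mode == "jc_ml") jc_distance(P, clamp = clamp, ceiling = ceiling) else P
  D <- matrix(D, nrow(P), dimnames = dimnames(P))
  diag(D) <- 0
  D
}

#' Anchor-based estimate of the maximum pairwise distance
#'
#' Picks one isolate uniformly at random (the anchor) and computes its
#' distance to every other isolate; the maximum of these n-1 values is the
#' estimate. For any distance satisfying the triangle inequality the true
#' maximum D_max over all pairs obeys `dhat_max <= D_max <= 2 * dhat_max`,
#' so the estimate is a factor-2 stand-in computable in linear time.
#'
#' @param x an alignment with at least two rows.
#' @param mode distance mode (see [pairwise_distances()]).
#' @param seed optional seed for the anchor draw.
#' @param clamp,ceiling saturation handling for `"jc_ml"`.
#' @return an object of class `hpc_dmax`: list with `anchor`, `dhat_max`,
#'   `mode`, and the per-isolate anchor `distances`.
#' @export
anchor_dmax <- function(x, mode = c("jc_ml", "p_distance"), seed = NULL,
                        clamp = FALSE, ceiling = 5) {
  mode <- match.arg(mode)
  x <- as_alignment(x)
  n <- nrow(x)
  if (n < 2L) .stop_fmt("need at least 2 isolates to estimate D_max")
  anchor_i <- with_seed(seed, sample.int(n, 1L))
  d <- anchor_distances(x, anchor_i, mode, clamp = clamp, ceiling = ceiling)
  structure(
    list(anchor = rownames(x)[anchor_i], dhat_max = max(d), mode = mode,
         distances = d),
    class = "hpc_dmax")
}

# Distances from row `i` to every row of `x` (self = 0), without forming
# the full matrix.
anchor_distances <- function(x, i, mode = c("jc_ml", "p_distance"),
                             clamp = FALSE, ceiling = 5) {
  mode <- match.arg(mode)
  raw <- unclass(x)
  a <- raw[i, ]
  am <- .acgt_mask(a)
  d <- numeric(nrow(x))
  for (j in seq_len(nrow(x))) {
    if (j == i) next
    b <- raw[j, ]
    ok <- am & .acgt_mask(b)
    n_ok <- sum(ok)
    if (n_ok == 0L)
      .stop_fmt("undefined distance between '%s' and '%s'",
                rownames(x)[i], rownames(x)[j])
    d[j] <- sum(a[ok] != b[ok]) / n_ok
  }
  if (mode == "jc_ml") d <- jc_distance(d, clamp = clamp, ceiling = ceiling)
  names(d) <- rownames(x)
  d
}

#' @export
print.hpc_dmax <- function(x, ...) {
  cat("Anchor-based D_max estimate\n")
  cat("  anchor:   ", x$anchor, "\n", sep = "")
  cat("  dhat_max: ", format(x$dhat_max, digits = 6), " (mode ", x$mode, ")\n",
      sep = "")
  invisible(x)
}

#' Export a distance matrix as square tab-separated text
#' @param D symmetric matrix from [pairwise_distances()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(D, path) {
  df <- data.frame(name = rownames(D), D, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
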