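# Partition of the isolate set into a group H of moderately similar
# isolates and per-representative subgroups of highly similar isolates.

#' Are two isolates highly similar?
#'
#' Two isolates p and q are highly similar when the ratio of the (estimated)
#' maximum pairwise distance to their own distance exceeds the distance
#' ratio cutoff delta. A zero distance (identical isolates) is an infinite
#' ratio and always counts as highly similar.
#'
#' @param d_pq pairwise distance, `>= 0`.
#' @param dhat_max estimated maximum pairwise distance, `>= 0`.
#' @param delta distance ratio cutoff, `> 0`.
#' @return logical.
#' @export
is_highly_similar <- function(d_pq, dhat_max, delta) {
  stopifnot(d_pq >= 0, dhat_max >= 0, delta > 0)
  if (d_pq == 0) return(TRUE)
  dhat_max / d_pq > delta
}

#' Partition isolates into group H and subgroups of highly similar isolates
#'
#' Greedy single pass in seeded random order. The first isolate seeds H;
#' each subsequent isolate joins H when it is not highly similar to any
#' current member of H, and otherwise is appended to the subgroup of the
#' H member it is most similar to (smallest distance). Distances to H are
#' computed lazily, so the pass needs O(n |H|) pairwise comparisons rather
#' than the full matrix.
#'
#' @param x an alignment with at least two rows.
#' @param delta distance ratio cutoff (default 100; use 50 when the anchor
#'   estimate may sit near half of the true maximum).
#' @param mode distance mode; `"p_distance"` is the fast percent-difference
#'   shortcut, `"jc_ml"` the JC69-corrected distance.
#' @param seed optional seed controlling the anchor draw and the pass order.
#' @param dmax optional precomputed [anchor_dmax()] result to reuse.
#' @return an object of class `hpc_partition`: list with `group_H`
#'   (ordered names), `subgroups` (named list keyed by representative,
#'   possibly empty character vectors), `delta`, `dhat_max`, `anchor`,
#'   `mode`, and `order` (the processing order used).
#' @export
partition_isolates <- function(x, delta = 100,
                               mode = c("p_distance", "jc_ml"),
                               seed = NULL, dmax = NULL) {
  mode <- match.arg(mode)
  stopifnot(delta > 0)
  x <- as_alignment(x)
  n <- nrow(x)
  if (n < 2L) .stop_fmt("need at least 2 isolates to partition")
  nms <- rownames(x)

  with_seed(seed, {
    if (is.null(dmax)) dmax <- anchor_dmax(x, mode = mode, clamp = TRUE)
    ord <- sample.int(n)

    raw <- unclass(x)
    masks <- vector("list", n)
    getmask <- function(i) {
      if (is.null(masks[[i]])) masks[[i]] <<- .acgt_mask(raw[i, ])
      masks[[i]]
    }
    pdist <- function(i, j) {
      ok <- getmask(i) & getmask(j)
      n_ok <- sum(ok)
      if (n_ok == 0L)
        .stop_fmt("undefined distance between '%s' and '%s'", nms[i], nms[j])
      p <- sum(raw[i, ok] != raw[j, ok]) / n_ok
      if (mode == "jc_ml") jc_distance(p, clamp = TRUE) else p
    }

    H <- integer(0)
    sub <- list()
    for (i in ord) {
      if (length(H) == 0L) {
        H <- i
        sub[[nms[i]]] <- character(0)
        next
      }
      d_to_H <- vapply(H, function(h) pdist(i, h), numeric(1))
      sim <- vapply(d_to_H, is_highly_similar, logical(1),
                    dhat_max = dmax$dhat_max, delta = delta)
      if (any(sim)) {
        h <- H[sim][which.min(d_to_H[sim])]
        sub[[nms[h]]] <- c(sub[[nms[h]]], nms[i])
      } else {
        H <- c(H, i)
        sub[[nms[i]]] <- character(0)
      }
    }

    structure(
      list(group_H = nms[H], subgroups = sub[nms[H]], delta = delta,
           dhat_max = dmax$dhat_max, anchor = dmax$anchor, mode = mode,
           order = nms[ord]),
      class = "hpc_partition")
  })
}

#' @export
print.hpc_partition <- function(x, ...) {
  ns <- lengths(x$subgroups)
  cat("Isolate partition (delta = ", format(x$delta), ", mode = ", x$mode,
      ")\n", sep = "")
  cat("  group H: ", length(x$group_H), " isolates (anchor '", x$anchor,
      "', dhat_max = ", format(x$dhat_max, digits = 6), ")\n", sep = "")
  cat("  subgroups: ", sum(ns > 0), " non-empty of ", length(ns),
      if (sum(ns > 0)) paste0("; sizes ", paste(sort(ns[ns > 0]), collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

#' Export a partition as two-column tab-separated text
#'
#' One row per isolate: its name and its representative, or `"H"` for
#' members of the moderately similar group.
#'
#' @param part an `hpc_partition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(part, path) {
  iso <- c(part$group_H, unlist(part$subgroups, use.names = FALSE))
  rep_of <- c(rep("H", length(part$group_H)),
              rep(names(part$subgroups), lengths(part$subgroups)))
  utils::write.table(data.frame(isolate = iso, representative = rep_of),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Membership map of a partition
#' @param part an `hpc_partition`.
#' @return named character vector: isolate -> representative or `"H"`.
#' @export
partition_membership <- function(part) {
  m <- c(stats::setNames(rep("H", length(part$group_H)), part$group_H),
         stats::setNames(rep(names(part$subgroups), lengths(part$subgroups)),
                         unlist(part$subgroups, use.names = FALSE)))
  m
}
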