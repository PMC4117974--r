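#' Build a symmetric Ks matrix from pairwise estimates
#'
#' Undefined entries (missing pairs, infinite or NA Ks) are left as `NA` and
#' are excluded from cluster medians downstream.
#'
#' @param pairs Tibble with `gene_a`, `gene_b` and a Ks column.
#' @param value Name of the Ks column (default `"dS"`).
#' @return Symmetric numeric matrix with zero diagonal, gene ids as
#'   dimnames.
#' @export
ks_matrix <- function(pairs, value = "dS") {
  genes <- sort(unique(c(pairs$gene_a, pairs$gene_b)))
  m <- matrix(NA_real_, length(genes), length(genes),
              dimnames = list(genes, genes))
  ks <- pairs[[value]]
  ks[!is.finite(ks)] <- NA_real_
  m[cbind(pairs$gene_a, pairs$gene_b)] <- ks
  m[cbind(pairs$gene_b, pairs$gene_a)] <- ks
  diag(m) <- 0
  m
}

#' Median-Ks agglomerative clustering of a paralog group
#'
#' The Blanc-Wolfe procedure: (1) every gene starts as its own cluster;
#' (2) the Ks values for all cluster pairs are compared, where the Ks of a
#' multi-member pair is the median over all cross pairs; (3) the pair with
#' the smallest Ks is merged; (4) that median is recorded as the height of
#' the merge (the duplication event); (5) repeat until one cluster remains.
#' Undefined Ks entries are excluded from medians; a cluster pair with no
#' defined cross pair cannot be merged, and a step at which no pair can be
#' merged is an error. The median of an even-sized set is the mean of the
#' two middle values. Ties for the smallest Ks are broken toward the pair
#' whose lexicographically smallest member sorts first.
#'
#' @param ks Symmetric Ks matrix (see [ks_matrix()]); `NA` = undefined.
#' @return An object of class `ks_clust`: list with `labels`, `merge`
#'   (hclust-style, negative entries are leaves), `height` (median Ks per
#'   merge) and `members` (leaf labels under each internal node).
#' @export
median_ks_linkage <- function(ks) {
  stopifnot(is.matrix(ks), nrow(ks) == ncol(ks), nrow(ks) >= 2L)
  labels <- rownames(ks)
  n <- nrow(ks)
  # active clusters: leaf index sets; ids follow hclust conventions
  clusters <- as.list(seq_len(n))
  ids <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(clusters)
    best <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in seq((i + 1L), k)) {
        cross <- ks[clusters[[i]], clusters[[j]], drop = FALSE]
        vals <- cross[!is.na(cross)]
        if (length(vals) == 0L) next
        med <- median(vals)
        key <- sort(c(min(labels[clusters[[i]]]), min(labels[clusters[[j]]])))
        cand <- list(i = i, j = j, med = med, key = key)
        if (is.null(best) || med < best$med ||
            (med == best$med && (key[1] < best$key[1] ||
                                 (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- cand
        }
      }
    }
    if (is.null(best)) {
      stranded <- vapply(clusters,
                         function(cl) paste(labels[cl], collapse = ","),
                         character(1))
      abort(paste0("no defined Ks between remaining clusters: {",
                   paste(stranded, collapse = "} {"), "}"))
    }
    merge[step, ] <- c(ids[best$i], ids[best$j])
    height[step] <- best$med
    new_members <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    members[[step]] <- labels[new_members]
    clusters <- c(clusters[-c(best$i, best$j)], list(new_members))
    ids <- c(ids[-c(best$i, best$j)], step)
  }
  structure(list(labels = labels, merge = merge, height = height,
                 members = members),
            class = "ks_clust")
}

#' @export
print.ks_clust <- function(x, ...) {
  cat("Median-Ks agglomerative tree\n")
  cat("  leaves:", length(x$labels), "  merges:", length(x$height), "\n")
  cat("  merge heights (Ks):", paste(signif(x$height, 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Date a duplication event from its Ks value
#'
#' Applies the neutral-rate molecular clock `T = Ks / (2 * lambda)` with the
#' plant nuclear synonymous rate `lambda = 1.5e-8` substitutions per
#' synonymous site per year by default.
#'
#' @param ks Ks value(s), >= 0.
#' @param lambda Neutral substitution rate per site per year.
#' @return Age(s) in years.
#' @export
date_duplication <- function(ks, lambda = 1.5e-8) {
  if (any(ks < 0)) abort("ks must be non-negative")
  stopifnot(lambda > 0)
  ks / (2 * lambda)
}

#' @describeIn median_ks_linkage Node table of a `ks_clust` tree: one row
#'   per internal node with its members, median Ks and age in years.
#' @param x A `ks_clust` object.
#' @param lambda Neutral rate used to date nodes (see [date_duplication()]).
#' @param ... Unused.
#' @export
tidy.ks_clust <- function(x, lambda = 1.5e-8, ...) {
  tibble(
    node_id = seq_along(x$height),
    members = vapply(x$members, paste, character(1), collapse = ","),
    n_members = lengths(x$members),
    median_ks = x$height,
    date_years = date_duplication(x$height, lambda)
  )
}

#' @describeIn median_ks_linkage One-row summary of a `ks_clust` tree.
#' @export
glance.ks_clust <- function(x, ...) {
  child_h <- function(id) if (id < 0L) 0 else x$height[id]
  inversions <- vapply(seq_along(x$height), function(i) {
    x$height[i] < max(vapply(x$merge[i, ], child_h, numeric(1)))
  }, logical(1))
  tibble(
    n_leaves = length(x$labels),
    n_merges = length(x$height),
    min_ks = min(x$height),
    max_ks = max(x$height),
    n_inversions = sum(inversions)
  )
}

#' Serialise a median-Ks tree to Newick
#'
#' Branch lengths are parent height minus child height (leaves sit at height
#' zero). Median linkage can invert heights (a child node higher than its
#' parent); such branches are clamped to zero with a warning. Children are
#' ordered deterministically by their lexicographically smallest leaf.
#'
#' @param tree A `ks_clust` object.
#' @return A Newick string terminated with `;`.
#' @export
to_newick <- function(tree) {
  n_clamped <- 0L
  node_str <- function(id) {
    # id: negative = leaf, positive = internal node; returns label + height
    if (id < 0L) {
      return(list(str = tree$labels[-id], height = 0,
                  min_leaf = tree$labels[-id]))
    }
    ch <- lapply(tree$merge[id, ], node_str)
    ord <- order(vapply(ch, `[[`, character(1), "min_leaf"))
    ch <- ch[ord]
    h <- tree$height[id]
    bl <- vapply(ch, function(c) h - c$height, numeric(1))
    if (any(bl < 0)) {
      n_clamped <<- n_clamped + sum(bl < 0)
      bl[bl < 0] <- 0
    }
    list(
      str = paste0("(", paste0(vapply(ch, `[[`, character(1), "str"),
                               ":", format_bl(bl), collapse = ","), ")"),
      height = h,
      min_leaf = ch[[1]]$min_leaf
    )
  }
  root <- node_str(length(tree$height))
  if (n_clamped > 0L) {
    warn(paste0(n_clamped,
                " negative branch length(s) clamped to 0 (median-linkage ",
                "height inversion)"))
  }
  paste0(root$str, ";")
}

format_bl <- function(x) {
  sub("\\.?0+$", "", formatC(x, digits = 10, format = "f"))
}

#' Dendrogram plot of a median-Ks tree
#'
#' @param object A `ks_clust` object.
#' @param ... Unused.
#' @return A ggplot: leaves along x, merge heights (Ks) on y.
#' @export
autoplot.ks_clust <- function(object, ...) {
  n <- length(object$labels)
  pos <- new.env()
  leaf_x <- 0
  layout <- function(id) {
    if (id < 0L) {
      leaf_x <<- leaf_x + 1
      return(c(x = leaf_x, h = 0))
    }
    ch <- lapply(object$merge[id, ], layout)
    x <- mean(vapply(ch, function(c) c[["x"]], numeric(1)))
    h <- object$height[id]
    segs <- rbind(
      data.frame(x = ch[[1]][["x"]], xend = ch[[1]][["x"]],
                 y = ch[[1]][["h"]], yend = h),
      data.frame(x = ch[[2]][["x"]], xend = ch[[2]][["x"]],
                 y = ch[[2]][["h"]], yend = h),
      data.frame(x = ch[[1]][["x"]], xend = ch[[2]][["x"]], y = h, yend = h)
    )
    pos$segs <- rbind(pos$segs, segs)
    c(x = x, h = h)
  }
  leaf_order <- function(id) {
    if (id < 0L) return(object$labels[-id])
    unlist(lapply(object$merge[id, ], leaf_order))
  }
  layout(length(object$height))
  leaves <- leaf_order(length(object$height))
  ggplot2::ggplot(pos$segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = seq_len(n), labels = leaves) +
    ggplot2::labs(x = NULL, y = "median Ks") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
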