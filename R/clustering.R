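#' Agglomerative hierarchical clustering of a precomputed distance matrix
#'
#' Standard bottom-up clustering (Lance-Williams updates via [stats::hclust])
#' on the vector-Wasserstein distance matrix, cut at `k` clusters. Average
#' linkage is the default: Ward-type criteria assume Euclidean geometry,
#' which a transport distance does not provide. Cluster labels are
#' renumbered 1..k in order of first appearance over the sample list, so the
#' labelling is deterministic and invariant (up to relabelling) under
#' permutations of the input.
#'
#' @param dist symmetric nonnegative matrix with zero diagonal and sample
#'   ids as dimnames, e.g. from [pairwise_distance_matrix()].
#' @param k number of clusters, `2 <= k <= n` (also `k = n`, all singletons).
#' @param linkage one of `"average"`, `"single"`, `"complete"`, `"weighted"`
#'   (McQuitty / WPGMA).
#' @return An object of class `cluster_assignment`: list with `sample_ids`,
#'   `labels` (named integer vector, values in 1..k), `k`, `linkage` and
#'   `tree` (the `hclust` merge record, for dendrogram export).
#' @export
hierarchical_cluster <- function(dist, k,
                                 linkage = c("average", "single",
                                             "complete", "weighted")) {
  linkage <- match.arg(linkage)
  dist <- as.matrix(dist)
  if (any(is.na(dist))) stop("distance matrix contains NA")
  n <- nrow(dist)
  if (n != ncol(dist)) stop("distance matrix must be square")
  if (max(abs(dist - t(dist))) > 1e-8) {
    stop("distance matrix is not symmetric")
  }
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 2L || k > n) {
    stop("k must be an integer in [2, ", n, "]")
  }
  ids <- rownames(dist)
  if (is.null(ids)) ids <- paste0("sample", seq_len(n))
  method <- c(average = "average", single = "single",
              complete = "complete", weighted = "mcquitty")[[linkage]]
  tree <- stats::hclust(stats::as.dist(dist), method = method)
  tree$labels <- ids
  raw <- stats::cutree(tree, k = k)
  # renumber by first appearance for a canonical labelling
  first <- unique(raw)
  labels <- setNames(match(raw, first), ids)
  structure(
    list(sample_ids = ids, labels = labels, k = as.integer(k),
         linkage = linkage, tree = tree),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment> ", length(x$sample_ids), " samples, k = ", x$k,
      " (", x$linkage, " linkage)\n", sep = "")
  print(table(cluster = x$labels))
  invisible(x)
}

#' Export a clustering dendrogram as a Newick string
#'
#' Converts the merge record to a phylogeny-style tree in which the path
#' length between two leaves equals their cophenetic (merge) distance, i.e.
#' each merge at height *h* places the joined branches at depth *h*/2.
#'
#' @param assignment a `cluster_assignment`.
#' @return A single Newick string (terminated by `;`).
#' @export
export_dendrogram <- function(assignment) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  phy <- ape::as.phylo(assignment$tree)
  ape::write.tree(phy)
}
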