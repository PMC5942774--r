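#' Pearson correlation distance
#'
#' Distance between two category-profile vectors, defined as
#' \eqn{1 - r} with \eqn{r} the Pearson correlation of the paired values,
#' so identical shapes are at distance 0 and perfectly anti-correlated
#' shapes at 2. Positions missing (`NA`) in either vector are dropped
#' pairwise before computing.
#'
#' @param u,v Equal-length numeric vectors with at least 3 complete pairs
#'   and nonzero variance.
#' @return A number in `[0, 2]`.
#' @export
correlation_distance <- function(u, v) {
  if (length(u) != length(v)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  ok <- !is.na(u) & !is.na(v)
  if (sum(ok) < 3L) {
    stop("need at least 3 complete pairs (got ", sum(ok), ")", call. = FALSE)
  }
  uu <- u[ok]
  vv <- v[ok]
  if (stats::sd(uu) == 0 || stats::sd(vv) == 0) {
    stop("correlation distance undefined for a zero-variance vector",
         call. = FALSE)
  }
  1 - stats::cor(uu, vv)
}

#' Correlation-distance matrix of strain profiles
#'
#' @param profiles Numeric matrix, one row per strain (rownames are strain
#'   labels), one column per category; `NA` cells allowed (pairwise
#'   deletion).
#' @return A `dist` object.
#' @export
profile_dist <- function(profiles) {
  labs <- rownames(profiles)
  if (is.null(labs)) labs <- paste0("strain", seq_len(nrow(profiles)))
  n <- nrow(profiles)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      dij <- tryCatch(
        correlation_distance(profiles[i, ], profiles[j, ]),
        error = function(e) {
          stop("distance undefined for strains '", labs[i], "' and '",
               labs[j], "': ", conditionMessage(e), call. = FALSE)
        }
      )
      d[i, j] <- dij
      d[j, i] <- dij
    }
  }
  stats::as.dist(d)
}

#' Average-linkage clustering of strains by category-wise mean CIB
#'
#' Agglomerative hierarchical clustering of strain profiles (mean CIB per
#' functional category) under unweighted average linkage, with Pearson
#' correlation distance between profiles. Rows are sorted by label before
#' clustering so the result is invariant (up to isomorphism) under input
#' permutation, and merge ties resolve deterministically towards
#' lexicographically smaller labels. No row centering or scaling is
#' applied.
#'
#' @param profiles Numeric matrix, strains x categories, rownames required
#'   for meaningful output.
#' @return An object of class `cib_dendrogram`: list with `hclust` (the
#'   [stats::hclust()] tree), `merges` (data frame: members of the two
#'   merged clusters and the merge height), `labels`, and `newick` (the
#'   tree in Newick format, branch lengths from merge heights).
#' @export
average_linkage_cluster <- function(profiles) {
  if (is.null(dim(profiles)) || nrow(profiles) < 2L) {
    stop("need at least 2 strains to cluster", call. = FALSE)
  }
  if (is.null(rownames(profiles))) {
    rownames(profiles) <- paste0("strain", seq_len(nrow(profiles)))
  }
  profiles <- profiles[order(rownames(profiles)), , drop = FALSE]
  d <- profile_dist(profiles)
  hc <- stats::hclust(d, method = "average")
  merges <- hclust_merge_table(hc)
  phy <- ape::as.phylo(hc)
  newick <- ape::write.tree(phy)
  structure(
    list(hclust = hc, merges = merges, labels = hc$labels, newick = newick),
    class = "cib_dendrogram"
  )
}

# Flatten an hclust merge matrix into a readable merge table.
hclust_merge_table <- function(hc) {
  n <- length(hc$labels)
  members <- vector("list", nrow(hc$merge))
  get_members <- function(id) {
    if (id < 0) hc$labels[-id] else members[[id]]
  }
  out <- vector("list", nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    a <- get_members(hc$merge[s, 1L])
    b <- get_members(hc$merge[s, 2L])
    members[[s]] <- sort(c(a, b))
    out[[s]] <- data.frame(
      step = s,
      cluster_a = paste(sort(a), collapse = ","),
      cluster_b = paste(sort(b), collapse = ","),
      height = hc$height[s],
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' @export
print.cib_dendrogram <- function(x, ...) {
  cat("average-linkage dendrogram over", length(x$labels), "strains\n")
  print(x$merges)
  invisible(x)
}

#' Write a dendrogram as a Newick file
#' @param dend A `cib_dendrogram`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(dend, path) {
  writeLines(dend$newick, path)
  invisible(path)
}
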