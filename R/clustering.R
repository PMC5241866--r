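#' @include AllClasses.R
NULL

#' Agglomerative hierarchical clustering of expression profiles
#'
#' Clusters rows with distance `1 - Pearson r` and average linkage — the
#' classic configuration for time-course expression heat maps — using
#' Lance-Williams updates so the linkage is exact. Tie-breaking is fully
#' deterministic: clusters are indexed in creation order (leaves first,
#' then merges), and among equally close pairs the lexicographically
#' smallest `(i, j)` index pair merges first. The leaf order comes from a
#' recursive left-before-right traversal of the merge tree.
#'
#' Rows should already be preprocessed with [preprocessForClustering()];
#' zero-variance rows make the Pearson distance undefined and are an error
#' here.
#'
#' @param tab numeric matrix, >= 2 rows and >= 2 columns, with rownames.
#' @param distance only `"pearson"` is implemented.
#' @param linkage only `"average"` is implemented.
#' @return a [ClusterTree-class].
#' @examples
#' tab <- rbind(A = c(1, 2, 3), B = c(2, 4, 6), C = c(3, 2, 1))
#' tr <- hcluster(tab)        # A,B merge at height 0; C joins at height 2
#' clusterHeights(tr)
#' @export
hcluster <- function(tab, distance = c("pearson"), linkage = c("average")) {
  match.arg(distance); match.arg(linkage)
  tab <- as.matrix(tab)
  n <- nrow(tab)
  if (n < 2L) .stopf("need at least 2 rows to cluster")
  if (ncol(tab) < 2L) .stopf("need at least 2 columns to cluster")
  labels <- rownames(tab)
  if (is.null(labels)) labels <- sprintf("row%d", seq_len(n))
  ## cor() warns on zero-variance rows before producing NA; we raise the
  ## proper error below instead
  D <- 1 - suppressWarnings(stats::cor(t(tab)))
  if (any(is.na(D)))
    .stopf("Pearson distance undefined (zero-variance rows?); run preprocessForClustering first")
  ## active clusters kept in creation order; hclust node codes alongside
  M <- D
  diag(M) <- Inf
  code <- -seq_len(n)
  size <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    up <- M
    up[lower.tri(up, diag = TRUE)] <- Inf
    dmin <- min(up)
    hit <- which(up == dmin, arr.ind = TRUE)
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    i <- hit[1L, 1L]; j <- hit[1L, 2L]
    merge[s, ] <- c(code[i], code[j])
    height[s] <- max(dmin, 0)
    if (s < n - 1L) {
      newd <- (size[i] * M[i, ] + size[j] * M[j, ]) / (size[i] + size[j])
      keep <- setdiff(seq_along(code), c(i, j))
      M <- rbind(cbind(M[keep, keep, drop = FALSE], newd[keep]),
                 c(newd[keep], Inf))
      code <- c(code[keep], s)
      size <- c(size[keep], size[i] + size[j])
    }
  }
  ord <- integer(0)
  walk <- function(k) {
    if (k < 0L) ord <<- c(ord, -k)
    else { walk(merge[k, 1L]); walk(merge[k, 2L]) }
  }
  walk(n - 1L)
  methods::new("ClusterTree", merge = merge, height = height,
               order = as.integer(ord), labels = labels)
}

#' @export
setMethod("leafOrder", "ClusterTree", function(x)
  stats::setNames(x@order, x@labels[x@order]))

#' @export
setMethod("clusterMerges", "ClusterTree", function(x) x@merge)

#' @export
setMethod("clusterHeights", "ClusterTree", function(x) x@height)

#' Coerce a ClusterTree to a stats::hclust object
#'
#' Allows plotting and cutting with the standard tools
#' (`plot`, `stats::cutree`, heat-map annotation).
#' @param x a [ClusterTree-class].
#' @param ... ignored.
#' @export
as.hclust.ClusterTree <- function(x, ...) {
  structure(list(merge = x@merge, height = x@height, order = x@order,
                 labels = x@labels, method = "average",
                 dist.method = "1 - Pearson r"),
            class = "hclust")
}

#' Write a ClusterTree as a merge-list TSV plus leaf order
#'
#' The merge list has one row per merge (`node_i`, `node_j`, `height`;
#' negative nodes are leaves); a companion `<path>.leaves` file holds the
#' leaf order, one label per line.
#' @param x a [ClusterTree-class].
#' @param path output TSV.
#' @export
writeClusterTree <- function(x, path) {
  lines <- c("node_i\tnode_j\theight",
             sprintf("%d\t%d\t%s", x@merge[, 1L], x@merge[, 2L],
                     .fmtNum(x@height)))
  writeLines(lines, path)
  writeLines(x@labels[x@order], paste0(path, ".leaves"))
  invisible(path)
}
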