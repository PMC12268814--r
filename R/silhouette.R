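#' Mean silhouette score of labelled points
#'
#' For each point *i* with cluster label *l(i)*, let `a_i` be the mean
#' Euclidean distance from *i* to the other points of its own cluster and
#' `b_i` the smallest, over the other clusters, of the mean distance from
#' *i* to that cluster's points. The silhouette of *i* is
#' \eqn{s_i = (b_i - a_i) / \max(a_i, b_i)} and the mean silhouette score
#' (MSS) is the average of the `s_i`. MSS lies in \[-1, 1\]; values near 1
#' indicate tight, well-separated clusters, values near 0 overlapping ones.
#' It is used both to score single features for inter-target separability
#' and as the clustering-based inter-target distance for assay ranking.
#'
#' @param x numeric matrix (rows are points) or vector (1-D points).
#' @param labels cluster labels, one per point; at least two clusters, each
#'   with at least two points.
#' @return The mean silhouette score, a single number in \[-1, 1\].
#' @examples
#' mean_silhouette(c(0, 1, 2, 3), c("a", "a", "b", "b"))  # 7/15
#' @export
mean_silhouette <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (nrow(x) != length(labels))
    stop("labels must have one entry per point")
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least 2 clusters")
  if (any(tab < 2))
    stop("singleton cluster(s): ",
         paste(names(tab)[tab < 2], collapse = ", "),
         " (a_i undefined)")
  d <- as.matrix(stats::dist(x))
  ulab <- names(tab)
  n <- nrow(x)
  s <- numeric(n)
  # mean distance from each point to each cluster
  md <- vapply(ulab, function(l) rowMeans(d[, labels == l, drop = FALSE]),
               numeric(n))
  for (i in seq_len(n)) {
    li <- labels[i]
    ni <- tab[[li]]
    a_i <- md[i, li] * ni / (ni - 1)  # exclude self from own-cluster mean
    b_i <- min(md[i, setdiff(ulab, li)])
    m <- max(a_i, b_i)
    s[i] <- if (m > 0) (b_i - a_i) / m else 0
  }
  mean(s)
}

#' Inter-target separability of a single feature
#'
#' The mean silhouette score of one feature column under the natural target
#' labels: how well this feature alone separates the targets.
#'
#' @param features numeric matrix or data frame of features (columns named).
#' @param labels target labels, one per row.
#' @param feature name of the feature column to score.
#' @return Mean silhouette score of the 1-D feature values.
#' @export
feature_mss <- function(features, labels, feature) {
  features <- as.data.frame(features)
  if (!feature %in% names(features))
    stop("unknown feature: ", feature)
  v <- features[[feature]]
  if (any(!is.finite(v))) stop("feature contains non-finite values")
  mean_silhouette(matrix(v, ncol = 1), labels)
}
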