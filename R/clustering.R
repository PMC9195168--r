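# Hierarchical classification of the 2n recovery vectors: UPGMA linkage,
# silhouette-based choice of the class count, and healthy/pathological
# labeling by control-hemisphere majority.

#' UPGMA agglomerative clustering
#'
#' Hierarchical clustering with Euclidean pairwise distances and
#' unweighted-average (UPGMA) linkage,
#' \deqn{d(A \cup B, C) = \frac{|A| d(A,C) + |B| d(B,C)}{|A| + |B|},}
#' i.e. the unweighted mean of all pairwise member distances. Ties are
#' broken by the smallest (index_a, index_b) pair, indexing clusters by
#' their smallest original member. Merge heights are non-decreasing
#' (UPGMA is monotone), which is asserted on every run.
#'
#' @param mat numeric matrix, one observation per row (or a `dist`).
#' @return a [Dendrogram-class].
#' @export
#' @examples
#' d <- upgmaLinkage(matrix(c(0, 1, 10), ncol = 1))
#' d   # merges {0,1} at height 1, then {10} at (10 + 9) / 2 = 9.5
upgmaLinkage <- function(mat) {
  D <- if (inherits(mat, "dist")) as.matrix(mat) else {
    if (any(!is.finite(mat))) stop("rows with non-finite values are not allowed")
    as.matrix(stats::dist(mat))
  }
  n <- nrow(D)
  stopifnot(n >= 2)
  diag(D) <- Inf
  size <- rep(1L, n)
  minMember <- seq_len(n)            # tie-break key: smallest original member
  nodeId <- -seq_len(n)              # hclust convention: negative = leaf
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  msize <- integer(n - 1)
  for (step in seq_len(n - 1)) {
    act <- which(active)
    # smallest distance; ties by smallest (minMember_a, minMember_b)
    sub <- D[act, act, drop = FALSE]
    h <- min(sub)
    cand <- which(sub - h <= 0, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- cbind(pmin(minMember[act][cand[, 1]], minMember[act][cand[, 2]]),
                 pmax(minMember[act][cand[, 1]], minMember[act][cand[, 2]]))
    pick <- order(key[, 1], key[, 2])[1]
    i <- act[cand[pick, 1]]; j <- act[cand[pick, 2]]
    if (minMember[j] < minMember[i]) { tmp <- i; i <- j; j <- tmp }
    merge[step, ] <- c(nodeId[i], nodeId[j])
    height[step] <- h
    # UPGMA update into slot i
    others <- act[act != i & act != j]
    if (length(others)) {
      newd <- (size[i] * D[i, others] + size[j] * D[j, others]) / (size[i] + size[j])
      D[i, others] <- newd; D[others, i] <- newd
    }
    size[i] <- size[i] + size[j]
    msize[step] <- size[i]
    minMember[i] <- min(minMember[i], minMember[j])
    nodeId[i] <- step
    active[j] <- FALSE
    D[j, ] <- Inf; D[, j] <- Inf
  }
  stopifnot(all(diff(height) >= -1e-9))
  new("Dendrogram", merge = merge, height = height, size = msize,
      leafCount = as.integer(n))
}

#' Convert a Dendrogram to an `hclust` object
#' @param dend a [Dendrogram-class].
#' @return an object of class `hclust` (plottable).
#' @export
asHclust <- function(dend) {
  n <- dend@leafCount
  # build a leaf order by walking the tree
  collect <- function(node) {
    if (node < 0) return(-node)
    c(collect(dend@merge[node, 1]), collect(dend@merge[node, 2]))
  }
  structure(list(merge = dend@merge, height = dend@height,
                 order = collect(n - 1L), labels = as.character(seq_len(n)),
                 method = "average", dist.method = "euclidean"),
            class = "hclust")
}

#' Cut a dendrogram into k clusters
#'
#' Removes the (k - 1) largest merge heights, i.e. keeps the first
#' `leafCount - k` merges of the agglomeration.
#'
#' @param dend a [Dendrogram-class].
#' @param k number of clusters (1..leafCount).
#' @return integer cluster ids (1..k), numbered by first appearance.
#' @export
cutDendrogram <- function(dend, k) {
  n <- dend@leafCount
  if (k > n) stop("k exceeds the number of leaves")
  assign <- seq_len(n)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  nodeRep <- integer(n - 1)
  nm <- n - k
  if (nm > 0) {
    for (s in seq_len(nm)) {
      a <- dend@merge[s, 1]; b <- dend@merge[s, 2]
      ra <- if (a < 0) find(-a) else find(nodeRep[a])
      rb <- if (b < 0) find(-b) else find(nodeRep[b])
      parent[rb] <- ra
      nodeRep[s] <- ra
    }
  } else {
    nodeRep <- integer(0)
  }
  reps <- vapply(seq_len(n), find, integer(1))
  as.integer(factor(reps, levels = unique(reps)))
}

# per-point silhouette widths s(i) = (b - a) / max(a, b); singletons and
# 0/0 give 0
silhouetteWidths <- function(D, assignment) {
  n <- nrow(D)
  ks <- sort(unique(assignment))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- assignment[i]
    sameIdx <- which(assignment == own)
    if (length(sameIdx) == 1) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(sameIdx, i)])
    b <- min(vapply(setdiff(ks, own), function(kk)
      mean(D[i, assignment == kk]), numeric(1)))
    denom <- max(a, b)
    s[i] <- if (denom == 0) 0 else (b - a) / denom
  }
  s
}

#' Mean silhouette across candidate class counts
#'
#' For each k in `kMin:kMax`, cuts the dendrogram into k clusters and
#' computes the mean silhouette width
#' \eqn{s(i) = (b_i - a_i) / \max(a_i, b_i)} under Euclidean distance in
#' the same feature space the clustering used. Singleton clusters and 0/0
#' contribute 0.
#'
#' @param mat the feature matrix the dendrogram was built from.
#' @param dend its [Dendrogram-class].
#' @param kMin,kMax scanned range of class counts (default 2..5).
#' @return data.frame with columns `k`, `meanSilhouette` and attribute
#'   `bestK` (argmax, ties to the smallest k).
#' @export
silhouetteByK <- function(mat, dend, kMin = 2L, kMax = 5L) {
  if (kMax > dend@leafCount) stop("kMax exceeds the number of observations")
  D <- as.matrix(stats::dist(mat))
  ks <- seq.int(kMin, kMax)
  msil <- vapply(ks, function(k)
    mean(silhouetteWidths(D, cutDendrogram(dend, k))), numeric(1))
  prof <- data.frame(k = ks, meanSilhouette = msil)
  attr(prof, "bestK") <- ks[which.max(msil)] # which.max takes first -> smallest k
  prof
}

#' Silhouette-optimal class count
#' @param profile a profile from [silhouetteByK()].
#' @return integer k attaining the maximum mean silhouette (ties ->
#'   smallest k).
#' @export
selectK <- function(profile) {
  stopifnot(nrow(profile) > 0)
  as.integer(profile$k[which.max(profile$meanSilhouette)])
}

#' Label binary clusters healthy / pathological by hemisphere majority
#'
#' The cluster holding the strict majority of its members in the right
#' (control) hemisphere is labeled `"H"`, the other `"P"`. If both
#' clusters have a right majority (or both a left majority) the one with
#' the larger right fraction becomes `"H"` and a warning flags the
#' degenerate classification; an exact tie is broken by the mean fitted
#' T2 of the member voxels (higher T2 is `"P"`).
#'
#' @param assignment integer cluster ids (2 clusters).
#' @param selection the [VoxelSelection-class] the rows refer to.
#' @param t2map optional [ParameterMap-class] for the tie-break.
#' @param profile,dend optional silhouette profile / dendrogram to store.
#' @return a [ClassificationResult-class].
#' @export
labelByHemisphere <- function(assignment, selection, t2map = NULL,
                              profile = NULL, dend = NULL) {
  ks <- sort(unique(assignment))
  if (length(ks) != 2) stop("binary assignment required (k = 2)")
  rightFrac <- vapply(ks, function(kk)
    mean(selection@hemisphere[assignment == kk] == "right"), numeric(1))
  if (abs(rightFrac[1] - rightFrac[2]) < 1e-12) {
    if (is.null(t2map)) stop("tied hemisphere majority and no T2 map for the tie-break")
    meanT2 <- vapply(ks, function(kk) {
      co <- selection@coords[assignment == kk, , drop = FALSE]
      mean(tauImage(t2map)[co], na.rm = TRUE)
    }, numeric(1))
    hIdx <- which.min(meanT2)
  } else {
    hIdx <- which.max(rightFrac)
    if (all(rightFrac > 0.5))
      warning("both clusters have a right-hemisphere majority; ",
              "labeling the larger right-fraction cluster H")
    if (all(rightFrac < 0.5))
      warning("both clusters have a left-hemisphere majority; ",
              "labeling the larger right-fraction cluster H")
  }
  mapping <- stats::setNames(rep("P", 2), as.character(ks))
  mapping[as.character(ks[hIdx])] <- "H"
  labels <- unname(mapping[as.character(assignment)])
  if (is.null(profile))
    profile <- data.frame(k = 2L, meanSilhouette = NA_real_)
  if (is.null(dend)) {
    dend <- new("Dendrogram", merge = matrix(c(-1L, -2L), 1),
                height = 0, size = 2L, leafCount = 2L)
  }
  bk <- attr(profile, "bestK")
  new("ClassificationResult", labels = labels,
      clusterAssignment = as.integer(assignment), kUsed = 2L,
      profile = as.data.frame(profile),
      bestK = as.integer(if (is.null(bk)) 2L else bk),
      mapping = mapping, dendrogram = dend, selection = selection)
}

#' Classify the 2n voxels into healthy vs pathological tissue
#'
#' End-to-end classification step: extract the raw T1-recovery matrix,
#' build the UPGMA dendrogram, scan the mean silhouette over k = kMin..kMax,
#' select the silhouette-optimal k (asserting a binary classification: if
#' the optimum is not 2 the analysis proceeds with 2 classes and warns),
#' and label the two clusters by control-hemisphere majority.
#' Deterministic.
#'
#' @param t1series co-registered T1 [RelaxationSeries-class].
#' @param t2map fitted T2 [ParameterMap-class].
#' @param selection 2n-voxel [VoxelSelection-class] (selected + mirrored).
#' @param kMin,kMax silhouette scan range.
#' @return a [ClassificationResult-class].
#' @export
classifyVoxels <- function(t1series, t2map, selection, kMin = 2L, kMax = 5L) {
  if (selection@nSelected < 2) stop("need at least 2 selected voxels")
  m <- extractRecoveryMatrix(t1series, selection)
  dend <- upgmaLinkage(m)
  prof <- silhouetteByK(m, dend, kMin, min(kMax, nrow(m)))
  k <- selectK(prof)
  if (k != 2)
    warning("silhouette optimum at k = ", k,
            "; proceeding with the binary classification (k = 2)")
  assignment <- cutDendrogram(dend, 2L)
  labelByHemisphere(assignment, selection, t2map, profile = prof, dend = dend)
}
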