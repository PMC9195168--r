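# Shared fixtures and independent oracles. Oracles deliberately use naive
# direct computations (loops over the definitions) so they share no code
# path with the package implementations they check.

smallPhantom <- function(seed = 3, shape = "circular", area = 60,
                         grid = c(64L, 64L), rimWidthPx = 0, rimMix = 0.5) {
  generatePhantom(phantomSpec(grid = grid, lesionShape = shape,
                              lesionAreaPx = area, rimWidthPx = rimWidthPx,
                              rimMix = rimMix, seed = seed))
}

# naive UPGMA: at every step recompute every average inter-cluster
# distance directly from the original pairwise distances (O(n^4))
naiveUPGMAHeights <- function(mat) {
  D0 <- as.matrix(dist(mat))
  clusters <- as.list(seq_len(nrow(mat)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- NULL; bestd <- Inf
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      dd <- mean(D0[clusters[[i]], clusters[[j]]])
      if (dd < bestd - 1e-12) { bestd <- dd; best <- c(i, j) }
    }
    heights <- c(heights, bestd)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  heights
}

# direct silhouette formula, point by point
naiveSilhouette <- function(mat, assignment) {
  D <- as.matrix(dist(mat))
  n <- nrow(D)
  out <- numeric(n)
  for (i in seq_len(n)) {
    mine <- which(assignment == assignment[i])
    if (length(mine) == 1) { out[i] <- 0; next }
    a <- sum(D[i, mine]) / (length(mine) - 1)
    b <- Inf
    for (k in setdiff(unique(assignment), assignment[i])) {
      other <- which(assignment == k)
      b <- min(b, sum(D[i, other]) / length(other))
    }
    out[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  out
}

# per-voxel confusion tally, one voxel at a time
naiveConfusion <- function(labels, coords, trueMask) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(labels)) {
    inside <- trueMask[coords[i, 1], coords[i, 2]] > 0
    if (labels[i] == "P" && inside) tp <- tp + 1L
    if (labels[i] == "P" && !inside) fp <- fp + 1L
    if (labels[i] == "H" && inside) fn <- fn + 1L
    if (labels[i] == "H" && !inside) tn <- tn + 1L
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# build a VoxelSelection directly (bypassing selection logic) for scoring
# and labeling tests
manualSelection <- function(coords, midline, maskDim = c(20L, 20L)) {
  mask <- matrix(1, maskDim[1], maskDim[2])
  co <- matrix(as.integer(coords), ncol = 2,
               dimnames = list(NULL, c("row", "col")))
  new("VoxelSelection", coords = co,
      hemisphere = ifelse(co[, 2] > midline, "left", "right"),
      origin = rep("selected", nrow(co)), nSelected = nrow(co),
      midlineCol = midline, brainMask = mask)
}

# fitted T2 map + auto 2n selection for a phantom; the standard front half
# of the pipeline used by several tests
fitAndSelect <- function(ph, noiseSigma = 0, n = 12, seed = 7,
                         windowMarginPx = 5) {
  s2 <- simulateSeries(ph, acquisitionProtocol("t2_series",
                                               noiseSigma = noiseSigma,
                                               seed = seed))
  m2 <- fitMap(s2)
  tau <- tauImage(m2); tau[is.na(tau)] <- 0
  mid <- estimateMidline(tau, brainMask(ph))
  sel <- selectSuspectVoxels(m2, "auto", n = n, midline = mid,
                             brainMask = brainMask(ph),
                             windowMarginPx = windowMarginPx)
  list(map = m2, midline = mid, selection = mirrorContralateral(sel))
}

# wrap externally chosen labels in a valid ClassificationResult
fakeResult <- function(labels, selection) {
  assign <- ifelse(labels == "H", 1L, 2L)
  mapping <- c("1" = "H", "2" = "P")
  dend <- new("Dendrogram", merge = matrix(c(-1L, -2L), 1), height = 0,
              size = 2L, leafCount = 2L)
  new("ClassificationResult", labels = labels,
      clusterAssignment = assign, kUsed = 2L,
      profile = data.frame(k = 2L, meanSilhouette = NA_real_),
      bestK = 2L, mapping = mapping, dendrogram = dend,
      selection = selection)
}
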