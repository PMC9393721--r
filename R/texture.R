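# Texture matrices and features: GLCM, GLRLM, GLSZM.
# All matrices are aggregated over the 13 unique 3D directions (pairs counted
# in both orders for the GLCM, i.e. the 26-neighbourhood) and features are
# computed once from the aggregated matrix.

#' @keywords internal
shift_pairs <- function(lev, off) {
  # Returns the level pairs (a, b) for voxels v and v + off, both inside the
  # ROI, as a 2-column matrix. `lev` carries NA outside the ROI.
  d <- dim(lev)
  x1 <- max(1L, 1L - off[1]); x2 <- min(d[1], d[1] - off[1])
  y1 <- max(1L, 1L - off[2]); y2 <- min(d[2], d[2] - off[2])
  z1 <- max(1L, 1L - off[3]); z2 <- min(d[3], d[3] - off[3])
  if (x1 > x2 || y1 > y2 || z1 > z2) return(NULL)
  a <- lev[x1:x2, y1:y2, z1:z2, drop = FALSE]
  b <- lev[(x1:x2) + off[1], (y1:y2) + off[2], (z1:z2) + off[3], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NULL)
  cbind(a[ok], b[ok])
}

#' Gray-level co-occurrence matrix
#'
#' Counts of level pairs at the given offset distance along each direction,
#' accumulated in both orders (symmetric) over all directions, then
#' normalized to probabilities.
#'
#' @param d a \code{\link{discretize}}d ROI.
#' @param distance offset length in voxels (default 1).
#' @param directions matrix of direction offsets (default all 13).
#' @return \code{n_g x n_g} probability matrix (entries >= 0, sums to 1).
#' @export
glcm_matrix <- function(d, distance = 1L, directions = texture_directions()) {
  ng <- d$n_g
  counts <- matrix(0, ng, ng)
  for (r in seq_len(nrow(directions))) {
    pr <- shift_pairs(d$levels, directions[r, ] * as.integer(distance))
    if (is.null(pr)) next
    tab <- tabulate(pr[, 1] + ng * (pr[, 2] - 1L), nbins = ng * ng)
    m <- matrix(tab, ng, ng)
    counts <- counts + m + t(m)
  }
  if (sum(counts) == 0)
    stop_data("no valid voxel pairs at this distance")
  counts / sum(counts)
}

#' GLCM feature roster
#'
#' Computes 26 features from the aggregated symmetric GLCM: joint statistics
#' (maximum, average, variance, entropy, energy), contrast-family statistics
#' (contrast, dissimilarity, four inverse-difference variants, inverse
#' variance), correlation-family statistics (correlation, autocorrelation,
#' cluster tendency/shade/prominence), sum- and difference-distribution
#' statistics, the two information measures of correlation and the maximal
#' correlation coefficient. With a single occupied gray level the correlation
#' is 1 by convention and both information measures are 0.
#'
#' @param d a \code{\link{discretize}}d ROI.
#' @param distance offset distance in voxels.
#' @param directions direction set (default all 13).
#' @return named numeric vector of length 26.
#' @export
glcm_features <- function(d, distance = 1L,
                          directions = texture_directions()) {
  P <- glcm_matrix(d, distance, directions)
  glcm_features_from_matrix(P)
}

#' @keywords internal
glcm_features_from_matrix <- function(P) {
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  pi_ <- rowSums(P)
  mu <- sum(i * P)
  sigma2 <- sum((i - mu)^2 * P)
  nz <- P > 0
  ent <- -sum(P[nz] * log2(P[nz]))

  # sum and difference distributions
  ksum <- as.vector(i + j); kdiff <- as.vector(abs(i - j))
  psum <- tapply(as.vector(P), ksum, sum)         # k = 2..2ng
  pdiff <- tapply(as.vector(P), kdiff, sum)       # k = 0..ng-1
  ks <- as.numeric(names(psum)); kd <- as.numeric(names(pdiff))
  sa <- sum(ks * psum); sv <- sum((ks - sa)^2 * psum)
  se <- -sum(psum[psum > 0] * log2(psum[psum > 0]))
  da <- sum(kd * pdiff); dv <- sum((kd - da)^2 * pdiff)
  de <- -sum(pdiff[pdiff > 0] * log2(pdiff[pdiff > 0]))

  corr <- if (sigma2 <= 0) 1 else (sum(i * j * P) - mu^2) / sigma2

  # information measures (HX = HY by symmetry)
  pij <- outer(pi_, pi_)
  okm <- P > 0 & pij > 0
  hxy1 <- -sum(P[okm] * log2(pij[okm]))
  okp <- pij > 0
  hxy2 <- -sum(pij[okp] * log2(pij[okp]))
  hx <- -sum(pi_[pi_ > 0] * log2(pi_[pi_ > 0]))
  imc1 <- if (hx > 0) (ent - hxy1) / hx else 0
  imc2 <- if (hx > 0) sqrt(max(0, 1 - exp(-2 * (hxy2 - ent)))) else 0

  # maximal correlation coefficient: sqrt of the second eigenvalue of
  # Q(a,b) = sum_k P(a,k) P(b,k) / (p_a p_k), over occupied levels
  occ <- which(pi_ > 0)
  mcc <- if (length(occ) < 2L) 1 else {
    Psub <- P[occ, occ, drop = FALSE]
    psub <- pi_[occ]
    A <- sweep(Psub, 2, psub, `/`)
    Q <- (A %*% t(Psub)) / psub
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, min(1, ev[2])))
  }

  c(JointMaximum = max(P),
    JointAverage = mu,
    JointVariance = sigma2,
    Entropy = ent,
    Energy = sum(P^2),
    Contrast = sum((i - j)^2 * P),
    Dissimilarity = sum(abs(i - j) * P),
    InverseDifference = sum(P / (1 + abs(i - j))),
    InverseDifferenceNorm = sum(P / (1 + abs(i - j) / ng)),
    InverseDifferenceMoment = sum(P / (1 + (i - j)^2)),
    InverseDifferenceMomentNorm = sum(P / (1 + ((i - j) / ng)^2)),
    InverseVariance = sum(P[i != j] / (i[i != j] - j[i != j])^2),
    Correlation = corr,
    Autocorrelation = sum(i * j * P),
    ClusterTendency = sum((i + j - 2 * mu)^2 * P),
    ClusterShade = sum((i + j - 2 * mu)^3 * P),
    ClusterProminence = sum((i + j - 2 * mu)^4 * P),
    SumAverage = sa, SumVariance = sv, SumEntropy = se,
    DifferenceAverage = da, DifferenceVariance = dv, DifferenceEntropy = de,
    IMC1 = imc1, IMC2 = imc2, MCC = mcc)
}

#' Gray-level run-length matrix
#'
#' Runs of consecutive equal levels along each direction; voxels outside the
#' ROI break runs. Matrices from the requested directions are summed.
#'
#' @param d a \code{\link{discretize}}d ROI.
#' @param directions direction set (default all 13).
#' @return list with \code{matrix} (n_g x max run length counts),
#'   \code{n_runs}, \code{n_directions}, \code{n_voxels}.
#' @export
glrlm_matrix <- function(d, directions = texture_directions()) {
  lev <- d$levels
  dd <- dim(lev)
  pos <- which(!is.na(lev), arr.ind = TRUE)
  lv <- lev[!is.na(lev)]
  maxlen <- max(dd)
  counts <- matrix(0, d$n_g, maxlen)
  for (r in seq_len(nrow(directions))) {
    o <- directions[r, ]
    k <- sum(o != 0L)
    t_par <- as.vector(pos %*% o)   # increases by k per step along a line
    line <- pos * k - outer(t_par, o)  # constant integer triple per line
    B <- 16 * maxlen
    key <- (line[, 1] + 8 * maxlen) * B^2 +
           (line[, 2] + 8 * maxlen) * B +
           (line[, 3] + 8 * maxlen)
    ord <- order(key, t_par)
    kk <- key[ord]; tv <- t_par[ord]; ll <- lv[ord]
    n <- length(ord)
    newrun <- c(TRUE, kk[-1] != kk[-n] | tv[-1] != tv[-n] + k |
                      ll[-1] != ll[-n])
    rid <- cumsum(newrun)
    rl <- tabulate(rid)
    rlev <- ll[newrun]
    tb <- tabulate(rlev + d$n_g * (rl - 1L), nbins = d$n_g * maxlen)
    counts <- counts + matrix(tb, d$n_g, maxlen)
  }
  list(matrix = counts, n_runs = sum(counts),
       n_directions = nrow(directions), n_voxels = d$n_voxels)
}

#' GLRLM feature roster (18 features)
#'
#' Standard run-length statistics (short/long run emphasis, gray-level and
#' run-length non-uniformity and their normalized variants, run percentage,
#' gray-level and run-length variance and entropy, the four joint
#' low/high-gray-level run emphases) plus the mean gray level (GLA) and mean
#' run length (RLA) underlying the two variances.
#'
#' @inheritParams glrlm_matrix
#' @return named numeric vector of length 18.
#' @export
glrlm_features <- function(d, directions = texture_directions()) {
  g <- glrlm_matrix(d, directions)
  R <- g$matrix
  nr <- g$n_runs
  p <- R / nr
  i <- matrix(seq_len(nrow(R)), nrow(R), ncol(R))
  j <- t(matrix(seq_len(ncol(R)), ncol(R), nrow(R)))
  ri <- rowSums(R); rj <- colSums(R)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  nz <- p > 0
  c(SRE = sum(p / j^2),
    LRE = sum(p * j^2),
    GLN = sum(ri^2) / nr,
    GLNN = sum(ri^2) / nr^2,
    RLN = sum(rj^2) / nr,
    RLNN = sum(rj^2) / nr^2,
    RP = nr / (g$n_voxels * g$n_directions),
    GLV = sum(p * (i - mu_i)^2),
    RLV = sum(p * (j - mu_j)^2),
    RE = -sum(p[nz] * log2(p[nz])),
    LGLRE = sum(p / i^2),
    HGLRE = sum(p * i^2),
    SRLGLE = sum(p / (i^2 * j^2)),
    SRHGLE = sum(p * i^2 / j^2),
    LRLGLE = sum(p * j^2 / i^2),
    LRHGLE = sum(p * i^2 * j^2),
    GLA = mu_i,
    RLA = mu_j)
}

#' Gray-level size-zone matrix
#'
#' Zones are 26-connected components of equal gray level within the ROI
#' (connectivity is independent of direction, so there is a single matrix).
#'
#' @param d a \code{\link{discretize}}d ROI.
#' @return list with \code{matrix} (n_g x max zone size counts),
#'   \code{n_zones}, \code{n_voxels}.
#' @export
glszm_matrix <- function(d) {
  lev <- d$levels
  idx <- which(!is.na(lev))
  node <- rep(NA_integer_, length(lev))     # array cell -> node id
  node[idx] <- seq_along(idx)
  dirs <- texture_directions()
  edges <- list()
  for (r in seq_len(nrow(dirs))) {
    o <- dirs[r, ]
    dd <- dim(lev)
    x1 <- max(1L, 1L - o[1]); x2 <- min(dd[1], dd[1] - o[1])
    y1 <- max(1L, 1L - o[2]); y2 <- min(dd[2], dd[2] - o[2])
    z1 <- max(1L, 1L - o[3]); z2 <- min(dd[3], dd[3] - o[3])
    if (x1 > x2 || y1 > y2 || z1 > z2) next
    lin_a <- as.vector(outer(outer((x1:x2), (y1:y2 - 1) * dd[1], `+`),
                             (z1:z2 - 1) * dd[1] * dd[2], `+`))
    lin_b <- as.vector(outer(outer((x1:x2) + o[1],
                                   (y1:y2 - 1 + o[2]) * dd[1], `+`),
                             (z1:z2 - 1 + o[3]) * dd[1] * dd[2], `+`))
    ok <- !is.na(lev[lin_a]) & !is.na(lev[lin_b]) &
      lev[lin_a] == lev[lin_b]
    if (any(ok)) edges[[length(edges) + 1L]] <-
        cbind(node[lin_a[ok]], node[lin_b[ok]])
  }
  g <- igraph::graph_from_edgelist(
    if (length(edges)) do.call(rbind, edges) else matrix(0L, 0, 2),
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)
  sizes <- comp$csize
  zone_level <- lev[idx][match(seq_len(comp$no), comp$membership)]
  maxsz <- max(sizes)
  tb <- tabulate(zone_level + d$n_g * (sizes - 1L), nbins = d$n_g * maxsz)
  list(matrix = matrix(tb, d$n_g, maxsz), n_zones = comp$no,
       n_voxels = d$n_voxels)
}

#' GLSZM feature roster (18 features)
#'
#' Zone-size analogues of the run-length statistics: small/large area
#' emphasis, gray-level and zone-size non-uniformity (GLN, SZN) and their
#' normalized variants, zone percentage, gray-level and zone-size variance
#' and entropy, the four joint emphases, plus the mean gray level (GLA) and
#' mean zone size (ZSA).
#'
#' @param d a \code{\link{discretize}}d ROI.
#' @return named numeric vector of length 18.
#' @export
glszm_features <- function(d) {
  g <- glszm_matrix(d)
  S <- g$matrix
  nzn <- g$n_zones
  p <- S / nzn
  i <- matrix(seq_len(nrow(S)), nrow(S), ncol(S))
  j <- t(matrix(seq_len(ncol(S)), ncol(S), nrow(S)))
  si <- rowSums(S); sj <- colSums(S)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  nz <- p > 0
  c(SAE = sum(p / j^2),
    LAE = sum(p * j^2),
    GLN = sum(si^2) / nzn,
    GLNN = sum(si^2) / nzn^2,
    SZN = sum(sj^2) / nzn,
    SZNN = sum(sj^2) / nzn^2,
    ZP = nzn / g$n_voxels,
    GLV = sum(p * (i - mu_i)^2),
    ZV = sum(p * (j - mu_j)^2),
    ZE = -sum(p[nz] * log2(p[nz])),
    LGLZE = sum(p / i^2),
    HGLZE = sum(p * i^2),
    SALGLE = sum(p / (i^2 * j^2)),
    SAHGLE = sum(p * i^2 / j^2),
    LALGLE = sum(p * j^2 / i^2),
    LAHGLE = sum(p * i^2 * j^2),
    GLA = mu_i,
    ZSA = mu_j)
}
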