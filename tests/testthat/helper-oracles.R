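# Independent brute-force oracles: naive triple-loop enumeration of voxel
# pairs, runs and zones, plus plain-loop feature formulas. Deliberately
# written without reusing any package internals.

oracle_directions <- function() {
  dirs <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    key <- c(dx, dy, dz)
    if (any(vapply(dirs, function(d) all(d == -key), TRUE))) next
    dirs[[length(dirs) + 1L]] <- key
  }
  dirs
}

# lev: 3D integer array with NA outside the ROI
oracle_glcm <- function(lev, ng, distance = 1L, dirs = oracle_directions()) {
  d <- dim(lev)
  counts <- matrix(0, ng, ng)
  for (dir in dirs) {
    o <- dir * distance
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      a <- lev[x, y, z]
      if (is.na(a)) next
      x2 <- x + o[1]; y2 <- y + o[2]; z2 <- z + o[3]
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] ||
          z2 < 1 || z2 > d[3]) next
      b <- lev[x2, y2, z2]
      if (is.na(b)) next
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  }
  counts / sum(counts)
}

oracle_glcm_features <- function(P) {
  ng <- nrow(P)
  mu <- 0
  for (i in 1:ng) for (j in 1:ng) mu <- mu + i * P[i, j]
  s2 <- 0
  for (i in 1:ng) for (j in 1:ng) s2 <- s2 + (i - mu)^2 * P[i, j]
  pi_ <- rowSums(P)
  f <- c(JointMaximum = max(P), JointAverage = mu, JointVariance = s2)
  ent <- 0; en <- 0; ctr <- 0; dis <- 0; id <- 0; idn <- 0; idm <- 0
  idmn <- 0; iv <- 0; ac <- 0; ct <- 0; cs <- 0; cp <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    if (p > 0) ent <- ent - p * log2(p)
    en <- en + p^2
    ctr <- ctr + (i - j)^2 * p
    dis <- dis + abs(i - j) * p
    id <- id + p / (1 + abs(i - j))
    idn <- idn + p / (1 + abs(i - j) / ng)
    idm <- idm + p / (1 + (i - j)^2)
    idmn <- idmn + p / (1 + ((i - j) / ng)^2)
    if (i != j) iv <- iv + p / (i - j)^2
    ac <- ac + i * j * p
    ct <- ct + (i + j - 2 * mu)^2 * p
    cs <- cs + (i + j - 2 * mu)^3 * p
    cp <- cp + (i + j - 2 * mu)^4 * p
  }
  corr <- if (s2 <= 0) 1 else (ac - mu^2) / s2
  psum <- rep(0, 2 * ng); pdiff <- rep(0, ng)  # index k+1 for diff k
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + P[i, j]
  }
  sa <- sum((1:(2 * ng)) * psum)
  sv <- sum(((1:(2 * ng)) - sa)^2 * psum)
  se <- -sum(psum[psum > 0] * log2(psum[psum > 0]))
  da <- sum((0:(ng - 1)) * pdiff)
  dv <- sum(((0:(ng - 1)) - da)^2 * pdiff)
  de <- -sum(pdiff[pdiff > 0] * log2(pdiff[pdiff > 0]))
  hx <- 0
  for (i in 1:ng) if (pi_[i] > 0) hx <- hx - pi_[i] * log2(pi_[i])
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    pp <- pi_[i] * pi_[j]
    if (pp > 0) {
      if (P[i, j] > 0) hxy1 <- hxy1 - P[i, j] * log2(pp)
      hxy2 <- hxy2 - pp * log2(pp)
    }
  }
  imc1 <- if (hx > 0) (ent - hxy1) / hx else 0
  imc2 <- if (hx > 0) sqrt(max(0, 1 - exp(-2 * (hxy2 - ent)))) else 0
  occ <- which(pi_ > 0)
  mcc <- if (length(occ) < 2) 1 else {
    m <- length(occ)
    Q <- matrix(0, m, m)
    for (a in 1:m) for (b in 1:m) {
      s <- 0
      for (k in 1:m)
        s <- s + P[occ[a], occ[k]] * P[occ[b], occ[k]] /
          (pi_[occ[a]] * pi_[occ[k]])
      Q[a, b] <- s
    }
    ev <- sort(Re(eigen(Q)$values), decreasing = TRUE)
    sqrt(max(0, min(1, ev[2])))
  }
  c(f, Entropy = ent, Energy = en, Contrast = ctr, Dissimilarity = dis,
    InverseDifference = id, InverseDifferenceNorm = idn,
    InverseDifferenceMoment = idm, InverseDifferenceMomentNorm = idmn,
    InverseVariance = iv, Correlation = corr, Autocorrelation = ac,
    ClusterTendency = ct, ClusterShade = cs, ClusterProminence = cp,
    SumAverage = sa, SumVariance = sv, SumEntropy = se,
    DifferenceAverage = da, DifferenceVariance = dv, DifferenceEntropy = de,
    IMC1 = imc1, IMC2 = imc2, MCC = mcc)
}

# naive run enumeration: walk every line voxel by voxel
oracle_glrlm <- function(lev, ng, dirs = oracle_directions()) {
  d <- dim(lev)
  maxlen <- max(d)
  counts <- matrix(0, ng, maxlen)
  inside <- function(v) all(v >= 1) && all(v <= d)
  for (dir in dirs) {
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      v <- c(x, y, z)
      a <- lev[x, y, z]
      if (is.na(a)) next
      prev <- v - dir
      prev_in_run <- inside(prev) && !is.na(lev[prev[1], prev[2], prev[3]]) &&
        lev[prev[1], prev[2], prev[3]] == a
      if (prev_in_run) next              # not a run start
      len <- 1
      nxt <- v + dir
      while (inside(nxt) && !is.na(lev[nxt[1], nxt[2], nxt[3]]) &&
             lev[nxt[1], nxt[2], nxt[3]] == a) {
        len <- len + 1
        nxt <- nxt + dir
      }
      counts[a, len] <- counts[a, len] + 1
    }
  }
  counts
}

# flood-fill zone enumeration with an explicit stack (26-connectivity)
oracle_glszm <- function(lev, ng) {
  d <- dim(lev)
  visited <- array(FALSE, d)
  zones <- list()
  neigh <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  neigh <- neigh[rowSums(abs(neigh)) > 0, ]
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (visited[x, y, z] || is.na(lev[x, y, z])) next
    val <- lev[x, y, z]
    stack <- list(c(x, y, z))
    visited[x, y, z] <- TRUE
    size <- 0
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (r in seq_len(nrow(neigh))) {
        w <- v + neigh[r, ]
        if (any(w < 1) || any(w > d)) next
        if (visited[w[1], w[2], w[3]]) next
        lw <- lev[w[1], w[2], w[3]]
        if (is.na(lw) || lw != val) next
        visited[w[1], w[2], w[3]] <- TRUE
        stack[[length(stack) + 1L]] <- w
      }
    }
    zones[[length(zones) + 1L]] <- c(level = val, size = size)
  }
  maxsz <- max(vapply(zones, `[[`, 0, "size"))
  S <- matrix(0, ng, maxsz)
  for (zn in zones) S[zn["level"], zn["size"]] <- S[zn["level"], zn["size"]] + 1
  S
}

oracle_rl_features <- function(R, n_voxels, n_dirs) {
  ng <- nrow(R); nl <- ncol(R)
  nr <- sum(R)
  out <- c(SRE = 0, LRE = 0, GLN = 0, GLNN = 0, RLN = 0, RLNN = 0,
           RP = nr / (n_voxels * n_dirs), GLV = 0, RLV = 0, RE = 0,
           LGLRE = 0, HGLRE = 0, SRLGLE = 0, SRHGLE = 0, LRLGLE = 0,
           LRHGLE = 0, GLA = 0, RLA = 0)
  mu_i <- 0; mu_j <- 0
  for (i in 1:ng) for (j in 1:nl) {
    p <- R[i, j] / nr
    mu_i <- mu_i + i * p; mu_j <- mu_j + j * p
    out["SRE"] <- out["SRE"] + p / j^2
    out["LRE"] <- out["LRE"] + p * j^2
    out["LGLRE"] <- out["LGLRE"] + p / i^2
    out["HGLRE"] <- out["HGLRE"] + p * i^2
    out["SRLGLE"] <- out["SRLGLE"] + p / (i^2 * j^2)
    out["SRHGLE"] <- out["SRHGLE"] + p * i^2 / j^2
    out["LRLGLE"] <- out["LRLGLE"] + p * j^2 / i^2
    out["LRHGLE"] <- out["LRHGLE"] + p * i^2 * j^2
    if (p > 0) out["RE"] <- out["RE"] - p * log2(p)
  }
  for (i in 1:ng) out["GLN"] <- out["GLN"] + sum(R[i, ])^2
  for (j in 1:nl) out["RLN"] <- out["RLN"] + sum(R[, j])^2
  out["GLNN"] <- out["GLN"] / nr^2; out["GLN"] <- out["GLN"] / nr
  out["RLNN"] <- out["RLN"] / nr^2; out["RLN"] <- out["RLN"] / nr
  for (i in 1:ng) for (j in 1:nl) {
    p <- R[i, j] / nr
    out["GLV"] <- out["GLV"] + p * (i - mu_i)^2
    out["RLV"] <- out["RLV"] + p * (j - mu_j)^2
  }
  out["GLA"] <- mu_i; out["RLA"] <- mu_j
  out
}

oracle_sz_features <- function(S, n_voxels) {
  f <- oracle_rl_features(S, n_voxels, 1)
  names(f) <- c("SAE", "LAE", "GLN", "GLNN", "SZN", "SZNN", "ZP", "GLV",
                "ZV", "ZE", "LGLZE", "HGLZE", "SALGLE", "SAHGLE", "LALGLE",
                "LAHGLE", "GLA", "ZSA")
  f
}

# random small ROI for oracle comparisons: levels 1..ng with random holes
random_roi <- function(ng = 4L, shape = c(4L, 4L, 4L), p_roi = 0.8) {
  lev <- array(sample.int(ng, prod(shape), replace = TRUE), shape)
  roi <- array(runif(prod(shape)) < p_roi, shape)
  if (sum(roi) < 2) roi[1:2] <- TRUE
  lev[!roi] <- NA
  lev
}

# wrap a bare level array as a discretized_roi
as_droi <- function(lev, ng) {
  structure(list(levels = lev, n_g = as.integer(ng),
                 range = range(lev, na.rm = TRUE),
                 n_voxels = sum(!is.na(lev)),
                 values = lev[!is.na(lev)]),
            class = "discretized_roi")
}

# exhaustive pairwise AUC oracle
oracle_auc <- function(scores, positive) {
  xs <- scores[positive]; ys <- scores[!positive]
  tot <- 0
  for (x in xs) for (y in ys)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(xs) * length(ys))
}
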