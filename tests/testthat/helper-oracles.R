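# Independent brute-force oracles: every routine here recomputes a quantity
# from its textbook definition with explicit loops, sharing no code with the
# package implementations they check.

# Mutual information of two discrete variables by direct evaluation of
# sum p(x,y) log2( p(x,y) / (p(x) p(y)) ).
oracle_ig <- function(x, y) {
  n <- length(y)
  ig <- 0
  for (xv in unique(x)) for (yv in unique(y)) {
    pxy <- sum(x == xv & y == yv) / n
    if (pxy == 0) next
    ig <- ig + pxy * log2(pxy / ((sum(x == xv) / n) * (sum(y == yv) / n)))
  }
  ig
}

oracle_entropy <- function(labels) {
  n <- length(labels)
  h <- 0
  for (v in unique(labels)) {
    p <- sum(labels == v) / n
    h <- h - p * log2(p)
  }
  h
}

# First-order statistics from their definitions (loops and base R only).
oracle_first_order <- function(values, spacing, p_hist) {
  n <- length(values)
  mu <- sum(values) / n
  m2 <- sum((values - mu)^2) / n
  m3 <- sum((values - mu)^3) / n
  m4 <- sum((values - mu)^4) / n
  q <- quantile(values, c(.1, .25, .5, .75, .9), names = FALSE, type = 7)
  rob <- values[values >= q[1] & values <= q[5]]
  ph <- p_hist[p_hist > 0]
  c(Energy = sum(values^2),
    TotalEnergy = spacing[1] * spacing[2] * sum(values^2),
    Entropy = -sum(ph * log2(ph)),
    Minimum = min(values),
    `10Percentile` = q[1], `90Percentile` = q[5],
    Maximum = max(values), Mean = mu, Median = q[3],
    InterquartileRange = q[4] - q[2], Range = max(values) - min(values),
    MeanAbsoluteDeviation = sum(abs(values - mu)) / n,
    RobustMeanAbsoluteDeviation = sum(abs(rob - mean(rob))) / length(rob),
    RootMeanSquared = sqrt(sum(values^2) / n),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p_hist^2))
}

# GLCM by explicit pixel-pair enumeration for one (dr, dc) offset.
oracle_glcm_matrix <- function(levels, ng, dr, dc) {
  P <- matrix(0, ng, ng)
  nr <- nrow(levels); nc <- ncol(levels)
  for (r in 1:nr) for (c_ in 1:nc) {
    r2 <- r + dr; c2 <- c_ + dc
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    a <- levels[r, c_]; b <- levels[r2, c2]
    if (is.na(a) || is.na(b)) next
    P[a, b] <- P[a, b] + 1
    P[b, a] <- P[b, a] + 1
  }
  if (sum(P) > 0) P / sum(P) else P
}

oracle_glcm_features <- function(P) {
  ng <- nrow(P)
  px <- sapply(1:ng, function(i) sum(P[i, ]))
  py <- sapply(1:ng, function(j) sum(P[, j]))
  mux <- sum((1:ng) * px); muy <- sum((1:ng) * py)
  sdx <- sqrt(sum(((1:ng) - mux)^2 * px))
  sdy <- sqrt(sum(((1:ng) - muy)^2 * py))
  psum <- rep(0, 2 * ng); pdif <- rep(0, ng)
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + P[i, j]
  }
  l2 <- function(q) { s <- 0; for (v in q) if (v > 0) s <- s - v * log2(v); s }
  acor <- cp <- cs <- ct <- con <- je <- hxy <- idm <- idmn <- idf <- idn <-
    iv <- ss <- 0
  hxy1 <- hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    acor <- acor + i * j * p
    cp <- cp + (i + j - mux - muy)^4 * p
    cs <- cs + (i + j - mux - muy)^3 * p
    ct <- ct + (i + j - mux - muy)^2 * p
    con <- con + (i - j)^2 * p
    je <- je + p^2
    if (p > 0) hxy <- hxy - p * log2(p)
    idm <- idm + p / (1 + (i - j)^2)
    idmn <- idmn + p / (1 + ((i - j) / ng)^2)
    idf <- idf + p / (1 + abs(i - j))
    idn <- idn + p / (1 + abs(i - j) / ng)
    if (i != j) iv <- iv + p / (i - j)^2
    ss <- ss + (i - mux)^2 * p
    if (px[i] * py[j] > 0) {
      hxy1 <- hxy1 - p * log2(px[i] * py[j])
      hxy2 <- hxy2 - px[i] * py[j] * log2(px[i] * py[j])
    }
  }
  da <- 0; for (k in 0:(ng - 1)) da <- da + k * pdif[k + 1]
  dv <- 0; for (k in 0:(ng - 1)) dv <- dv + (k - da)^2 * pdif[k + 1]
  sa <- 0; for (k in 2:(2 * ng)) sa <- sa + k * psum[k]
  hx <- l2(px); hy <- l2(py)
  corr <- if (sdx > 0 && sdy > 0) (acor - mux * muy) / (sdx * sdy) else 1
  Q <- matrix(0, ng, ng)
  for (i in 1:ng) for (j in 1:ng) {
    s <- 0
    for (k in 1:ng)
      if (px[i] > 0 && py[k] > 0) s <- s + P[i, k] * P[j, k] / (px[i] * py[k])
    Q[i, j] <- s
  }
  ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
  mcc <- if (ng == 1) 1 else sqrt(max(0, min(1, ev[2])))
  c(Autocorrelation = acor, JointAverage = mux, ClusterProminence = cp,
    ClusterShade = cs, ClusterTendency = ct, Contrast = con,
    Correlation = corr, DifferenceAverage = da, DifferenceEntropy = l2(pdif),
    DifferenceVariance = dv, JointEnergy = je, JointEntropy = hxy,
    IMC1 = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0,
    IMC2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))),
    IDM = idm, IDMN = idmn, ID = idf, IDN = idn, InverseVariance = iv,
    MaximumProbability = max(P), SumAverage = sa, SumEntropy = l2(psum),
    SumSquares = ss, MCC = mcc)
}

oracle_glcm <- function(levels, ng, angles = c(0, 45, 90, 135)) {
  offs <- list("0" = c(0, 1), "45" = c(-1, 1), "90" = c(-1, 0),
               "135" = c(-1, -1))
  acc <- NULL
  for (a in angles) {
    o <- offs[[as.character(a)]]
    f <- oracle_glcm_features(oracle_glcm_matrix(levels, ng, o[1], o[2]))
    acc <- if (is.null(acc)) f else acc + f
  }
  acc / length(angles)
}

# Run enumeration by explicit walking along each direction.
oracle_runs <- function(levels, dr, dc) {
  nr <- nrow(levels); nc <- ncol(levels)
  runs <- list()
  seen <- matrix(FALSE, nr, nc)
  for (r in 1:nr) for (c_ in 1:nc) {
    if (is.na(levels[r, c_]) || seen[r, c_]) next
    # only start a run at a pixel with no same-run predecessor
    pr <- r - dr; pc <- c_ - dc
    prev_same <- pr >= 1 && pr <= nr && pc >= 1 && pc <= nc &&
      !is.na(levels[pr, pc]) && levels[pr, pc] == levels[r, c_]
    if (prev_same) next
    len <- 0; rr <- r; cc <- c_
    while (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
           !is.na(levels[rr, cc]) && levels[rr, cc] == levels[r, c_]) {
      seen[rr, cc] <- TRUE
      len <- len + 1; rr <- rr + dr; cc <- cc + dc
    }
    runs[[length(runs) + 1]] <- c(level = levels[r, c_], len = len)
  }
  runs
}

oracle_rl_features <- function(P, np, names) {
  ng <- nrow(P); ns <- ncol(P)
  nr_tot <- sum(P)
  if (nr_tot == 0) return(setNames(rep(0, 16), names))
  sre <- lre <- lgl <- hgl <- srl <- srh <- lrl <- lrh <- 0
  for (i in 1:ng) for (s in 1:ns) {
    p <- P[i, s]
    sre <- sre + p / s^2; lre <- lre + p * s^2
    lgl <- lgl + p / i^2; hgl <- hgl + p * i^2
    srl <- srl + p / (i^2 * s^2); srh <- srh + p * i^2 / s^2
    lrl <- lrl + p * s^2 / i^2; lrh <- lrh + p * i^2 * s^2
  }
  gln <- 0; for (i in 1:ng) gln <- gln + sum(P[i, ])^2
  rln <- 0; for (s in 1:ns) rln <- rln + sum(P[, s])^2
  mu_i <- 0; mu_s <- 0
  for (i in 1:ng) for (s in 1:ns) {
    mu_i <- mu_i + i * P[i, s] / nr_tot
    mu_s <- mu_s + s * P[i, s] / nr_tot
  }
  glv <- rv <- re <- 0
  for (i in 1:ng) for (s in 1:ns) {
    p <- P[i, s] / nr_tot
    glv <- glv + (i - mu_i)^2 * p
    rv <- rv + (s - mu_s)^2 * p
    if (p > 0) re <- re - p * log2(p)
  }
  setNames(c(sre / nr_tot, lre / nr_tot, gln / nr_tot, gln / nr_tot^2,
             rln / nr_tot, rln / nr_tot^2, nr_tot / np, glv, rv, re,
             lgl / nr_tot, hgl / nr_tot, srl / nr_tot, srh / nr_tot,
             lrl / nr_tot, lrh / nr_tot), names)
}

oracle_glrlm <- function(levels, ng, angles = c(0, 45, 90, 135)) {
  offs <- list("0" = c(0, 1), "45" = c(-1, 1), "90" = c(-1, 0),
               "135" = c(-1, -1))
  np <- sum(!is.na(levels))
  maxlen <- max(dim(levels))
  nms <- c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
           "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
           "RunLengthNonUniformityNormalized", "RunPercentage",
           "GrayLevelVariance", "RunVariance", "RunEntropy",
           "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
           "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
           "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")
  acc <- NULL
  for (a in angles) {
    o <- offs[[as.character(a)]]
    P <- matrix(0, ng, maxlen)
    for (run in oracle_runs(levels, o[1], o[2]))
      P[run["level"], run["len"]] <- P[run["level"], run["len"]] + 1
    f <- oracle_rl_features(P, np, nms)
    acc <- if (is.null(acc)) f else acc + f
  }
  acc / length(angles)
}

# 8-connected zone labeling by BFS flood fill.
oracle_zones <- function(levels) {
  nr <- nrow(levels); nc <- ncol(levels)
  seen <- matrix(FALSE, nr, nc)
  zones <- list()
  for (r in 1:nr) for (c_ in 1:nc) {
    if (is.na(levels[r, c_]) || seen[r, c_]) next
    lev <- levels[r, c_]
    queue <- list(c(r, c_)); seen[r, c_] <- TRUE; size <- 0
    while (length(queue) > 0) {
      q <- queue[[1]]; queue <- queue[-1]; size <- size + 1
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- q[1] + dr; cc <- q[2] + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (seen[rr, cc] || is.na(levels[rr, cc])) next
        if (levels[rr, cc] == lev) {
          seen[rr, cc] <- TRUE
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
    zones[[length(zones) + 1]] <- c(level = lev, size = size)
  }
  zones
}

oracle_glszm <- function(levels, ng) {
  zones <- oracle_zones(levels)
  np <- sum(!is.na(levels))
  ns <- max(1, sapply(zones, function(z) z["size"]))
  P <- matrix(0, ng, ns)
  for (z in zones) P[z["level"], z["size"]] <- P[z["level"], z["size"]] + 1
  nms <- c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
           "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
           "SizeZoneNonUniformityNormalized", "ZonePercentage",
           "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
           "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
           "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
           "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")
  oracle_rl_features(P, np, nms)
}

oracle_gldm <- function(levels, ng, alpha = 0) {
  nr <- nrow(levels); nc <- ncol(levels)
  recs <- list()
  for (r in 1:nr) for (c_ in 1:nc) {
    if (is.na(levels[r, c_])) next
    k <- 1
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c_ + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      if (!is.na(levels[rr, cc]) &&
          abs(levels[rr, cc] - levels[r, c_]) <= alpha) k <- k + 1
    }
    recs[[length(recs) + 1]] <- c(i = levels[r, c_], k = k)
  }
  nd <- max(sapply(recs, function(x) x["k"]))
  P <- matrix(0, ng, nd)
  for (x in recs) P[x["i"], x["k"]] <- P[x["i"], x["k"]] + 1
  nz <- sum(P)
  sde <- lde <- lgl <- hgl <- sdl <- sdh <- ldl <- ldh <- 0
  for (i in 1:ng) for (k in 1:nd) {
    p <- P[i, k]
    sde <- sde + p / k^2; lde <- lde + p * k^2
    lgl <- lgl + p / i^2; hgl <- hgl + p * i^2
    sdl <- sdl + p / (i^2 * k^2); sdh <- sdh + p * i^2 / k^2
    ldl <- ldl + p * k^2 / i^2; ldh <- ldh + p * i^2 * k^2
  }
  gln <- 0; for (i in 1:ng) gln <- gln + sum(P[i, ])^2
  dn <- 0; for (k in 1:nd) dn <- dn + sum(P[, k])^2
  mu_i <- mu_k <- 0
  for (i in 1:ng) for (k in 1:nd) {
    mu_i <- mu_i + i * P[i, k] / nz; mu_k <- mu_k + k * P[i, k] / nz
  }
  glv <- dv <- de <- 0
  for (i in 1:ng) for (k in 1:nd) {
    p <- P[i, k] / nz
    glv <- glv + (i - mu_i)^2 * p
    dv <- dv + (k - mu_k)^2 * p
    if (p > 0) de <- de - p * log2(p)
  }
  c(SmallDependenceEmphasis = sde / nz, LargeDependenceEmphasis = lde / nz,
    GrayLevelNonUniformity = gln / nz, DependenceNonUniformity = dn / nz,
    DependenceNonUniformityNormalized = dn / nz^2, GrayLevelVariance = glv,
    DependenceVariance = dv, DependenceEntropy = de,
    LowGrayLevelEmphasis = lgl / nz, HighGrayLevelEmphasis = hgl / nz,
    SmallDependenceLowGrayLevelEmphasis = sdl / nz,
    SmallDependenceHighGrayLevelEmphasis = sdh / nz,
    LargeDependenceLowGrayLevelEmphasis = ldl / nz,
    LargeDependenceHighGrayLevelEmphasis = ldh / nz)
}

oracle_ngtdm <- function(levels, ng) {
  nr <- nrow(levels); nc <- ncol(levels)
  s_i <- rep(0, ng); n_i <- rep(0, ng); nvp <- 0
  for (r in 1:nr) for (c_ in 1:nc) {
    if (is.na(levels[r, c_])) next
    nb <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c_ + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      if (!is.na(levels[rr, cc])) nb <- c(nb, levels[rr, cc])
    }
    if (length(nb) == 0) next
    nvp <- nvp + 1
    i <- levels[r, c_]
    n_i[i] <- n_i[i] + 1
    s_i[i] <- s_i[i] + abs(i - mean(nb))
  }
  p_i <- n_i / nvp
  act <- which(n_i > 0); ngp <- length(act)
  coarse <- { d <- sum(p_i * s_i); if (d > 0) min(1 / d, 1e6) else 1e6 }
  contrast <- 0
  if (ngp > 1) {
    for (a in act) for (b in act)
      contrast <- contrast + p_i[a] * p_i[b] * (a - b)^2
    contrast <- contrast / (ngp * (ngp - 1)) * sum(s_i) / nvp
  }
  bden <- 0
  for (a in act) for (b in act) bden <- bden + abs(a * p_i[a] - b * p_i[b])
  busy <- if (bden > 0) sum(p_i * s_i) / bden else 0
  cplx <- 0
  if (ngp > 1) {
    for (a in act) for (b in act)
      cplx <- cplx + abs(a - b) * (p_i[a] * s_i[a] + p_i[b] * s_i[b]) /
        (p_i[a] + p_i[b])
    cplx <- cplx / nvp
  }
  stren <- 0
  if (ngp > 1 && sum(s_i) > 0) {
    for (a in act) for (b in act)
      stren <- stren + (p_i[a] + p_i[b]) * (a - b)^2
    stren <- stren / sum(s_i)
  }
  c(Coarseness = coarse, Contrast = contrast, Busyness = busy,
    Complexity = cplx, Strength = stren)
}

# Random small test ROI: a levels matrix with NA border noise and its ng.
random_levels <- function(seed, max_dim = 8, max_ng = 4) {
  set.seed(seed)
  nr <- sample(3:max_dim, 1); nc <- sample(3:max_dim, 1)
  ng <- sample(2:max_ng, 1)
  lev <- matrix(sample(1:ng, nr * nc, replace = TRUE), nr, nc)
  drop <- runif(nr * nc) < 0.2
  # keep at least 4 pixels
  if (sum(!drop) < 4) drop[seq_len(nr * nc) <= 4] <- FALSE
  lev[drop] <- NA
  list(levels = lev, ng = max(lev, na.rm = TRUE))
}
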