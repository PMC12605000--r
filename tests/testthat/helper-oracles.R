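# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementations they check.

# Local entropy recomputed voxel by voxel with an explicit window scan.
naive_local_entropy <- function(img, mask, w = 9L, B = 32L) {
  d <- dim(img)
  r <- (w - 1L) %/% 2L
  v <- img[mask]
  rng <- range(v)
  binof <- function(x) {
    if (diff(rng) < .Machine$double.eps) return(1L)
    min(B, 1L + floor(B * (x - rng[1]) / diff(rng)))
  }
  H <- array(NA_real_, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (!mask[x, y, z]) next
    cnt <- numeric(B)
    for (dx in -r:r) for (dy in -r:r) {
      nx <- x + dx; ny <- y + dy
      if (nx < 1 || nx > d[1] || ny < 1 || ny > d[2]) next
      if (!mask[nx, ny, z]) next
      b <- binof(img[nx, ny, z])
      cnt[b] <- cnt[b] + 1
    }
    p <- cnt[cnt > 0] / sum(cnt)
    H[x, y, z] <- -sum(p * log2(p))
  }
  H
}

# CH index from the definition, written against a plain loop.
naive_ch <- function(X, labels) {
  X <- as.matrix(X)
  N <- nrow(X); K <- length(unique(labels))
  g <- colMeans(X)
  B <- 0; W <- 0
  for (k in unique(labels)) {
    sub <- X[labels == k, , drop = FALSE]
    ck <- colMeans(sub)
    B <- B + nrow(sub) * sum((ck - g)^2)
    for (i in seq_len(nrow(sub))) W <- W + sum((sub[i, ] - ck)^2)
  }
  (B / (K - 1)) / (W / (N - K))
}

naive_silhouette <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    di <- sqrt(rowSums(sweep(X, 2, X[i, ])^2))
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(di[own])
    b <- Inf
    for (l in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(di[labels == l]))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# AUC by explicit pair enumeration (ties count 1/2).
naive_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Youden scan over an explicit cutoff grid.
naive_youden_J <- function(scores, labels) {
  s <- sort(unique(scores))
  cand <- c(min(s) - 1, (s[-1] + s[-length(s)]) / 2, max(s) + 1)
  best <- -Inf
  for (ct in cand) {
    pred <- scores >= ct
    sen <- sum(pred & labels == 1) / sum(labels == 1)
    spe <- sum(!pred & labels == 0) / sum(labels == 0)
    best <- max(best, sen + spe - 1)
  }
  best
}

# Step-interpolated AUPRC by walking the sorted scores.
naive_auprc <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]; sc <- scores[o]
  ths <- unique(sc)
  rec0 <- 0; area <- 0
  for (t in ths) {
    sel <- sc >= t
    prec <- sum(y[sel]) / sum(sel)
    rec <- sum(y[sel]) / sum(y)
    area <- area + (rec - rec0) * prec
    rec0 <- rec
  }
  area
}

# Exact Shapley values by enumerating all coalitions, mean imputation.
naive_shapley <- function(weights, const, x, bg_mean) {
  p <- length(weights)
  fval <- function(S) {
    xi <- bg_mean
    xi[S] <- x[S]
    sum(weights * xi) + const
  }
  phi <- numeric(p)
  idx <- seq_len(p)
  for (f in idx) {
    others <- setdiff(idx, f)
    for (sz in 0:length(others)) {
      combs <- if (sz == 0) list(integer(0)) else
        utils::combn(others, sz, simplify = FALSE)
      for (S in combs) {
        wgt <- factorial(sz) * factorial(p - sz - 1) / factorial(p)
        phi[f] <- phi[f] + wgt * (fval(c(S, f)) - fval(S))
      }
    }
  }
  phi
}

# Brute-force GLCM of a tiny array: explicit pair enumeration.
naive_glcm_iv <- function(img, mask, n_bins, mode = "3D") {
  lev <- habitrad::discretize(img, mask, n_bins)
  d <- dim(img)
  offs <- if (mode == "2D") list(c(1,0,0), c(0,1,0), c(1,1,0), c(1,-1,0))
  else {
    o <- list()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dz > 0 || (dz == 0 && dy > 0) || (dz == 0 && dy == 0 && dx > 0))
        o[[length(o) + 1]] <- c(dx, dy, dz)
    }
    o
  }
  vals <- c()
  for (off in offs) {
    P <- matrix(0, n_bins, n_bins)
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
      if (!mask[x, y, z]) next
      nx <- x + off[1]; ny <- y + off[2]; nz <- z + off[3]
      if (nx < 1 || nx > d[1] || ny < 1 || ny > d[2] || nz < 1 || nz > d[3]) next
      if (!mask[nx, ny, nz]) next
      i <- lev[x, y, z]; j <- lev[nx, ny, nz]
      P[i, j] <- P[i, j] + 1
      P[j, i] <- P[j, i] + 1
    }
    if (sum(P) == 0) next
    P <- P / sum(P)
    s <- 0
    for (i in seq_len(n_bins)) for (j in seq_len(n_bins))
      if (i != j) s <- s + P[i, j] / (i - j)^2
    vals <- c(vals, s)
  }
  mean(vals)
}

# Brute-force dependence counts for the GLDM.
naive_gldm_dnn <- function(img, mask, n_bins, alpha = 0, mode = "3D") {
  lev <- habitrad::discretize(img, mask, n_bins)
  d <- dim(img)
  rng_z <- if (mode == "2D") 0 else -1:1
  deps <- c()
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (!mask[x, y, z]) next
    dep <- 1
    for (dx in -1:1) for (dy in -1:1) for (dz in rng_z) {
      if (dx == 0 && dy == 0 && dz == 0) next
      nx <- x + dx; ny <- y + dy; nz <- z + dz
      if (nx < 1 || nx > d[1] || ny < 1 || ny > d[2] || nz < 1 || nz > d[3]) next
      if (mask[nx, ny, nz] && abs(lev[nx, ny, nz] - lev[x, y, z]) <= alpha)
        dep <- dep + 1
    }
    deps <- c(deps, dep)
  }
  tab <- table(deps)
  sum(as.numeric(tab)^2) / length(deps)^2
}

# Brute-force size zones by repeated flood fill over coordinates.
naive_glszm_sae <- function(img, mask, n_bins, mode = "3D") {
  lev <- habitrad::discretize(img, mask, n_bins)
  d <- dim(img)
  coords <- which(mask, arr.ind = TRUE)
  seen <- rep(FALSE, nrow(coords))
  key <- function(c3) paste(c3, collapse = ",")
  kmap <- stats::setNames(seq_len(nrow(coords)),
                          apply(coords, 1, paste, collapse = ","))
  rng_z <- if (mode == "2D") 0 else -1:1
  sizes <- c()
  for (i in seq_len(nrow(coords))) {
    if (seen[i]) next
    g <- lev[coords[i, 1], coords[i, 2], coords[i, 3]]
    stack <- i; seen[i] <- TRUE; size <- 0
    while (length(stack)) {
      cur <- stack[1]; stack <- stack[-1]; size <- size + 1
      cc <- coords[cur, ]
      for (dx in -1:1) for (dy in -1:1) for (dz in rng_z) {
        if (dx == 0 && dy == 0 && dz == 0) next
        nb <- cc + c(dx, dy, dz)
        j <- kmap[key(nb)]
        if (!is.na(j) && !seen[j] &&
            lev[nb[1], nb[2], nb[3]] == g) {
          seen[j] <- TRUE
          stack <- c(stack, j)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sum(1 / sizes^2) / length(sizes)
}

# Small random lesion fixture: arbitrary intensities on an irregular mask.
random_fixture <- function(seed, dims = c(6, 6, 3), p_mask = 0.8,
                           levels = NULL) {
  set.seed(seed)
  img <- array(stats::rnorm(prod(dims)), dims)
  if (!is.null(levels))
    img <- array(sample(levels, prod(dims), TRUE), dims)
  mask <- array(stats::runif(prod(dims)) < p_mask, dims)
  if (sum(mask) < 8) mask[seq_len(8)] <- TRUE
  list(img = img, mask = mask)
}

make_small_cohort <- function(n = 8, seed = 1, prevalence = 0.5, ...) {
  habitrad::generate_cohort(habitrad::cohort_spec(n_patients = n, seed = seed,
                                                  prevalence = prevalence,
                                                  ...))
}

# Brute-force MCC: builds each angle's co-occurrence matrix by explicit
# pair enumeration, forms Q elementwise, and extracts the second-largest
# eigenvalue.
naive_glcm_mcc <- function(img, mask, n_bins, mode = "3D") {
  lev <- habitrad::discretize(img, mask, n_bins)
  d <- dim(img)
  offs <- list()
  if (mode == "2D") {
    offs <- list(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, -1, 0))
  } else {
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1)
      if (dz > 0 || (dz == 0 && dy > 0) || (dz == 0 && dy == 0 && dx > 0))
        offs[[length(offs) + 1]] <- c(dx, dy, dz)
  }
  vals <- c()
  for (off in offs) {
    P <- matrix(0, n_bins, n_bins)
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
      if (!mask[x, y, z]) next
      nx <- x + off[1]; ny <- y + off[2]; nz <- z + off[3]
      if (nx < 1 || nx > d[1] || ny < 1 || ny > d[2] || nz < 1 || nz > d[3]) next
      if (!mask[nx, ny, nz]) next
      i <- lev[x, y, z]; j <- lev[nx, ny, nz]
      P[i, j] <- P[i, j] + 1; P[j, i] <- P[j, i] + 1
    }
    if (sum(P) == 0) next
    P <- P / sum(P)
    px <- rowSums(P); keep <- px > 0
    if (sum(keep) < 2) next
    P <- P[keep, keep, drop = FALSE]
    px <- rowSums(P); py <- colSums(P)
    m <- nrow(P)
    Q <- matrix(0, m, m)
    for (i in seq_len(m)) for (j in seq_len(m)) {
      s <- 0
      for (k in seq_len(m)) s <- s + P[i, k] * P[j, k] / (px[i] * py[k])
      Q[i, j] <- s
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    vals <- c(vals, sqrt(max(0, min(1, ev[2]))))
  }
  mean(vals)
}

# Two-sided Mann-Whitney p by full enumeration of group assignments
# (tiny samples only).
naive_mw_p <- function(x, y) {
  all_v <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(all_v), n1)
  u_of <- function(a, b) {
    u <- 0
    for (ai in a) for (bi in b) u <- u + (ai > bi) + 0.5 * (ai == bi)
    u
  }
  u_obs <- u_of(x, y)
  n <- ncol(idx)
  us <- vapply(seq_len(n), function(j) {
    a <- all_v[idx[, j]]; b <- all_v[-idx[, j]]
    u_of(a, b)
  }, numeric(1))
  mu <- length(x) * length(y) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}
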