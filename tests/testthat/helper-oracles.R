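# Independent oracles used to check package implementations by a second route.

# ARI by direct pair counting (no contingency-table shortcut).
pairCountARI <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / den
}

# BH step-up by direct evaluation of the rule on sorted p-values.
stepUpBH <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  kmax <- 0
  for (i in seq_len(m)) if (ps[i] <= i / m * alpha) kmax <- i
  rej <- logical(m)
  if (kmax > 0) rej[o[seq_len(kmax)]] <- TRUE
  q <- numeric(m)
  run <- Inf
  for (i in m:1) {
    run <- min(run, m * ps[i] / i)
    q[o[i]] <- min(run, 1)
  }
  list(q = q, reject = rej)
}

# 3D connected components by breadth-first flood fill.
floodFillLabel <- function(mask, connectivity) {
  dims <- dim(mask)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  deg <- rowSums(abs(off))
  off <- off[switch(as.character(connectivity),
                    "6" = deg == 1, "18" = deg <= 2, "26" = deg <= 3), ,
             drop = FALSE]
  lab <- array(0L, dims)
  cur <- 0L
  for (v in which(mask)) {
    if (lab[v] != 0L) next
    cur <- cur + 1L
    queue <- matrix(arrayInd(v, dims), ncol = 3)
    lab[v] <- cur
    while (nrow(queue) > 0) {
      pt <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      for (r in seq_len(nrow(off))) {
        nb <- pt + off[r, ]
        if (any(nb < 1) || any(nb > dims)) next
        if (mask[nb[1], nb[2], nb[3]] && lab[nb[1], nb[2], nb[3]] == 0L) {
          lab[nb[1], nb[2], nb[3]] <- cur
          queue <- rbind(queue, nb)
        }
      }
    }
  }
  lab
}

# Best label alignment by exhaustive search over permutations (small K).
exhaustiveAlign <- function(a, b) {
  K <- max(a, b)
  perms <- gtoolsPerms(K)
  best <- -1
  bestPerm <- NULL
  for (r in seq_len(nrow(perms))) {
    hits <- sum(perms[r, ][b] == a)
    if (hits > best) {
      best <- hits
      bestPerm <- perms[r, ]
    }
  }
  list(perm = bestPerm, matches = best)
}

# All permutations of 1..K (tiny K only).
gtoolsPerms <- function(K) {
  if (K == 1) return(matrix(1L, 1, 1))
  sub <- gtoolsPerms(K - 1)
  out <- NULL
  for (pos in K:1) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], K,
                   if (pos <= K - 1) sub[, pos:(K - 1), drop = FALSE])
    out <- rbind(out, block)
  }
  out
}

# Partial correlation via the precision (inverse covariance) matrix.
precisionPartialCor <- function(x, y, Z) {
  M <- cbind(x, y, Z)
  P <- solve(stats::cov(M))
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# Small, quickly separable cohort for structural tests.
tinyCohort <- function(seed = 1, effectSize = 1.5, nRegions = 60,
                       nControls = 30, n1 = 12, n2 = 12) {
  simulateCohort(cohortDesign(nControls = nControls, nSubtype1 = n1,
                              nSubtype2 = n2, nRegions = nRegions,
                              affectedRegions = 1:10,
                              effectSize = effectSize, seed = seed))
}

# All set partitions of n elements as label vectors (for exhaustive ARI).
allPartitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in allPartitions(n - 1)) {
    for (k in seq_len(max(p) + 1L)) out[[length(out) + 1L]] <- c(p, k)
  }
  out
}
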