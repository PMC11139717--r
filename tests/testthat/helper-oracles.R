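# Independent brute-force oracles, written before the optimized builders
# and kept deliberately naive: explicit loops, no shared code with R/.

# Wrap a level matrix (0 = outside ROI) as a quantized_roi.
make_q <- function(lev, Ng = max(lev)) {
  lev <- as.matrix(lev)
  storage.mode(lev) <- "integer"
  structure(list(levels = lev, Ng = as.integer(Ng),
                 bin_edges = seq(0.5, Ng + 0.5, length.out = Ng + 1L)),
            class = "quantized_roi")
}

oracle_offsets <- function(directions, d = 1L) {
  m <- list("0" = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L),
            "135" = c(-d, -d))
  m[as.character(directions)]
}

oracle_glcm <- function(lev, Ng, distance = 1L, directions = c(0, 45, 90, 135),
                        symmetric = TRUE) {
  acc <- matrix(0, Ng, Ng)
  used <- 0L
  for (off in oracle_offsets(directions, distance)) {
    cnt <- matrix(0, Ng, Ng)
    for (r in seq_len(nrow(lev))) {
      for (cl in seq_len(ncol(lev))) {
        r2 <- r + off[1]; c2 <- cl + off[2]
        if (r2 < 1 || r2 > nrow(lev) || c2 < 1 || c2 > ncol(lev)) next
        a <- lev[r, cl]; b <- lev[r2, c2]
        if (a == 0 || b == 0) next
        cnt[a, b] <- cnt[a, b] + 1
        if (symmetric) cnt[b, a] <- cnt[b, a] + 1
      }
    }
    if (sum(cnt) > 0) {
      acc <- acc + cnt / sum(cnt)
      used <- used + 1L
    }
  }
  if (used == 0L) stop("oracle: no valid pair")
  acc / used
}

# Maximal runs: walk every line pixel by pixel.
oracle_glrlm_dir <- function(lev, Ng, direction) {
  step <- switch(as.character(direction),
                 "0" = c(0L, 1L), "45" = c(-1L, 1L),
                 "90" = c(1L, 0L), "135" = c(1L, 1L))
  nr <- nrow(lev); nc <- ncol(lev)
  at <- function(r, cl) {
    if (r < 1 || r > nr || cl < 1 || cl > nc) 0L else lev[r, cl]
  }
  runs <- list()
  for (r in seq_len(nr)) {
    for (cl in seq_len(nc)) {
      v <- lev[r, cl]
      if (v == 0L) next
      # start of a run iff the previous cell along the line differs
      if (at(r - step[1], cl - step[2]) == v) next
      len <- 1L
      while (at(r + len * step[1], cl + len * step[2]) == v) len <- len + 1L
      runs[[length(runs) + 1L]] <- c(v, len)
    }
  }
  runs <- do.call(rbind, runs)
  rmax <- max(runs[, 2])
  P <- matrix(0, Ng, rmax)
  for (i in seq_len(nrow(runs))) {
    P[runs[i, 1], runs[i, 2]] <- P[runs[i, 1], runs[i, 2]] + 1
  }
  P
}

# Zones by explicit stack-based flood fill.
oracle_glszm <- function(lev, Ng, connectivity = 8) {
  nr <- nrow(lev); nc <- ncol(lev)
  seen <- matrix(FALSE, nr, nc)
  nbrs <- if (connectivity == 8) {
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
          c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  } else {
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  zones <- list()
  for (r in seq_len(nr)) {
    for (cl in seq_len(nc)) {
      if (lev[r, cl] == 0L || seen[r, cl]) next
      g <- lev[r, cl]
      stack <- list(c(r, cl))
      seen[r, cl] <- TRUE
      size <- 0L
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        size <- size + 1L
        for (k in seq_len(nrow(nbrs))) {
          r2 <- p[1] + nbrs[k, 1]; c2 <- p[2] + nbrs[k, 2]
          if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
          if (seen[r2, c2] || lev[r2, c2] != g) next
          seen[r2, c2] <- TRUE
          stack[[length(stack) + 1L]] <- c(r2, c2)
        }
      }
      zones[[length(zones) + 1L]] <- c(g, size)
    }
  }
  zones <- do.call(rbind, zones)
  smax <- max(zones[, 2])
  P <- matrix(0, Ng, smax)
  for (i in seq_len(nrow(zones))) {
    P[zones[i, 1], zones[i, 2]] <- P[zones[i, 1], zones[i, 2]] + 1
  }
  P
}

oracle_ngtdm <- function(lev, Ng) {
  nr <- nrow(lev); nc <- ncol(lev)
  n_i <- numeric(Ng); s_i <- numeric(Ng)
  for (r in seq_len(nr)) {
    for (cl in seq_len(nc)) {
      v <- lev[r, cl]
      if (v == 0L) next
      nb <- c()
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr; c2 <- cl + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (lev[r2, c2] > 0L) nb <- c(nb, lev[r2, c2])
      }
      if (!length(nb)) next
      n_i[v] <- n_i[v] + 1
      s_i[v] <- s_i[v] + abs(v - mean(nb))
    }
  }
  list(n_i = n_i, s_i = s_i, n_valid = sum(n_i))
}

# Exhaustive Youden search: every midpoint threshold, both directions.
oracle_youden_max <- function(values, labels) {
  u <- sort(unique(values))
  cand <- c(-Inf, (u[-1] + u[-length(u)]) / 2, Inf)
  pos <- values[labels == 1]
  neg <- values[labels == 0]
  best <- -Inf
  for (t in cand) {
    j_g <- mean(pos > t) + mean(neg <= t) - 1
    j_l <- mean(pos <= t) + mean(neg > t) - 1
    best <- max(best, j_g, j_l)
  }
  best
}

# Exact two-sided McNemar by direct binomial enumeration (choose-based).
oracle_mcnemar_exact <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  k <- min(b, c)
  min(1, 2 * sum(choose(n, 0:k)) / 2^n)
}

# Random quantized test image: random dims, levels in 0..Ng (0 = background),
# guaranteed at least 2 ROI pixels and at least one adjacent ROI pair.
random_level_image <- function(Ng = 3L, max_dim = 8L) {
  repeat {
    nr <- sample(2:max_dim, 1)
    nc <- sample(2:max_dim, 1)
    lev <- matrix(sample(0:Ng, nr * nc, replace = TRUE,
                         prob = c(0.3, rep(0.7 / Ng, Ng))), nr, nc)
    if (sum(lev > 0) < 2) next
    # need one 8-adjacent ROI pair for GLCM/NGTDM validity
    ok <- FALSE
    for (r in seq_len(nr)) for (cl in seq_len(nc)) {
      if (lev[r, cl] == 0) next
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr; c2 <- cl + dc
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc && lev[r2, c2] > 0) {
          ok <- TRUE
        }
      }
    }
    if (ok) return(lev)
  }
}

# Small synthetic image/mask pair for feature-level tests.
patch_from_values <- function(vals_mat, spacing = c(1, 1)) {
  n <- max(16L, nrow(vals_mat), ncol(vals_mat))
  px <- matrix(-850, n, n)
  px[seq_len(nrow(vals_mat)), seq_len(ncol(vals_mat))] <- vals_mat
  image_patch(px, spacing = spacing)
}

mask_from_levels <- function(lev, n = NULL) {
  n <- n %||% max(16L, nrow(lev), ncol(lev))
  m <- matrix(FALSE, n, n)
  m[seq_len(nrow(lev)), seq_len(ncol(lev))] <- lev > 0
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
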