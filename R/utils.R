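# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. Every stochastic operation in the package
# funnels through this so that (spec, seed) fully determines the output.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single non-missing number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive `n` child seeds from one parent seed; keeps every derived seed
# strictly below 2^31 so it is a valid R integer.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Label connected components of a logical/0-1 matrix. Vectorized
# breadth-first growth: the frontier of each component expands in whole
# batches, so cost is proportional to foreground size, not image size.
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  nr <- nrow(mask)
  nc <- ncol(mask)
  inmask <- mask != 0
  lab <- matrix(0L, nr, nc)
  dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
  dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  if (connectivity == 4) {
    dr <- dr[1:4]
    dc <- dc[1:4]
  }
  cur <- 0L
  for (p in which(inmask)) {
    if (lab[p] != 0L) next
    cur <- cur + 1L
    lab[p] <- cur
    frontier <- p
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      c <- (frontier - 1L) %/% nr + 1L
      nb_r <- rep(r, times = length(dr)) + rep(dr, each = length(r))
      nb_c <- rep(c, times = length(dc)) + rep(dc, each = length(c))
      ok <- nb_r >= 1L & nb_r <= nr & nb_c >= 1L & nb_c <= nc
      idx <- unique((nb_c[ok] - 1L) * nr + nb_r[ok])
      idx <- idx[inmask[idx] & lab[idx] == 0L]
      lab[idx] <- cur
      frontier <- idx
    }
  }
  list(labels = lab, n = cur)
}

component_sizes <- function(lab) {
  if (lab$n == 0L) return(integer(0))
  tabulate(lab$labels[lab$labels > 0L], nbins = lab$n)
}

# Separable Gaussian smoothing with edge replication; used for the speckle
# field of the nodule generator.
smooth_gaussian <- function(m, sigma) {
  h <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-h:h, sd = sigma)
  k <- k / sum(k)
  pad_rows <- function(mm, n) {
    rbind(mm[rep(1L, n), , drop = FALSE], mm, mm[rep(nrow(mm), n), , drop = FALSE])
  }
  mp <- pad_rows(m, h)
  mp <- t(pad_rows(t(mp), h))
  fc <- apply(mp, 2, function(v) stats::filter(v, k, sides = 2))
  fr <- t(apply(fc, 1, function(v) stats::filter(v, k, sides = 2)))
  fr[(h + 1):(h + nrow(m)), (h + 1):(h + ncol(m)), drop = FALSE]
}

# Population (n-denominator) standard deviation; the texture-software
# convention used for the coefficient of variation.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be TRUE or FALSE", name), call. = FALSE)
  }
  invisible(x)
}
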