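## Shared fixtures and independent brute-force oracles. The oracles use
## plain voxel loops so they share no code path with the package's
## vectorized implementations.

tiny_volume <- function(values, dims = NULL, spacing = c(1, 1, 1)) {
  if (is.null(dims)) dims <- dim(values)
  volume3d(array(values, dims), spacing)
}

full_mask <- function(dims, spacing = c(1, 1, 1)) {
  mask3d(array(1L, dims), spacing)
}

## random quantized grid (levels 1..ng inside, 0 where masked out)
random_quantized_grid <- function(dims, ng = 3, p_hole = 0.2) {
  q <- array(sample.int(ng, prod(dims), replace = TRUE), dims)
  q[runif(prod(dims)) < p_hole] <- 0L
  q
}

all_offsets_26 <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
all_offsets_26 <- all_offsets_26[rowSums(abs(all_offsets_26)) > 0, ]

in_bounds <- function(cc, d) {
  all(cc >= 1L) && all(cc <= d)
}

## ---- brute-force GLCM: enumerate every ordered voxel pair at +/- offset
bf_glcm <- function(q, ng, dir) {
  d <- dim(q)
  m <- matrix(0, ng, ng)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (q[i, j, k] == 0L) next
    for (s in c(1, -1)) {
      cc <- c(i, j, k) + s * dir
      if (in_bounds(cc, d) && q[cc[1], cc[2], cc[3]] > 0L) {
        m[q[i, j, k], q[cc[1], cc[2], cc[3]]] <-
          m[q[i, j, k], q[cc[1], cc[2], cc[3]]] + 1
      }
    }
  }
  m
}

## ---- brute-force GLRLM: walk runs voxel by voxel
bf_glrlm <- function(q, ng, dir) {
  d <- dim(q)
  runs <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    g <- q[i, j, k]
    if (g == 0L) next
    prev <- c(i, j, k) - dir
    if (in_bounds(prev, d) && q[prev[1], prev[2], prev[3]] == g) next
    len <- 1L
    cur <- c(i, j, k) + dir
    while (in_bounds(cur, d) && q[cur[1], cur[2], cur[3]] == g) {
      len <- len + 1L
      cur <- cur + dir
    }
    runs[[length(runs) + 1L]] <- c(g, len)
  }
  if (length(runs) == 0L) return(matrix(0, ng, 1))
  rr <- do.call(rbind, runs)
  lmax <- max(rr[, 2])
  m <- matrix(0, ng, lmax)
  for (r in seq_len(nrow(rr))) m[rr[r, 1], rr[r, 2]] <- m[rr[r, 1], rr[r, 2]] + 1
  m
}

## ---- brute-force GLSZM: stack-based flood fill, 26-connectivity
bf_glszm_zones <- function(q) {
  d <- dim(q)
  seen <- array(FALSE, d)
  zones <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (q[i, j, k] == 0L || seen[i, j, k]) next
    g <- q[i, j, k]
    stack <- list(c(i, j, k))
    seen[i, j, k] <- TRUE
    size <- 0L
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (r in seq_len(nrow(all_offsets_26))) {
        cc <- p + all_offsets_26[r, ]
        if (in_bounds(cc, d) && !seen[cc[1], cc[2], cc[3]] &&
              q[cc[1], cc[2], cc[3]] == g) {
          seen[cc[1], cc[2], cc[3]] <- TRUE
          stack[[length(stack) + 1L]] <- cc
        }
      }
    }
    zones[[length(zones) + 1L]] <- c(g, size)
  }
  zones
}

bf_glszm <- function(q, ng) {
  zones <- bf_glszm_zones(q)
  if (length(zones) == 0L) return(matrix(0, ng, 1))
  zz <- do.call(rbind, zones)
  smax <- max(zz[, 2])
  m <- matrix(0, ng, smax)
  for (r in seq_len(nrow(zz))) m[zz[r, 1], zz[r, 2]] <- m[zz[r, 1], zz[r, 2]] + 1
  m
}

## ---- brute-force GLDM: count matching neighbors per voxel
bf_gldm <- function(q, ng, alpha = 0) {
  d <- dim(q)
  m <- matrix(0, ng, 27)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    g <- q[i, j, k]
    if (g == 0L) next
    dep <- 0L
    for (r in seq_len(nrow(all_offsets_26))) {
      cc <- c(i, j, k) + all_offsets_26[r, ]
      if (in_bounds(cc, d) && q[cc[1], cc[2], cc[3]] > 0L &&
            abs(q[cc[1], cc[2], cc[3]] - g) <= alpha) {
        dep <- dep + 1L
      }
    }
    m[g, dep + 1L] <- m[g, dep + 1L] + 1
  }
  m
}

## ---- brute-force NGTDM: neighborhood means per voxel
bf_ngtdm <- function(q, ng) {
  d <- dim(q)
  n_g <- numeric(ng); s_g <- numeric(ng); n_valid <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    g <- q[i, j, k]
    if (g == 0L) next
    vals <- c()
    for (r in seq_len(nrow(all_offsets_26))) {
      cc <- c(i, j, k) + all_offsets_26[r, ]
      if (in_bounds(cc, d) && q[cc[1], cc[2], cc[3]] > 0L) {
        vals <- c(vals, q[cc[1], cc[2], cc[3]])
      }
    }
    if (length(vals) == 0L) next
    n_valid <- n_valid + 1L
    n_g[g] <- n_g[g] + 1
    s_g[g] <- s_g[g] + abs(g - mean(vals))
  }
  list(n = n_g, s = s_g, n_valid = n_valid)
}

## brute-force AUC: fraction of concordant positive/negative pairs (+1/2 ties)
bf_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

## small synthetic patient shared across tests (cached per session)
cached_patient <- local({
  env <- new.env()
  function(seed = 7) {
    key <- paste0("p", seed)
    if (is.null(env[[key]])) {
      env[[key]] <- generate_cohort(
        cohort_config(n_patients = 1, seed = seed)
      )[[1]]
    }
    env[[key]]
  }
})
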