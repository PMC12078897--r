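#' K-means habitat clustering of within-VOI voxel intensities
#'
#' Clusters the 1-D standardized (z-scored) voxel intensities inside the VOI
#' into `k` habitats with k-means, taking the best of `restarts`
#' k-means++ initializations by within-cluster sum of squared errors (SSE).
#' Labels are reordered by descending cluster mean intensity so habitat 1 is
#' always the high-signal subregion.
#'
#' @param volume a [volume3d()].
#' @param mask a `mask3d`; nonzero voxels define the VOI.
#' @param k number of clusters (>= 1); the VOI must contain at least `k`
#'   distinct intensities.
#' @param seed integer seed (restarts are drawn deterministically from it).
#' @param restarts number of k-means++ restarts (default 25).
#' @param max_iter,tol k-means iteration cap and relative SSE tolerance.
#' @return A `habitat_map`: list with `labels` (`mask3d`, 0 outside the VOI,
#'   1..k inside), `cluster_means` (original intensity units, decreasing),
#'   `sse` (on the standardized scale), `k`, and `sequence`.
#' @export
cluster_voxels <- function(volume, mask, k, seed = 1, restarts = 25,
                           max_iter = 300, tol = 1e-6) {
  check_same_grid(volume, mask)
  inside <- mask$data != 0L
  vals <- volume$data[inside]
  n <- length(vals)
  if (k < 1L) abort("`k` must be >= 1.")
  if (n < k) abort("VOI has fewer voxels than clusters.")
  n_distinct <- length(unique(vals))
  if (k > n_distinct) {
    abort(sprintf("k = %d exceeds the %d distinct intensities in the VOI.",
                  k, n_distinct))
  }
  x <- as.numeric(scale(vals))
  if (all(!is.finite(x))) x <- rep(0, n)  # constant VOI, k must be 1

  if (k == 1L) {
    assign <- rep(1L, n)
    sse <- sum((x - mean(x))^2)
  } else {
    set.seed(seed)
    best <- NULL
    for (r in seq_len(restarts)) {
      centers <- kmeanspp_centers(x, k)
      km <- tryCatch(
        kmeans(x, centers = matrix(centers, ncol = 1), iter.max = max_iter),
        error = function(e) NULL, warning = function(w) {
          suppressWarnings(kmeans(x, centers = matrix(centers, ncol = 1),
                                  iter.max = max_iter))
        })
      if (is.null(km)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss - tol *
            max(best$tot.withinss, 1e-12) ||
          km$tot.withinss < best$tot.withinss) {
        best <- km
      }
    }
    if (is.null(best)) abort("k-means failed for every restart.")
    assign <- best$cluster
    sse <- best$tot.withinss
  }

  ## relabel by descending mean original intensity: habitat1 = high signal
  means <- vapply(seq_len(k), function(c) mean(vals[assign == c]), numeric(1))
  ord <- order(means, decreasing = TRUE)
  relab <- integer(k); relab[ord] <- seq_len(k)
  labels_arr <- array(0L, dim(volume$data))
  labels_arr[inside] <- relab[assign]
  structure(
    list(labels = mask3d(labels_arr, volume$spacing),
         cluster_means = sort(means, decreasing = TRUE),
         sse = sse, k = as.integer(k), sequence = volume$sequence),
    class = "habitat_map"
  )
}

#' @export
print.habitat_map <- function(x, ...) {
  cat(sprintf("<habitat_map> k = %d%s, SSE %.4g, cluster means: %s\n",
              x$k, if (is.null(x$sequence)) "" else
                paste0(" (", x$sequence, ")"),
              x$sse, paste(signif(x$cluster_means, 4), collapse = ", ")))
  invisible(x)
}

## k-means++ seeding on a 1-D vector.
kmeanspp_centers <- function(x, k) {
  n <- length(x)
  centers <- numeric(k)
  centers[1] <- x[sample.int(n, 1)]
  d2 <- (x - centers[1])^2
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) {
      centers[j] <- x[sample.int(n, 1)]
    } else {
      centers[j] <- x[sample.int(n, 1, prob = d2)]
    }
    d2 <- pmin(d2, (x - centers[j])^2)
  }
  ## kmeans() requires distinct centers; jitter exact duplicates
  while (anyDuplicated(centers)) {
    dup <- which(duplicated(centers))
    centers[dup] <- centers[dup] + rnorm(length(dup), 0, 1e-6 * (sd(x) + 1e-12))
  }
  centers
}

#' SSE curve over a range of cluster counts
#'
#' Runs [cluster_voxels()] for K = 1..`kmax` and collects the SSE curve used
#' by the elbow rule.
#'
#' @inheritParams cluster_voxels
#' @param kmax largest K to scan (>= 3).
#' @return tibble with columns `k` and `sse` (class `sse_curve`).
#' @export
sse_curve <- function(volume, mask, kmax = 8, seed = 1, restarts = 25) {
  n_distinct <- length(unique(mask_values(volume, mask)))
  ks <- seq_len(min(kmax, n_distinct))
  out <- tibble(
    k = as.integer(ks),
    sse = vapply(ks, function(k) {
      cluster_voxels(volume, mask, k, seed = seed + k, restarts = restarts)$sse
    }, numeric(1))
  )
  class(out) <- c("sse_curve", class(out))
  out
}

#' Select the number of clusters by the SSE elbow
#'
#' Operationalizes the elbow as the K whose (K, SSE) point lies farthest
#' (perpendicular distance) from the chord joining the first and last points
#' of the curve, after min-max normalizing both axes (Kneedle-style). Ties
#' break toward smaller K. A non-monotone curve (beyond a small tolerance,
#' as can happen across independent restarts) is isotonically regressed
#' first, with a warning.
#'
#' @param curve data frame with columns `k` (1..Kmax, Kmax >= 3) and `sse`.
#' @param tol relative tolerance for monotonicity violations.
#' @return the selected K (integer).
#' @examples
#' elbow_select_k(data.frame(k = 1:5, sse = c(100, 10, 9, 8.5, 8.2)))
#' @export
elbow_select_k <- function(curve, tol = 1e-8) {
  k <- curve$k
  sse <- curve$sse
  if (length(k) < 3L) abort("elbow selection needs K = 1..Kmax with Kmax >= 3.")
  if (is.unsorted(k)) {
    ord <- order(k); k <- k[ord]; sse <- sse[ord]
  }
  viol <- diff(sse) > tol * max(abs(sse), 1e-12)
  if (any(viol)) {
    warn("SSE curve is not non-increasing; applying isotonic regression.")
    iso <- isoreg(k, -sse)
    sse <- -iso$yf
  }
  kn <- (k - k[1]) / (k[length(k)] - k[1])
  rng <- max(sse) - min(sse)
  if (rng < 1e-15) return(as.integer(k[min(2L, length(k))]))
  sn <- (sse - min(sse)) / rng
  ## distance from (kn, sn) to chord from (kn[1], sn[1]) to (kn[m], sn[m]);
  ## with normalized axes the chord is y = 1 - x, distance |x + y - 1|/sqrt(2)
  m <- length(k)
  a <- sn[m] - sn[1]; b <- kn[1] - kn[m]
  cc <- kn[m] * sn[1] - kn[1] * sn[m]
  dist <- abs(a * kn + b * sn + cc) / sqrt(a^2 + b^2)
  interior <- seq(2L, m - 1L)
  best <- interior[which.max(dist[interior])]  # which.max ties -> smallest K
  as.integer(k[best])
}

#' Pooled cohort SSE curves and global elbow K
#'
#' Computes per-patient, per-sequence SSE curves on within-VOI standardized
#' intensities, min-max normalizes each curve, averages them over the cohort,
#' and applies the elbow rule once, yielding a single K shared by all
#' patients (required for named subregion models to exist cohort-wide).
#'
#' @param cohort an `mri_cohort` (or any list of patients with `t2w`, `dwi`,
#'   `voi`, `voi_dwi` fields).
#' @param kmax largest K scanned.
#' @param seed root seed for the k-means restarts.
#' @param restarts k-means++ restarts per fit.
#' @return list with `curves` (tibble: patient_id, sequence, k, sse,
#'   sse_norm), `mean_curve` (tibble k, sse), `k` (selected).
#' @export
cohort_elbow <- function(cohort, kmax = 8, seed = 7, restarts = 25) {
  rows <- list()
  for (i in seq_along(cohort)) {
    p <- cohort[[i]]
    for (sq in c("T2WI", "DWI")) {
      vol <- if (sq == "T2WI") p$t2w else p$dwi
      msk <- if (sq == "T2WI") p$voi else p$voi_dwi
      cv <- sse_curve(vol, msk, kmax = kmax,
                      seed = substream_seed(seed, i,
                                            3L + (sq == "DWI")),
                      restarts = restarts)
      rng <- max(cv$sse) - min(cv$sse)
      cv$sse_norm <- if (rng > 0) (cv$sse - min(cv$sse)) / rng else
        rep(0, nrow(cv))
      rows[[length(rows) + 1L]] <-
        dplyr::bind_cols(tibble(patient_id = p$id, sequence = sq), cv)
    }
  }
  curves <- dplyr::bind_rows(rows)
  mean_curve <- curves |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(sse = mean(.data$sse_norm), .groups = "drop")
  class(mean_curve) <- c("sse_curve", class(mean_curve))
  list(curves = curves,
       mean_curve = mean_curve,
       k = elbow_select_k(mean_curve))
}

#' Split a habitat map into per-label masks and volume fractions
#'
#' @param map a `habitat_map` from [cluster_voxels()].
#' @return list with `masks` (named list of `mask3d`, one per nonempty
#'   label, `habitat1` = highest-signal cluster) and `fractions` (tibble
#'   `habitat`, `n_voxels`, `fraction`; fractions sum to 1).
#' @export
habitat_masks <- function(map) {
  lab <- map$labels$data
  total <- sum(lab != 0L)
  masks <- list()
  rows <- list()
  for (h in seq_len(map$k)) {
    nh <- sum(lab == h)
    if (nh == 0L) {
      warn(sprintf("habitat %d is empty and was excluded.", h))
      next
    }
    arr <- array(0L, dim(lab))
    arr[lab == h] <- 1L
    masks[[paste0("habitat", h)]] <- mask3d(arr, map$labels$spacing)
    rows[[length(rows) + 1L]] <- tibble(habitat = h, n_voxels = nh,
                                        fraction = nh / total)
  }
  list(masks = masks, fractions = dplyr::bind_rows(rows))
}

#' Cluster both sequences of a patient at a fixed K
#'
#' @param patient a patient with `t2w`, `dwi`, `voi`, `voi_dwi`.
#' @param k number of habitats per sequence.
#' @param seed root seed.
#' @param restarts k-means++ restarts.
#' @return named list of `habitat_map`s (`T2WI`, `DWI`).
#' @export
patient_habitats <- function(patient, k = 2, seed = 7, restarts = 25) {
  idx <- as.integer(sub("^P", "", patient$id))
  list(
    T2WI = cluster_voxels(patient$t2w, patient$voi, k,
                          seed = substream_seed(seed, idx, 5L),
                          restarts = restarts),
    DWI = cluster_voxels(patient$dwi, patient$voi_dwi, k,
                         seed = substream_seed(seed, idx, 6L),
                         restarts = restarts)
  )
}
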