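# Exploratory spatial data analysis over region centroids: k-nearest-
# neighbour weights (great-circle distance), global Moran's I with
# permutation inference, and local Moran (LISA) with cluster typing.

#' k-nearest-neighbour spatial weights from region centroids
#'
#' Neighbour sets by great-circle (haversine) distance between centroids;
#' asymmetric (k-NN is not a symmetric relation) and row-standardized, so
#' each region's k neighbour weights sum to 1. Distance ties are broken by
#' region-identifier order. Duplicate coordinates are allowed (the tie
#' rule applies).
#'
#' @param centroids Tibble with columns `region`, `lon`, `lat` (degrees).
#' @param k Number of neighbours (default 7); must be `< n`.
#' @return Object of class `"knn_weights"`: list with `region`,
#'   `neighbours` (n x k integer matrix of row indices), `weights`
#'   (n x k, rows summing to 1), `k`.
#' @export
knn_weights <- function(centroids, k = 7) {
  centroids <- tibble::as_tibble(centroids)
  stopifnot(all(c("region", "lon", "lat") %in% names(centroids)))
  centroids <- dplyr::arrange(centroids, .data$region)
  n <- nrow(centroids)
  if (k >= n) stop("k must be smaller than the number of regions",
                   call. = FALSE)
  if (any(!is.finite(centroids$lon)) || any(!is.finite(centroids$lat))) {
    stop("centroid coordinates must be finite", call. = FALSE)
  }
  d <- geosphere::distm(as.matrix(centroids[, c("lon", "lat")]),
                        fun = geosphere::distHaversine)
  nb <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))   # ties by region order
    ord <- ord[ord != i]
    nb[i, ] <- ord[seq_len(k)]
  }
  structure(list(region = centroids$region, neighbours = nb,
                 weights = matrix(1 / k, n, k), k = k),
            class = "knn_weights")
}

# spatial lag of a value vector under row-standardized k-NN weights
spatial_lag <- function(values, w) {
  lag <- rowSums(matrix(values[w$neighbours], nrow = length(values)) *
                   w$weights)
  lag
}

moran_stat <- function(z, w) {
  n <- length(z)
  s0 <- sum(w$weights)
  (n / s0) * sum(z * spatial_lag(z, w)) / sum(z^2)
}

#' Global Moran's I with permutation inference
#'
#' `I = (n/S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` on mean-deviations
#' `z`. The pseudo p-value is one-sided for positive autocorrelation:
#' `(1 + #{permuted I >= observed}) / (1 + nperm)`, permuting values over
#' regions. Deterministic given the seed.
#'
#' @param values Numeric region vector aligned with `w$region`
#'   (non-constant).
#' @param w `knn_weights` object.
#' @param nperm Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return List with `I`, `p_value`, `expected` (`-1/(n-1)`), `nperm`.
#' @export
morans_i <- function(values, w, nperm = 999, seed = 1) {
  n <- length(values)
  stopifnot(n == length(w$region))
  if (stats::sd(values) == 0) {
    stop("Moran's I is undefined for a constant vector", call. = FALSE)
  }
  z <- values - mean(values)
  obs <- moran_stat(z, w)
  ge <- 0L
  if (nperm > 0) {
    with_preserved_seed(seed, {
      for (b in seq_len(nperm)) {
        zp <- z[sample.int(n)]
        if (moran_stat(zp, w) >= obs) ge <- ge + 1L
      }
    })
  }
  list(I = obs, p_value = (1 + ge) / (1 + nperm),
       expected = -1 / (n - 1), nperm = nperm)
}

#' Local Moran (LISA) with conditional permutation and cluster typing
#'
#' `I_i = z_i * lag_i / (sum_k z_k^2 / n)`. For each region the
#' permutation holds `z_i` fixed and redraws its k neighbours from the
#' remaining regions; the pseudo p-value is two-tailed-free, taken on the
#' side of the observed statistic: `(1 + #{extreme}) / (1 + nperm)` with
#' "extreme" meaning `>=` for positive `I_i` and `<=` for negative.
#' Significant regions are classed by the quadrant of `(z_i, lag_i)`:
#' high-high, low-low, high-low, low-high; no multiple-testing correction
#' is applied (pass `adjust = "fdr"` to apply one).
#'
#' @inheritParams morans_i
#' @param alpha Significance level for cluster classing (default 0.05).
#' @param adjust P-value adjustment method (default `"none"`).
#' @return Tibble (`region`, `value`, `local_i`, `p_value`, `cluster`).
#' @export
local_moran <- function(values, w, nperm = 999, alpha = 0.05, seed = 1,
                        adjust = "none") {
  n <- length(values)
  stopifnot(n == length(w$region))
  if (stats::sd(values) == 0) {
    stop("local Moran is undefined for a constant vector", call. = FALSE)
  }
  z <- values - mean(values)
  m2 <- sum(z^2) / n
  lag <- spatial_lag(z, w)
  li <- z * lag / m2
  p <- numeric(n)
  k <- w$k
  with_preserved_seed(seed, {
    for (i in seq_len(n)) {
      others <- z[-i]
      extreme <- 0L
      for (b in seq_len(nperm)) {
        nb <- others[sample.int(n - 1, k)]
        lib <- z[i] * mean(nb) / m2
        if ((li[i] >= 0 && lib >= li[i]) || (li[i] < 0 && lib <= li[i])) {
          extreme <- extreme + 1L
        }
      }
      p[i] <- (1 + extreme) / (1 + nperm)
    }
  })
  p_adj <- stats::p.adjust(p, method = adjust)
  cluster <- dplyr::case_when(
    p_adj > alpha ~ "not_significant",
    z >= 0 & lag >= 0 ~ "HH",
    z < 0 & lag < 0 ~ "LL",
    z >= 0 & lag < 0 ~ "HL",
    .default = "LH")
  tibble::tibble(region = w$region, value = values, local_i = li,
                 p_value = p_adj, cluster = cluster)
}

# Run `expr` under a fixed seed, restoring the caller's RNG state after.
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) {
            rm(".Random.seed", envir = globalenv())
          })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Read region centroids from CSV or GeoJSON
#'
#' CSV needs columns `region`, `lon`, `lat`. A GeoJSON FeatureCollection
#' is reduced to representative points: the mean of each feature's
#' coordinate vertices, keyed by a `region` property.
#'
#' @param path File path (`.csv`, `.json`, or `.geojson`).
#' @return Tibble (`region`, `lon`, `lat`).
#' @export
read_centroids <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    stopifnot(all(c("region", "lon", "lat") %in% names(out)))
    out$region <- as.character(out$region)
    return(out[, c("region", "lon", "lat")])
  }
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  rows <- lapply(feats, function(f) {
    coords <- unlist(f$geometry$coordinates)
    xy <- matrix(coords, ncol = 2, byrow = TRUE)
    tibble::tibble(region = as.character(f$properties$region),
                   lon = mean(xy[, 1]), lat = mean(xy[, 2]))
  })
  dplyr::bind_rows(rows)
}
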