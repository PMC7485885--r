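#' Standardize a feature matrix for clustering
#'
#' Column-wise z-scoring after dropping rows with any missing value;
#' zero-variance columns are removed with a warning. K-means works on
#' Euclidean distance, so without scaling the device-unit pressure columns
#' would dominate the Hz- and mm-scaled ones.
#'
#' @param features Data frame or matrix of numeric feature columns.
#' @return Numeric matrix with attributes `dropped_rows` (original row
#'   indices removed) and `dropped_cols` (constant columns removed).
#' @export
standardize_matrix <- function(features) {
  m <- as.matrix(as.data.frame(features))
  storage.mode(m) <- "double"
  keep_rows <- complete.cases(m)
  m <- m[keep_rows, , drop = FALSE]
  if (nrow(m) == 0) abort("no complete rows", class = "handwritr_data_error")
  sds <- apply(m, 2, sd)
  const <- sds == 0 | is.na(sds)
  if (any(const)) {
    warn(paste0("dropping zero-variance column(s): ",
                paste(colnames(m)[const], collapse = ", ")))
  }
  if (all(const)) abort("no usable columns", class = "handwritr_data_error")
  out <- scale(m[, !const, drop = FALSE])
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "dropped_rows") <- which(!keep_rows)
  attr(out, "dropped_cols") <- colnames(m)[const]
  out
}

#' Seeded K-means fit
#'
#' Best of `n_init` Lloyd runs with k-means++-style random starts
#' (`stats::kmeans` with multiple starts), deterministic under the given
#' seed.
#'
#' @param m Numeric matrix (rows = children).
#' @param k Number of clusters (2 <= k < n).
#' @param seed Integer seed.
#' @param n_init Random restarts.
#' @return List: `assignments`, `centroids`, `inertia` (total
#'   within-cluster sum of squares), `k`, `seed`.
#' @export
kmeans_fit <- function(m, k, seed = 1L, n_init = 25) {
  n <- nrow(m)
  if (k >= n) abort("k must be smaller than the number of rows",
                    class = "handwritr_parameter_error")
  if (k < 1) abort("k must be >= 1", class = "handwritr_parameter_error")
  set.seed(seed)
  km <- kmeans(m, centers = k, nstart = n_init, iter.max = 100)
  list(assignments = unname(km$cluster), centroids = unname(km$centers),
       inertia = km$tot.withinss, k = k, seed = seed)
}

# internal quality indices -------------------------------------------------

calinski_harabasz <- function(m, cl) {
  n <- nrow(m); k <- length(unique(cl))
  overall <- colMeans(m)
  W <- 0; B <- 0
  for (g in unique(cl)) {
    rows <- m[cl == g, , drop = FALSE]
    cen <- colMeans(rows)
    W <- W + sum(sweep(rows, 2, cen)^2)
    B <- B + nrow(rows) * sum((cen - overall)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

davies_bouldin <- function(m, cl) {
  gs <- sort(unique(cl)); k <- length(gs)
  cens <- t(vapply(gs, function(g) colMeans(m[cl == g, , drop = FALSE]),
                   numeric(ncol(m))))
  s <- vapply(seq_along(gs), function(i) {
    rows <- m[cl == gs[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(rows, 2, cens[i, ])^2)))
  }, numeric(1))
  mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      (s[i] + s[j]) / sqrt(sum((cens[i, ] - cens[j, ])^2))
    }, numeric(1)))
  }, numeric(1)))
}

#' Choose the number of clusters by index majority
#'
#' Scans `k_range`, computing five indices: the elbow of the
#' within-cluster-SS curve (maximum discrete curvature), mean silhouette
#' width, Calinski-Harabasz (maximized), Davies-Bouldin (minimized) and the
#' gap statistic (first-SE-max rule). Each index votes for one k; the
#' majority wins, ties broken toward the smaller k. A winner backed by two
#' or fewer of the five indices is flagged low-confidence.
#'
#' @param m Standardized feature matrix.
#' @param k_range Candidate k values (default 2:8).
#' @param seed Integer seed.
#' @param n_init Restarts per K-means fit.
#' @param gap_b Reference sets for the gap statistic.
#' @return List: `chosen_k`, `votes` (tibble index -> k), `inertia` (tibble
#'   k, within-SS over the scanned range incl. k = 1), `low_confidence`.
#' @export
choose_k <- function(m, k_range = 2:8, seed = 1L, n_init = 25, gap_b = 50) {
  n <- nrow(m)
  if (n <= max(k_range)) {
    abort("too few rows for the requested k range",
          class = "handwritr_parameter_error")
  }
  ks_wss <- c(1L, k_range, max(k_range) + 1L)
  wss <- vapply(ks_wss, function(k) {
    if (k == 1) sum(scale(m, scale = FALSE)^2)
    else kmeans_fit(m, k, seed = seed + k, n_init = n_init)$inertia
  }, numeric(1))
  fits <- lapply(k_range, function(k)
    kmeans_fit(m, k, seed = seed + k, n_init = n_init))
  names(fits) <- k_range

  # elbow: maximal second difference of the within-SS curve
  curv <- vapply(k_range, function(k) {
    i <- match(k, ks_wss)
    wss[i - 1] - 2 * wss[i] + wss[i + 1]
  }, numeric(1))
  vote_elbow <- k_range[which.max(curv)]

  d <- dist(m)
  sil <- vapply(seq_along(k_range), function(i) {
    mean(cluster::silhouette(fits[[i]]$assignments, d)[, 3])
  }, numeric(1))
  vote_sil <- k_range[which.max(sil)]

  ch <- vapply(seq_along(k_range), function(i)
    calinski_harabasz(m, fits[[i]]$assignments), numeric(1))
  vote_ch <- k_range[which.max(ch)]

  db <- vapply(seq_along(k_range), function(i)
    davies_bouldin(m, fits[[i]]$assignments), numeric(1))
  vote_db <- k_range[which.min(db)]

  set.seed(seed)
  gap <- cluster::clusGap(m, FUNcluster = function(x, k)
    list(cluster = kmeans(x, k, nstart = n_init, iter.max = 100)$cluster),
    K.max = max(k_range), B = gap_b, verbose = FALSE)
  gtab <- gap$Tab[k_range, , drop = FALSE]
  vote_gap <- k_range[cluster::maxSE(gtab[, "gap"], gtab[, "SE.sim"],
                                     method = "firstSEmax")]

  votes <- tibble::tibble(
    index = c("elbow", "silhouette", "calinski_harabasz", "davies_bouldin",
              "gap"),
    k = c(vote_elbow, vote_sil, vote_ch, vote_db, vote_gap))
  tally <- table(votes$k)
  best <- max(tally)
  chosen <- min(as.integer(names(tally)[tally == best]))
  list(chosen_k = chosen, votes = votes,
       inertia = tibble::tibble(k = ks_wss, wss = wss),
       low_confidence = best <= 2)
}

#' Hopkins clustering-tendency statistic
#'
#' Samples `m = ceiling(m_fraction * n)` data points and as many uniform
#' points over the data's bounding hyper-rectangle; with `w` the
#' nearest-neighbour distances of the sampled data points to the remaining
#' data and `u` those of the uniform points to the data,
#' `H = sum(w) / (sum(w) + sum(u))`. Under the convention used here,
#' spatially uniform data gives H near 0.5 and clustered data pushes H
#' below 0.5 (the opposite labelling also circulates in the literature;
#' this one makes "small H = clusterable").
#'
#' @param m Numeric matrix.
#' @param m_fraction Fraction of rows to sample (default 0.1).
#' @param seed Integer seed.
#' @return H in (0, 1).
#' @export
hopkins_statistic <- function(m, m_fraction = 0.1, seed = 1L) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (n < 10) abort("need at least 10 rows",
                    class = "handwritr_insufficient_data")
  set.seed(seed)
  msamp <- ceiling(m_fraction * n)
  idx <- sample.int(n, msamp)
  lo <- apply(m, 2, min); hi <- apply(m, 2, max)
  unif <- sapply(seq_along(lo), function(j) runif(msamp, lo[j], hi[j]))
  unif <- matrix(unif, nrow = msamp)
  nn_dist <- function(points, refs) {
    vapply(seq_len(nrow(points)), function(i) {
      sqrt(min(rowSums(sweep(refs, 2, points[i, ])^2)))
    }, numeric(1))
  }
  w <- vapply(idx, function(i) {
    sqrt(min(rowSums(sweep(m[-i, , drop = FALSE], 2, m[i, ])^2)))
  }, numeric(1))
  u <- nn_dist(unif, m)
  sum(w) / (sum(w) + sum(u))
}

jaccard <- function(a, b) {
  i <- length(intersect(a, b))
  if (i == 0) return(0)
  i / length(union(a, b))
}

#' Bootstrap cluster stability (Jaccard)
#'
#' Resamples the rows with replacement `B` times, re-runs K-means on each
#' resample, matches each original cluster to its best-overlapping
#' bootstrap cluster by Jaccard similarity on the shared points (unique
#' resampled rows), and reports the per-original-cluster mean Jaccard.
#' Values near 1 mean the cluster re-forms reliably under perturbation;
#' below ~0.6-0.7 a cluster is usually considered dissolved. Resamples
#' holding `<= k` distinct rows (possible on small cohorts at large k)
#' cannot be clustered at k and are discarded from the average.
#'
#' @param m Standardized feature matrix.
#' @param k Number of clusters.
#' @param B Bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @param n_init Restarts per fit.
#' @return Numeric vector of length k: mean Jaccard per original cluster.
#' @export
cluster_stability <- function(m, k, B = 100, seed = 1L, n_init = 10) {
  base <- kmeans_fit(m, k, seed = seed, n_init = n_init)
  orig <- lapply(seq_len(k), function(g) which(base$assignments == g))
  set.seed(seed + 1L)
  jac <- matrix(NA_real_, nrow = B, ncol = k)
  n <- nrow(m)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    shared <- unique(idx)
    # a resample can hold fewer distinct points than k on small cohorts;
    # such replicates cannot be clustered at k and are discarded
    if (length(shared) <= k) next
    km <- kmeans(m[idx, , drop = FALSE], centers = k, nstart = n_init,
                 iter.max = 100)
    # assign every original shared point to its bootstrap cluster via the
    # nearest bootstrap centroid
    cen <- km$centers
    boot_cl <- apply(m[shared, , drop = FALSE], 1, function(p) {
      which.min(colSums((t(cen) - p)^2))
    })
    boot_sets <- lapply(seq_len(k), function(g) shared[boot_cl == g])
    for (g in seq_len(k)) {
      os <- intersect(orig[[g]], shared)
      jac[b, g] <- max(vapply(boot_sets, function(bs)
        jaccard(os, intersect(bs, shared)), numeric(1)))
    }
  }
  colMeans(jac, na.rm = TRUE)
}

#' Table-style per-cluster summary
#'
#' Per-cluster mean (SD) of each raw digital feature, demographic counts,
#' and omnibus group tests: Kruskal-Wallis for continuous columns,
#' chi-squared for categorical ones (Fisher's exact test when any expected
#' count falls below 5). SDs of singleton clusters are reported missing.
#'
#' @param cohort Cohort tibble (rows used in the clustering, in order).
#' @param assignments Integer cluster labels for those rows.
#' @param features Continuous columns to summarise.
#' @param categorical Categorical columns to cross-tabulate.
#' @return List of class `hw_cluster_summary`: `continuous` (tibble:
#'   variable, per-cluster `mean_k` / `sd_k`, `p.value`), `categorical`
#'   (variable, level counts per cluster, `p.value`), `sizes`.
#' @export
summarize_clusters <- function(cohort, assignments,
                               features = intersect(feature_names(),
                                                    names(cohort)),
                               categorical = intersect(
                                 c("gender", "handedness"), names(cohort))) {
  stopifnot(nrow(cohort) == length(assignments))
  ks <- sort(unique(assignments))
  single <- length(ks) == 1

  cont <- purrr::map_dfr(features, function(f) {
    vals <- cohort[[f]]
    row <- tibble::tibble(variable = f)
    for (g in ks) {
      v <- vals[assignments == g]
      row[[paste0("mean_", g)]] <- mean(v, na.rm = TRUE)
      row[[paste0("sd_", g)]] <-
        if (sum(!is.na(v)) > 1) sd(v, na.rm = TRUE) else NA_real_
    }
    row$p.value <- if (single || sum(!is.na(vals)) < length(ks) + 1) {
      NA_real_
    } else {
      tryCatch(kruskal.test(vals, factor(assignments))$p.value,
               error = function(e) NA_real_)
    }
    row
  })

  cat_tab <- purrr::map_dfr(categorical, function(f) {
    tab <- table(cohort[[f]], assignments)
    p <- if (single) NA_real_ else {
      exp_counts <- suppressWarnings(chisq.test(tab)$expected)
      if (any(exp_counts < 5)) {
        tryCatch(fisher.test(tab)$p.value, error = function(e) NA_real_)
      } else {
        chisq.test(tab)$p.value
      }
    }
    counts <- as.data.frame(tab)
    names(counts) <- c("level", "cluster", "n")
    tibble::tibble(variable = f,
                   counts = list(tibble::as_tibble(counts)), p.value = p)
  })

  structure(list(continuous = cont, categorical = cat_tab,
                 sizes = tibble::tibble(cluster = ks,
                                        n = as.integer(table(assignments)))),
            class = "hw_cluster_summary")
}

#' @export
print.hw_cluster_summary <- function(x, ...) {
  cat("<hw_cluster_summary> cluster sizes:",
      paste(x$sizes$n, collapse = ", "), "\n")
  print(x$continuous)
  invisible(x)
}

#' K-means subtyping of a dysgraphic cohort
#'
#' End-to-end convenience wrapper used by the pipeline: standardizes the
#' feature columns, selects k by index majority (unless fixed), fits
#' K-means, and attaches Hopkins clustering tendency, bootstrap-Jaccard
#' stability and the per-cluster summary.
#'
#' @param cohort Cohort tibble holding the twelve feature columns (usually
#'   the dysgraphic subset).
#' @param k Number of clusters, or `NULL` to choose by [choose_k()].
#' @param seed Integer seed.
#' @param stability_B Bootstrap replicates for [cluster_stability()].
#' @return A `hw_cluster_result`: assignments (NA for dropped rows),
#'   centroids, chosen k and vote table, inertia curve, `hopkins`,
#'   `stability`, `summary`. [tidy()] returns per-child assignments,
#'   [glance()] the diagnostics, [autoplot()] a 2-D principal-component
#'   view.
#' @export
subtype_clustering <- function(cohort, k = NULL, seed = 1L,
                               stability_B = 100) {
  feats <- intersect(feature_names(), names(cohort))
  m <- standardize_matrix(cohort[feats])
  used <- setdiff(seq_len(nrow(cohort)), attr(m, "dropped_rows"))
  sel <- if (is.null(k)) {
    choose_k(m, k_range = 2:min(8, nrow(m) - 1), seed = seed)
  } else {
    list(chosen_k = k, votes = NULL, inertia = NULL, low_confidence = FALSE)
  }
  fit <- kmeans_fit(m, sel$chosen_k, seed = seed)
  assignments <- rep(NA_integer_, nrow(cohort))
  assignments[used] <- fit$assignments
  structure(list(
    k = sel$chosen_k, votes = sel$votes, inertia = sel$inertia,
    low_confidence = sel$low_confidence,
    assignments = assignments, centroids = fit$centroids,
    matrix = m, used_rows = used, seed = seed,
    hopkins = hopkins_statistic(m, seed = seed),
    stability = cluster_stability(m, sel$chosen_k, B = stability_B,
                                  seed = seed),
    summary = summarize_clusters(cohort[used, ], fit$assignments)),
    class = "hw_cluster_result")
}

#' @export
print.hw_cluster_result <- function(x, ...) {
  cat(sprintf("<hw_cluster_result> k = %d, Hopkins = %.3f\n", x$k,
              x$hopkins))
  cat("stability:", paste(sprintf("%.2f", x$stability), collapse = ", "),
      "\n")
  print(x$summary$sizes)
  invisible(x)
}

#' @rdname subtype_clustering
#' @param x A `hw_cluster_result`.
#' @param ... Unused.
#' @method tidy hw_cluster_result
#' @export
tidy.hw_cluster_result <- function(x, ...) {
  tibble::tibble(row = seq_along(x$assignments), cluster = x$assignments)
}

#' @rdname subtype_clustering
#' @method glance hw_cluster_result
#' @export
glance.hw_cluster_result <- function(x, ...) {
  tibble::tibble(k = x$k, hopkins = x$hopkins,
                 min_stability = min(x$stability),
                 low_confidence = x$low_confidence,
                 n = length(x$used_rows))
}
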