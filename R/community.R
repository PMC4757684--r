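# Beta-diversity between samples: 1 - Pearson correlation of square-root
# transformed all-rank abundance vectors (the sqrt raises the weight of
# low-abundance taxa). The distance lives in [0, 2] and is kept unclipped.

dist_from_vectors <- function(va, vb, name_a = "a", name_b = "b") {
  sa <- sqrt(va); sb <- sqrt(vb)
  if (stats::sd(sa) == 0) {
    abort(paste0("degenerate sample '", name_a,
                 "': constant abundance vector"))
  }
  if (stats::sd(sb) == 0) {
    abort(paste0("degenerate sample '", name_b,
                 "': constant abundance vector"))
  }
  1 - cor(sa, sb)
}

#' Taxonomic distance between two samples
#'
#' `d = 1 - r`, with `r` the Pearson correlation between the square-root
#' transformed all-rank abundance vectors of the two samples over a shared
#' taxon universe.
#'
#' @param profiles A normalized profiles tibble containing both samples.
#' @param a,b Sample ids.
#' @param universe Shared universe (defaults to the universe of the two
#'   samples; pass the study-wide universe for consistency with
#'   [distance_matrix()]).
#' @return A single distance in `[0, 2]`.
#' @export
pairwise_distance <- function(profiles, a, b,
                              universe = NULL) {
  pair <- profiles %>% filter(.data$sample_id %in% c(a, b))
  if (length(unique(pair$sample_id)) != 2L) {
    abort("samples 'a' and 'b' must both be present and distinct")
  }
  if (is.null(universe)) universe <- taxon_universe(pair)
  mat <- all_rank_matrix(pair, universe)
  dist_from_vectors(mat[a, ], mat[b, ], a, b)
}

#' Distance matrix over a study set
#'
#' @param profiles A normalized profiles tibble with at least two samples.
#' @param universe Taxon universe; defaults to the union over all samples.
#' @return A symmetric matrix of class `commpath_dist` with zero diagonal;
#'   sample metadata travels in the `"meta"` attribute for
#'   [stability_test()].
#' @export
distance_matrix <- function(profiles, universe = taxon_universe(profiles)) {
  check_profiles(profiles, need_normalized = TRUE)
  mat <- all_rank_matrix(profiles, universe)
  n <- nrow(mat)
  if (n < 2L) abort("need at least two samples")
  sm <- sqrt(mat)
  sds <- apply(sm, 1L, stats::sd)
  if (any(sds == 0)) {
    abort(paste0("degenerate sample(s): ",
                 paste(rownames(mat)[sds == 0], collapse = ", ")))
  }
  d <- 1 - cor(t(sm))
  diag(d) <- 0
  structure(d, class = c("commpath_dist", "matrix"),
            meta = profile_meta(profiles))
}

#' @export
tidy.commpath_dist <- function(x, ...) {
  ids <- rownames(x)
  pairs <- which(upper.tri(x), arr.ind = TRUE)
  tibble(sample_a = ids[pairs[, 1]], sample_b = ids[pairs[, 2]],
         distance = x[pairs])
}

#' Ward's minimum-variance clustering of a distance matrix
#'
#' Standard agglomerative Ward clustering: the Lance-Williams update runs
#' on squared dissimilarities and merge heights are reported back on the
#' distance scale (so two samples at distance d merge at height d). Set
#' `heights = "squared"` to keep heights on the squared scale instead; the
#' tree topology is identical.
#'
#' @param dm A `commpath_dist` (or any symmetric matrix with labels).
#' @param heights Scale on which merge heights are reported.
#' @return An `hclust` tree; convert with [ape::as.phylo()] for Newick
#'   export.
#' @export
ward_linkage <- function(dm, heights = c("distance", "squared")) {
  heights <- match.arg(heights)
  if (nrow(dm) < 2L) abort("need at least two samples to cluster")
  m <- unclass(dm)
  attr(m, "meta") <- NULL
  if (heights == "distance") {
    hclust(as.dist(m), method = "ward.D2")
  } else {
    hclust(as.dist(m^2), method = "ward.D")
  }
}

#' Principal components of square-root transformed profiles
#'
#' PCA of the centred samples-by-taxa matrix of square-root all-rank
#' abundances. Component signs are fixed by forcing each component's
#' largest-magnitude loading positive, so coordinates are reproducible.
#'
#' @param profiles A normalized profiles tibble (at least two samples).
#' @param universe Taxon universe; defaults to the union over samples.
#' @param n_components Number of components to keep; `NULL` keeps all
#'   (at most `n_samples - 1`); larger requests are truncated with a
#'   warning.
#' @return A `commpath_pca` object: `coords` (tibble sample_id, PC1, ...),
#'   `explained` (variance fractions), `loadings`, `meta`.
#' @export
pca_coords <- function(profiles, universe = taxon_universe(profiles),
                       n_components = NULL) {
  check_profiles(profiles, need_normalized = TRUE)
  mat <- sqrt(all_rank_matrix(profiles, universe))
  if (nrow(mat) < 2L) abort("need at least two samples")
  fit <- prcomp(mat, center = TRUE, scale. = FALSE)
  nz <- sum(fit$sdev > max(fit$sdev) * 1e-12)
  k <- n_components %||% nz
  if (k > nz) {
    warn(paste0("only ", nz, " non-degenerate component(s); truncating"))
    k <- nz
  }
  scores <- fit$x[, seq_len(k), drop = FALSE]
  loads <- fit$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (loads[which.max(abs(loads[, j])), j] < 0) {
      loads[, j] <- -loads[, j]
      scores[, j] <- -scores[, j]
    }
  }
  explained <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(
    coords = as_tibble(scores) %>%
      mutate(sample_id = rownames(scores), .before = 1L),
    explained = explained[seq_len(k)],
    loadings = loads,
    meta = profile_meta(profiles)
  ), class = "commpath_pca")
}

#' @export
tidy.commpath_pca <- function(x, ...) {
  left_join(x$coords, x$meta, by = "sample_id")
}

#' Scatter plot of two principal components
#'
#' @param object A `commpath_pca`.
#' @param components Which two components to draw (2 and 3 are a common
#'   choice when a dominant gradient occupies component 1).
#' @param ... Unused.
#' @return A ggplot object, points coloured by plant, shaped by compartment.
#' @export
autoplot.commpath_pca <- function(object, components = c(1L, 2L), ...) {
  cn <- paste0("PC", components)
  if (!all(cn %in% names(object$coords))) {
    abort("requested components were not computed")
  }
  df <- tidy(object)
  pct <- round(100 * object$explained[components], 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[cn[1]]], y = .data[[cn[2]]],
                                   colour = .data$plant,
                                   shape = .data$compartment)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = paste0(cn[1], " (", pct[1], "%)"),
                  y = paste0(cn[2], " (", pct[2], "%)")) +
    ggplot2::theme_minimal()
}

#' Two-sided Mann-Whitney U test with an exact small-sample null
#'
#' Exact enumeration-based p-value when both groups have at most
#' `exact_max` observations and no ties are present; otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric vectors.
#' @param exact_max Largest group size for which the exact null is used.
#' @return List with `U` (number of (x, y) pairs with x > y, ties counted
#'   half), `p_two_sided`, and `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(x, y, exact_max = 12L) {
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- length(x) <= exact_max && length(y) <= exact_max && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)
  )
  list(U = unname(wt$statistic), p_two_sided = wt$p.value,
       method = if (exact) "exact" else "normal")
}

#' Temporal-stability test: activated sludge vs incoming wastewater
#'
#' For each (plant, compartment), all distances between samples taken at
#' different dates form a pool (with 3 monthly samplings each pool holds
#' the 3 month-vs-month distances). The AS pools are
#' concatenated, the IW pools are concatenated, and the two groups are
#' compared with a two-sided Mann-Whitney U test: a stable sludge community
#' gives systematically smaller cross-month distances than the incoming
#' sewage.
#'
#' @param dm A `commpath_dist` from [distance_matrix()] over
#'   replicate-merged samples (one sample per plant, compartment and date).
#' @param meta Sample metadata; defaults to the metadata attached to `dm`.
#' @return A `commpath_stability` object: `as_pool`, `iw_pool`, per-pool
#'   tibble `pools`, `U`, `p_two_sided`, `method`.
#' @export
stability_test <- function(dm, meta = attr(dm, "meta")) {
  if (is.null(meta)) abort("sample metadata required")
  ids <- rownames(dm)
  meta <- meta %>% filter(.data$sample_id %in% ids)
  key <- paste(meta$plant, meta$compartment, meta$date)
  if (anyDuplicated(key)) {
    abort("replicates must be merged before the stability test")
  }
  pools <- meta %>%
    group_by(.data$plant, .data$compartment) %>%
    dplyr::group_modify(function(g, k) {
      if (nrow(g) < 2L) {
        abort(paste0("need >= 2 time points for plant ", k$plant,
                     " compartment ", k$compartment))
      }
      pr <- combn(g$sample_id, 2L)
      tibble(sample_a = pr[1, ], sample_b = pr[2, ],
             distance = dm[cbind(pr[1, ], pr[2, ])])
    }) %>%
    ungroup()
  as_pool <- pools$distance[pools$compartment == "AS"]
  iw_pool <- pools$distance[pools$compartment == "IW"]
  if (!length(as_pool) || !length(iw_pool)) {
    abort("both compartments (AS, IW) are required")
  }
  mw <- mann_whitney_u(as_pool, iw_pool)
  structure(list(as_pool = as_pool, iw_pool = iw_pool, pools = pools,
                 U = mw$U, p_two_sided = mw$p_two_sided,
                 method = mw$method),
            class = "commpath_stability")
}

#' @export
print.commpath_stability <- function(x, ...) {
  cat("Temporal stability (pooled Mann-Whitney U, ", x$method, " null)\n",
      "  AS pool: n = ", length(x$as_pool), ", median d = ",
      signif(stats::median(x$as_pool), 3), "\n",
      "  IW pool: n = ", length(x$iw_pool), ", median d = ",
      signif(stats::median(x$iw_pool), 3), "\n",
      "  U = ", x$U, ", two-sided p = ", signif(x$p_two_sided, 3), "\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.commpath_stability <- function(x, ...) {
  x$pools
}

#' @export
glance.commpath_stability <- function(x, ...) {
  tibble(n_as = length(x$as_pool), n_iw = length(x$iw_pool),
         median_as = stats::median(x$as_pool),
         median_iw = stats::median(x$iw_pool),
         U = x$U, p_two_sided = x$p_two_sided, method = x$method)
}
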