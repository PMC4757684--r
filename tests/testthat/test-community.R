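two_sample_profiles <- function(ca, cb) {
  dplyr::bind_rows(
    toy_profile(ca, sample_id = "a", replicate = 1L, normalized = TRUE),
    toy_profile(cb, sample_id = "b", replicate = 2L, normalized = TRUE))
}

test_that("1 - r distance on sqrt vectors matches hand computations", {
  gl <- function(x) paste0("domain:Bacteria;genus:", x)
  # identical content -> 0
  ca <- stats::setNames(c(0.5, 0.3, 0.2), gl(c("A", "B", "C")))
  expect_equal(pairwise_distance(two_sample_profiles(ca, ca), "a", "b"), 0,
               tolerance = 1e-12)
  # (4,1,1)/6 vs (1,1,4)/6: sqrt vectors (2,1,1), (1,1,2) -> r = -0.5
  ca <- stats::setNames(c(4, 1, 1) / 6, gl(c("A", "B", "C")))
  cb <- stats::setNames(c(1, 1, 4) / 6, gl(c("A", "B", "C")))
  pr <- two_sample_profiles(ca, cb)
  uni <- taxon_universe(pr) %>% dplyr::filter(rank == "genus")
  expect_equal(pairwise_distance(pr, "a", "b", uni), 1.5, tolerance = 1e-12)
  # anti-correlated two-taxon profiles -> r = -1, d = 2
  ca <- stats::setNames(c(1, 0), gl(c("A", "B")))
  cb <- stats::setNames(c(0, 1), gl(c("A", "B")))
  pr <- two_sample_profiles(ca, cb)
  uni <- taxon_universe(pr) %>% dplyr::filter(rank == "genus")
  expect_equal(pairwise_distance(pr, "a", "b", uni), 2, tolerance = 1e-12)
})

test_that("distance is symmetric, bounded and depth-invariant", {
  set.seed(101)
  gl <- function(x) paste0("domain:Bacteria;genus:Gen", x)
  for (i in 1:25) {
    ca <- stats::setNames(stats::rpois(6, 30) + 1, gl(1:6))
    cb <- stats::setNames(stats::rpois(6, 30) + 1, gl(1:6))
    pa <- normalize_profiles(toy_profile(ca, sample_id = "a",
                                         replicate = 1L))
    pb <- normalize_profiles(toy_profile(cb, sample_id = "b",
                                         replicate = 2L))
    pr <- dplyr::bind_rows(pa, pb)
    d <- pairwise_distance(pr, "a", "b")
    expect_equal(pairwise_distance(pr, "b", "a"), d, tolerance = 1e-12)
    expect_gte(d, 0 - 1e-12); expect_lte(d, 2 + 1e-12)
    # multiplying one profile's pre-normalization counts is invisible
    pb2 <- normalize_profiles(toy_profile(cb * 17, sample_id = "b",
                                          replicate = 2L))
    expect_equal(pairwise_distance(dplyr::bind_rows(pa, pb2), "a", "b"), d,
                 tolerance = 1e-12)
  }
})

test_that("the distance matrix agrees with pairwise calls and permutes", {
  set.seed(102)
  gl <- function(x) paste0("domain:Bacteria;genus:Gen", x)
  profs <- dplyr::bind_rows(lapply(1:4, function(i) {
    normalize_profiles(toy_profile(
      stats::setNames(stats::rpois(5, 20) + 1, gl(1:5)),
      sample_id = paste0("s", i), replicate = i))
  }))
  dm <- distance_matrix(profs)
  uni <- taxon_universe(profs)
  for (a in rownames(dm)) for (b in colnames(dm)) {
    if (a == b) { expect_equal(dm[a, b], 0); next }
    expect_equal(dm[a, b], pairwise_distance(profs, a, b, uni),
                 tolerance = 1e-12)
  }
  # input order does not matter beyond labels
  dm2 <- distance_matrix(profs %>% dplyr::arrange(dplyr::desc(sample_id)))
  expect_equal(dm2[rownames(dm), colnames(dm)], unclass(dm)[, ],
               ignore_attr = TRUE)
  # a uniform sample is constant at a single rank and refused by name
  flat <- normalize_profiles(toy_profile(
    stats::setNames(rep(1, 5), gl(1:5)), sample_id = "flat",
    replicate = 9L))
  genus_uni <- uni %>% dplyr::filter(rank == "genus")
  expect_error(distance_matrix(dplyr::bind_rows(profs, flat), genus_uni),
               "flat")
})

test_that("Ward clustering matches a textbook Lance-Williams oracle", {
  # n = 2 base case: single merge at the pair distance
  m <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"),
                                                    c("a", "b")))
  hc <- ward_linkage(m)
  expect_equal(hc$height, 0.4, tolerance = 1e-12)
  # forced first merge of the coincident pair
  m3 <- matrix(c(0, 0, 1, 0, 0, 1.1, 1, 1.1, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  hc3 <- ward_linkage(m3)
  expect_equal(sort(hc3$merge[1, ]), c(-2, -1))
  # random matrices: cophenetic equality with the oracle
  set.seed(103)
  for (i in 1:15) {
    n <- sample(6:10, 1)
    pts <- matrix(stats::rnorm(n * 3), n)
    d <- as.matrix(stats::dist(pts))
    d <- d / max(d)
    dimnames(d) <- list(letters[1:n], letters[1:n])
    got <- as.matrix(stats::cophenetic(ward_linkage(d)))
    want <- ward_oracle_cophenetic(d)
    expect_equal(got[letters[1:n], letters[1:n]], want, tolerance = 1e-9,
                 label = paste("matrix", i))
    # heights never decrease along the agglomeration
    expect_true(!is.unsorted(ward_linkage(d)$height))
  }
})

test_that("PCA coordinates match an independent eigen-decomposition", {
  set.seed(104)
  gl <- function(x) paste0("domain:Bacteria;genus:Gen", x)
  profs <- dplyr::bind_rows(lapply(1:5, function(i) {
    normalize_profiles(toy_profile(
      stats::setNames(stats::rpois(7, 25) + 1, gl(1:7)),
      sample_id = paste0("s", i), replicate = i))
  }))
  pc <- pca_coords(profs)
  mat <- sqrt(all_rank_matrix(profs))
  cen <- scale(mat, center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(cen))
  k <- length(pc$explained)
  for (j in seq_len(k)) {
    got <- pc$coords[[paste0("PC", j)]]
    want <- unname(drop(cen %*% eig$vectors[, j]))
    # same axis up to sign; the package fixes sign via the top loading
    expect_equal(abs(got), abs(want), tolerance = 1e-8)
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
  }
  expect_equal(pc$explained,
               (eig$values / sum(eig$values))[seq_len(k)], tolerance = 1e-8)

  # two samples: one non-degenerate component carrying all the variance
  two <- profs %>% dplyr::filter(sample_id %in% c("s1", "s2"))
  pc2 <- pca_coords(two)
  expect_equal(length(pc2$explained), 1L)
  expect_equal(pc2$explained, 1, tolerance = 1e-12)

  # duplicated samples coincide
  dup <- dplyr::bind_rows(profs,
                          profs %>% dplyr::filter(sample_id == "s1") %>%
                            dplyr::mutate(sample_id = "s1b",
                                          replicate = 99L))
  pcd <- pca_coords(dup)
  co <- pcd$coords
  expect_equal(unlist(co[co$sample_id == "s1", -1]),
               unlist(co[co$sample_id == "s1b", -1]), tolerance = 1e-9)
})

test_that("exact Mann-Whitney p-values match full enumeration", {
  set.seed(105)
  for (i in 1:30) {
    nx <- sample(2:7, 1); ny <- sample(2:7, 1)
    x <- stats::rnorm(nx); y <- stats::rnorm(ny) + stats::runif(1, -1, 1)
    mw <- mann_whitney_u(x, y)
    expect_equal(mw$method, "exact")
    expect_equal(mw$p_two_sided, enum_mw_p(x, y), tolerance = 1e-12,
                 label = paste("sizes", nx, ny))
  }
  # complete separation at 9 vs 9: p = 2 / C(18, 9)
  mw <- mann_whitney_u(1:9, 11:19)
  expect_equal(mw$p_two_sided, 2 / choose(18, 9), tolerance = 1e-12)
  # identical pools -> no evidence
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_two_sided, 1)
})

test_that("the stability test pools cross-time distances per location", {
  d <- sim_design(seed = 11)
  pr <- simulate_profiles(d)
  merged <- normalize_profiles(merge_replicates(pr))
  dm <- distance_matrix(merged)
  st <- stability_test(dm)
  # 3 plants x C(3,2) dates = 9 distances per compartment
  expect_length(st$as_pool, 9L)
  expect_length(st$iw_pool, 9L)
  expect_equal(st$method, "exact")
  g <- glance(st)
  expect_lt(g$median_as, g$median_iw)
  # unmerged replicates are refused
  expect_error(stability_test(distance_matrix(normalize_profiles(pr))),
               "merged")
  # missing compartment is refused
  as_only <- merged %>% dplyr::filter(compartment == "AS")
  expect_error(stability_test(distance_matrix(as_only)), "compartments")
})
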