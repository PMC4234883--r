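test_that("standardization is a population z-score per voxel", {
  m <- matrix(c(1, 2, 3), 3, 1, dimnames = list(letters[1:3], "v1"))
  z <- standardize_profiles(m)
  expect_equal(unname(z[, 1]), c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(unname(z[, 1]), c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  expect_equal(standardize_profiles(z), z)  # idempotent

  const <- matrix(c(5, 5, 5), 3, 1, dimnames = list(letters[1:3], "vc"))
  expect_error(standardize_profiles(const), "zero expression variance.*vc")
})

test_that("norm-correlation distance behaves as 1 - Pearson r", {
  base <- matrix(c(1, 2, 3, 1, 2, 3, 3, 2, 1, 1, 3, 2), 3, 4,
                 dimnames = list(letters[1:3], paste0("v", 1:4)))
  z <- standardize_profiles(base)
  D <- pairwise_norm_correlation(z)
  expect_equal(D["v1", "v2"], 0)                     # identical profiles
  expect_equal(D["v1", "v3"], 2)                     # negated profile
  expect_equal(D["v1", "v4"], 0.5)                   # hand Pearson r = 0.5
  expect_true(isSymmetric(D))
  expect_equal(unname(diag(D)), rep(0, 4))
  expect_true(all(D >= 0 & D <= 2))

  # invariance to per-voxel affine rescaling of the raw profiles
  resc <- sweep(sweep(base, 2, c(2, 3, 0.5, 10), `*`), 2, c(1, -4, 2, 0), `+`)
  expect_equal(pairwise_norm_correlation(standardize_profiles(resc)), D,
               tolerance = 1e-12)
})

test_that("metric SVD lens is classical MDS with fixed signs", {
  D <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(paste0("v", 1:3), paste0("v", 1:3)))
  lens <- metric_svd_lens(D, k = 1)
  expect_equal(lens$lens_1, c(-1, 0, 1), tolerance = 1e-9)

  # all-equal distances (equilateral triangle): equidistant from the centroid
  De <- matrix(1, 3, 3) - diag(3)
  dimnames(De) <- list(paste0("v", 1:3), paste0("v", 1:3))
  l2 <- metric_svd_lens(De, k = 2)
  norms <- sqrt(l2$lens_1^2 + l2$lens_2^2)
  expect_equal(norms, rep(norms[1], 3), tolerance = 1e-9)

  expect_error(metric_svd_lens(D, k = 3), "k")
})

test_that("lenses reproduce Euclidean configurations up to isometry", {
  pts <- withr::with_seed(5, matrix(rnorm(30 * 2), 30, 2))
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(paste0("v", 1:30), paste0("v", 1:30))
  lens <- metric_svd_lens(D, k = 2)
  X <- scale(as.matrix(lens[, c("lens_1", "lens_2")]), scale = FALSE)
  Y <- scale(pts, scale = FALSE)
  s <- svd(crossprod(X, Y))
  resid <- sqrt(sum((X %*% (s$u %*% t(s$v)) - Y)^2))
  expect_lt(resid, 1e-8)
})

test_that("equalized covers partition at gain 1 and overlap at higher gain", {
  lens8 <- tibble::tibble(voxel_id = paste0("v", 1:8), lens_1 = as.numeric(1:8))
  cov1 <- build_cover(lens8, resolution = 4, gain = 1)
  mem1 <- bin_membership(cov1, lens8)
  expect_equal(nrow(mem1), 8)  # disjoint partition
  expect_equal(unname(split(mem1$voxel_id, mem1$bin_id)[["1"]]), c("v1", "v2"))
  expect_equal(cov1$dims[[1]]$n_base, rep(2L, 4))

  lens4 <- tibble::tibble(voxel_id = paste0("v", 1:4), lens_1 = as.numeric(1:4))
  cov2 <- build_cover(lens4, resolution = 2, gain = 2)
  mem2 <- bin_membership(cov2, lens4)
  both <- names(which(table(mem2$voxel_id) == 2))
  expect_setequal(both, c("v2", "v3"))  # middle points fall in both bins

  expect_error(build_cover(lens4, resolution = 9, gain = 1), "resolution")
})

test_that("every voxel lies in >= 1 and at most ceil(gain) + 1 bins per dimension", {
  for (seed in 1:5) {
    x <- withr::with_seed(seed, runif(60))
    lens <- tibble::tibble(voxel_id = paste0("v", seq_along(x)), lens_1 = x)
    for (g in c(1, 2.5, 4)) {
      cov <- build_cover(lens, resolution = 8, gain = g)
      mem <- bin_membership(cov, lens)
      counts <- table(factor(mem$voxel_id, levels = lens$voxel_id))
      expect_true(all(counts >= 1))
      expect_true(all(counts <= ceiling(g) + 1))
      # brute-force membership oracle over the stored intervals
      iv <- cov$dims[[1]]
      oracle <- vapply(x, function(v) sum(v >= iv$lo_exp & v <= iv$hi_exp),
                       numeric(1))
      expect_equal(as.vector(counts), as.vector(oracle))
    }
  }
})

test_that("per-bin clustering cuts at the first merge-height gap", {
  ids <- paste0("v", 1:4)
  D <- matrix(1, 4, 4, dimnames = list(ids, ids))
  D[1, 2] <- D[2, 1] <- 0.01
  D[3, 4] <- D[4, 3] <- 0.01
  diag(D) <- 0
  parts <- cluster_bin(ids, D)
  expect_length(parts, 2)
  expect_setequal(vapply(parts, paste, character(1), collapse = "+"),
                  c("v1+v2", "v3+v4"))

  expect_equal(cluster_bin("v1", D), list("v1"))

  Deq <- matrix(1, 4, 4, dimnames = list(ids, ids))
  diag(Deq) <- 0
  expect_length(cluster_bin(ids, Deq), 1)  # no gap: one cluster
})

test_that("nerve edges appear exactly when member sets intersect", {
  parts <- list(b1 = list(c("v1", "v2")), b2 = list(c("v2", "v3")))
  g <- build_nerve(parts)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$weight, 1L)

  g0 <- build_nerve(list(b1 = list(c("v1", "v2")), b2 = list(c("v3", "v4"))))
  expect_equal(nrow(g0$edges), 0)

  # random instances vs brute-force pairwise intersection oracle
  for (seed in 1:5) {
    parts <- withr::with_seed(seed, {
      bins <- lapply(1:6, function(b) {
        members <- sample(paste0("v", 1:25), sample(3:8, 1))
        split(members, sample(1:2, length(members), replace = TRUE))
      })
      names(bins) <- paste0("b", 1:6)
      bins
    })
    g <- build_nerve(parts)
    n <- nrow(g$nodes)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        shared <- length(intersect(g$nodes$members[[i]], g$nodes$members[[j]]))
        hit <- g$edges[g$edges$from == i & g$edges$to == j, ]
        expect_equal(nrow(hit), as.integer(shared > 0))
        if (shared > 0) expect_equal(hit$weight, shared)
      }
    }
  }
})

test_that("graph-only segmentation respects components, weights and k", {
  two_comp <- build_nerve(list(b1 = list(c("v1", "v2")), b2 = list(c("v2", "v3")),
                               b3 = list(c("v8", "v9")), b4 = list(c("v9"))))
  lab <- segment_nerve(two_comp)
  k_found <- length(unique(lab$cluster))
  expect_equal(k_found, 2)
  expect_equal(length(unique(lab$cluster[lab$voxel_id %in% c("v1", "v2", "v3")])), 1)

  # chain with heavy A-B edge splits off C at k = 2
  chain <- build_nerve(list(
    b1 = list(c("v1", "v2", "v3", "v4")),
    b2 = list(c("v1", "v2", "v3", "v5")),
    b3 = list(c("v5", "v6"))
  ))
  lab2 <- segment_nerve(chain, k = 2)
  expect_equal(length(unique(lab2$cluster)), 2)
  comm <- attr(lab2, "node_communities")
  expect_equal(comm[1], comm[2])
  expect_false(comm[1] == comm[3])

  lab3 <- segment_nerve(chain, k = 3)
  expect_equal(length(unique(attr(lab3, "node_communities"))), 3)

  expect_error(segment_nerve(chain, k = 4), "exceeds")
})

test_that("the full pipeline is deterministic and keeps duplicates together", {
  fx <- generate_fixture(synthetic_config(rows = 8, cols = 6, n_genes = 300,
                                          markers_per_program = 30, seed = 9))
  expr <- normalize_per_million(fx$counts)
  # duplicate one voxel's profile
  expr2 <- cbind(expr, dup = expr[, 3])
  colnames(expr2)[ncol(expr2)] <- "vdup"
  fit <- run_mapper(expr2, resolution = c(6, 5))
  orig <- colnames(expr2)[3]
  l <- fit$labels
  expect_equal(l$cluster[l$voxel_id == "vdup"], l$cluster[l$voxel_id == orig])
  nodes_with <- function(v) which(vapply(fit$graph$nodes$members,
                                         function(m) v %in% m, logical(1)))
  expect_equal(nodes_with("vdup"), nodes_with(orig))

  fit2 <- run_mapper(expr2, resolution = c(6, 5))
  expect_identical(fit$labels, fit2$labels)
  expect_identical(fit$graph$edges, fit2$graph$edges)
})
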