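test_that("gene projection places values at grid positions, background elsewhere", {
  grid <- tibble::tibble(
    voxel_id = c("a", "b", "c"), section_id = "S1",
    row = c(0L, 0L, 1L), col = c(0L, 1L, 0L)
  )
  expr <- matrix(c(0, 0, 5, 0, 0, 0), 2, 3,
                 dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  img <- project_gene(expr, grid, "g1", "S1")
  expect_equal(dim(img$values), c(2L, 2L))
  expect_equal(img$values[1, 2], 5)
  expect_equal(sum(img$values != 0, na.rm = TRUE), 1)
  expect_true(is.na(img$values[2, 2]))       # background

  # pixel -> voxel lookup inverts the projection on the mask
  for (i in seq_len(nrow(grid))) {
    expect_equal(pixel_voxel(img, grid$row[i] + 1, grid$col[i] + 1),
                 grid$voxel_id[i])
  }
  expect_true(is.na(pixel_voxel(img, 2, 2)))

  expect_error(project_gene(expr, grid, "nope", "S1"), "unknown gene")
  expect_error(project_gene(expr, grid, "g1", "S9"), "unknown section")
})

test_that("cluster projection reports 4-connected components", {
  grid <- tibble::tibble(
    voxel_id = paste0("v", 1:4), section_id = "S1",
    row = c(0L, 0L, 1L, 1L), col = c(0L, 1L, 0L, 1L)
  )
  uni <- tibble::tibble(voxel_id = grid$voxel_id, cluster = 1L)
  img1 <- project_clusters(uni, grid, "S1")
  expect_equal(img1$contiguity$n_components, 1L)

  checker <- tibble::tibble(voxel_id = grid$voxel_id,
                            cluster = c(1L, 2L, 2L, 1L))
  img2 <- project_clusters(checker, grid, "S1")
  expect_equal(img2$contiguity$n_components, c(2L, 2L))

  expect_error(project_clusters(uni[-1, ], grid, "S1"), "unlabeled voxel")
})

test_that("planted spatial programs back-project onto their bands", {
  # near-exclusive markers so projected mass concentrates in the planted band
  cfg <- synthetic_config(rows = 12, cols = 8, n_genes = 300,
                          markers_per_program = 20, effect_log2 = 10,
                          dropout = 0, seed = 1)
  fx <- generate_fixture(cfg)
  expr <- normalize_per_million(fx$counts)
  vz_marker <- fx$marker_genes$gene[fx$marker_genes$program == 1][1]
  img <- project_gene(expr, fx$grid, vz_marker, "S1")
  band1 <- fx$truth$voxel_id[fx$truth$program == 1]
  vals <- expr[vz_marker, ]
  expect_gte(sum(vals[band1]) / sum(vals), 0.95)

  # bands 1-3 contiguous; interleaved programs 4/5 fragment but their union
  # forms the single ventral band
  timg <- project_clusters(
    tibble::tibble(voxel_id = fx$truth$voxel_id, cluster = fx$truth$program),
    fx$grid, "S1"
  )
  ct <- timg$contiguity
  expect_equal(ct$n_components[ct$cluster %in% 1:3], rep(1L, 3))
  expect_true(all(ct$n_components[ct$cluster %in% 4:5] > 1L))
  merged <- tibble::tibble(voxel_id = fx$truth$voxel_id,
                           cluster = pmin(fx$truth$program, 4L))
  mimg <- project_clusters(merged, fx$grid, "S1")
  expect_equal(mimg$contiguity$n_components[mimg$contiguity$cluster == 4], 1L)
})

test_that("PNG rendering is deterministic, scales blocks, and round-trips labels", {
  grid <- tibble::tibble(voxel_id = "a", section_id = "S1", row = 0L, col = 0L)
  expr <- matrix(3, 1, 1, dimnames = list("g1", "a"))
  img <- project_gene(expr, grid, "g1", "S1")
  p <- withr::local_tempfile(fileext = ".png")
  render_png(img, p, scale = 10)
  decoded <- png::readPNG(p)
  expect_equal(dim(decoded)[1:2], c(10L, 10L))

  p2 <- withr::local_tempfile(fileext = ".png")
  render_png(img, p2, scale = 10)
  expect_identical(readBin(p, "raw", n = 1e6), readBin(p2, "raw", n = 1e6))

  # categorical decode recovers the label array exactly
  grid4 <- tibble::tibble(voxel_id = paste0("v", 1:4), section_id = "S1",
                          row = c(0L, 0L, 1L, 1L), col = c(0L, 1L, 0L, 1L))
  labs <- tibble::tibble(voxel_id = grid4$voxel_id, cluster = c(1L, 2L, 3L, 1L))
  cimg <- project_clusters(labs, grid4, "S1")
  pc <- withr::local_tempfile(fileext = ".png")
  render_png(cimg, pc, scale = 3)
  dec <- png::readPNG(pc)
  pal <- grDevices::col2rgb(grDevices::palette.colors(9, "Okabe-Ito")) / 255
  recovered <- matrix(NA_integer_, 2, 2)
  for (i in 1:2) {
    for (j in 1:2) {
      px <- dec[(i - 1) * 3 + 1, (j - 1) * 3 + 1, 1:3]
      recovered[i, j] <- which.min(colSums((pal - px)^2))
    }
  }
  expect_equal(recovered, matrix(c(1L, 3L, 2L, 1L), 2, 2))
})

test_that("continuous images scale to the section maximum", {
  cfg <- synthetic_config(rows = 8, cols = 6, n_genes = 100,
                          markers_per_program = 10, seed = 4)
  fx <- generate_fixture(cfg)
  expr <- normalize_per_million(fx$counts)
  g <- rownames(expr)[which.max(rowSums(expr))]
  img <- project_gene(expr, fx$grid, g, "S1")
  expect_equal(max(img$values, na.rm = TRUE), max(expr[g, ]))
  cols <- image_colors(img)
  ramp <- grDevices::hcl.colors(256, "Inferno")
  expect_equal(cols[which(img$values == max(img$values, na.rm = TRUE))[1]],
               ramp[256])
})
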