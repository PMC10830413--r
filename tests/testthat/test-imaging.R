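test_that("binarization is strict and monotone in threshold", {
  u <- matrix(10, 3, 3)
  expect_false(any(binarize(u, 10)))
  expect_true(all(binarize(u, 9.9)))
  m <- matrix(c(0, 5, 2, 7, 1, 9, 3, 4, 6), 3, 3)
  expect_equal(binarize(m, 4), m > 4)
  for (t2 in c(2, 5, 8)) {
    expect_true(all(binarize(m, t2) | !binarize(m, t2)))
    expect_lte(sum(binarize(m, t2 + 1)), sum(binarize(m, t2)))
  }
})

test_that("8-connectivity labeling merges diagonal touches", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE  # diagonal contact
  m[5, 5] <- TRUE
  l8 <- label_components(m, 8)
  expect_equal(max(l8), 2)
  expect_equal(l8[1, 1], l8[2, 2])
  l4 <- label_components(m, 4)
  expect_equal(max(l4), 3)
})

test_that("synapse puncta follow the area and halo rules", {
  mk <- function() matrix(FALSE, 40, 40)
  dend <- mk(); dend[20, 5:35] <- TRUE

  # 4-px overlap 3 px from the dendrite: one punctum
  v <- mk(); h <- mk()
  v[16:17, 10:11] <- TRUE; h[16:17, 10:11] <- TRUE
  expect_equal(synapse_puncta(v, h, dend)$count, 1)

  # 2-px overlap on the dendrite: below "more than two pixels"
  v2 <- mk(); h2 <- mk()
  v2[20, 15:16] <- TRUE; h2[20, 15:16] <- TRUE
  expect_equal(synapse_puncta(v2, h2, dend)$count, 0)

  # 6-px overlap 8 px away: outside the 5-px halo
  v3 <- mk(); h3 <- mk()
  v3[10:11, 25:27] <- TRUE; h3[10:11, 25:27] <- TRUE
  expect_equal(synapse_puncta(v3, h3, dend)$count, 0)

  # overlap requirement: signals in only one channel never count
  v4 <- mk(); v4[19:21, 30:32] <- TRUE
  expect_equal(synapse_puncta(v4, mk(), dend)$count, 0)
})

test_that("puncta counting is translation invariant", {
  sc <- gen_synapse_scene(dendrite_length_um = 30, puncta_per_um = 0.4,
                          seed = 8)
  v <- binarize(sc$vglut, sc$threshold)
  h <- binarize(sc$homer, sc$threshold)
  d <- binarize(sc$map2, sc$threshold)
  base <- synapse_puncta(v, h, d)$count
  sh <- function(m) {
    out <- matrix(FALSE, nrow(m) + 7, ncol(m) + 3)
    out[8:(nrow(m) + 7), 4:(ncol(m) + 3)] <- m
    out
  }
  expect_equal(synapse_puncta(sh(v), sh(h), sh(d))$count, base)
})

test_that("puncta density arithmetic", {
  expect_equal(puncta_density(10, 20), 0.5)
  expect_equal(puncta_density(0, 20), 0)
  expect_error(puncta_density(3, 0), "positive")
})

test_that("soma counting applies the strict size rules exactly", {
  sc <- gen_soma_scene(c(100, 80, 30, 200, 151), seed = 2)
  expect_equal(count_somas(sc$mask, 81), 3)
  expect_equal(count_somas(sc$mask, 151), 2)
  expect_equal(count_somas(matrix(FALSE, 10, 10), 81), 0)
  # generator plants exact areas
  lab <- label_components(sc$mask, 8)
  expect_setequal(tabulate(lab[lab > 0]), c(100, 80, 30, 200, 151))
})

test_that("connectivity ratios normalize to starters", {
  expect_equal(unname(connectivity_ratios(c(ipsiCA3 = 120), 30)), 4)
  r <- connectivity_ratios(c(ipsiCA3 = 120, contraCA3 = 60, LEC = 0), 30)
  expect_equal(unname(r), c(4, 2, 0))
  expect_error(connectivity_ratios(c(a = 1), 0), "positive")
})

test_that("droplet line profile distinguishes shell from uniform filling", {
  for (sh in c(FALSE, TRUE)) {
    d <- gen_droplet_scene(cluster_sizes = 1, radius_range = c(28, 28),
                           shell = sh, img_size = 150, seed = 2)
    pr <- droplet_line_profile(list(reporter = d$reporter),
                               d$truth$centers[1, ])
    if (sh) expect_gt(pr$enrichment[["reporter"]], 1)
    else expect_lt(pr$enrichment[["reporter"]], 1)
  }
  # all-zero image gives a zero profile
  z <- droplet_line_profile(list(a = matrix(0, 150, 150)), c(75, 75))
  expect_true(all(z$profiles == 0))
  expect_error(droplet_line_profile(list(a = matrix(0, 20, 20)), c(10, 10)),
               "bounds")
})

test_that("droplet clustering counts contacting droplets as one cluster", {
  d <- gen_droplet_scene(cluster_sizes = c(2, 1), radius_range = c(8, 10),
                         seed = 4)
  st <- droplet_cluster_stats(binarize(d$droplet, d$threshold))
  expect_equal(st$n_clusters, 2)
  expect_setequal(st$droplets_per_cluster, c(2, 1))

  one <- gen_droplet_scene(cluster_sizes = 1, seed = 5)
  st1 <- droplet_cluster_stats(binarize(one$droplet, one$threshold))
  expect_equal(st1$n_clusters, 1)
  expect_equal(st1$droplets_per_cluster, 1L)
})

test_that("field-of-view intensity ratio", {
  expect_equal(fov_intensity_ratio(matrix(2, 2, 2), matrix(4, 2, 2)), 0.5)
  p <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(fov_intensity_ratio(p, p), 1)
  q <- matrix(c(2, 4, 6, 8), 2, 2)
  expect_equal(fov_intensity_ratio(q, p), 2)
  expect_equal(fov_intensity_ratio(q, p, background = 1),
               mean(q - 1) / mean(p - 1))
  expect_error(fov_intensity_ratio(p, matrix(0, 2, 2)), "positive")
})

test_that("max projection collapses a z-stack", {
  st <- array(0, c(2, 2, 3)); st[1, 1, 2] <- 5; st[2, 2, 3] <- 2
  mp <- max_projection(st)
  expect_equal(mp, matrix(c(5, 0, 0, 2), 2, 2))
})

test_that("TIFF planes round-trip", {
  f <- tempfile(fileext = ".tif")
  img <- matrix(seq(0, 1, length.out = 16), 4, 4)
  tiff::writeTIFF(img, f)
  back <- read_image_planes(f)
  expect_equal(back[[1]], img, tolerance = 1e-4)
})
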