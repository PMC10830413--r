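test_that("generators are deterministic in the seed", {
  cat1 <- toy_gene_catalog()
  a <- gen_junction_reads(cat1, c(E2 = 40, E4 = 60), depth = 200, seed = 5)
  b <- gen_junction_reads(cat1, c(E2 = 40, E4 = 60), depth = 200, seed = 5)
  expect_identical(a, b)
  c1 <- gen_sc_counts(n_cells = 50, seed = 3)
  c2 <- gen_sc_counts(n_cells = 50, seed = 3)
  expect_identical(c1, c2)
  expect_false(identical(c1$counts,
                         gen_sc_counts(n_cells = 50, seed = 4)$counts))
  s1 <- gen_synapse_scene(dendrite_length_um = 20, seed = 6)
  s2 <- gen_synapse_scene(dendrite_length_um = 20, seed = 6)
  expect_identical(s1$vglut, s2$vglut)
  t1 <- gen_ca_traces(seed = 7); t2 <- gen_ca_traces(seed = 7)
  expect_identical(t1$traces, t2$traces)
  f1 <- gen_frap_curve(seed = 8); f2 <- gen_frap_curve(seed = 8)
  expect_identical(f1$intensities, f2$intensities)
})

test_that("junction reads at psi extremes close the loop exactly", {
  cat1 <- toy_gene_catalog()
  g <- gen_junction_reads(cat1, c(E2 = 100, E4 = 100), depth = 500, seed = 2)
  pt <- psi_table(g$reads, cat1)
  expect_equal(pt$psi[pt$exon == "E2"], 100)
  expect_equal(pt$psi[pt$exon == "E4"], 100)
  g0 <- gen_junction_reads(cat1, c(E2 = 0, E4 = 0), depth = 500, seed = 2)
  pt0 <- psi_table(g0$reads, cat1)
  expect_equal(pt0$psi[pt0$exon == "E2"], 0)
  expect_equal(pt0$psi[pt0$exon == "E4"], 0)
  # generated blocks never extend past exon boundaries
  expect_true(all(g$reads$end > g$reads$start))
})

test_that("single-cell generator couples activity to E31 usage", {
  s <- gen_sc_counts(n_cells = 400, psi_coupling = 2, seed = 11)
  hi <- s$truth$activity > 0.7; lo <- s$truth$activity < 0.3
  expect_gt(mean(s$truth$usage_e31[hi]), mean(s$truth$usage_e31[lo]))
  # beta = 0 gives constant usage
  s0 <- gen_sc_counts(n_cells = 100, psi_coupling = 0, seed = 12)
  expect_equal(diff(range(s0$truth$usage_e31)), 0)
  # panel genes respond to activity
  panel_sum <- colSums(s$counts[ieg_panel(), ])
  expect_gt(cor(panel_sum, s$truth$activity), 0.5)
})

test_that("synapse scene ground truth is recoverable", {
  sc <- gen_synapse_scene(dendrite_length_um = 40, puncta_per_um = 0.5,
                          seed = 13)
  v <- binarize(sc$vglut, sc$threshold)
  h <- binarize(sc$homer, sc$threshold)
  d <- binarize(sc$map2, sc$threshold)
  got <- synapse_puncta(v, h, d)$count
  expect_lte(abs(got - sc$truth$n_paired_on), 1)

  # zero density plants nothing
  sc0 <- gen_synapse_scene(dendrite_length_um = 40, puncta_per_um = 0,
                           seed = 13)
  expect_equal(synapse_puncta(binarize(sc0$vglut, 0.3),
                              binarize(sc0$homer, 0.3),
                              binarize(sc0$map2, 0.3))$count, 0)

  # puncta planted 8 px off the dendrite are excluded by the halo rule
  scoff <- gen_synapse_scene(dendrite_length_um = 40, puncta_per_um = 0.25,
                             n_off = 4, off_offset_px = 8, seed = 14)
  goto <- synapse_puncta(binarize(scoff$vglut, scoff$threshold),
                         binarize(scoff$homer, scoff$threshold),
                         binarize(scoff$map2, scoff$threshold))$count
  expect_lte(abs(goto - scoff$truth$n_paired_on), 1)
})

test_that("droplet scenes reproduce their contact-graph components", {
  d <- gen_droplet_scene(cluster_sizes = c(3, 2, 1, 1), seed = 15)
  st <- droplet_cluster_stats(binarize(d$droplet, d$threshold))
  expect_equal(st$n_clusters, 4)
  expect_equal(sort(st$droplets_per_cluster),
               sort(d$truth$cluster_sizes))
  # contact edges connect consecutive in-cluster droplets only
  expect_equal(nrow(d$truth$contact_edges),
               sum(d$truth$cluster_sizes - 1))
})

test_that("calcium trains respect the minimum separation and close the loop", {
  g <- gen_ca_traces(n_cells = 4, noise_sd = 0, amp_jitter_sd = 0, seed = 16)
  expect_true(all(diff(g$truth$event_samples) >= 25))
  ev <- detect_events(synchronous_trace(g$traces))
  expect_equal(nrow(ev), g$truth$n_events)
  expect_equal(ev$index, g$truth$event_samples)
  # single cell: synchronous trace equals that cell's trace
  g1 <- gen_ca_traces(n_cells = 1, seed = 17)
  expect_equal(synchronous_trace(g1$traces), as.numeric(g1$traces[1, ]))
})

test_that("amplicon generator truth matches its oracle labels", {
  ref <- toy_amplicon()
  spec <- data.frame(type = c("none", "del"), position = c(NA, 47),
                     length = c(0, 2), prob = c(0.5, 0.5))
  g <- gen_amplicon_reads(ref, spec, n_reads = 30, seed = 18)
  expect_equal(length(g$reads), 30)
  relab <- vapply(g$calls, protein_ko_oracle, character(1), ref = ref)
  expect_identical(g$truth$classification, relab)
  # wild-type reads equal the reference sequence
  wt <- vapply(g$calls, function(x) nrow(x$indels) == 0, logical(1))
  expect_true(all(g$reads[wt] == ref$sequence))
})
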