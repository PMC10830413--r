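# Synthetic-data generators. Every generator is a deterministic function of
# its arguments and seed (Mersenne-Twister with inversion normals, fixed
# explicitly so outputs are reproducible across platforms), and every
# generator returns the ground truth needed to score the corresponding
# estimator without re-simulation.

.set_sim_seed <- function(seed) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
}

#' Toy gene annotation and catalog
#'
#' A synthetic plus-strand gene with five constitutive-ish exons: E1, a
#' cassette E2, E3, and two mutually exclusive terminal exons (lengths
#' \code{e31_len} and \code{e32_len}, mirroring the long/short terminal-exon
#' geometry). \code{toy_gene_catalog} builds the full catalog by running the
#' construction pipeline on the toy annotation with complete evidence.
#'
#' @param e31_len,e32_len terminal exon lengths in bases.
#' @param cassette include the cassette exon's skipping transcript.
#' @return \code{toy_annotation}: annotation data.frame;
#'   \code{toy_gene_catalog}: an \code{\link{exon_catalog}}.
#' @export
toy_annotation <- function(e31_len = 2000, e32_len = 500, cassette = TRUE) {
  ex <- function(tx, s, e, region = "coding")
    data.frame(gene_id = "ToyGene", transcript_id = tx, chrom = "chr1",
               start = s, end = e, strand = "+", region = region)
  e1 <- c(0, 300); e2 <- c(500, 650); e3 <- c(1000, 1300)
  e4 <- c(2000, 2000 + e31_len); e5 <- c(6000, 6000 + e32_len)
  rows <- list(ex("T1", e1[1], e1[2]), ex("T1", e2[1], e2[2]),
               ex("T1", e3[1], e3[2]), ex("T1", e4[1], e4[2]),
               ex("T2", e1[1], e1[2]), ex("T2", e2[1], e2[2]),
               ex("T2", e3[1], e3[2]), ex("T2", e5[1], e5[2]))
  if (cassette)
    rows <- c(rows, list(ex("T3", e1[1], e1[2]), ex("T3", e3[1], e3[2]),
                         ex("T3", e4[1], e4[2])))
  do.call(rbind, rows)
}

#' @rdname toy_annotation
#' @export
toy_gene_catalog <- function(e31_len = 2000, e32_len = 500,
                             cassette = TRUE) {
  ann <- toy_annotation(e31_len, e32_len, cassette)
  # full-coverage evidence: one read per exon plus a cassette-skipping read
  uniq <- unique(ann[, c("start", "end")])
  ev <- data.frame(read_id = paste0("ev", seq_len(nrow(uniq))),
                   start = uniq$start, end = uniq$end)
  if (cassette) {
    skip <- data.frame(read_id = "ev_skip",
                       start = c(250, 1000), end = c(300, 1050))
    ev <- rbind(ev, skip)
  }
  build_catalog(ann, ev, "ToyGene")
}

# map reads [s, s+len) in isoform coordinates to genomic blocks, vectorized
# over starts (one isoform chain, many reads)
.iso_blocks <- function(chain, starts, len, strand, read_ids) {
  exlen <- chain$end - chain$start
  offs <- cumsum(c(0, exlen))
  out <- vector("list", nrow(chain))
  for (i in seq_len(nrow(chain))) {
    lo <- pmax(starts, offs[i]); hi <- pmin(starts + len, offs[i + 1])
    sel <- lo < hi
    if (any(sel)) {
      if (strand == "+") {
        gs <- chain$start[i] + (lo[sel] - offs[i])
        ge <- gs + (hi[sel] - lo[sel])
      } else {
        ge <- chain$end[i] - (lo[sel] - offs[i])
        gs <- ge - (hi[sel] - lo[sel])
      }
      out[[i]] <- data.frame(read_id = read_ids[sel], start = gs, end = ge)
    }
  }
  do.call(rbind, out)
}

#' Simulate junction and terminal-exon reads with known PSI
#'
#' For an internal cassette target, each read picks the inclusion isoform
#' with probability psi/100 and its start is uniform over the junction-
#' spanning window of that isoform, so every read is informative and
#' \code{\link{psi_internal}} estimates a plain binomial proportion. For a
#' terminal pair, the isoform is chosen with probability proportional to
#' abundance times effective length (standard fragment sampling) and the
#' start is uniform along the isoform; terminal containment counts are then
#' proportional to abundance times exon length, which the length-normalized
#' terminal rule inverts.
#'
#' @param catalog an \code{\link{exon_catalog}}.
#' @param true_psi named numeric vector (percent), one entry per target
#'   exon; for a terminal pair the value is the transcript-abundance percent
#'   of the target's first exon.
#' @param depth reads per target.
#' @param read_len read length in bases.
#' @param seed integer seed.
#' @return list with \code{reads} (read-blocks data.frame) and
#'   \code{truth} (per-target true PSI and isoform draws).
#' @export
gen_junction_reads <- function(catalog, true_psi, depth, read_len = 100,
                               seed = 1) {
  .set_sim_seed(seed)
  ex <- catalog$exons
  strand <- catalog$strand
  all_reads <- list(); truth <- list()
  for (ti in seq_len(nrow(catalog$psi_targets))) {
    tg <- catalog$psi_targets[ti, ]
    psi <- true_psi[[tg$exon]]
    stopifnot(psi >= 0, psi <= 100)
    if (tg$mode == "internal") {
      up <- ex[ex$name == tg$flank_up, ]
      t0 <- ex[ex$name == tg$exon, ]
      dn <- ex[ex$name == tg$flank_down, ]
      chain_in <- rbind(up, t0, dn)
      chain_ex <- rbind(up, dn)
      win <- function(chain, jpos) {
        L <- sum(chain$end - chain$start)
        if (read_len > L) stop("read longer than isoform")
        unlist(lapply(jpos, function(j)
          seq(max(0, j - read_len + 1), min(j - 1, L - read_len))))
      }
      lu <- up$end - up$start; lt <- t0$end - t0$start
      win_in <- unique(win(chain_in, c(lu, lu + lt)))
      win_ex <- win(chain_ex, lu)
      incl <- runif(depth) < psi / 100
      starts <- integer(depth)
      starts[incl] <- win_in[sample.int(length(win_in), sum(incl),
                                        replace = TRUE)]
      starts[!incl] <- win_ex[sample.int(length(win_ex), sum(!incl),
                                         replace = TRUE)]
      rid <- paste0(tg$exon, "_r", seq_len(depth))
      all_reads[[length(all_reads) + 1L]] <- rbind(
        .iso_blocks(chain_in, starts[incl], read_len, strand, rid[incl]),
        .iso_blocks(chain_ex, starts[!incl], read_len, strand, rid[!incl]))
      truth[[tg$exon]] <- list(mode = "internal", true_psi = psi,
                               n_inclusion = sum(incl))
    } else {
      a <- ex[ex$name == tg$exon, ]; b <- ex[ex$name == tg$partner, ]
      ord <- order(if (strand == "+") ex$start else -ex$end)
      terminal_pos <- match(c(a$name, b$name), ex$name[ord])
      prev <- ex[ord[min(terminal_pos) - 1L], ]
      chain_a <- rbind(prev, a); chain_b <- rbind(prev, b)
      La <- sum(chain_a$end - chain_a$start)
      Lb <- sum(chain_b$end - chain_b$start)
      if (read_len > min(La, Lb)) stop("read longer than isoform")
      effA <- La - read_len + 1; effB <- Lb - read_len + 1
      wa <- (psi / 100) * effA
      wb <- (1 - psi / 100) * effB
      pick_a <- runif(depth) < wa / (wa + wb)
      starts <- integer(depth)
      starts[pick_a] <- sample.int(effA, sum(pick_a), replace = TRUE) - 1L
      starts[!pick_a] <- sample.int(effB, sum(!pick_a), replace = TRUE) - 1L
      rid <- paste0(tg$exon, "_t", seq_len(depth))
      all_reads[[length(all_reads) + 1L]] <- rbind(
        .iso_blocks(chain_a, starts[pick_a], read_len, strand, rid[pick_a]),
        .iso_blocks(chain_b, starts[!pick_a], read_len, strand,
                    rid[!pick_a]))
      truth[[tg$exon]] <- list(mode = "terminal_pair",
                               true_abundance_pct = psi,
                               n_isoform_a = sum(pick_a))
    }
  }
  list(reads = do.call(rbind, all_reads), truth = truth)
}

#' Simulate single-cell counts with an activity gradient
#'
#' Each cell carries a latent activity a ~ Uniform(0, 1). The five IEG panel
#' genes have Poisson means scaling as exp(k * a); background genes are
#' activity-independent Poisson. Per-cell terminal-exon reads are Poisson
#' with mean \code{lphn_rate}, split between E31 and E32 with inclusion
#' probability logistic(alpha + beta * a). The length-normalized per-cell
#' PSI is a strictly monotone transform of that inclusion probability, so
#' any activity ordering of the bins carries through to PSI.
#'
#' @param n_cells number of cells (>= 10).
#' @param n_genes total genes including the 5-gene panel.
#' @param ieg_effect k, log-scale activity effect on panel means.
#' @param psi_coupling beta, activity effect on E31 usage (log-odds).
#' @param depth expected total counts per cell.
#' @param lphn_rate expected terminal-exon reads per cell.
#' @param alpha baseline E31 usage log-odds.
#' @param e31_len,e32_len terminal exon lengths.
#' @param seed integer seed.
#' @return list with \code{counts} (genes x cells), \code{e31}, \code{e32}
#'   count vectors, \code{e31_len}, \code{e32_len} and \code{truth}
#'   (latent activity and true usage per cell).
#' @export
gen_sc_counts <- function(n_cells = 500, n_genes = 60, ieg_effect = 2,
                          psi_coupling = 2, depth = 2000, lphn_rate = 2,
                          alpha = 0, e31_len = 2000, e32_len = 500,
                          seed = 1) {
  stopifnot(n_cells >= 10, n_genes >= 6)
  .set_sim_seed(seed)
  panel <- ieg_panel()
  a <- runif(n_cells)
  base_bg <- exp(rnorm(n_genes - 5, 0, 1))
  base_bg <- base_bg / sum(base_bg) * depth * 0.9
  base_panel <- rep(depth * 0.1 / 5, 5)
  mu_panel <- outer(base_panel, exp(ieg_effect * (a - 0.5)))
  mu_bg <- matrix(base_bg, n_genes - 5, n_cells)
  counts <- rbind(matrix(rpois(5 * n_cells, mu_panel), 5, n_cells),
                  matrix(rpois((n_genes - 5) * n_cells, mu_bg),
                         n_genes - 5, n_cells))
  rownames(counts) <- c(panel, paste0("Gene", seq_len(n_genes - 5)))
  colnames(counts) <- paste0("cell", seq_len(n_cells))
  usage <- stats::plogis(alpha + psi_coupling * a)
  n_term <- rpois(n_cells, lphn_rate)
  e31 <- rbinom(n_cells, n_term, usage)
  e32 <- n_term - e31
  list(counts = counts, e31 = e31, e32 = e32,
       e31_len = e31_len, e32_len = e32_len,
       truth = list(activity = a, usage_e31 = usage))
}

.stamp <- function(img, r0, c0, sigma, amp = 1, radius = NULL) {
  if (is.null(radius)) radius <- ceiling(3 * sigma)
  rr <- max(1, round(r0) - radius):min(nrow(img), round(r0) + radius)
  cc <- max(1, round(c0) - radius):min(ncol(img), round(c0) + radius)
  d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
  img[rr, cc] <- pmax(img[rr, cc], amp * exp(-d2 / (2 * sigma^2)))
  img
}

#' Simulate a three-channel synapse scene
#'
#' A dendrite is rendered as a smoothed random-walk curve of the requested
#' arc length (Gaussian profile, ~3 px wide) in the MAP2 channel. Paired
#' synaptic puncta (Gaussian spots) are planted in both the vGluT1 and HOMER
#' channels within \code{on_offset_px} of the curve; unpaired puncta go into
#' a single channel; optional decoy puncta are planted \code{off_offset_px}
#' from the curve to probe the halo rule. Gaussian noise is added to every
#' channel. Binarizing at the suggested threshold (attribute
#' \code{threshold}) reproduces the planted geometry.
#'
#' @param dendrite_length_um target dendrite arc length.
#' @param puncta_per_um planted paired-puncta density.
#' @param paired_fraction fraction of puncta present in both channels.
#' @param n_off number of decoy puncta planted off the dendrite.
#' @param on_offset_px,off_offset_px perpendicular offsets in pixels. For a
#'   decoy to be excluded by the 5-px halo, its offset must exceed the halo
#'   radius plus the dendrite half-width plus the spot's thresholded radius
#'   (about 8 px at the defaults: ~1.4 + 5 + ~1.5).
#' @param spot_sigma Gaussian spot sigma in pixels (default 0.9, a ~0.5 um
#'   punctum at the default pixel size).
#' @param noise_sd Gaussian noise sd.
#' @param pixel_size_um microns per pixel.
#' @param seed integer seed.
#' @return list with channels \code{map2}, \code{vglut}, \code{homer},
#'   suggested \code{threshold}, and \code{truth} (punctum table, planted
#'   count, path).
#' @export
gen_synapse_scene <- function(dendrite_length_um = 60, puncta_per_um = 0.5,
                              paired_fraction = 1, n_off = 0,
                              on_offset_px = 2, off_offset_px = 8,
                              spot_sigma = 0.9, noise_sd = 0.02,
                              pixel_size_um = default_pixel_size(),
                              seed = 1) {
  .set_sim_seed(seed)
  n_path <- round(dendrite_length_um / pixel_size_um)
  nr <- 2L * (off_offset_px + 30L) + 60L
  nc <- n_path + 60L
  # heading random walk, steered back toward the centre line
  theta <- numeric(n_path); y <- numeric(n_path); x <- numeric(n_path)
  y[1] <- nr / 2; x[1] <- 30
  for (i in 2:n_path) {
    theta[i] <- 0.97 * theta[i - 1] + rnorm(1, 0, 0.04) -
      0.002 * (y[i - 1] - nr / 2)
    theta[i] <- max(min(theta[i], 0.5), -0.5)
    x[i] <- x[i - 1] + cos(theta[i])
    y[i] <- y[i - 1] + sin(theta[i])
  }
  map2 <- matrix(0, nr, nc)
  for (i in seq_len(n_path)) map2 <- .stamp(map2, y[i], x[i], 0.9)
  vglut <- matrix(0, nr, nc); homer <- matrix(0, nr, nc)
  n_puncta <- round(puncta_per_um * dendrite_length_um)
  truth <- NULL
  if (n_puncta > 0) {
    at <- round(seq(5, n_path - 5, length.out = n_puncta))
    nx <- -sin(theta[at]); ny <- cos(theta[at])  # unit normal
    off <- runif(n_puncta, 0, on_offset_px) * sample(c(-1, 1), n_puncta,
                                                     replace = TRUE)
    pr <- y[at] + ny * off; pc <- x[at] + nx * off
    paired <- runif(n_puncta) < paired_fraction
    for (i in seq_len(n_puncta)) {
      if (paired[i]) {
        vglut <- .stamp(vglut, pr[i], pc[i], spot_sigma)
        homer <- .stamp(homer, pr[i], pc[i], spot_sigma)
      } else if (runif(1) < 0.5) {
        vglut <- .stamp(vglut, pr[i], pc[i], spot_sigma)
      } else {
        homer <- .stamp(homer, pr[i], pc[i], spot_sigma)
      }
    }
    truth <- data.frame(row = pr, col = pc, paired = paired,
                        on_dendrite = TRUE)
  }
  if (n_off > 0) {
    at <- round(seq(15, n_path - 15, length.out = n_off))
    nx <- -sin(theta[at]); ny <- cos(theta[at])
    pr <- y[at] + ny * off_offset_px; pc <- x[at] + nx * off_offset_px
    for (i in seq_len(n_off)) {
      vglut <- .stamp(vglut, pr[i], pc[i], spot_sigma)
      homer <- .stamp(homer, pr[i], pc[i], spot_sigma)
    }
    truth <- rbind(truth, data.frame(row = pr, col = pc, paired = TRUE,
                                     on_dendrite = FALSE))
  }
  noisy <- function(img) pmax(img + matrix(rnorm(length(img), 0, noise_sd),
                                           nrow(img)), 0)
  list(map2 = noisy(map2), vglut = noisy(vglut), homer = noisy(homer),
       threshold = 0.3,
       truth = list(puncta = truth,
                    n_paired_on = sum(truth$paired & truth$on_dendrite),
                    path = data.frame(row = y, col = x),
                    length_um = (n_path - 1) * pixel_size_um))
}

#' Simulate a soma-counting scene
#'
#' Plants non-touching blobs with exact pixel areas (the nearest-k-pixels
#' disc around each centre), so size-rule counting can be checked exactly.
#'
#' @param areas integer vector of blob areas in pixels.
#' @param img_size scene side length.
#' @param seed integer seed.
#' @return list with \code{mask} (logical) and \code{truth} (areas,
#'   centres).
#' @export
gen_soma_scene <- function(areas, img_size = 256, seed = 1) {
  .set_sim_seed(seed)
  mask <- matrix(FALSE, img_size, img_size)
  radii <- ceiling(sqrt(areas / pi)) + 1
  centers <- matrix(NA_real_, length(areas), 2)
  for (i in seq_along(areas)) {
    for (try in 1:2000) {
      r0 <- runif(1, radii[i] + 2, img_size - radii[i] - 2)
      c0 <- runif(1, radii[i] + 2, img_size - radii[i] - 2)
      if (i == 1 || all(sqrt((centers[seq_len(i - 1), 1] - r0)^2 +
                               (centers[seq_len(i - 1), 2] - c0)^2) >
                          radii[i] + radii[seq_len(i - 1)] + 4)) {
        centers[i, ] <- c(r0, c0); break
      }
      if (try == 2000) stop("could not place non-touching blobs")
    }
    # exact-area blob: the `areas[i]` pixels nearest the centre
    w <- radii[i] + 2
    rr <- (round(centers[i, 1]) - w):(round(centers[i, 1]) + w)
    cc <- (round(centers[i, 2]) - w):(round(centers[i, 2]) + w)
    grid <- expand.grid(r = rr, c = cc)
    d <- (grid$r - centers[i, 1])^2 + (grid$c - centers[i, 2])^2
    pick <- grid[order(d)[seq_len(areas[i])], ]
    mask[cbind(pick$r, pick$c)] <- TRUE
  }
  list(mask = mask, truth = list(areas = areas, centers = centers))
}

#' Simulate a droplet scene with a known contact graph
#'
#' Droplets are discs placed in clusters: within a cluster consecutive
#' droplets touch (centre distance = sum of radii - 1), and clusters are
#' placed far apart, so the ground-truth contact-graph components are the
#' clusters. The droplet channel is uniform discs; the reporter channel is
#' either uniform (shell = FALSE, intensity 0.5) or surface-localized
#' (shell = TRUE: rim annulus at intensity 1 over an interior of 0.25).
#'
#' @param cluster_sizes integer vector, droplets per cluster.
#' @param radius_range min/max droplet radius in pixels.
#' @param shell logical, surface-localized reporter.
#' @param img_size scene side length (enlarged automatically if needed).
#' @param seed integer seed.
#' @return list with \code{droplet} and \code{reporter} intensity planes,
#'   \code{threshold}, and \code{truth} (centres, radii, cluster id and
#'   contact edges).
#' @export
gen_droplet_scene <- function(cluster_sizes = c(2, 1, 3), radius_range = c(6, 12),
                              shell = FALSE, img_size = NULL, seed = 1) {
  .set_sim_seed(seed)
  n_cl <- length(cluster_sizes)
  rmax <- radius_range[2]
  cell <- (max(cluster_sizes) + 1) * 2 * rmax + 10
  grid_n <- ceiling(sqrt(n_cl))
  if (is.null(img_size)) img_size <- grid_n * cell + 2 * rmax
  centers <- NULL; radii <- NULL; cluster <- NULL; edges <- NULL
  id <- 0L
  slots <- sample(grid_n^2, n_cl)
  for (k in seq_len(n_cl)) {
    gr <- (slots[k] - 1) %/% grid_n; gc <- (slots[k] - 1) %% grid_n
    base_r <- gr * cell + cell / 2; base_c <- gc * cell + cell / 2
    ang <- runif(1, 0, 2 * pi)
    for (j in seq_len(cluster_sizes[k])) {
      id <- id + 1L
      r <- runif(1, radius_range[1], radius_range[2])
      if (j == 1) {
        ctr <- c(base_r, base_c)
      } else {
        prev <- centers[id - 1L, ]
        ang <- ang + runif(1, -0.5, 0.5)
        d <- radii[id - 1L] + r - 1
        ctr <- prev + d * c(sin(ang), cos(ang))
        edges <- rbind(edges, c(id - 1L, id))
      }
      centers <- rbind(centers, ctr); radii <- c(radii, r)
      cluster <- c(cluster, k)
    }
  }
  droplet <- matrix(0, img_size, img_size)
  reporter <- matrix(0, img_size, img_size)
  rows <- row(droplet); cols <- col(droplet)
  for (i in seq_len(nrow(centers))) {
    d <- sqrt((rows - centers[i, 1])^2 + (cols - centers[i, 2])^2)
    inside <- d <= radii[i]
    droplet[inside] <- 1
    if (shell) {
      rim <- inside & d >= radii[i] - 1.5
      reporter[inside & !rim] <- pmax(reporter[inside & !rim], 0.25)
      reporter[rim] <- 1
    } else {
      reporter[inside] <- 0.5
    }
  }
  list(droplet = droplet, reporter = reporter, threshold = 0.1,
       truth = list(centers = centers, radii = radii, cluster = cluster,
                    contact_edges = edges,
                    cluster_sizes = as.integer(cluster_sizes)))
}

#' Simulate population dF/F traces sharing one event train
#'
#' A single event train (exponential gaps with a hard minimum separation)
#' drives every cell: each cell's trace is the train convolved with an
#' exponential-decay kernel (instantaneous rise, decay tau), scaled by a
#' per-cell amplitude factor, plus Gaussian noise.
#'
#' @param n_cells number of somata.
#' @param rate_hz target event rate.
#' @param amplitude event amplitude (dF/F units).
#' @param amp_jitter_sd per-cell amplitude-factor sd (around 1).
#' @param decay_tau_s decay time constant (default 0.4 s).
#' @param frame_interval_s sampling interval (default 0.085 s).
#' @param duration_s recording length (default 60 s).
#' @param noise_sd Gaussian noise sd.
#' @param min_sep_samples hard minimum event separation in samples.
#' @param seed integer seed.
#' @return list with \code{traces} (cells x samples),
#'   \code{frame_interval_s}, and \code{truth} (event sample indices,
#'   amplitude).
#' @export
gen_ca_traces <- function(n_cells = 10, rate_hz = 0.25, amplitude = 0.5,
                          amp_jitter_sd = 0.1, decay_tau_s = 0.4,
                          frame_interval_s = 0.085, duration_s = 60,
                          noise_sd = 0.02, min_sep_samples = 25, seed = 1) {
  .set_sim_seed(seed)
  n <- round(duration_s / frame_interval_s)
  mean_gap <- 1 / (rate_hz * frame_interval_s)
  excess <- max(mean_gap - min_sep_samples, 1)
  t <- 5 + round(rexp(1, 1 / excess))
  events <- integer(0)
  while (t <= n - 5) {
    events <- c(events, t)
    t <- t + min_sep_samples + round(rexp(1, 1 / excess))
  }
  rho <- exp(-frame_interval_s / decay_tau_s)
  impulse <- numeric(n); impulse[events] <- amplitude
  kernelized <- as.numeric(stats::filter(impulse, rho, method = "recursive"))
  gain <- pmax(rnorm(n_cells, 1, amp_jitter_sd), 0.2)
  traces <- outer(gain, kernelized) +
    matrix(rnorm(n_cells * n, 0, noise_sd), n_cells, n)
  list(traces = traces, frame_interval_s = frame_interval_s,
       truth = list(event_samples = events, amplitude = amplitude,
                    n_events = length(events)))
}

#' Simulate a FRAP recovery curve
#'
#' y(t) = a exp(-b t) + c with Gaussian noise; a is negative for a
#' recovering (rising) trace.
#'
#' @param a,b,c model parameters.
#' @param sigma noise sd.
#' @param n_points number of samples over \code{t_max}.
#' @param t_max recording length in seconds (default 360, i.e. 6 min).
#' @param seed integer seed.
#' @return list with \code{times}, \code{intensities}, and \code{truth}.
#' @export
gen_frap_curve <- function(a = -0.6, b = 0.02, c = 0.8, sigma = 0.01,
                           n_points = 73, t_max = 360, seed = 1) {
  .set_sim_seed(seed)
  times <- seq(0, t_max, length.out = n_points)
  y <- a * exp(-b * times) + c + rnorm(n_points, 0, sigma)
  list(times = times, intensities = y,
       truth = list(a = a, b = b, c = c, t_half_s = log(2) / b))
}

#' The package's toy amplicon reference
#'
#' A 60-bp amplicon: 6-bp 5' flank, an ATG-initiated coding sequence whose
#' last three codons are the PBM, and a TAA stop ending the amplicon. The
#' coding sequence upstream of the stop contains no codon starting with T,
#' so in-frame indels cannot create premature stop codons and the
#' nucleotide-level classification rule and the protein-level oracle can be
#' compared cleanly over exhaustive indel enumerations.
#' @export
toy_amplicon <- function() {
  seq <- paste0("GCAGCA",
                "ATGGCACGAAACGACCAGGAACCGAGCACGGCCAAGCAAGAG",
                "ACAGAAGCA", "TAA")
  amplicon_reference(seq, cds_start = 6, pbm_start = 48, pbm_end = 57,
                     edit_site = 48)
}

#' Simulate amplicon reads with a specified indel spectrum
#'
#' Each read draws one entry from the spectrum (type "none" for wild type),
#' applies it to the reference, and optionally adds uniform substitution
#' errors. Per-read ground-truth classification comes from the
#' protein-level oracle.
#'
#' @param ref an \code{\link{amplicon_reference}}.
#' @param spectrum data.frame with columns \code{type} ("none", "ins",
#'   "del"), \code{position}, \code{length}, \code{prob} (normalized
#'   internally).
#' @param n_reads number of reads.
#' @param error_rate per-base substitution error probability.
#' @param seed integer seed.
#' @return list with \code{reads} (sequences), \code{calls} (true edit
#'   calls) and \code{truth} (data.frame read_id, classification).
#' @export
gen_amplicon_reads <- function(ref, spectrum, n_reads, error_rate = 0,
                               seed = 1) {
  .set_sim_seed(seed)
  p <- spectrum$prob / sum(spectrum$prob)
  pick <- sample.int(nrow(spectrum), n_reads, replace = TRUE, prob = p)
  reads <- character(n_reads); calls <- vector("list", n_reads)
  cls <- character(n_reads)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(n_reads)) {
    sp <- spectrum[pick[i], ]
    ind <- if (sp$type == "none")
      data.frame(position = integer(0), length = integer(0),
                 type = character(0), bases = character(0))
    else
      data.frame(position = sp$position, length = sp$length,
                 type = sp$type,
                 bases = if (sp$type == "ins")
                   paste(rep("C", sp$length), collapse = "") else "")
    subs <- data.frame(position = integer(0), base = character(0))
    if (error_rate > 0) {
      hit <- which(runif(nchar(ref$sequence)) < error_rate)
      if (length(hit) > 0) {
        orig_b <- strsplit(ref$sequence, "")[[1]][hit]
        newb <- vapply(orig_b, function(x)
          sample(setdiff(bases, x), 1), character(1))
        subs <- data.frame(position = hit - 1L, base = unname(newb))
      }
    }
    call <- list(read_id = paste0("read", i), indels = ind,
                 substitutions = subs)
    calls[[i]] <- call
    reads[i] <- .edited_sequence(call, ref)
    cls[i] <- protein_ko_oracle(call, ref)
  }
  list(reads = reads, calls = calls,
       truth = data.frame(read_id = paste0("read", seq_len(n_reads)),
                          classification = cls))
}
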