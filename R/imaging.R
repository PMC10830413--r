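# Fluorescence-image quantification. All rules follow the strict readings:
# binarization is intensity > threshold, "more than two neighbouring pixels"
# is component area >= 3 under 8-connectivity, soma rules are >= 81 (red) and
# >= 151 (green) pixels, the dendrite halo is a Euclidean disk of radius 5 px.
# The default pixel size is 0.20714 um per pixel.

#' Default pixel size (microns per pixel)
#' @export
default_pixel_size <- function() 0.20714

.shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Label connected components
#'
#' 8-connected (default) or 4-connected labeling of a binary mask. The
#' 4-connected pass uses \code{EBImage::bwlabel}; 8-connectivity is obtained
#' by merging labels that touch diagonally.
#'
#' @param mask logical matrix.
#' @param connectivity 8 or 4.
#' @return integer matrix of labels (0 = background), with compact labels
#'   1..n.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  lab <- EBImage::imageData(EBImage::bwlabel(matrix(as.numeric(mask),
                                                    nrow(mask), ncol(mask))))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (connectivity == 8 && max(lab) > 1L) {
    pairs <- NULL
    for (d in list(c(1, 1), c(1, -1))) {
      a <- lab
      b <- .shift_mat(lab, d[1], d[2])
      sel <- a > 0L & b > 0L & a != b
      if (any(sel)) pairs <- rbind(pairs, cbind(a[sel], b[sel]))
    }
    if (!is.null(pairs)) {
      g <- igraph::graph_from_edgelist(matrix(as.character(pairs), ncol = 2),
                                       directed = FALSE)
      memb <- igraph::components(g)$membership
      map <- seq_len(max(lab))
      map[as.integer(names(memb))] <- max(lab) + memb
      lab[lab > 0L] <- map[lab[lab > 0L]]
    }
  }
  # compact relabel
  u <- sort(unique(lab[lab > 0L]))
  if (length(u)) lab[lab > 0L] <- match(lab[lab > 0L], u)
  lab
}

#' Euclidean disk structuring element
#' @param r radius in pixels.
#' @return 0/1 matrix of size (2r+1) x (2r+1) with pixels at Euclidean
#'   distance <= r set to 1.
#' @export
disk_kernel <- function(r) {
  d <- 2L * as.integer(r) + 1L
  idx <- seq_len(d) - (r + 1L)
  outer(idx, idx, function(i, j) as.numeric(i^2 + j^2 <= r^2))
}

#' Binarize an image plane
#'
#' Strict thresholding: a pixel is foreground when its intensity is strictly
#' greater than the threshold. Thresholds are user-supplied per channel per
#' batch.
#'
#' @param plane numeric intensity matrix.
#' @param threshold finite numeric threshold.
#' @return logical matrix.
#' @export
binarize <- function(plane, threshold) {
  stopifnot(is.finite(threshold))
  plane > threshold
}

#' Count colocalized synapse puncta
#'
#' The candidate region is the pixel-wise overlap of the vGluT1 and HOMER
#' binary masks, restricted to a halo around the dendrite (the dendrite mask
#' dilated by a Euclidean disk of radius \code{halo_px}, capturing synapses
#' up to ~1 um off the shaft). Puncta are 8-connected components of the
#' candidate region with area >= \code{min_punctum_px} ("more than two
#' neighbouring pixels").
#'
#' @param vglut,homer,dendrite logical masks of identical shape.
#' @param halo_px halo radius in pixels (default 5).
#' @param min_punctum_px minimum component area (default 3).
#' @return list with \code{count}, \code{labels} (labelled punctum matrix)
#'   and \code{areas}.
#' @export
synapse_puncta <- function(vglut, homer, dendrite, halo_px = 5,
                           min_punctum_px = 3) {
  stopifnot(identical(dim(vglut), dim(homer)),
            identical(dim(vglut), dim(dendrite)))
  halo <- if (halo_px > 0)
    EBImage::dilate(matrix(as.numeric(dendrite), nrow(dendrite)),
                    disk_kernel(halo_px)) > 0
  else dendrite
  cand <- vglut & homer & halo
  lab <- label_components(cand, 8)
  if (max(lab) == 0L)
    return(list(count = 0L, labels = lab, areas = integer(0)))
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_punctum_px)
  lab[!(lab %in% keep)] <- 0L
  u <- sort(unique(lab[lab > 0L]))
  if (length(u)) lab[lab > 0L] <- match(lab[lab > 0L], u)
  list(count = length(keep), labels = lab, areas = areas[keep])
}

#' Puncta density per micron of dendrite
#' @param count punctum count.
#' @param length_um dendrite length in microns (> 0).
#' @export
puncta_density <- function(count, length_um) {
  if (length_um <= 0) stop("dendrite length must be positive")
  count / length_um
}

#' Count neuronal somata in a binary mask
#'
#' 8-connected components with area >= \code{min_px} count as somata. The
#' conventional rules are \code{min_px = 81} for the red channel (CA1) and
#' \code{min_px = 151} for the green channel (CA3/LEC), i.e. strictly more
#' than 80 / 150 neighbouring pixels.
#'
#' @param mask logical matrix.
#' @param min_px minimum component area (>= 1).
#' @return integer count.
#' @export
count_somas <- function(mask, min_px) {
  stopifnot(min_px >= 1)
  lab <- label_components(mask, 8)
  if (max(lab) == 0L) return(0L)
  sum(tabulate(lab[lab > 0L]) >= min_px)
}

#' Presynaptic-to-starter connectivity ratios
#'
#' @param presyn_counts named numeric vector of presynaptic soma counts per
#'   region.
#' @param starter_count number of starter neurons (> 0).
#' @return named vector of ratios.
#' @export
connectivity_ratios <- function(presyn_counts, starter_count) {
  if (starter_count <= 0) stop("starter count must be positive")
  presyn_counts / starter_count
}

.bilinear <- function(plane, r, c) {
  # r, c are fractional 1-based matrix coordinates
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  r1 <- pmin(r0 + 1, nrow(plane)); c1 <- pmin(c0 + 1, ncol(plane))
  plane[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    plane[cbind(r1, c0)] * fr * (1 - fc) +
    plane[cbind(r0, c1)] * (1 - fr) * fc +
    plane[cbind(r1, c1)] * fr * fc
}

#' Intensity line profile across a droplet
#'
#' Samples each channel along a straight segment of fixed physical length
#' (default 12.86 um) centred on the droplet centre, at pixel spacing with
#' bilinear interpolation. Also reports an edge/centre enrichment ratio: the
#' mean of the outer 20 percent of samples divided by the mean of the
#' central 20 percent, which exceeds 1 for surface-localized (shell) signal.
#'
#' @param planes named list of intensity matrices.
#' @param center numeric(2) centre as (row, col), 1-based pixel coordinates.
#' @param length_um physical profile length (default 12.86).
#' @param angle orientation in radians (default 0 = along columns).
#' @param pixel_size_um microns per pixel.
#' @return list with \code{distance_um}, per-channel \code{profiles}
#'   (matrix, one column per channel) and \code{enrichment} (named vector).
#' @export
droplet_line_profile <- function(planes, center, length_um = 12.86,
                                 angle = 0,
                                 pixel_size_um = default_pixel_size()) {
  half <- length_um / 2
  t_um <- seq(-half, half, by = pixel_size_um)
  dr <- sin(angle); dc <- cos(angle)
  r <- center[1] + t_um / pixel_size_um * dr
  c <- center[2] + t_um / pixel_size_um * dc
  p1 <- planes[[1L]]
  if (any(r < 1 | r > nrow(p1) | c < 1 | c > ncol(p1)))
    stop("profile line exceeds image bounds")
  prof <- vapply(planes, .bilinear, numeric(length(t_um)), r = r, c = c)
  n <- length(t_um)
  k <- max(1L, round(0.2 * n / 2))  # outer 20% split across both ends
  edge_idx <- c(seq_len(k), seq(n - k + 1L, n))
  mid <- (n + 1) / 2
  ctr_idx <- seq(floor(mid - 0.1 * n), ceiling(mid + 0.1 * n))
  enr <- apply(prof, 2L, function(x) {
    ce <- mean(x[ctr_idx])
    if (ce == 0) NA_real_ else mean(x[edge_idx]) / ce
  })
  list(distance_um = t_um, profiles = prof, enrichment = enr)
}

.local_maxima <- function(d, min_sep, mask) {
  # candidates: pixels attaining the max of their (2*min_sep+1)^2 window
  mx <- d
  for (dr in -min_sep:min_sep) for (dc in -min_sep:min_sep) {
    if (dr == 0 && dc == 0) next
    mx <- pmax(mx, .shift_mat(d, dr, dc, fill = -Inf))
  }
  which(mask & d >= mx & d > 0, arr.ind = TRUE)
}

#' Droplet clusters and per-cluster droplet counts
#'
#' A cluster is an 8-connected component of the droplet mask ("contacting
#' droplets count as one cluster"). Individual droplets inside a cluster are
#' resolved by distance-transform maxima (markers) with a minimum separation
#' of \code{min_sep} pixels; plateau or near-coincident maxima are merged.
#' Droplet areas come from growing the markers over the mask.
#'
#' @param mask logical droplet mask.
#' @param min_sep minimum marker separation in pixels (default 3).
#' @return list with \code{n_clusters}, \code{droplets_per_cluster} (integer
#'   vector, one entry per cluster), \code{droplet_areas}, \code{markers}
#'   (data.frame row/col/cluster) and \code{cluster_labels}.
#' @export
droplet_cluster_stats <- function(mask, min_sep = 3) {
  clab <- label_components(mask, 8)
  n_cl <- max(clab)
  if (n_cl == 0L)
    return(list(n_clusters = 0L, droplets_per_cluster = integer(0),
                droplet_areas = integer(0),
                markers = data.frame(row = integer(0), col = integer(0),
                                     cluster = integer(0)),
                cluster_labels = clab))
  d <- EBImage::imageData(EBImage::distmap(
    matrix(as.numeric(mask), nrow(mask), ncol(mask))))
  cand <- .local_maxima(d, min_sep, mask)
  # merge candidate maxima closer than min_sep (plateaus and split maxima)
  if (nrow(cand) > 1L) {
    dm <- as.matrix(stats::dist(cand))
    g <- igraph::graph_from_adjacency_matrix(dm <= min_sep, mode = "undirected")
    memb <- igraph::components(g)$membership
    cand <- do.call(rbind, lapply(split(seq_len(nrow(cand)), memb),
                                  function(i) round(colMeans(cand[i, , drop = FALSE]))))
  }
  markers <- data.frame(row = cand[, 1], col = cand[, 2])
  markers$cluster <- clab[as.matrix(markers[, c("row", "col")])]
  per_cluster <- tabulate(markers$cluster, nbins = n_cl)
  per_cluster[per_cluster == 0L] <- 1L  # a cluster always holds >= 1 droplet
  # droplet areas: grow markers over the mask (Voronoi-like propagation)
  seeds <- matrix(0L, nrow(mask), ncol(mask))
  seeds[as.matrix(markers[, c("row", "col")])] <- seq_len(nrow(markers))
  areas <- tryCatch({
    grown <- EBImage::propagate(matrix(as.numeric(mask), nrow(mask)),
                                seeds, mask = mask)
    tabulate(EBImage::imageData(grown)[EBImage::imageData(grown) > 0])
  }, error = function(e) tabulate(markers$cluster, nbins = n_cl))
  list(n_clusters = n_cl, droplets_per_cluster = per_cluster,
       droplet_areas = as.integer(areas), markers = markers,
       cluster_labels = clab)
}

#' Field-of-view intensity ratio
#'
#' Mean intensity of the numerator plane divided by the mean of the
#' denominator plane after constant background subtraction (the reporter
#' ratio, e.g. pink flamindo 2 over GFP).
#'
#' @param numerator_plane,denominator_plane intensity matrices.
#' @param background constant offset subtracted from both planes (default 0).
#' @export
fov_intensity_ratio <- function(numerator_plane, denominator_plane,
                                background = 0) {
  den <- mean(denominator_plane - background)
  if (den <= 0) stop("denominator mean must be positive")
  mean(numerator_plane - background) / den
}

#' Maximum-intensity projection of a z-stack
#' @param stack 3D array (rows x cols x z).
#' @export
max_projection <- function(stack) {
  apply(stack, c(1, 2), max)
}

#' Read a (multi-channel) TIFF as numeric matrices
#' @param file TIFF path.
#' @return list of intensity matrices, one per plane.
#' @export
read_image_planes <- function(file) {
  img <- tiff::readTIFF(file, all = TRUE)
  lapply(img, function(p) if (length(dim(p)) == 3L) p[, , 1L] else p)
}
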