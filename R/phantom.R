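#' Specification of a geometric phantom
#'
#' Describes a synthetic instance-label volume: one ellipsoidal tumor
#' and any number of ellipsoidal lymph nodes on a slice grid with known
#' geometry. Physical coordinates are (slice mm, row mm, col mm) with
#' the voxel at index (0,0,0) at the origin; the through-plane position
#' of slice s is s x (T + G) mm (center-to-center slice pitch).
#'
#' @param dim grid shape (slices, rows, cols).
#' @param pixel_spacing in-plane spacing (row, col) in mm.
#' @param slice_thickness slice thickness T (mm).
#' @param slice_gap inter-slice gap G (mm).
#' @param tumor list with `center` (length-3 mm) and `radii`
#'   (length-3 mm, order slice/row/col).
#' @param nodes list of such lists, one per node.
#' @param patient_id identifier.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim, pixel_spacing, slice_thickness, slice_gap,
                         tumor, nodes, patient_id = "phantom") {
  stopifnot(length(dim) == 3L, all(dim >= 1))
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  shp <- function(s) {
    stopifnot(is.list(s), length(s$center) == 3L, length(s$radii) == 3L,
              all(s$radii >= 0))
    list(center = as.numeric(s$center), radii = as.numeric(s$radii))
  }
  structure(list(dim = as.integer(dim),
                 pixel_spacing = as.numeric(pixel_spacing),
                 slice_thickness = as.numeric(slice_thickness),
                 slice_gap = as.numeric(slice_gap),
                 tumor = shp(tumor), nodes = lapply(nodes, shp),
                 patient_id = as.character(patient_id)),
            class = "phantom_spec")
}

# squared normalized distance of grid coordinates to an ellipsoid axis;
# radius 0 degenerates to exact coincidence with the center plane
.axis_q <- function(coords, center, radius) {
  if (radius > 0) ((coords - center) / radius)^2
  else ifelse(abs(coords - center) < 1e-9, 0, Inf)
}

.rasterize_ellipsoid <- function(spec, shape) {
  zc <- (seq_len(spec$dim[1L]) - 1) * (spec$slice_thickness + spec$slice_gap)
  yc <- (seq_len(spec$dim[2L]) - 1) * spec$pixel_spacing[1L]
  xc <- (seq_len(spec$dim[3L]) - 1) * spec$pixel_spacing[2L]
  qz <- .axis_q(zc, shape$center[1L], shape$radii[1L])
  qy <- .axis_q(yc, shape$center[2L], shape$radii[2L])
  qx <- .axis_q(xc, shape$center[3L], shape$radii[3L])
  q <- outer(outer(qz, qy, `+`), qx, `+`)
  q <= 1 + 1e-12
}

#' Rasterize a phantom and compute its analytic ground truth
#'
#' A voxel belongs to a shape iff its center lies inside the ellipsoid
#' (no partial volumes), which makes the ground truth exact. The
#' returned `truth` is computed by a deliberately independent
#' straightforward routine (explicit index decoding and summation,
#' sharing no geometry code with the feature-extraction module): exact
#' per-node voxel counts recounted from the emitted mask, centroids,
#' slice offsets and drainage distances from the through-plane rule
#' \[DeltaS x G + (DeltaS - 1) x T\]^2, plus the tLNV/tLND totals.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (an [annotated_volume()]) and `truth`
#'   (list: `tumor_centroid`, per-node data.frame `nodes`, `tLNV`,
#'   `tLND`).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  # shapes must fit inside the voxel-center extent of the grid
  ext <- c((spec$dim[1L] - 1) * (spec$slice_thickness + spec$slice_gap),
           (spec$dim[2L] - 1) * spec$pixel_spacing[1L],
           (spec$dim[3L] - 1) * spec$pixel_spacing[2L])
  for (s in c(list(spec$tumor), spec$nodes))
    if (any(s$center - s$radii < -1e-9) || any(s$center + s$radii > ext + 1e-9))
      stop("shape does not fit inside the grid")

  vox <- array(0L, spec$dim)
  shapes <- c(list(spec$tumor), spec$nodes)
  for (i in seq_along(shapes)) {
    m <- .rasterize_ellipsoid(spec, shapes[[i]])
    if (!any(m)) stop(sprintf("shape %d contains no voxel center", i))
    if (any(vox[m] != 0L)) stop("shapes overlap")
    vox[m] <- i  # tumor = 1, nodes = 2..K
  }
  vol <- annotated_volume(vox, spec$pixel_spacing, spec$slice_thickness,
                          spec$slice_gap, spec$patient_id, relabel = "never")
  list(volume = vol, truth = .phantom_truth(vox, spec))
}

# Independent ground-truth evaluation, brute force on the emitted mask.
# Kept free of any code shared with node_volume()/node_distance() so
# that equivalence tests between the two are meaningful.
.phantom_truth <- function(vox, spec) {
  d1 <- dim(vox)[1L]; d2 <- dim(vox)[2L]
  sr <- spec$pixel_spacing[1L]; sc <- spec$pixel_spacing[2L]
  Tt <- spec$slice_thickness; G <- spec$slice_gap
  rh <- function(x) if (x >= 0) floor(x + 0.5) else ceiling(x - 0.5)

  centroid_of <- function(lab) {
    ss <- 0; sy <- 0; sx <- 0; n <- 0L
    for (v in which(vox == lab)) {
      r <- v - 1L
      s <- r %% d1; r <- r %/% d1
      y <- r %% d2; x <- r %/% d2
      ss <- ss + s; sy <- sy + y; sx <- sx + x; n <- n + 1L
    }
    list(n = n, slice = ss / n, row_mm = sy / n * sr, col_mm = sx / n * sc)
  }

  tum <- centroid_of(1L)
  labs <- sort(unique(vox[vox >= 2L]))
  out <- data.frame(label = integer(0), n_voxels = integer(0),
                    volume_mm3 = numeric(0), centroid_slice = numeric(0),
                    delta_s = integer(0), distance_mm = numeric(0))
  for (lb in labs) {
    ce <- centroid_of(lb)
    ds <- abs(rh(ce$slice) - rh(tum$slice))
    th <- if (ds == 0) 0 else (ds * G + (ds - 1) * Tt)^2
    dist <- sqrt((ce$row_mm - tum$row_mm)^2 + (ce$col_mm - tum$col_mm)^2 + th)
    out <- rbind(out, data.frame(
      label = lb, n_voxels = ce$n, volume_mm3 = ce$n * (sr * sc),
      centroid_slice = ce$slice, delta_s = as.integer(ds),
      distance_mm = dist))
  }
  list(tumor_centroid = c(slice = tum$slice, row_mm = tum$row_mm,
                          col_mm = tum$col_mm),
       nodes = out, tLNV = sum(out$volume_mm3), tLND = sum(out$distance_mm))
}

#' Randomly parameterized phantom specification
#'
#' Draws grid geometry (in-plane spacing 0.4-1 mm, T 3-5 mm, G 0-1.5 mm),
#' a mid-grid tumor and 1-5 non-overlapping ellipsoidal nodes. Shape
#' centers snap to voxel centers so every shape contains at least one
#' voxel; node placement uses rejection sampling with a conservative
#' center-distance margin so rasterized shapes cannot touch.
#'
#' @param seed integer seed; the spec is a deterministic function of it.
#' @param dim grid shape (slices, rows, cols).
#' @param n_nodes number of nodes; default drawn uniformly from 1..5.
#' @return a [phantom_spec()].
#' @export
random_phantom_spec <- function(seed, dim = c(20L, 64L, 64L),
                                n_nodes = NULL) {
  .with_seed(seed, {
    sp <- stats::runif(2, 0.4, 1.0)
    Tt <- stats::runif(1, 3, 5)
    G <- stats::runif(1, 0, 1.5)
    pitch <- Tt + G
    if (is.null(n_nodes)) n_nodes <- sample(1:5, 1L)
    ext <- c((dim[1L] - 1) * pitch, (dim[2L] - 1) * sp[1L],
             (dim[3L] - 1) * sp[2L])
    steps <- c(pitch, sp)
    # center drawn on the voxel-center grid, far enough from the border
    # that the whole ellipsoid fits inside the voxel-center extent
    draw_center <- function(radii) {
      idx <- vapply(1:3, function(a) {
        lo <- ceiling(radii[a] / steps[a])
        hi <- floor((ext[a] - radii[a]) / steps[a])
        if (hi < lo) stop("shape too large for grid")
        if (hi == lo) lo else sample(lo:hi, 1L)
      }, numeric(1L))
      idx * steps
    }

    tumor_radii <- c(stats::runif(1, 1, 2) * pitch,
                     stats::runif(2, 5, 10))
    tumor_center <- round(ext / 2 / steps) * steps

    nodes <- list(); placed <- list(list(center = tumor_center,
                                         radii = tumor_radii))
    for (k in seq_len(n_nodes)) {
      for (try in 1:1000) {
        radii <- c(stats::runif(1, 0.6, 1.6) * pitch, stats::runif(2, 1.5, 4))
        center <- draw_center(radii)
        ok <- all(vapply(placed, function(p) {
          sqrt(sum((p$center - center)^2)) >
            max(p$radii) + max(radii) + 1.5
        }, logical(1L)))
        if (ok) break
        if (try == 1000) stop("could not place node without overlap")
      }
      nd <- list(center = center, radii = radii)
      nodes[[k]] <- nd
      placed[[length(placed) + 1L]] <- nd
    }
    phantom_spec(dim, sp, Tt, G, tumor = list(center = tumor_center,
                                              radii = tumor_radii),
                 nodes = nodes,
                 patient_id = sprintf("phantom-%d", as.integer(seed)))
  })
}
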