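#' @name lnmts-features
#' @title Lymph-node volume and drainage-distance features
#'
#' @description
#' Per-node features are computed from the instance labels of an
#' [annotated_volume()]:
#'
#' * **Volume** (mm^3 by convention): V = N x p, where N is the node's
#'   pixel count and p the in-plane pixel area (row spacing x col
#'   spacing, mm^2). Three counting modes are supported, see
#'   [node_volume()].
#' * **Drainage distance** (mm): the Euclidean distance between the node
#'   centroid and the tumor centroid, with the through-plane separation
#'   of DeltaS slices contributing \[DeltaS x G + (DeltaS - 1) x T\]^2,
#'   where T is the slice thickness and G the inter-slice gap. Nodes
#'   centred on the tumor slice (DeltaS = 0) have a purely in-plane
#'   distance.
#'
#' Patient-level totals tLNV and tLND are the exact sums of the
#' per-node values.
NULL

# arithmetic mean of voxel-center physical coordinates of one label;
# slice kept as (0-based) index, in-plane axes converted to mm
.structure_centroid <- function(volume, label) {
  idx <- which(volume$voxels == label)
  if (!length(idx)) stop(sprintf("label %d absent from mask", label))
  ai <- arrayInd(idx, dim(volume$voxels))
  c(slice = mean(ai[, 1L] - 1L),
    row_mm = mean((ai[, 2L] - 1L) * volume$pixel_spacing[[1L]]),
    col_mm = mean((ai[, 3L] - 1L) * volume$pixel_spacing[[2L]]))
}

.max_cross_section_count <- function(volume, label) {
  slices <- arrayInd(which(volume$voxels == label), dim(volume$voxels))[, 1L]
  max(tabulate(slices, nbins = dim(volume$voxels)[1L]))
}

#' Volume of one lymph node
#'
#' Counts the node's labeled pixels and converts the count to a volume
#' as N x p with p the in-plane pixel area (mm^2).
#'
#' @param volume an [annotated_volume()].
#' @param node_label integer label (>= 2) of the node.
#' @param mode pixel-counting mode:
#'   `"accumulated"` (default) sums the labeled pixels over all slices;
#'   `"max_cross_section"` uses only the largest single-slice
#'   cross-section; `"voxel_volume"` uses the accumulated count scaled
#'   additionally by the slice pitch (T + G), giving a true voxel
#'   volume in mm^3.
#' @return list with `node_label`, `pixel_count` (N), `volume` (V) and
#'   `mode`.
#' @examples
#' v <- array(0L, c(3, 8, 8)); v[1, 2, 2] <- 1L; v[2, 4:5, 3:7] <- 2L
#' av <- annotated_volume(v, 0.5, slice_thickness = 4, slice_gap = 1)
#' node_volume(av, 2L)           # N = 10, V = 10 * 0.25 = 2.5
#' @export
node_volume <- function(volume, node_label,
                        mode = c("accumulated", "max_cross_section",
                                 "voxel_volume")) {
  stopifnot(inherits(volume, "annotated_volume"))
  mode <- match.arg(mode)
  node_label <- as.integer(node_label)
  if (node_label < 2L) stop("node labels are >= 2")
  n_acc <- sum(volume$voxels == node_label)
  if (n_acc == 0L) stop(sprintf("label %d absent from mask", node_label))
  p <- volume$pixel_spacing[[1L]] * volume$pixel_spacing[[2L]]
  if (mode == "accumulated") {
    n <- n_acc; v <- n * p
  } else if (mode == "max_cross_section") {
    n <- .max_cross_section_count(volume, node_label); v <- n * p
  } else {
    n <- n_acc
    v <- n * p * (volume$slice_thickness + volume$slice_gap)
  }
  list(node_label = node_label, pixel_count = as.integer(n), volume = v,
       mode = mode)
}

#' Drainage distance of one lymph node from the tumor
#'
#' Centroids are arithmetic means of voxel-center physical coordinates.
#' The in-plane terms are millimetre differences of the centroid row and
#' column positions; the through-plane term is
#' \[DeltaS x G + (DeltaS - 1) x T\]^2 with DeltaS the absolute
#' difference of the two centroid slice indices, each rounded to the
#' nearest integer (half away from zero). DeltaS = 0 contributes no
#' through-plane term.
#'
#' @inheritParams node_volume
#' @return list with `node_label`, `centroid` (slice index, row mm,
#'   col mm), `tumor_centroid`, `delta_s` and `distance` (mm).
#' @export
node_distance <- function(volume, node_label) {
  stopifnot(inherits(volume, "annotated_volume"))
  node_label <- as.integer(node_label)
  if (node_label < 2L) stop("node labels are >= 2")
  ct <- .structure_centroid(volume, 1L)
  cn <- .structure_centroid(volume, node_label)
  ds <- abs(.round_half_away(cn[["slice"]]) - .round_half_away(ct[["slice"]]))
  through2 <- if (ds == 0) 0 else
    (ds * volume$slice_gap + (ds - 1) * volume$slice_thickness)^2
  d <- sqrt((cn[["row_mm"]] - ct[["row_mm"]])^2 +
            (cn[["col_mm"]] - ct[["col_mm"]])^2 + through2)
  list(node_label = node_label, centroid = cn, tumor_centroid = ct,
       delta_s = as.integer(ds), distance = d)
}

#' Annotate per-node size and distance classes
#'
#' Individual nodes are dichotomized into large vs small (L-LN / S-LN)
#' and distant vs near (D-LN / N-LN) classes. Size uses the equivalent
#' diameter of the node's maximal cross-section (diameter of the circle
#' with the same area); both thresholds are inclusive on the
#' large/distant side.
#'
#' @param nodes per-node feature data.frame with columns
#'   `max_cross_section_mm2` and `distance`.
#' @param size_threshold diameter threshold in mm (default 5 mm,
#'   i.e. 0.5 cm).
#' @param distance_threshold distance threshold in mm (default 50 mm,
#'   i.e. 5 cm).
#' @return `nodes` with added columns `equiv_diameter_mm`, `size_class`
#'   and `distance_class`.
#' @export
annotate_node_classes <- function(nodes, size_threshold = 5,
                                  distance_threshold = 50) {
  stopifnot(is.data.frame(nodes),
            all(c("max_cross_section_mm2", "distance") %in% names(nodes)))
  nodes$equiv_diameter_mm <- 2 * sqrt(nodes$max_cross_section_mm2 / pi)
  nodes$size_class <- ifelse(nodes$equiv_diameter_mm >= size_threshold,
                             "L-LN", "S-LN")
  nodes$distance_class <- ifelse(nodes$distance >= distance_threshold,
                                 "D-LN", "N-LN")
  nodes
}

#' Per-patient lymph-node feature set
#'
#' Computes every node's volume and drainage distance and aggregates the
#' patient totals tLNV = sum of V_i and tLND = sum of D_i. A patient
#' with no visible nodes gets tLNV = tLND = 0, node_count = 0 and is
#' flagged (`no_nodes = TRUE`).
#'
#' @inheritParams node_volume
#' @param size_threshold,distance_threshold node-class thresholds,
#'   see [annotate_node_classes()].
#' @return An object of class `patient_features`: list with
#'   `patient_id`, `mode`, per-node data.frame `nodes`, totals `tLNV`
#'   (mm^3), `tLND` (mm), `node_count`, and flag `no_nodes`.
#' @export
patient_features <- function(volume,
                             mode = c("accumulated", "max_cross_section",
                                      "voxel_volume"),
                             size_threshold = 5, distance_threshold = 50) {
  stopifnot(inherits(volume, "annotated_volume"))
  mode <- match.arg(mode)
  labs <- node_labels(volume)
  p <- volume$pixel_spacing[[1L]] * volume$pixel_spacing[[2L]]
  if (length(labs)) {
    rows <- lapply(labs, function(lb) {
      nv <- node_volume(volume, lb, mode)
      nd <- node_distance(volume, lb)
      data.frame(node_label = lb,
                 pixel_count = nv$pixel_count,
                 volume = nv$volume,
                 centroid_slice = nd$centroid[["slice"]],
                 centroid_row_mm = nd$centroid[["row_mm"]],
                 centroid_col_mm = nd$centroid[["col_mm"]],
                 delta_s = nd$delta_s,
                 distance = nd$distance,
                 max_cross_section_mm2 =
                   .max_cross_section_count(volume, lb) * p)
    })
    nodes <- annotate_node_classes(do.call(rbind, rows),
                                   size_threshold, distance_threshold)
  } else {
    nodes <- annotate_node_classes(data.frame(
      node_label = integer(0), pixel_count = integer(0), volume = numeric(0),
      centroid_slice = numeric(0), centroid_row_mm = numeric(0),
      centroid_col_mm = numeric(0), delta_s = integer(0),
      distance = numeric(0), max_cross_section_mm2 = numeric(0)),
      size_threshold, distance_threshold)
  }
  structure(list(patient_id = volume$patient_id, mode = mode, nodes = nodes,
                 tLNV = sum(nodes$volume), tLND = sum(nodes$distance),
                 node_count = nrow(nodes), no_nodes = nrow(nodes) == 0L),
            class = "patient_features")
}

#' @export
print.patient_features <- function(x, ...) {
  cat(sprintf("patient_features '%s' (volume mode: %s)\n",
              x$patient_id, x$mode))
  cat(sprintf("  node_count = %d%s\n", x$node_count,
              if (x$no_nodes) "  [no visible nodes]" else ""))
  cat(sprintf("  tLNV = %.6g mm^3, tLND = %.6g mm\n", x$tLNV, x$tLND))
  invisible(x)
}

#' Patient-level feature table over a set of volumes
#'
#' @param volumes list of [annotated_volume()] objects.
#' @inheritParams patient_features
#' @return data.frame with one row per patient: `patient_id`, `tLNV`,
#'   `tLND`, `node_count`, `no_nodes`, `volume_mode`.
#' @export
features_table <- function(volumes, mode = "accumulated",
                           size_threshold = 5, distance_threshold = 50) {
  stopifnot(is.list(volumes))
  rows <- lapply(volumes, function(v) {
    pf <- patient_features(v, mode, size_threshold, distance_threshold)
    data.frame(patient_id = pf$patient_id, tLNV = pf$tLNV, tLND = pf$tLND,
               node_count = pf$node_count, no_nodes = pf$no_nodes,
               volume_mode = pf$mode)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
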