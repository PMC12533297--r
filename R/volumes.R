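#' Instance-labeled MRI volume with acquisition geometry
#'
#' An `annotated_volume` couples a 3D integer label array with the
#' acquisition geometry needed to convert voxel counts and index offsets
#' into physical millimetres. Array axis 1 is the slice (through-plane)
#' axis; axes 2 and 3 are in-plane rows and columns. Label 0 is
#' background, label 1 the primary tumor, and labels >= 2 individual
#' lymph nodes. The physical coordinate of a voxel is its 0-based index
#' times the spacing (voxel-center convention); origins cancel in all
#' distance differences.
#'
#' If the mask carries a single node label (only label 2) that splits
#' into several 26-connected components, the components are relabeled
#' as distinct nodes with a warning: nodes are annotated individually,
#' but common mask exports merge them into one label.
#'
#' @param voxels 3D array of whole-number labels, dim = (slices, rows, cols).
#' @param pixel_spacing in-plane spacing in mm, length 2 (row, col) or a
#'   single value used for both.
#' @param slice_thickness slice thickness T in mm (> 0).
#' @param slice_gap inter-slice gap G in mm (>= 0); taken as the
#'   edge-to-edge spacing between adjacent slices, so the center-to-center
#'   slice distance is T + G.
#' @param patient_id identifier string.
#' @param relabel `"auto"` (default) applies the single-label
#'   connected-component pass described above; `"never"` disables it.
#' @return An object of class `annotated_volume`.
#' @export
annotated_volume <- function(voxels, pixel_spacing, slice_thickness,
                             slice_gap, patient_id = "patient",
                             relabel = c("auto", "never")) {
  relabel <- match.arg(relabel)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3D array (slice, row, col)")
  if (anyNA(voxels)) stop("'voxels' contains missing values")
  if (is.double(voxels)) {
    if (max(abs(voxels - round(voxels))) > 0)
      stop("non-integer labels in mask")
    storage.mode(voxels) <- "integer"
  }
  if (!is.integer(voxels)) stop("non-integer labels in mask")
  if (min(voxels) < 0L) stop("negative labels in mask")

  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  if (length(pixel_spacing) != 2L || anyNA(pixel_spacing) ||
      any(pixel_spacing <= 0))
    stop("'pixel_spacing' must be two strictly positive values (mm)")
  if (missing(slice_thickness) || is.null(slice_thickness) ||
      is.na(slice_thickness[1L]) || slice_thickness <= 0)
    stop("'slice_thickness' (T, mm) missing or not strictly positive")
  if (missing(slice_gap) || is.null(slice_gap) || is.na(slice_gap[1L]) ||
      slice_gap < 0)
    stop("'slice_gap' (G, mm) missing or negative")
  if (!any(voxels == 1L)) stop("tumor label absent (no voxel with label 1)")

  node_labels <- sort(unique(voxels[voxels >= 2L]))
  if (relabel == "auto" && identical(node_labels, 2L)) {
    comp <- .connected_components_26(voxels == 2L)
    k <- max(comp)
    if (k > 1L) {
      warning(sprintf(
        "single node label split into %d 26-connected components; relabeled 2..%d",
        k, k + 1L))
      voxels[comp > 0L] <- comp[comp > 0L] + 1L
    }
  }

  structure(list(
    voxels = voxels,
    pixel_spacing = c(row = as.numeric(pixel_spacing[1L]),
                      col = as.numeric(pixel_spacing[2L])),
    slice_thickness = as.numeric(slice_thickness),
    slice_gap = as.numeric(slice_gap),
    patient_id = as.character(patient_id)
  ), class = "annotated_volume")
}

#' @export
print.annotated_volume <- function(x, ...) {
  dm <- dim(x$voxels)
  cat(sprintf("annotated_volume '%s': %d x %d x %d (slice x row x col)\n",
              x$patient_id, dm[1L], dm[2L], dm[3L]))
  cat(sprintf("  spacing %.4g x %.4g mm, T = %.4g mm, G = %.4g mm\n",
              x$pixel_spacing[1L], x$pixel_spacing[2L],
              x$slice_thickness, x$slice_gap))
  cat(sprintf("  tumor voxels: %d; nodes: %d\n",
              sum(x$voxels == 1L), length(node_labels(x))))
  invisible(x)
}

#' Node labels present in an annotated volume
#' @param volume an `annotated_volume`.
#' @return sorted integer vector of node labels (>= 2), possibly empty.
#' @export
node_labels <- function(volume) {
  stopifnot(inherits(volume, "annotated_volume"))
  sort(unique(volume$voxels[volume$voxels >= 2L]))
}

# 26-connectivity component labeling by iterative flood fill.
# Label masks are sparse, so work is proportional to foreground size.
.connected_components_26 <- function(mask) {
  dm <- dim(mask)
  lab <- array(0L, dm)
  offs <- as.matrix(expand.grid(ds = -1:1, dr = -1:1, dc = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
  d12 <- dm[1L] * dm[2L]
  nextlab <- 0L
  for (v in which(mask)) {
    if (lab[v] != 0L) next
    nextlab <- nextlab + 1L
    lab[v] <- nextlab
    queue <- v
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ci <- arrayInd(cur, dm)
      nb <- offs + matrix(as.integer(ci), nrow(offs), 3L, byrow = TRUE)
      ok <- nb[, 1L] >= 1L & nb[, 1L] <= dm[1L] &
            nb[, 2L] >= 1L & nb[, 2L] <= dm[2L] &
            nb[, 3L] >= 1L & nb[, 3L] <= dm[3L]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1L] + (nb[, 2L] - 1L) * dm[1L] + (nb[, 3L] - 1L) * d12
      lin <- lin[mask[lin] & lab[lin] == 0L]
      if (length(lin)) {
        lab[lin] <- nextlab
        queue <- c(queue, lin)
      }
    }
  }
  lab
}

.sidecar_path <- function(image_path) {
  base <- sub("\\.nii(\\.gz)?$", "", image_path)
  for (ext in c(".yaml", ".yml", ".json")) {
    p <- paste0(base, ext)
    if (file.exists(p)) return(p)
  }
  NULL
}

.read_sidecar <- function(path) {
  # YAML parser also accepts flow-style JSON sidecars
  yaml::read_yaml(path)
}

#' Read an instance-label volume with its geometry
#'
#' Reads a NIfTI label volume and attaches acquisition geometry. In-plane
#' pixel spacing may come from the NIfTI header (`pixdim`), but slice
#' thickness T and slice gap G cannot be represented separately in the
#' header and must be supplied through `metadata` or a sidecar file
#' (`<image>.yaml`/`.yml`/`.json`) with fields `pixel_spacing`
#' (length 2, mm), `slice_thickness`, `slice_gap` and optionally
#' `patient_id`. When both the header and the sidecar carry in-plane
#' spacing, the sidecar wins and the override is logged via `message()`.
#' Missing thickness or spacing is a hard error: geometry is never
#' defaulted silently.
#'
#' @param image_path path to a 3D NIfTI file (axis 1 = slice).
#' @param metadata `NULL` (look for a sidecar next to the image), a path
#'   to a sidecar file, or a named list with the sidecar fields.
#' @param relabel passed to [annotated_volume()].
#' @return An [annotated_volume()].
#' @export
read_annotated_volume <- function(image_path, metadata = NULL,
                                  relabel = c("auto", "never")) {
  if (!file.exists(image_path)) stop("image file not found: ", image_path)
  img <- RNifti::readNifti(image_path)
  if (length(dim(img)) != 3L) stop("expected a 3D volume: ", image_path)
  arr <- array(as.vector(img), dim(img))  # plain array, header attrs dropped
  pd <- RNifti::pixdim(img)

  side <- NULL
  if (is.null(metadata)) {
    sp <- .sidecar_path(image_path)
    if (!is.null(sp)) side <- .read_sidecar(sp)
  } else if (is.character(metadata)) {
    if (!file.exists(metadata)) stop("sidecar file not found: ", metadata)
    side <- .read_sidecar(metadata)
  } else if (is.list(metadata)) {
    side <- metadata
  } else stop("'metadata' must be NULL, a file path or a list")

  header_spacing <- if (length(pd) >= 3L) as.numeric(pd[2:3]) else NULL
  spacing <- side$pixel_spacing %||% header_spacing
  if (is.null(spacing))
    stop("in-plane pixel spacing missing from both header and sidecar")
  if (!is.null(side$pixel_spacing) && !is.null(header_spacing) &&
      any(abs(as.numeric(side$pixel_spacing) - header_spacing) > 1e-6))
    message("sidecar pixel_spacing overrides NIfTI header pixdim for ",
            image_path)

  thickness <- side$slice_thickness %||% side$slice_thickness_T
  gap <- side$slice_gap %||% side$slice_gap_G
  if (is.null(thickness))
    stop("slice_thickness (T) missing: supply it in the sidecar/metadata")
  if (is.null(gap))
    stop("slice_gap (G) missing: supply it in the sidecar/metadata")

  pid <- side$patient_id %||%
    sub("\\.nii(\\.gz)?$", "", basename(image_path))

  annotated_volume(arr, pixel_spacing = as.numeric(spacing),
                   slice_thickness = as.numeric(thickness),
                   slice_gap = as.numeric(gap),
                   patient_id = pid, relabel = relabel)
}

#' Write an annotated volume as NIfTI plus a geometry sidecar
#'
#' The label array is written as integer NIfTI with header `pixdim`
#' set to (T + G, row spacing, col spacing); the full geometry,
#' including T and G separately, goes into a YAML sidecar so that
#' [read_annotated_volume()] round-trips the object field-for-field.
#'
#' @param volume an [annotated_volume()].
#' @param image_path output path (`.nii` or `.nii.gz`).
#' @return `image_path`, invisibly.
#' @export
write_annotated_volume <- function(volume, image_path) {
  stopifnot(inherits(volume, "annotated_volume"))
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- c(volume$slice_thickness + volume$slice_gap,
                           volume$pixel_spacing)
  RNifti::writeNifti(img, image_path)
  side <- list(
    patient_id = volume$patient_id,
    pixel_spacing = as.numeric(volume$pixel_spacing),
    slice_thickness = volume$slice_thickness,
    slice_gap = volume$slice_gap
  )
  # precision 17 makes the double fields round-trip bit-exactly
  yaml::write_yaml(side, paste0(sub("\\.nii(\\.gz)?$", "", image_path),
                                ".yaml"), precision = 17L)
  invisible(image_path)
}
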