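# NIfTI volume records and pure preprocessing transforms.
#
# A VolumeRecord holds a (H, W, D, C) image array, an optional integer
# (H, W, D) label map, per-axis voxel spacing in mm, and opaque orientation
# metadata passed through from the source file. Voxel indices are 0-based in
# all coordinate arithmetic; crop windows are half-open [lo, hi).

#' Construct a volume record
#'
#' @param image Numeric array, `(H, W, D)` or `(H, W, D, C)`; a 3D array is
#'   promoted to a single channel.
#' @param labels Optional integer `(H, W, D)` label map, spatially congruent
#'   with `image`.
#' @param spacing Positive voxel size per axis (mm); length 3.
#' @param id Identifier string.
#' @param affine Optional 4x4 orientation matrix (passthrough metadata).
#' @return An object of class `afms_volume`.
#' @export
volume_record <- function(image, labels = NULL, spacing = c(1, 1, 1),
                          id = "volume", affine = NULL) {
  if (length(dim(image)) == 3L) dim(image) <- c(dim(image), 1L)
  if (length(dim(image)) != 4L)
    abort_validation("image must be a 3D or 4D array")
  if (!is.null(labels)) {
    if (!identical(dim(labels)[1:3], dim(image)[1:3]) || length(dim(labels)) != 3L)
      abort_validation("labels must be a 3D array congruent with the image")
    storage.mode(labels) <- "integer"
  }
  if (length(spacing) != 3L || any(spacing <= 0))
    abort_validation("spacing must be 3 positive values (mm)")
  structure(list(image = image, labels = labels, spacing = as.numeric(spacing),
                 id = as.character(id), affine = affine),
            class = "afms_volume")
}

#' @export
print.afms_volume <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<afms_volume '%s'> %dx%dx%d, %d channel(s), spacing %s mm%s\n",
              x$id, d[1], d[2], d[3], d[4],
              paste(signif(x$spacing, 3), collapse = "x"),
              if (is.null(x$labels)) "" else ", labeled"))
  invisible(x)
}

#' Read / write a volume in NIfTI format
#'
#' @param path Path to a `.nii` / `.nii.gz` file (3D image or 4D
#'   multi-channel image).
#' @param label_path Optional path of a matching integer label volume.
#' @param id Identifier; defaults to the file name.
#' @return An `afms_volume`.
#' @export
read_volume <- function(path, label_path = NULL, id = NULL) {
  if (!file.exists(path)) abort_io(sprintf("cannot read volume: no such file '%s'", path))
  im <- tryCatch(RNifti::readNifti(path), error = function(e)
    abort_io(sprintf("failed to read NIfTI file '%s': %s", path, conditionMessage(e))))
  arr <- as.array(im)
  attributes(arr) <- list(dim = dim(arr))  # drop niftiImage metadata
  nd <- length(dim(arr))
  if (nd < 3L || nd > 4L)
    abort_io(sprintf("'%s' is %dD; only 3D/4D volumes are supported", path, nd))
  spacing <- RNifti::pixdim(im)[1:3]
  labels <- NULL
  if (!is.null(label_path)) {
    if (!file.exists(label_path))
      abort_io(sprintf("cannot read labels: no such file '%s'", label_path))
    labels <- as.array(RNifti::readNifti(label_path))
    attributes(labels) <- list(dim = dim(labels))
    if (length(dim(labels)) == 4L && dim(labels)[4] == 1L) dim(labels) <- dim(labels)[1:3]
    storage.mode(labels) <- "integer"
  }
  volume_record(arr, labels = labels, spacing = spacing,
                id = if (is.null(id)) sub("\\.nii(\\.gz)?$", "", basename(path)) else id,
                affine = structure(RNifti::xform(im), code = NULL))
}

#' @rdname read_volume
#' @param record An `afms_volume`.
#' @param what Which component to write: `"image"` or `"labels"`.
#' @export
write_volume <- function(record, path, what = c("image", "labels")) {
  what <- match.arg(what)
  arr <- if (what == "image") {
    a <- record$image
    if (dim(a)[4] == 1L) { d <- dim(a)[1:3]; dim(a) <- d }
    a
  } else {
    if (is.null(record$labels)) abort_validation("record has no labels to write")
    record$labels
  }
  nd <- length(dim(arr))
  im <- RNifti::asNifti(arr, reference = NULL)
  RNifti::pixdim(im) <- if (nd == 4L) c(record$spacing, 1) else record$spacing
  ok <- tryCatch({ RNifti::writeNifti(im, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) abort_io(sprintf("failed to write '%s'", path))
  invisible(path)
}

#' Central crop
#'
#' Crops image and labels to `target_shape` with a centered window. When the
#' size difference along an axis is odd, the low side keeps
#' `floor(diff / 2)` voxels, i.e. the extra voxel is dropped from the
#' high-index side.
#'
#' @param record An `afms_volume`.
#' @param target_shape Integer length-3 target spatial shape; each entry must
#'   not exceed the source shape.
#' @return Cropped `afms_volume`.
#' @export
central_crop <- function(record, target_shape) {
  src <- dim(record$image)[1:3]
  tgt <- as.integer(target_shape)
  if (length(tgt) != 3L || any(tgt < 1L)) abort_validation("target_shape must be 3 positive integers")
  if (any(tgt > src))
    abort_validation(sprintf("target shape (%s) exceeds source shape (%s)",
                             paste(tgt, collapse = "x"), paste(src, collapse = "x")))
  lo <- (src - tgt) %/% 2L  # 0-based low index of the kept window [lo, lo+tgt)
  ix <- lapply(1:3, function(a) seq.int(lo[a] + 1L, lo[a] + tgt[a]))
  record$image <- record$image[ix[[1]], ix[[2]], ix[[3]], , drop = FALSE]
  if (!is.null(record$labels))
    record$labels <- record$labels[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  record
}

#' Symmetric zero padding (inverse companion of [central_crop()])
#'
#' @inheritParams central_crop
#' @param target_shape Target spatial shape, at least the source shape.
#' @param value Fill value for the image (labels pad with 0).
#' @export
central_pad <- function(record, target_shape, value = 0) {
  src <- dim(record$image)[1:3]
  tgt <- as.integer(target_shape)
  if (any(tgt < src)) abort_validation("target shape must be >= source shape")
  lo <- (tgt - src) %/% 2L
  img <- array(value, c(tgt, dim(record$image)[4]))
  ix <- lapply(1:3, function(a) seq.int(lo[a] + 1L, lo[a] + src[a]))
  img[ix[[1]], ix[[2]], ix[[3]], ] <- record$image
  record$image <- img
  if (!is.null(record$labels)) {
    lab <- array(0L, tgt)
    lab[ix[[1]], ix[[2]], ix[[3]]] <- record$labels
    record$labels <- lab
  }
  record
}

# Map output voxel index (0-based) to input coordinate, aligning the centers
# of the two fields of view: coord = (i + 0.5) * S_in/S_out - 0.5.
resample_coords <- function(s_in, s_out) {
  (seq_len(s_out) - 0.5) * (s_in / s_out) - 0.5
}

#' Resample a volume to a target spacing or shape
#'
#' The image is interpolated trilinearly; labels use nearest-neighbour so no
#' new label values can appear. Exactly one of `target_spacing` and
#' `target_shape` must be given.
#'
#' @param record An `afms_volume`.
#' @param target_spacing Desired voxel size per axis (mm); the output shape is
#'   `round(shape * spacing / target_spacing)`.
#' @param target_shape Desired spatial shape; the output spacing is scaled
#'   accordingly.
#' @return Resampled `afms_volume` with updated spacing.
#' @export
resample_volume <- function(record, target_spacing = NULL, target_shape = NULL) {
  src <- dim(record$image)[1:3]
  if (is.null(target_spacing) == is.null(target_shape))
    abort_validation("give exactly one of target_spacing or target_shape")
  if (!is.null(target_spacing)) {
    if (any(target_spacing <= 0)) abort_validation("target spacing must be positive")
    tgt <- pmax(1L, as.integer(round(src * record$spacing / target_spacing)))
    new_spacing <- as.numeric(target_spacing)
  } else {
    tgt <- as.integer(target_shape)
    if (any(tgt < 1L)) abort_validation("target shape must be positive")
    new_spacing <- record$spacing * src / tgt
  }
  if (identical(tgt, as.integer(src))) return(record)
  cx <- resample_coords(src[1], tgt[1])
  cy <- resample_coords(src[2], tgt[2])
  cz <- resample_coords(src[3], tgt[3])
  C <- dim(record$image)[4]
  out <- array(0, c(tgt, C))
  clamp <- function(v, hi) pmin(pmax(v, 0), hi)
  i0 <- clamp(floor(cx), src[1] - 1); fx <- clamp(cx, src[1] - 1) - i0
  j0 <- clamp(floor(cy), src[2] - 1); fy <- clamp(cy, src[2] - 1) - j0
  k0 <- clamp(floor(cz), src[3] - 1); fz <- clamp(cz, src[3] - 1) - k0
  i1 <- pmin(i0 + 1, src[1] - 1); j1 <- pmin(j0 + 1, src[2] - 1); k1 <- pmin(k0 + 1, src[3] - 1)
  gx0 <- rep(i0 + 1, times = tgt[2] * tgt[3]); gx1 <- rep(i1 + 1, times = tgt[2] * tgt[3])
  wx <- rep(fx, times = tgt[2] * tgt[3])
  gy0 <- rep(rep(j0 + 1, each = tgt[1]), times = tgt[3])
  gy1 <- rep(rep(j1 + 1, each = tgt[1]), times = tgt[3])
  wy <- rep(rep(fy, each = tgt[1]), times = tgt[3])
  gz0 <- rep(k0 + 1, each = tgt[1] * tgt[2]); gz1 <- rep(k1 + 1, each = tgt[1] * tgt[2])
  wz <- rep(fz, each = tgt[1] * tgt[2])
  lin <- function(i, j, k) i + src[1] * ((j - 1) + src[2] * (k - 1))
  for (c in seq_len(C)) {
    v <- record$image[, , , c]
    acc <- v[lin(gx0, gy0, gz0)] * (1 - wx) * (1 - wy) * (1 - wz) +
      v[lin(gx1, gy0, gz0)] * wx * (1 - wy) * (1 - wz) +
      v[lin(gx0, gy1, gz0)] * (1 - wx) * wy * (1 - wz) +
      v[lin(gx1, gy1, gz0)] * wx * wy * (1 - wz) +
      v[lin(gx0, gy0, gz1)] * (1 - wx) * (1 - wy) * wz +
      v[lin(gx1, gy0, gz1)] * wx * (1 - wy) * wz +
      v[lin(gx0, gy1, gz1)] * (1 - wx) * wy * wz +
      v[lin(gx1, gy1, gz1)] * wx * wy * wz
    out[, , , c] <- acc
  }
  record$image <- out
  if (!is.null(record$labels)) {
    ni <- clamp(round(cx), src[1] - 1) + 1
    nj <- clamp(round(cy), src[2] - 1) + 1
    nk <- clamp(round(cz), src[3] - 1) + 1
    record$labels <- record$labels[ni, nj, nk, drop = FALSE]
    dim(record$labels) <- tgt
  }
  record$spacing <- new_spacing
  record
}

#' Z-score intensity normalization over the nonzero support
#'
#' Each channel is centered and scaled to unit variance over its nonzero
#' (brain) voxels; background zeros stay zero. A constant channel is zeroed
#' with a warning.
#'
#' @param record An `afms_volume`.
#' @return Normalized `afms_volume`.
#' @export
normalize_volume <- function(record) {
  C <- dim(record$image)[4]
  for (c in seq_len(C)) {
    v <- record$image[, , , c]
    sup <- v != 0
    if (!any(sup)) { warning(sprintf("channel %d is all zero", c)); next }
    x <- v[sup]
    mu <- mean(x)
    sdv <- sqrt(mean((x - mu)^2))
    if (sdv == 0) {
      warning(sprintf("channel %d is constant on its support; returning zeros", c))
      v[sup] <- 0
    } else {
      v[sup] <- (x - mu) / sdv
    }
    record$image[, , , c] <- v
  }
  record
}

gauss_kernel <- function(sigma) {
  if (sigma == 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Convolve along one axis with mirror (reflect) boundary handling.
conv_axis <- function(v, k, ax) {
  r <- (length(k) - 1L) / 2L
  if (r == 0L) return(v)
  d <- dim(v)
  n1 <- prod(d[seq_len(ax - 1L)]); n2 <- d[ax]; n3 <- prod(d) / (n1 * n2)
  m <- array(v, c(n1, n2, n3))
  out <- array(0, c(n1, n2, n3))
  for (o in seq(-r, r)) {
    idx <- seq_len(n2) + o
    idx[idx < 1] <- 1 - idx[idx < 1]            # reflect: index -i -> i + 1
    idx[idx > n2] <- 2 * n2 + 1 - idx[idx > n2]
    out <- out + k[o + r + 1] * m[, idx, , drop = FALSE]
  }
  array(out, d)
}

#' Isotropic Gaussian smoothing
#'
#' Separable Gaussian filter per channel, sigma in voxel units, kernel
#' truncated at 4 sigma and normalized to unit sum, mirror boundary. Labels
#' are untouched; `sigma = 0` is the identity.
#'
#' @param record An `afms_volume`.
#' @param sigma Standard deviation in voxels (>= 0).
#' @return Smoothed `afms_volume`.
#' @export
gaussian_smooth <- function(record, sigma = 0.5) {
  if (length(sigma) != 1L || sigma < 0) abort_validation("sigma must be a single value >= 0")
  if (sigma == 0) return(record)
  k <- gauss_kernel(sigma)
  C <- dim(record$image)[4]
  for (c in seq_len(C)) {
    v <- record$image[, , , c]
    for (ax in 1:3) v <- conv_axis(v, k, ax)
    record$image[, , , c] <- v
  }
  record
}

#' One-hot encode a label map
#'
#' Raw label values are remapped to contiguous class indices `0..K-1` in the
#' order of `label_values` (e.g. BraTS `0,1,2,4` maps raw 4 to class 3).
#'
#' @param labels Integer label array.
#' @param label_values Raw values in class order; default: sorted unique
#'   values of `labels`.
#' @param n_classes Number of classes `K`; defaults to
#'   `length(label_values)`.
#' @return Array `(dim(labels), K)` of 0/1 with channel sums 1.
#' @export
one_hot_labels <- function(labels, label_values = NULL, n_classes = NULL) {
  if (is.null(label_values)) label_values <- sort(unique(as.vector(labels)))
  if (is.null(n_classes)) n_classes <- length(label_values)
  if (length(label_values) > n_classes)
    abort_validation("more raw label values than classes")
  idx <- match(as.vector(labels), label_values)
  if (anyNA(idx))
    abort_validation(sprintf("label value(s) not in label_values: %s",
                             paste(setdiff(unique(as.vector(labels)), label_values), collapse = ", ")))
  out <- matrix(0, length(idx), n_classes)
  out[cbind(seq_along(idx), idx)] <- 1
  array(out, c(dim(labels), n_classes))
}

#' Fuse modalities and one-hot encode labels
#'
#' Stacks the given single-channel volumes on the channel axis in the declared
#' order and one-hot encodes the label map.
#'
#' @param modalities List of `afms_volume` records or 3D arrays, spatially
#'   congruent.
#' @param labels Integer label array congruent with the modalities.
#' @param label_values,n_classes Passed to [one_hot_labels()].
#' @return List with `image` `(H,W,D,C)` and `onehot` `(H,W,D,K)`.
#' @export
one_hot_and_fuse <- function(modalities, labels, label_values = NULL, n_classes = NULL) {
  arrs <- lapply(modalities, function(m) {
    a <- if (inherits(m, "afms_volume")) m$image else m
    if (length(dim(a)) == 4L) {
      if (dim(a)[4] != 1L) abort_validation("each modality must be single-channel")
      dim(a) <- dim(a)[1:3]
    }
    a
  })
  d0 <- dim(arrs[[1]])
  for (a in arrs) if (!identical(dim(a), d0))
    abort_validation("modalities are not spatially congruent")
  if (!identical(dim(labels), d0))
    abort_validation("labels are not congruent with the modalities")
  image <- array(unlist(arrs, use.names = FALSE), c(d0, length(arrs)))
  list(image = image, onehot = one_hot_labels(labels, label_values, n_classes))
}

#' Foreground fraction of a labeled record
#'
#' @param record An `afms_volume` with labels (or a bare label array).
#' @return Fraction of voxels with a non-zero label.
#' @export
foreground_fraction <- function(record) {
  lab <- if (inherits(record, "afms_volume")) record$labels else record
  if (is.null(lab)) abort_validation("record has no labels")
  mean(lab != 0)
}

#' Discard volumes with near-empty labels
#'
#' Keeps a record iff its non-zero-label voxel fraction is at least
#' `fraction`; a volume exactly at the boundary is kept (only strictly
#' smaller fractions are discarded).
#'
#' @param records List of labeled `afms_volume` records.
#' @param fraction Minimum foreground fraction (default 0.01, i.e. 1%).
#' @return The kept records (same order).
#' @export
low_label_filter <- function(records, fraction = 0.01) {
  keep <- vapply(records, function(r) foreground_fraction(r) >= fraction, logical(1))
  records[keep]
}

#' Deterministic train/validation/test split
#'
#' Shuffles the ids with the given seed, then partitions. Subset sizes are the
#' floors of `n * fraction`; any remainder goes to the training set.
#'
#' @param ids Character or integer vector of case identifiers.
#' @param fractions Positive fractions for train/validation/test, summing
#'   to 1.
#' @param seed Integer seed.
#' @return Named list `train`, `validation`, `test`: disjoint, union = `ids`.
#' @export
dataset_split <- function(ids, fractions = c(train = 0.8, validation = 0.1, test = 0.1),
                          seed = 1L) {
  if (length(fractions) != 3L || any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-8)
    abort_validation("fractions must be 3 positive values summing to 1")
  n <- length(ids)
  if (n < 3L) abort_validation("need at least as many ids as partitions")
  sizes <- floor(n * fractions)
  sizes[1] <- sizes[1] + (n - sum(sizes))
  shuffled <- withr::with_seed(as.integer(seed), sample(ids))
  list(train = shuffled[seq_len(sizes[1])],
       validation = shuffled[sizes[1] + seq_len(sizes[2])],
       test = shuffled[sizes[1] + sizes[2] + seq_len(sizes[3])])
}
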