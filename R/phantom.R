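# Synthetic 3D lesion phantoms.
#
# Phantoms emulate the statistical structure of multi-modal brain-lesion
# volumes: a handful of ellipsoidal lesions of varying size and location
# occupying a few percent of the volume, optional nested class shells
# (whole > intermediate > core, like WT/TC/ET), per-(class, channel) image
# contrast, and additive Gaussian noise. Axis-aligned ellipsoids are used
# deliberately: their analytic volume (4/3 pi rx ry rz) gives an independent
# oracle for the realized foreground fraction.

#' Phantom specification
#'
#' @param grid Spatial shape `(H, W, D)`.
#' @param n_channels Number of image channels (synthetic modalities).
#' @param n_lesions Inclusive integer range `c(min, max)` for the lesion
#'   count.
#' @param radii Inclusive range `c(min, max)` (voxels) for each ellipsoid
#'   semi-axis.
#' @param nested_factors Strictly decreasing scale factors, one per nested
#'   lesion class outer-to-inner (first must be 1). `c(1, 0.6, 0.35)` gives
#'   three nested classes; `1` gives a single class.
#' @param class_intensity Matrix `(n_lesion_classes, n_channels)` of mean
#'   image intensity inside each class shell; default
#'   `background + contrast * class / sqrt(channel)`.
#' @param contrast Lesion-to-background contrast step used for the default
#'   intensity table.
#' @param background_intensity Mean intensity outside lesions.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param lesions Optional list of fixed lesions (each
#'   `list(center =, radii =)`, 0-based centers), bypassing random placement.
#' @param seed Integer seed; the phantom is a deterministic function of the
#'   spec.
#' @return An object of class `afms_phantom_spec`.
#' @export
phantom_spec <- function(grid = c(64, 64, 64), n_channels = 2L,
                         n_lesions = c(1L, 3L), radii = c(4, 12),
                         nested_factors = c(1, 0.6, 0.35),
                         class_intensity = NULL, contrast = 0.6,
                         background_intensity = 1, noise_sd = 0.1,
                         lesions = NULL, seed = 1L) {
  grid <- as.integer(grid)
  if (length(grid) != 3L || any(grid < 4L)) abort_validation("grid must be 3 dims >= 4")
  if (length(n_lesions) == 1L) n_lesions <- c(n_lesions, n_lesions)
  if (n_lesions[1] < 0 || n_lesions[2] < n_lesions[1])
    abort_validation("n_lesions must be a non-negative range")
  if (length(radii) == 1L) radii <- c(radii, radii)
  if (radii[1] <= 0) abort_validation("radii must be positive")
  if (radii[2] >= min(grid) / 2)
    abort_validation("maximum radius must be smaller than half the smallest grid dimension")
  if (any(diff(nested_factors) >= 0) && length(nested_factors) > 1)
    abort_validation("nested_factors must be strictly decreasing (outer to inner)")
  if (abs(nested_factors[1] - 1) > 1e-12)
    abort_validation("the outermost nested factor must be 1")
  if (noise_sd < 0) abort_validation("noise_sd must be >= 0")
  K <- length(nested_factors)
  if (is.null(class_intensity))
    class_intensity <- outer(seq_len(K), seq_len(n_channels), function(k, c)
      background_intensity + contrast * k / sqrt(c))
  class_intensity <- matrix(class_intensity, nrow = K, ncol = n_channels)
  structure(list(grid = grid, n_channels = as.integer(n_channels),
                 n_lesions = as.integer(n_lesions), radii = as.numeric(radii),
                 nested_factors = as.numeric(nested_factors),
                 class_intensity = class_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, lesions = lesions,
                 seed = as.integer(seed)),
            class = "afms_phantom_spec")
}

# Paint one nested-ellipsoid lesion into an integer label array (in place
# semantics via return). Later lesions overwrite earlier labels.
paint_lesion <- function(labels, center, radii, factors) {
  g <- dim(labels)
  lo <- pmax(0L, floor(center - radii))
  hi <- pmin(g - 1L, ceiling(center + radii))
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  dx2 <- ((xs - center[1]) / radii[1])^2
  dy2 <- ((ys - center[2]) / radii[2])^2
  dz2 <- ((zs - center[3]) / radii[3])^2
  q <- outer(outer(dx2, dy2, `+`), dz2, `+`)  # normalized squared radius
  sub <- labels[xs + 1L, ys + 1L, zs + 1L, drop = FALSE]
  for (k in seq_along(factors)) {
    inside <- q <= factors[k]^2
    sub[inside] <- k
  }
  labels[xs + 1L, ys + 1L, zs + 1L] <- sub
  labels
}

#' Generate one phantom volume
#'
#' @param spec A [phantom_spec()].
#' @return A labeled [volume_record()] (unit spacing). The drawn lesion
#'   geometry is attached as attribute `"lesions"`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "afms_phantom_spec")) abort_config("spec must be an afms_phantom_spec")
  g <- spec$grid
  withr::with_seed(spec$seed, {
    lesions <- spec$lesions
    if (is.null(lesions)) {
      n <- if (spec$n_lesions[1] == spec$n_lesions[2]) spec$n_lesions[1]
      else sample(seq(spec$n_lesions[1], spec$n_lesions[2]), 1L)
      lesions <- lapply(seq_len(n), function(i) {
        r <- stats::runif(3, spec$radii[1], spec$radii[2])
        ctr <- vapply(1:3, function(a) {
          lo <- ceiling(r[a]); hi <- floor(g[a] - 1 - r[a])
          if (hi < lo) abort_validation("lesion radius does not fit inside the grid")
          sample(seq(lo, hi), 1L)
        }, numeric(1))
        list(center = ctr, radii = r)
      })
    }
    labels <- array(0L, g)
    for (le in lesions)
      labels <- paint_lesion(labels, le$center, le$radii, spec$nested_factors)
    img <- array(0, c(g, spec$n_channels))
    for (c in seq_len(spec$n_channels)) {
      base <- array(spec$background_intensity, g)
      for (k in seq_len(nrow(spec$class_intensity)))
        base[labels == k] <- spec$class_intensity[k, c]
      img[, , , c] <- base + stats::rnorm(prod(g), sd = spec$noise_sd)
    }
    rec <- volume_record(img, labels = labels, spacing = c(1, 1, 1),
                         id = sprintf("phantom_seed%d", spec$seed))
    attr(rec, "lesions") <- lesions
    rec
  })
}

#' Analytic foreground fraction of the drawn lesions
#'
#' Sum of ellipsoid volumes (4/3 pi rx ry rz) over the lesions drawn into a
#' phantom, divided by the grid volume. Ignores lesion overlap, so it is an
#' upper bound that is exact for non-overlapping lesions.
#'
#' @param record A [generate_phantom()] result.
#' @return Predicted foreground fraction.
#' @export
analytic_foreground_fraction <- function(record) {
  lesions <- attr(record, "lesions")
  if (is.null(lesions)) abort_validation("record carries no lesion geometry")
  v <- sum(vapply(lesions, function(le) 4 / 3 * pi * prod(le$radii), numeric(1)))
  v / prod(dim(record$labels))
}

#' Generate a phantom dataset on disk
#'
#' Writes `n_volumes` NIfTI image/label pairs and a CSV manifest. Per-volume
#' seeds are derived deterministically from the spec's master seed, so two
#' runs with the same spec produce identical files.
#'
#' @param spec A [phantom_spec()]; its `seed` is the master seed.
#' @param n_volumes Number of volumes.
#' @param out_dir Output directory (created if needed).
#' @return Manifest tibble (`id`, `image`, `labels`,
#'   `foreground_fraction`), also written to `manifest.csv` in `out_dir`.
#' @export
generate_dataset <- function(spec, n_volumes, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort_io(sprintf("cannot create output directory '%s'", out_dir))
  }
  seeds <- withr::with_seed(spec$seed, sample.int(2147483646L, n_volumes))
  rows <- lapply(seq_len(n_volumes), function(i) {
    sp <- spec; sp$seed <- seeds[i]
    rec <- generate_phantom(sp)
    rec$id <- sprintf("phantom_%03d", i)
    ipath <- file.path(out_dir, paste0(rec$id, "_image.nii.gz"))
    lpath <- file.path(out_dir, paste0(rec$id, "_labels.nii.gz"))
    write_volume(rec, ipath, "image")
    write_volume(rec, lpath, "labels")
    tibble::tibble(id = rec$id, image = ipath, labels = lpath,
                   foreground_fraction = foreground_fraction(rec))
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Read a dataset manifest and load its volumes
#'
#' @param path Path to a `manifest.csv` written by [generate_dataset()] (or a
#'   hand-written CSV with columns `id`, `image` and optionally `labels`).
#' @return Tibble manifest.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("no such manifest: '%s'", path))
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_manifest
#' @param manifest A manifest tibble.
#' @return For `load_dataset()`: list of `afms_volume` records.
#' @export
load_dataset <- function(manifest) {
  lapply(seq_len(nrow(manifest)), function(i)
    read_volume(manifest$image[i],
                label_path = if ("labels" %in% names(manifest)) manifest$labels[i] else NULL,
                id = manifest$id[i]))
}
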