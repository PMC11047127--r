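# Segmentation evaluation: confusion counts, overlap metrics, average
# Hausdorff distance, and BraTS-style nested evaluation regions.

#' Binarize a probability map
#'
#' A voxel is positive for a class when its probability is greater than or
#' equal to the threshold (a tie at exactly 0.5 counts as positive).
#'
#' @param prob Numeric array of probabilities in `[0, 1]`.
#' @param threshold Scalar in the open interval (0, 1); default 0.5.
#' @return Logical array of the same shape.
#' @export
binarize <- function(prob, threshold = 0.5) {
  if (length(threshold) != 1L || threshold <= 0 || threshold >= 1)
    abort_validation("threshold must lie strictly between 0 and 1")
  if (any(prob < 0 | prob > 1)) abort_validation("probabilities must lie in [0, 1]")
  out <- prob >= threshold
  if (!is.null(dim(prob))) dim(out) <- dim(prob)
  out
}

#' Voxelwise confusion counts
#'
#' @param pred,truth Congruent logical (binary) arrays.
#' @return A list of class `afms_confusion` with integer fields `tp`, `tn`,
#'   `fp`, `fn`; counts sum to the number of voxels.
#' @export
confusion_counts <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    abort_validation("pred and truth must have identical shapes")
  p <- as.logical(pred); t <- as.logical(truth)
  structure(list(tp = sum(p & t), tn = sum(!p & !t),
                 fp = sum(p & !t), fn = sum(!p & t)),
            class = "afms_confusion")
}

#' Overlap metrics from confusion counts
#'
#' Computes accuracy, precision, recall, Dice similarity coefficient and
#' intersection-over-union. When a denominator is zero the convention is:
#' both masks empty (vacuous agreement) gives 1, exactly one empty gives 0;
#' such cells are flagged in the `degenerate` column.
#'
#' @param counts An [confusion_counts()] result, or a list with fields
#'   `tp`, `tn`, `fp`, `fn`.
#' @return One-row tibble: `accuracy`, `precision`, `recall`, `dsc`, `iou`,
#'   `degenerate`.
#' @export
overlap_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  if (any(c(tp, tn, fp, fn) < 0)) abort_validation("counts must be non-negative")
  total <- tp + tn + fp + fn
  if (total == 0) abort_validation("all confusion counts are zero")
  safe <- function(num, den) {
    if (den > 0) return(num / den)
    if (tp + fp + fn == 0) 1 else 0
  }
  degenerate <- (tp + fp == 0) || (tp + fn == 0)
  tibble::tibble(accuracy = (tp + tn) / total,
                 precision = safe(tp, tp + fp),
                 recall = safe(tp, tp + fn),
                 dsc = safe(2 * tp, 2 * tp + fp + fn),
                 iou = safe(tp, tp + fp + fn),
                 degenerate = degenerate)
}

mask_points <- function(mask) {
  d <- dim(mask)
  w <- which(mask)
  if (length(w) == 0L) return(matrix(numeric(0), ncol = 3))
  k <- arrayInd(w, d) - 1L  # 0-based voxel coordinates
  storage.mode(k) <- "double"
  k
}

# Keep only foreground voxels with at least one 6-neighbour outside the mask.
surface_voxels <- function(mask) {
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  inner <- core &
    pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] & pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] & pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] & pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  core & !inner
}

#' Average Hausdorff distance between two voxel point sets
#'
#' The symmetric mean of directed nearest-neighbour distances:
#' `0.5 * (mean_p min_l d(p,l) + mean_l min_p d(p,l))`, with Euclidean
#' distances scaled by the voxel spacing (mm). Point sets are all foreground
#' voxels of each mask by default; `mode = "surface"` uses boundary voxels
#' only.
#'
#' @param pred,truth Logical 3D masks, or n-by-3 matrices of voxel
#'   coordinates.
#' @param spacing Voxel size per axis (mm), default isotropic 1 mm.
#' @param mode `"all"` (default) or `"surface"` (masks only).
#' @param empty_penalty Value returned when exactly one set is empty; by
#'   default the physical diagonal of the mask grid (`Inf` for bare point
#'   matrices). Both sets empty returns 0. Either degenerate case carries a
#'   `"degenerate"` attribute and a warning.
#' @return Non-negative scalar distance (mm).
#' @export
average_hausdorff <- function(pred, truth, spacing = c(1, 1, 1), mode = c("all", "surface"),
                              empty_penalty = NULL) {
  mode <- match.arg(mode)
  to_pts <- function(m) {
    if (is.matrix(m) && !is.logical(m)) return(m)
    if (is.null(dim(m)) || length(dim(m)) != 3L)
      abort_validation("masks must be 3D logical arrays or n-by-3 coordinate matrices")
    if (mode == "surface") m <- surface_voxels(m)
    mask_points(m)
  }
  if (is.null(empty_penalty)) {
    empty_penalty <- if (is.array(pred) && length(dim(pred)) == 3L)
      sqrt(sum((dim(pred) * spacing)^2)) else Inf
  }
  P <- to_pts(pred); L <- to_pts(truth)
  if (nrow(P) == 0 && nrow(L) == 0) {
    warning("both point sets are empty; AHD reported as 0")
    return(structure(0, degenerate = TRUE))
  }
  if (nrow(P) == 0 || nrow(L) == 0) {
    warning("one point set is empty; AHD reported as the configured penalty")
    return(structure(empty_penalty, degenerate = TRUE))
  }
  d_pl <- nn_min_dists_cpp(P, L, spacing)
  d_lp <- nn_min_dists_cpp(L, P, spacing)
  0.5 * (mean(d_pl) + mean(d_lp))
}

#' Nested evaluation regions from a raw label map
#'
#' Builds one binary mask per named region as the union of its raw labels.
#' The default follows the standard BraTS convention with raw labels
#' 1 = NCR (necrotic/non-enhancing core), 2 = ED (peritumoral edema),
#' 4 = ET (enhancing tumor): whole tumor WT = {1, 2, 4}, tumor core
#' TC = {1, 4}, ET = {4}.
#'
#' @param labels Integer 3D array of raw labels (0 = background).
#' @param regions Named list mapping region name to an integer vector of raw
#'   labels; default [brats_regions()].
#' @return Named list of logical arrays.
#' @export
region_binary_masks <- function(labels, regions = brats_regions()) {
  vals <- sort(unique(as.vector(labels)))
  known <- sort(unique(c(0L, unlist(regions))))
  bad <- setdiff(vals, known)
  if (length(bad) > 0)
    abort_validation(sprintf("unknown raw label value(s): %s",
                             paste(bad, collapse = ", ")))
  lapply(regions, function(v) {
    m <- array(labels %in% v, dim(labels))
    m
  })
}

#' @rdname region_binary_masks
#' @param tc_literal Use the alternative tumor-core definition TC = ED u NCR
#'   = {1, 2} instead of the standard NCR u ET = {1, 4}.
#' @export
brats_regions <- function(tc_literal = FALSE) {
  list(WT = c(1L, 2L, 4L),
       TC = if (tc_literal) c(1L, 2L) else c(1L, 4L),
       ET = 4L)
}

#' Per-class and per-region metrics report for one segmentation
#'
#' Compares a predicted label map against ground truth: one row per
#' foreground class (and per nested region when `regions` is given) with all
#' overlap metrics and the average Hausdorff distance, plus the unweighted
#' mean IoU over foreground classes (background excluded).
#'
#' @param pred_labels,true_labels Congruent integer 3D label maps.
#' @param classes Integer vector of foreground class values to evaluate;
#'   default: all non-zero values present in `true_labels` or `pred_labels`.
#' @param regions Optional named list of region definitions (raw label sets).
#' @param spacing Voxel spacing (mm per axis) for AHD.
#' @return A tibble of class `afms_metrics_report`, one row per class/region,
#'   with attribute `"mean_iou"`.
#' @export
metrics_report <- function(pred_labels, true_labels, classes = NULL,
                           regions = NULL, spacing = c(1, 1, 1)) {
  if (!identical(dim(pred_labels), dim(true_labels)))
    abort_validation("label maps must have identical shapes")
  if (is.null(classes))
    classes <- sort(setdiff(unique(c(as.vector(pred_labels), as.vector(true_labels))), 0))
  row_for <- function(unit, kind, pm, tm) {
    cc <- confusion_counts(pm, tm)
    om <- overlap_metrics(cc)
    ahd <- suppressWarnings(average_hausdorff(pm, tm, spacing = spacing))
    tibble::tibble(unit = unit, kind = kind,
                   tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn,
                   om, ahd = as.numeric(ahd))
  }
  rows <- lapply(classes, function(k)
    row_for(paste0("class_", k), "class",
            array(pred_labels == k, dim(pred_labels)),
            array(true_labels == k, dim(true_labels))))
  if (!is.null(regions)) {
    pm <- region_binary_masks(pred_labels, regions)
    tm <- region_binary_masks(true_labels, regions)
    rows <- c(rows, lapply(names(regions), function(r)
      row_for(r, "region", pm[[r]], tm[[r]])))
  }
  out <- do.call(rbind, rows)
  miou <- mean(out$iou[out$kind == "class"])
  attr(out, "mean_iou") <- miou
  class(out) <- c("afms_metrics_report", class(out))
  out
}

#' @importFrom generics tidy
#' @export
tidy.afms_metrics_report <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @importFrom generics glance
#' @export
glance.afms_metrics_report <- function(x, ...) {
  cls <- x[x$kind == "class", ]
  tibble::tibble(mean_iou = attr(x, "mean_iou"),
                 mean_dsc = mean(cls$dsc),
                 mean_ahd = mean(cls$ahd[is.finite(cls$ahd)]))
}

#' Write a metrics report as JSON and/or CSV
#'
#' @param report An [metrics_report()] tibble.
#' @param json,csv Optional output paths.
#' @return The report, invisibly.
#' @export
write_metrics_report <- function(report, json = NULL, csv = NULL) {
  if (!is.null(csv)) utils::write.csv(as.data.frame(unclass(report)), csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(list(mean_iou = attr(report, "mean_iou"),
                              rows = as.data.frame(unclass(report))),
                         json, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
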