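# Declarative run configuration (YAML) mapping onto the spec constructors.
#
# Recognized top-level keys:
#   network:    fields of network_spec()
#   loss:       gamma, eps, class_weights, focal_reduce
#   train:      lr, weight_decay, epochs, patience, seed, target_dsc
#   phantom:    fields of phantom_spec()
#   synth:      n_volumes, out_dir
#   preprocess: normalize (bool), smooth_sigma, crop (3 ints),
#               low_label_fraction
#   regions:    named lists of raw label values (evaluation regions)

#' Read a run configuration file
#'
#' @param path YAML file.
#' @return Nested list of class `afms_config` with parsed sub-specs under
#'   `network`, `loss`, `phantom` (when present) and the raw remainder.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("no such config file: '%s'", path))
  raw <- yaml::read_yaml(path)
  cfg <- raw
  if (!is.null(raw$network)) cfg$network <- do.call(network_spec, raw$network)
  if (!is.null(raw$loss)) cfg$loss <- do.call(loss_config, raw$loss)
  if (!is.null(raw$phantom)) cfg$phantom <- do.call(phantom_spec, raw$phantom)
  structure(cfg, class = "afms_config")
}

#' Apply the configured preprocessing chain to one record
#'
#' Order: central crop (if configured), z-score normalization, Gaussian
#' smoothing. Pure: returns a new record.
#'
#' @param record An `afms_volume`.
#' @param preprocess The `preprocess` section of a run configuration (list
#'   with optional `crop`, `normalize`, `smooth_sigma`).
#' @return Preprocessed `afms_volume`.
#' @export
apply_preprocess <- function(record, preprocess = list()) {
  if (!is.null(preprocess$crop)) record <- central_crop(record, preprocess$crop)
  if (isTRUE(preprocess$normalize)) record <- normalize_volume(record)
  sg <- preprocess$smooth_sigma
  if (!is.null(sg) && sg > 0) record <- gaussian_smooth(record, sg)
  record
}
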