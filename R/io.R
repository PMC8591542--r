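## File interfaces: multi-page TIFF stacks, label masks, tables and
## parameter echo.

#' Read a multi-page TIFF as a stack
#'
#' @param path TIFF file; pages become z-slices.
#' @return numeric array (height x width x slices).
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  array(unlist(pages), c(dim(pages[[1]]), length(pages)))
}

#' Write a stack as a multi-page TIFF
#'
#' @param stack matrix or 3D array; values are clamped to [0, 1].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1))
  pages <- lapply(seq_len(dim(stack)[3]),
                  function(k) pmin(pmax(stack[, , k], 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Read an integer label mask from TIFF
#'
#' Inverse of [write_label_mask()]: 16-bit grey levels are scaled back to
#' integer labels.
#'
#' @param path TIFF file written by [write_label_mask()].
#' @return integer label matrix.
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(round(m)), nrow(m), ncol(m))
}

#' Write an integer label mask as 16-bit TIFF
#'
#' @param labels integer matrix (labels 0..65535).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(labels, path) {
  assert_that(max(labels) <= 65535, "labels exceed 16-bit range")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' Write a rendered synthetic field to a directory
#'
#' One multi-page TIFF per channel, the truth label mask as 16-bit TIFF,
#' truth class masks, the per-cell truth table as CSV and the spec echoed
#' as YAML.
#'
#' @param field a `synthetic_field`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_field <- function(field, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in names(field$channels))
    write_stack(field$channels[[ch]], file.path(dir, paste0(ch, ".tif")))
  write_label_mask(field$truth_cells, file.path(dir, "truth_cells.tif"))
  for (m in intersect(c("truth_er", "truth_tubules", "truth_sheets",
                        "truth_clusters"), names(field)))
    write_label_mask(field[[m]] * 1L, file.path(dir, paste0(m, ".tif")))
  write.csv(field$per_cell_truth, file.path(dir, "per_cell_truth.csv"),
            row.names = FALSE)
  spec <- field$spec
  class(spec) <- NULL
  yaml::write_yaml(spec, file.path(dir, "spec.yaml"))
  invisible(dir)
}

#' Read classifier or pipeline parameters from YAML
#'
#' @param path YAML file with a subset of the constructor's arguments.
#' @param constructor one of [field_spec()], [midcell_params()],
#'   [classifier_params()], [screen_params()], [screen_sim_spec()].
#' @return the constructed parameter object.
#' @export
params_from_yaml <- function(path, constructor) {
  args <- yaml::read_yaml(path)
  do.call(constructor, args)
}
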