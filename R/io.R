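# Fixed intensity scale for 16-bit export. One global scale for all scenes
# mirrors constant acquisition settings: exported DN = intensity / scale *
# 65535, so intensities up to `scale` are representable.
TIFF_INTENSITY_SCALE <- 1024

#' Write a scene to disk as multi-page TIFF with sidecar and mask
#'
#' Pages are ordered protein, co-marker, nuclei; pixel data are written as
#' 16-bit at a fixed global intensity scale. A JSON sidecar records the
#' generating [scene_spec()] and seed; the ground-truth mask is written as a
#' 16-bit single-page label TIFF.
#'
#' @param scene A `coloc_scene`.
#' @param dir Output directory (created if needed).
#' @param id Basename for the scene files.
#' @return Invisibly, the paths written (image, mask, sidecar).
#' @export
write_scene <- function(scene, dir, id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(id, ".tif"))
  pages <- lapply(scene$channels[c("protein", "comarker", "nuclei")],
                  function(ch) pmin(pmax(ch / TIFF_INTENSITY_SCALE, 0), 1))
  tiff::writeTIFF(pages, img_path, bits.per.sample = 16)
  mask_path <- file.path(dir, paste0(id, "_mask.tif"))
  tiff::writeTIFF(scene$truth$mask / 65535, mask_path, bits.per.sample = 16)
  sidecar <- file.path(dir, paste0(id, ".json"))
  jsonlite::write_json(
    list(spec = unclass(scene$spec), intensity_scale = TIFF_INTENSITY_SCALE),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(image = img_path, mask = mask_path, sidecar = sidecar))
}

#' Read a scene written by [write_scene()]
#'
#' @param path Path to the multi-page image TIFF; the `.json` sidecar and
#'   `_mask.tif` are looked up next to it.
#' @return A `coloc_scene` (with `truth$mask` if the mask file exists;
#'   `per_cell_alpha` and `centers` are not recoverable from disk).
#' @export
read_scene <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 3) stop("expected >= 3 pages (protein, comarker, nuclei)")
  sidecar <- sub("\\.tif$", ".json", path)
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  scale <- meta$intensity_scale %||% TIFF_INTENSITY_SCALE
  channels <- lapply(pages[1:3], function(p) p * scale)
  names(channels) <- c("protein", "comarker", "nuclei")
  mask_path <- sub("\\.tif$", "_mask.tif", path)
  mask <- if (file.exists(mask_path))
    matrix(as.integer(round(tiff::readTIFF(mask_path) * 65535)),
           nrow(channels$protein), ncol(channels$protein))
  spec <- meta$spec
  structure(list(channels = channels,
                 comarker = spec$comarker %||% "PM",
                 genotype_label = spec$genotype_label %||% "unknown",
                 pixel_size = spec$pixel_size %||% NA_real_,
                 spec = spec,
                 truth = list(mask = mask, per_cell_alpha = NULL, centers = NULL)),
            class = "coloc_scene")
}

#' Write a dataset: per-scene TIFFs plus a manifest TSV
#'
#' @param dataset A `coloc_dataset`.
#' @param dir Output directory.
#' @return Invisibly, the manifest path. The manifest has columns path,
#'   genotype_label, comarker, seed.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- dataset$manifest
  man$path <- file.path(dir, paste0(man$scene_id, ".tif"))
  for (i in seq_len(nrow(man)))
    write_scene(dataset$scenes[[man$scene_id[i]]], dir, man$scene_id[i])
  out <- man[c("path", "genotype_label", "comarker", "seed")]
  man_path <- file.path(dir, "manifest.tsv")
  write_tsv(out, man_path)
  invisible(man_path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a label mask and its ROI table
#'
#' @param mask A `label_mask`.
#' @param dir Output directory.
#' @param id Basename.
#' @return Invisibly the paths written (16-bit label TIFF + ROI table TSV).
#' @export
write_mask <- function(mask, dir, id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tif <- file.path(dir, paste0(id, "_labels.tif"))
  tiff::writeTIFF(mask$labels / 65535, tif, bits.per.sample = 16)
  tsv <- file.path(dir, paste0(id, "_rois.tsv"))
  write_tsv(mask$table, tsv)
  invisible(c(labels = tif, table = tsv))
}

#' Read a 16-bit label TIFF into an integer label matrix
#' @param path Path to the label TIFF.
#' @return Integer matrix of labels (0 = background).
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}
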