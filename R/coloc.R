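#' Pearson correlation within one cell ROI
#'
#' Computes the Pearson correlation coefficient between two channels over
#' exactly the pixels carrying `label` in the mask. Every ROI pixel is
#' included — there is no intensity sub-thresholding inside the ROI.
#'
#' @param channel_a,channel_b Numeric matrices of identical dimensions.
#' @param mask A `label_mask` or integer label matrix.
#' @param label Cell label (> 0) present in the mask.
#' @return Pearson r in `[-1, 1]`.
#' @export
pearson_roi <- function(channel_a, channel_b, mask, label) {
  lab <- if (inherits(mask, "label_mask")) mask$labels else mask
  if (!all(dim(channel_a) == dim(channel_b)) || !all(dim(channel_a) == dim(lab)))
    stop("channels and mask must share dimensions")
  px <- lab == label
  if (!any(px)) stop(sprintf("label %s not present in mask", label))
  a <- channel_a[px]; b <- channel_b[px]
  if (sd(a) == 0 || sd(b) == 0)
    stop(structure(class = c("cellcoloc_constant_roi", "error", "condition"),
                   list(message = sprintf(
                     "undefined correlation: constant channel within ROI %s", label),
                     call = sys.call())))
  cor(a, b)
}

#' Batch per-cell colocalization measurements
#'
#' One measurement per (cell, scene): the Pearson correlation between the
#' protein channel and the scene's co-marker channel over the cell's pixels.
#' Cells with an undefined correlation (a constant channel inside the ROI)
#' are dropped and counted in the attached run log.
#'
#' @param stacks A `coloc_dataset`, or a named list of `coloc_scene` objects.
#' @param masks Named list of `label_mask` objects, one per scene (names must
#'   match scene ids). If omitted, masks are computed with [extract_rois()]
#'   under `params`.
#' @param params [segmentation_params()] used when `masks` is `NULL`.
#' @return A data.frame of class `coloc_records` with columns image_id,
#'   cell_label, genotype_label, comarker, pearson_r, n_pixels, provenance,
#'   sorted by (genotype_label, image_id, cell_label). Attribute `dropped`
#'   is a data.frame of skipped cells.
#' @export
measure_dataset <- function(stacks, masks = NULL, params = segmentation_params()) {
  scenes <- if (inherits(stacks, "coloc_dataset")) stacks$scenes else stacks
  if (is.null(names(scenes)) || any(!nzchar(names(scenes))))
    names(scenes) <- sprintf("image%03d", seq_along(scenes))
  if (is.null(masks)) {
    masks <- lapply(scenes, function(s) extract_rois(s$channels$protein, params))
  }
  if (length(masks) != length(scenes))
    stop("need exactly one mask per stack")
  if (is.null(names(masks))) names(masks) <- names(scenes)
  recs <- list(); dropped <- list()
  for (id in names(scenes)) {
    sc <- scenes[[id]]
    if (is.null(sc$channels$comarker))
      stop(sprintf("stack %s lacks the comarker channel", id))
    mk <- masks[[id]]
    for (i in seq_len(nrow(mk$table))) {
      l <- mk$table$label[i]
      r <- tryCatch(
        pearson_roi(sc$channels$protein, sc$channels$comarker, mk, l),
        cellcoloc_constant_roi = function(e) NA_real_)
      row <- data.frame(image_id = id, cell_label = l,
                        genotype_label = sc$genotype_label, comarker = sc$comarker,
                        pearson_r = r, n_pixels = mk$table$area[i],
                        provenance = mk$table$provenance[i], stringsAsFactors = FALSE)
      if (is.na(r)) dropped[[length(dropped) + 1L]] <- row
      else recs[[length(recs) + 1L]] <- row
    }
  }
  if (!length(recs)) {
    warning("no cells measured (empty masks?)")
    out <- data.frame(image_id = character(0), cell_label = integer(0),
                      genotype_label = character(0), comarker = character(0),
                      pearson_r = numeric(0), n_pixels = integer(0),
                      provenance = character(0), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, recs)
    out <- out[order(out$genotype_label, out$image_id, out$cell_label), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  if (length(dropped))
    message(sprintf("measure_dataset: dropped %d cell(s) with undefined correlation",
                    length(dropped)))
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else NULL
  class(out) <- c("coloc_records", class(out))
  out
}

#' Block-shuffle randomization p-value for one ROI
#'
#' Significance of an observed per-cell correlation against a spatial null:
#' the co-marker channel is shuffled in square blocks of side `block` within
#' the ROI bounding box (preserving local autocorrelation), the correlation
#' recomputed over the ROI pixels, and the p-value is the add-one-smoothed
#' fraction of shuffles reaching the observed r:
#' \eqn{p = (1 + \#\{r^* \ge r\}) / (1 + n_{shuffles})}.
#'
#' @inheritParams pearson_roi
#' @param n_shuffles Number of block shuffles (>= 1).
#' @param block Block side in pixels; must fit inside the ROI bounding box.
#' @param seed Integer seed for the shuffle sequence.
#' @return List with `p_value`, `observed_r` and `n_shuffles`.
#' @export
randomization_pvalue <- function(channel_a, channel_b, mask, label,
                                 n_shuffles = 99, block = 8, seed = 1L) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  lab <- if (inherits(mask, "label_mask")) mask$labels else mask
  px <- which(lab == label, arr.ind = TRUE)
  if (!nrow(px)) stop(sprintf("label %s not present in mask", label))
  r0 <- range(px[, 1]); c0 <- range(px[, 2])
  bh <- r0[2] - r0[1] + 1L; bw <- c0[2] - c0[1] + 1L
  if (block > bh || block > bw)
    stop(sprintf("block (%d) larger than ROI bounding box (%dx%d)", block, bh, bw))
  obs <- pearson_roi(channel_a, channel_b, mask, label)
  sub_b <- channel_b[r0[1]:r0[2], c0[1]:c0[2], drop = FALSE]
  roi_local <- cbind(px[, 1] - r0[1] + 1L, px[, 2] - c0[1] + 1L)
  a_vals <- channel_a[lab == label]
  nbr <- ceiling(bh / block); nbc <- ceiling(bw / block)
  with_seed(seed, {
    hits <- 0L
    for (s in seq_len(n_shuffles)) {
      perm <- sample.int(nbr * nbc)
      shuf <- matrix(NA_real_, bh, bw)
      for (t in seq_len(nbr * nbc)) {
        src <- perm[t] - 1L; dst <- t - 1L
        sr <- (src %% nbr) * block; sc <- (src %/% nbr) * block
        dr <- (dst %% nbr) * block; dc <- (dst %/% nbr) * block
        hh <- min(block, bh - sr, bh - dr); ww <- min(block, bw - sc, bw - dc)
        if (hh < 1 || ww < 1) next
        shuf[dr + seq_len(hh), dc + seq_len(ww)] <-
          sub_b[sr + seq_len(hh), sc + seq_len(ww)]
      }
      b_vals <- shuf[roi_local]
      ok <- !is.na(b_vals)
      if (sd(b_vals[ok]) == 0) next
      if (cor(a_vals[ok], b_vals[ok]) >= obs) hits <- hits + 1L
    }
    list(p_value = (1 + hits) / (1 + n_shuffles), observed_r = obs,
         n_shuffles = n_shuffles)
  })
}
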