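#' Segmentation parameters
#'
#' Parameters for [extract_rois()]: circular median pre-filter radius, Huang
#' histogram bin count, particle-size bounds and the policy for cells
#' touching the image border.
#'
#' @param median_radius Radius in pixels of the circular median filter
#'   (default 4; 0 disables filtering).
#' @param min_area,max_area Particle-size bounds in pixels squared; components
#'   outside `[min_area, max_area]` are discarded.
#' @param histogram_bins Bin count for the Huang threshold histogram.
#' @param border_policy `"keep"` (default) or `"drop"` components touching
#'   the image edge. Border contact is recorded per cell either way.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(median_radius = 4, min_area = 800,
                                max_area = Inf, histogram_bins = 256,
                                border_policy = c("keep", "drop")) {
  border_policy <- match.arg(border_policy)
  if (median_radius < 0) stop("median_radius must be >= 0")
  if (min_area < 1) stop("min_area must be >= 1")
  if (max_area <= min_area) stop("max_area must exceed min_area")
  if (histogram_bins < 2) stop("histogram_bins must be >= 2")
  structure(list(median_radius = median_radius, min_area = min_area,
                 max_area = max_area, histogram_bins = as.integer(histogram_bins),
                 border_policy = border_policy),
            class = "segmentation_params")
}

#' Circular-neighbourhood median filter
#'
#' Replaces each pixel by the median of the input pixels within Euclidean
#' distance `radius` (a disc, not a square box); neighbourhoods are truncated
#' at the image border.
#'
#' @param image Numeric matrix.
#' @param radius Neighbourhood radius in pixels (>= 0; 0 returns the input).
#' @return Filtered numeric matrix of the same dimensions.
#' @export
median_filter <- function(image, radius) {
  if (!is.matrix(image) || length(image) == 0) stop("empty image")
  if (radius == 0) return(image)
  median_filter_disc_cpp(image, radius)
}

#' Huang fuzzy-entropy automatic threshold
#'
#' Selects the histogram threshold minimizing the Huang-Wang measure of
#' fuzziness. For a candidate threshold `t`, each grey level `g` receives a
#' membership \eqn{\mu(g) = 1 / (1 + |g - \mu_{class}(t)| / C)} where
#' \eqn{\mu_{class}} is the mean of the below- or above-threshold class and
#' `C` the grey-level range; the fuzziness is the histogram-weighted Shannon
#' entropy \eqn{\sum_g h(g) [-\mu \ln \mu - (1-\mu)\ln(1-\mu)]}. Ties are
#' broken toward the lowest threshold. The image is min-max scaled onto
#' `bins` histogram bins before scanning.
#'
#' @param image Numeric matrix with at least two distinct values.
#' @param bins Number of histogram bins (default 256).
#' @return The threshold as an intensity value (a bin edge on the original
#'   scale): pixels `>= t` are foreground.
#' @export
huang_threshold <- function(image, bins = 256) {
  v <- as.numeric(image)
  lo <- min(v); hi <- max(v)
  if (!is.finite(lo) || hi == lo) stop("constant image: no threshold exists")
  idx <- pmin(floor((v - lo) / (hi - lo) * bins), bins - 1)  # 0 .. bins-1
  h <- tabulate(idx + 1L, nbins = bins)
  occ <- which(h > 0L) - 1L
  C <- max(occ) - min(occ)
  g <- 0:(bins - 1)
  csum_h <- cumsum(h); csum_gh <- cumsum(g * h)
  n <- csum_h[bins]; total_gh <- csum_gh[bins]
  # candidate t: below class = bins 0..t, above = t+1..; both classes non-empty
  cand <- which(csum_h > 0 & csum_h < n)  # 1-based position = t + 1
  best_t <- NA_integer_; best_s <- Inf
  ent <- function(mu) {
    mu <- pmin(pmax(mu, .Machine$double.eps), 1 - .Machine$double.eps)
    -mu * log(mu) - (1 - mu) * log(1 - mu)
  }
  for (pos in cand) {
    t <- pos - 1L
    mu0 <- csum_gh[pos] / csum_h[pos]
    mu1 <- (total_gh - csum_gh[pos]) / (n - csum_h[pos])
    mu <- ifelse(g <= t, 1 / (1 + abs(g - mu0) / C), 1 / (1 + abs(g - mu1) / C))
    s <- sum(h * ent(mu))
    if (s < best_s - 1e-12) { best_s <- s; best_t <- t }
  }
  # foreground = bins above t, i.e. intensity >= lower edge of bin t+1
  lo + (best_t + 1) * (hi - lo) / bins
}

#' Segment cells on the protein channel
#'
#' The particle-analysis pipeline: circular median filter, Huang threshold,
#' binarization (`>=` threshold), 8-connected component labelling, size
#' filtering and (optionally) removal of border-touching components.
#' Surviving components are relabelled consecutively from 1 in raster order
#' of their top-left pixel.
#'
#' @param image Numeric matrix (the protein channel).
#' @param params A [segmentation_params()] object.
#' @return An object of class `label_mask`: list with `labels` (integer
#'   matrix, 0 = background), `areas` (named integer vector) and `table`
#'   (data.frame: label, area, centroid_x, centroid_y, touches_border,
#'   provenance).
#' @export
extract_rois <- function(image, params = segmentation_params()) {
  stopifnot(inherits(params, "segmentation_params"))
  filt <- median_filter(image, params$median_radius)
  thr <- huang_threshold(filt, params$histogram_bins)
  lab <- label_components8_cpp(filt >= thr)
  build_label_mask(lab, params, provenance = "auto")
}

# Apply size/border filters to a raw label matrix and assemble the
# label_mask structure. Relabels survivors from 1 in raster order
# (row-major) of each component's top-left pixel.
build_label_mask <- function(lab, params, provenance) {
  h <- nrow(lab); w <- ncol(lab)
  labs <- sort(unique(lab[lab > 0L]))
  keep <- integer(0); info <- list()
  for (l in labs) {
    px <- which(lab == l)
    area <- length(px)
    rows <- (px - 1L) %% h + 1L
    cols <- (px - 1L) %/% h + 1L
    touches <- any(rows == 1L | rows == h | cols == 1L | cols == w)
    if (area < params$min_area || area > params$max_area) next
    if (params$border_policy == "drop" && touches) next
    keep <- c(keep, l)
    info[[as.character(l)]] <- list(
      area = area, cx = mean(cols), cy = mean(rows), touches = touches,
      # raster order key of the top-left pixel (lowest row, then column)
      key = min((rows - 1) * w + cols))
  }
  ord <- keep[order(vapply(info, `[[`, numeric(1), "key"))]
  out <- matrix(0L, h, w)
  rows <- vector("list", length(ord))
  for (k in seq_along(ord)) {
    l <- ord[k]; i <- info[[as.character(l)]]
    out[lab == l] <- k
    rows[[k]] <- data.frame(label = k, area = i$area, centroid_x = i$cx,
                            centroid_y = i$cy, touches_border = i$touches,
                            provenance = provenance, stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(0), area = integer(0), centroid_x = numeric(0),
               centroid_y = numeric(0), touches_border = logical(0),
               provenance = character(0), stringsAsFactors = FALSE)
  areas <- tab$area
  names(areas) <- tab$label
  structure(list(labels = out, areas = areas, table = tab, params = params),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %dx%d px, %d cells (areas %s px^2)\n",
              nrow(x$labels), ncol(x$labels), nrow(x$table),
              if (nrow(x$table)) paste(range(x$table$area), collapse = "-") else "-"))
  invisible(x)
}

#' Replace an automatic mask with a curated override
#'
#' File-based stand-in for interactive ROI correction: the override labels
#' replace the automatic ones wholesale, the particle-size and border filters
#' are re-applied, and each surviving cell is flagged with provenance
#' `"override"`.
#'
#' @param auto A `label_mask` from [extract_rois()].
#' @param override A `label_mask` or plain integer label matrix of the same
#'   dimensions.
#' @return A `label_mask` built from the override labels.
#' @export
apply_mask_override <- function(auto, override) {
  stopifnot(inherits(auto, "label_mask"))
  ov <- if (inherits(override, "label_mask")) override$labels else override
  if (!all(dim(ov) == dim(auto$labels)))
    stop(sprintf("override dimensions (%dx%d) do not match mask (%dx%d)",
                 nrow(ov), ncol(ov), nrow(auto$labels), ncol(auto$labels)))
  res <- build_label_mask(ov, auto$params, provenance = "override")
  n_in <- length(unique(ov[ov > 0L])); n_out <- nrow(res$table)
  if (n_out < n_in)
    message(sprintf("apply_mask_override: %d override label(s) removed by size/border filters",
                    n_in - n_out))
  res
}
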