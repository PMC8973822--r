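#' Specify a synthetic multi-channel fluorescence scene
#'
#' A scene emulates a field of view of transfected HeLa-like cells imaged in
#' three channels: a tagged membrane protein, a co-marker (plasma membrane,
#' "PM", in the style of a WGA stain, or endoplasmic reticulum, "ER", in the
#' style of a calreticulin stain) and nuclei. Each cell's protein signal is a
#' mixture of a membrane-ring component and a reticular intracellular
#' component; `alpha` is the membrane fraction of the mixture, so
#' `alpha = 1` is a purely plasma-membrane-localized protein and `alpha = 0`
#' a fully ER-retained one. Acquisition constancy is modelled by a single
#' global intensity scale: all scenes generated with the same amplitudes are
#' directly comparable.
#'
#' @param image_height,image_width Scene size in pixels.
#' @param n_cells Number of cells to place (non-overlapping; >= 0).
#' @param cell_radius_range Length-2 range of the ellipse semi-major axis in
#'   pixels. The semi-minor axis is drawn between 0.7 and 1 times the major
#'   axis, bounding eccentricity.
#' @param membrane_ring_width Width of the membrane ring in pixels.
#' @param er_texture_scale Spatial scale (pixels) of the band-pass noise used
#'   for the reticular ER texture.
#' @param alpha Membrane fraction of the protein signal, in `[0, 1]`.
#' @param protein_amplitude,marker_amplitude,background_level Intensities in
#'   arbitrary units (>= 0). Background is added to the protein channel only;
#'   co-marker and nuclei channels render pure templates.
#' @param psf_sigma Gaussian point-spread-function sigma in pixels (0 = none).
#' @param noise List with `poisson_gain` (photon/shot noise scale; 0 = off)
#'   and `gaussian_sd` (additive read noise; 0 = off).
#' @param comarker `"PM"` or `"ER"` — which co-marker the second channel
#'   renders.
#' @param genotype_label Free-text genotype tag carried through the pipeline.
#' @param pixel_size Pixel pitch in micrometres; metadata only, never used in
#'   any computation.
#' @param seed Integer seed; identical spec + seed gives bit-identical pixels.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(image_height = 256, image_width = 256,
                       n_cells = 2, cell_radius_range = c(34, 48),
                       membrane_ring_width = 3, er_texture_scale = 4,
                       alpha = 0.8,
                       protein_amplitude = 150, marker_amplitude = 150,
                       background_level = 10, psf_sigma = 1,
                       noise = list(poisson_gain = 0.25, gaussian_sd = 2),
                       comarker = c("PM", "ER"),
                       genotype_label = "WT", pixel_size = 0.16,
                       seed = 1L) {
  comarker <- match.arg(comarker)
  spec <- structure(list(
    image_height = as.integer(image_height), image_width = as.integer(image_width),
    n_cells = as.integer(n_cells), cell_radius_range = as.numeric(cell_radius_range),
    membrane_ring_width = as.numeric(membrane_ring_width),
    er_texture_scale = as.numeric(er_texture_scale), alpha = as.numeric(alpha),
    protein_amplitude = as.numeric(protein_amplitude),
    marker_amplitude = as.numeric(marker_amplitude),
    background_level = as.numeric(background_level),
    psf_sigma = as.numeric(psf_sigma),
    noise = list(poisson_gain = as.numeric(noise$poisson_gain %||% 0),
                 gaussian_sd = as.numeric(noise$gaussian_sd %||% 0)),
    comarker = comarker, genotype_label = as.character(genotype_label),
    pixel_size = as.numeric(pixel_size), seed = as.integer(seed)
  ), class = "scene_spec")
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  if (spec$image_height < 8 || spec$image_width < 8)
    stop("scene dimensions must be at least 8 x 8 pixels")
  if (is.na(spec$alpha) || spec$alpha < 0 || spec$alpha > 1)
    stop("alpha must lie in [0, 1]")
  if (spec$n_cells < 0) stop("n_cells must be >= 0")
  amps <- c(spec$protein_amplitude, spec$marker_amplitude, spec$background_level)
  if (any(amps < 0)) stop("amplitudes and background must be >= 0")
  if (length(spec$cell_radius_range) != 2 ||
      spec$cell_radius_range[1] > spec$cell_radius_range[2] ||
      spec$cell_radius_range[1] <= 0)
    stop("cell_radius_range must be an increasing positive pair")
  if (spec$noise$poisson_gain < 0 || spec$noise$gaussian_sd < 0)
    stop("noise parameters must be >= 0")
  invisible(spec)
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec> %dx%d px, %d cells, alpha=%.2f, comarker=%s, genotype=%s, seed=%d\n",
              x$image_height, x$image_width, x$n_cells, x$alpha, x$comarker,
              x$genotype_label, x$seed))
  invisible(x)
}

# Rejection-sample non-overlapping ellipse parameters. Overlap is forbidden
# outright: centres must be farther apart than the sum of the semi-major
# axes plus a small gap, and cells must fit inside the frame.
place_cells <- function(spec) {
  n <- spec$n_cells
  cells <- vector("list", n)
  if (n == 0) return(cells)
  gap <- 4
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(500)) {
      a <- runif(1, spec$cell_radius_range[1], spec$cell_radius_range[2])
      b <- a * runif(1, 0.7, 1)
      theta <- runif(1, 0, pi)
      margin <- a + 3
      if (2 * margin >= spec$image_width || 2 * margin >= spec$image_height) next
      cx <- runif(1, margin, spec$image_width - margin)
      cy <- runif(1, margin, spec$image_height - margin)
      ok <- TRUE
      for (j in seq_len(i - 1)) {
        cj <- cells[[j]]
        if (sqrt((cx - cj$cx)^2 + (cy - cj$cy)^2) <= a + cj$a + gap) { ok <- FALSE; break }
      }
      if (ok) { cells[[i]] <- list(cx = cx, cy = cy, a = a, b = b, theta = theta); placed <- TRUE; break }
    }
    if (!placed)
      stop(sprintf("could not place %d non-overlapping cells of radius %g-%g in a %dx%d scene",
                   n, spec$cell_radius_range[1], spec$cell_radius_range[2],
                   spec$image_width, spec$image_height))
  }
  cells
}

# Squared normalized elliptical radius for every pixel: <= 1 is inside the
# ellipse with semi-axes (a, b) rotated by theta about (cx, cy).
# Coordinates: rows = y (height), cols = x (width); pixel centres at integers.
ellipse_field <- function(h, w, cx, cy, a, b, theta) {
  x <- matrix(rep(seq_len(w), each = h), h, w) - cx
  y <- matrix(rep(seq_len(h), times = w), h, w) - cy
  u <- (x * cos(theta) + y * sin(theta)) / a
  v <- (-x * sin(theta) + y * cos(theta)) / b
  u^2 + v^2
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  size <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  size <- min(size, 2L * (min(dim(img)) %/% 2L) - 1L)
  brush <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
  as.matrix(EBImage::filter2(img, brush))
}

# Reticular texture: positive part of band-pass-filtered Gaussian noise,
# rescaled to [0, 1]. Consumes RNG draws, so must be called under the scene
# seed.
er_texture_field <- function(h, w, scale) {
  noise <- matrix(rnorm(h * w), h, w)
  band <- gaussian_blur(noise, scale / 2) - gaussian_blur(noise, scale * 2)
  band <- band / max(sd(band), .Machine$double.eps)
  pmin(pmax(band, 0) / 2, 1)
}

#' Render a synthetic scene with ground truth
#'
#' Renders the three channels of a [scene_spec()]: for each placed cell the
#' protein channel receives `alpha * ring + (1 - alpha) * er` (plus the scene
#' background), the co-marker channel the pure ring (PM) or reticular (ER)
#' template, and the nuclei channel one central blob per cell. All channels
#' are then convolved with a Gaussian PSF and degraded with scaled-Poisson
#' plus additive Gaussian noise. The ring and reticular templates used for
#' the co-marker are the same instances mixed into the protein channel, so
#' in the noise-free, PSF-free limit the per-cell correlation with the
#' matching co-marker is exactly 1 at `alpha` 1 (PM) or 0 (ER).
#'
#' @param spec A [scene_spec()].
#' @return An object of class `coloc_scene`: a list with `channels` (named
#'   list of numeric matrices `protein`, `comarker`, `nuclei`), `comarker`
#'   role, `genotype_label`, `pixel_size`, the originating `spec`, and
#'   `truth` (list: `mask` integer label matrix in placement order,
#'   `per_cell_alpha`, `centers` n x 2 matrix of (x, y)).
#' @export
generate_scene <- function(spec) {
  validate_scene_spec(spec)
  with_seed(spec$seed, {
    h <- spec$image_height; w <- spec$image_width
    cells <- place_cells(spec)
    tex <- er_texture_field(h, w, spec$er_texture_scale)

    ring_all <- matrix(0, h, w); er_all <- matrix(0, h, w)
    nuc_all <- matrix(0, h, w); mask <- matrix(0L, h, w)
    centers <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y")))
    for (i in seq_along(cells)) {
      cl <- cells[[i]]
      outer_f <- ellipse_field(h, w, cl$cx, cl$cy, cl$a, cl$b, cl$theta)
      wdt <- spec$membrane_ring_width
      inner_f <- ellipse_field(h, w, cl$cx, cl$cy, max(cl$a - wdt, 1), max(cl$b - wdt, 1), cl$theta)
      inside <- outer_f <= 1
      ring <- inside & inner_f > 1
      interior <- inner_f <= 1
      nuc <- ellipse_field(h, w, cl$cx, cl$cy, 0.4 * cl$a, 0.4 * cl$b, cl$theta) <= 1
      ring_all[ring] <- 1
      # reticular template: seeded band-pass texture over a constant pedestal,
      # confined to the interior (cell minus membrane ring)
      er_all[interior] <- 0.35 + 0.65 * tex[interior]
      nuc_all[nuc] <- 1
      mask[inside] <- i
      centers <- rbind(centers, c(cl$cx, cl$cy))
    }

    a <- spec$alpha
    protein <- spec$protein_amplitude * (a * ring_all + (1 - a) * er_all) +
      spec$background_level
    marker <- spec$marker_amplitude * (if (spec$comarker == "PM") ring_all else er_all)
    nuclei <- spec$marker_amplitude * nuc_all

    channels <- lapply(list(protein = protein, comarker = marker, nuclei = nuclei),
                       gaussian_blur, sigma = spec$psf_sigma)
    channels <- lapply(channels, apply_noise, noise = spec$noise)

    structure(list(
      channels = channels, comarker = spec$comarker,
      genotype_label = spec$genotype_label, pixel_size = spec$pixel_size,
      spec = spec,
      truth = list(mask = mask,
                   per_cell_alpha = rep(a, length(cells)),
                   centers = centers)
    ), class = "coloc_scene")
  })
}

apply_noise <- function(img, noise) {
  if (noise$poisson_gain > 0)
    img <- matrix(rpois(length(img), pmax(img, 0) / noise$poisson_gain),
                  nrow(img), ncol(img)) * noise$poisson_gain
  if (noise$gaussian_sd > 0)
    img <- img + matrix(rnorm(length(img), sd = noise$gaussian_sd),
                        nrow(img), ncol(img))
  pmax(img, 0)
}

#' @export
print.coloc_scene <- function(x, ...) {
  d <- dim(x$channels$protein)
  cat(sprintf("<coloc_scene> %dx%d px, %d cells, comarker=%s, genotype=%s\n",
              d[1], d[2], max(x$truth$mask), x$comarker, x$genotype_label))
  invisible(x)
}

#' Generate a seeded multi-genotype scene collection
#'
#' Renders `images_per_genotype` scenes for each genotype-level [scene_spec()]
#' with deterministic per-image seeds derived from `(base_seed, genotype index,
#' image index)`, and records a manifest row per scene.
#'
#' @param specs A list of [scene_spec()] objects, one per genotype (their
#'   `seed` fields are overridden by the derived seeds). Genotype labels must
#'   be unique.
#' @param images_per_genotype Number of fields of view per genotype (>= 1).
#' @param base_seed Integer base seed for the whole collection.
#' @return An object of class `coloc_dataset`: list with `scenes` (named list
#'   of `coloc_scene`) and `manifest` (data.frame: scene_id, genotype_label,
#'   comarker, seed).
#' @export
generate_dataset <- function(specs, images_per_genotype, base_seed = 1L) {
  if (inherits(specs, "scene_spec")) specs <- list(specs)
  if (images_per_genotype < 1) stop("images_per_genotype must be >= 1")
  labels <- vapply(specs, function(s) s$genotype_label, character(1))
  if (anyDuplicated(labels))
    stop("duplicate genotype_label in specs: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  scenes <- list(); manifest <- list()
  for (g in seq_along(specs)) {
    for (i in seq_len(images_per_genotype)) {
      seed <- as.integer((as.numeric(base_seed) * 7919 + g * 104729 + i) %% 2147483647)
      sp <- specs[[g]]; sp$seed <- seed
      id <- sprintf("%s_%s_img%02d", sp$genotype_label, sp$comarker, i)
      scenes[[id]] <- generate_scene(sp)
      manifest[[id]] <- data.frame(scene_id = id, genotype_label = sp$genotype_label,
                                   comarker = sp$comarker, seed = seed,
                                   stringsAsFactors = FALSE)
    }
  }
  structure(list(scenes = scenes,
                 manifest = do.call(rbind, c(manifest, make.row.names = FALSE))),
            class = "coloc_dataset")
}

#' @export
print.coloc_dataset <- function(x, ...) {
  cat(sprintf("<coloc_dataset> %d scenes, %d genotypes, comarkers: %s\n",
              nrow(x$manifest), length(unique(x$manifest$genotype_label)),
              paste(unique(x$manifest$comarker), collapse = ", ")))
  invisible(x)
}
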