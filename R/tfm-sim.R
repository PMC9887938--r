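#' Parameters for a synthetic TFM dataset
#'
#' Describes a fluorescent-bead TFM experiment on a linear-elastic substrate:
#' bead-seeded gel images (one relaxed reference, several stressed frames)
#' deformed by the surface displacement of a known traction field. Traction
#' is a sum of Gaussian-profile patches; each patch contributes
#' `peak * exp(-r^2 / (2 sigma^2)) * direction` with `sigma = radius / 2`,
#' so its integrated force is `peak * 2 pi sigma^2` per unit direction.
#'
#' @param image_shape image size in px, c(rows, cols) (default 256 x 256)
#' @param pixel_size um per px (default 0.1)
#' @param bead_density beads per um^2 (default 0.3, a densely seeded gel)
#' @param psf_sigma rendered spot SD in px (default 1.5)
#' @param traction_patches list of patches, each a list with `center` (um,
#'   c(x, y)), `radius` (um), `peak` (Pa), `direction` (unit vector c(x, y));
#'   default: a balanced contractile dipole
#' @param material a [material_params()] (default 1 kPa, nu = 0.5)
#' @param image_noise_sd additive Gaussian image noise SD, as a fraction of
#'   unit spot amplitude (default 0.05)
#' @param seed integer RNG seed
#' @return object of class `tfm_sim_params`
#' @export
tfm_sim_params <- function(image_shape = c(256, 256),
                           pixel_size = 0.1,
                           bead_density = 0.3,
                           psf_sigma = 1.5,
                           traction_patches = NULL,
                           material = material_params(1000, 0.5),
                           image_noise_sd = 0.05,
                           seed = 1L) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 32),
            pixel_size > 0, bead_density > 0, psf_sigma > 0,
            image_noise_sd >= 0, inherits(material, "material_params"))
  extent <- rev(image_shape) * pixel_size  # c(x, y) extent in um
  if (is.null(traction_patches)) {
    # contractile dipole sized to sit comfortably inside the field of view
    cx <- extent[1] / 2; cy <- extent[2] / 2
    off <- extent[1] / 8
    traction_patches <- list(
      list(center = c(cx - off, cy), radius = extent[1] / 8, peak = 200,
           direction = c(1, 0)),
      list(center = c(cx + off, cy), radius = extent[1] / 8, peak = 200,
           direction = c(-1, 0)))
  }
  for (p in traction_patches) {
    stopifnot(length(p$center) == 2, p$radius > 0, is.finite(p$peak),
              length(p$direction) == 2)
    if (any(p$center < 0) || p$center[1] > extent[1] || p$center[2] > extent[2])
      stop("traction patch centre lies outside the image")
  }
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size = pixel_size,
                 bead_density = bead_density,
                 psf_sigma = psf_sigma,
                 traction_patches = traction_patches,
                 material = material,
                 image_noise_sd = image_noise_sd,
                 seed = as.integer(seed)),
            class = "tfm_sim_params")
}

#' Evaluate a Gaussian-patch traction field on a grid
#'
#' @param patches list of patches (see [tfm_sim_params()])
#' @param x,y grid coordinates in um
#' @return a [vector_field()] in Pa
#' @export
patch_traction_field <- function(patches, x, y) {
  TX <- matrix(0, length(y), length(x))
  TY <- matrix(0, length(y), length(x))
  X <- matrix(x, length(y), length(x), byrow = TRUE)
  Y <- matrix(y, length(y), length(x))
  for (p in patches) {
    dir <- p$direction / sqrt(sum(p$direction^2))
    sig <- p$radius / 2
    g <- p$peak * exp(-((X - p$center[1])^2 + (Y - p$center[2])^2) /
                        (2 * sig^2))
    TX <- TX + g * dir[1]
    TY <- TY + g * dir[2]
  }
  vector_field(x, y, TX, TY, unit = "Pa")
}

#' Render a fluorescent-bead image
#'
#' Sum of isotropic Gaussian spots of SD `psf_sigma` (px) at the given bead
#' positions (um), on an image of `shape` px at `pixel_size` um/px.
#' Pixel centre of pixel (row r, col c), 1-based, sits at
#' ((c - 1) px, (r - 1) px) in um.
#'
#' @param beads matrix with columns x, y (um)
#' @param shape c(rows, cols)
#' @param pixel_size um per px
#' @param psf_sigma spot SD in px
#' @param amplitudes per-bead amplitudes (default 1)
#' @return numeric image matrix
#' @export
render_beads <- function(beads, shape, pixel_size, psf_sigma,
                         amplitudes = NULL) {
  img <- matrix(0, shape[1], shape[2])
  if (nrow(beads) == 0) return(img)
  if (is.null(amplitudes)) amplitudes <- rep(1, nrow(beads))
  halfw <- ceiling(4 * psf_sigma)
  for (b in seq_len(nrow(beads))) {
    cx <- beads[b, 1] / pixel_size  # 0-based px coords
    cy <- beads[b, 2] / pixel_size
    c0 <- floor(cx) + 1L; r0 <- floor(cy) + 1L
    rs <- max(1L, r0 - halfw):min(shape[1], r0 + halfw)
    cs <- max(1L, c0 - halfw):min(shape[2], c0 + halfw)
    if (length(rs) == 0 || length(cs) == 0) next
    gx <- exp(-((cs - 1L) - cx)^2 / (2 * psf_sigma^2))
    gy <- exp(-((rs - 1L) - cy)^2 / (2 * psf_sigma^2))
    img[rs, cs] <- img[rs, cs] + amplitudes[b] * outer(gy, gx)
  }
  img
}

#' Simulate a complete TFM dataset with ground truth
#'
#' Builds the ground-truth traction field from the Gaussian patches,
#' computes the substrate surface displacement with [forward_displacement()]
#' at pixel resolution, scatters beads uniformly over the field of view,
#' renders a reference image (relaxed gel) and `n_frames` stressed frames in
#' which each bead is moved by the displacement interpolated at its
#' position, and adds independent Gaussian image noise per frame. If the
#' patch set carries a nonzero net force the mean traction is projected out
#' (with a warning) for the displacement computation only; the stored
#' ground-truth field keeps the patches as specified.
#'
#' @param params a [tfm_sim_params()]
#' @param n_frames number of stressed frames (default 5)
#' @return object of class `tfm_bundle`: list with `reference`, `frames`
#'   (list of matrices), `beads` (um), `bead_disp` (um, per bead),
#'   `truth_traction` (pixel-grid [vector_field()], Pa),
#'   `displacement` (pixel-grid field, um), `roi` (logical matrix, pixel
#'   grid, covering the half plane of the first patch), `params`
#' @export
simulate_tfm_dataset <- function(params, n_frames = 5) {
  stopifnot(inherits(params, "tfm_sim_params"), n_frames >= 1)
  shape <- params$image_shape
  px <- params$pixel_size
  xg <- (seq_len(shape[2]) - 1) * px
  yg <- (seq_len(shape[1]) - 1) * px
  truth <- patch_traction_field(params$traction_patches, xg, yg)
  net <- c(mean(truth$fx), mean(truth$fy))
  scale <- max(mean(abs(truth$fx)), mean(abs(truth$fy)), .Machine$double.eps)
  balanced <- max(abs(net)) <= 1e-8 * scale
  disp <- forward_displacement(truth, params$material, pad = 1,
                               on_unbalanced = if (balanced) "error" else "project")

  area <- prod(rev(shape) * px)
  n_beads <- max(1L, round(params$bead_density * area))
  sim <- with_seed(params$seed, {
    beads <- cbind(x = stats::runif(n_beads, 0, shape[2] * px),
                   y = stats::runif(n_beads, 0, shape[1] * px))
    amps <- stats::runif(n_beads, 0.7, 1.3)
    noise <- lapply(seq_len(n_frames + 1L), function(i)
      if (params$image_noise_sd > 0)
        matrix(stats::rnorm(prod(shape), sd = params$image_noise_sd),
               shape[1], shape[2])
      else matrix(0, shape[1], shape[2]))
    list(beads = beads, amps = amps, noise = noise)
  })
  # displacement at bead positions (bilinear interpolation on the pixel grid)
  bx <- pracma::interp2(xg, yg, disp$fx, sim$beads[, "x"], sim$beads[, "y"],
                        method = "linear")
  by <- pracma::interp2(xg, yg, disp$fy, sim$beads[, "x"], sim$beads[, "y"],
                        method = "linear")
  bx[is.na(bx)] <- 0; by[is.na(by)] <- 0
  reference <- render_beads(sim$beads, shape, px, params$psf_sigma, sim$amps) +
    sim$noise[[1]]
  moved <- cbind(sim$beads[, "x"] + bx, sim$beads[, "y"] + by)
  stressed_clean <- render_beads(moved, shape, px, params$psf_sigma, sim$amps)
  frames <- lapply(seq_len(n_frames), function(i) stressed_clean + sim$noise[[i + 1L]])

  # ROI: half plane containing the first patch (splits a dipole at its
  # midline; covers everything for a single patch at the centre)
  p1 <- params$traction_patches[[1]]
  if (length(params$traction_patches) >= 2) {
    p2 <- params$traction_patches[[2]]
    mid <- (p1$center + p2$center) / 2
    axis <- p1$center - p2$center
  } else {
    mid <- c(0, 0); axis <- c(1, 0)
  }
  X <- matrix(xg, shape[1], shape[2], byrow = TRUE)
  Y <- matrix(yg, shape[1], shape[2])
  roi <- (X - mid[1]) * axis[1] + (Y - mid[2]) * axis[2] >= 0

  structure(list(reference = reference, frames = frames,
                 beads = sim$beads, bead_disp = cbind(ux = bx, uy = by),
                 truth_traction = truth, displacement = disp,
                 roi = roi, n_frames = n_frames, params = params),
            class = "tfm_bundle")
}

#' Ground-truth net force of a patch set
#'
#' Closed form: each Gaussian patch integrates to
#' `peak * 2 pi (radius/2)^2 * direction` (Pa um^2), converted to nN.
#'
#' @param patches list of patches (see [tfm_sim_params()])
#' @return matrix with one row per patch, columns Fx_nN, Fy_nN
#' @export
patch_net_force <- function(patches) {
  t(vapply(patches, function(p) {
    dir <- p$direction / sqrt(sum(p$direction^2))
    f <- p$peak * 2 * pi * (p$radius / 2)^2
    pa_um2_to_nN(f * dir)
  }, numeric(2))) -> m
  colnames(m) <- c("Fx_nN", "Fy_nN")
  m
}

#' Write a simulated TFM dataset to disk
#'
#' Writes the stressed frames as a multi-page float TIFF, the reference
#' frame as a single-page TIFF, the ROI as an 8-bit mask TIFF, and the
#' ground truth (patches, material, per-patch closed-form net force) as a
#' JSON sidecar.
#'
#' @param bundle a `tfm_bundle` from [simulate_tfm_dataset()]
#' @param dir output directory (created if needed)
#' @return named character vector of the written paths, invisibly
#' @export
write_tfm_dataset <- function(bundle, dir) {
  stopifnot(inherits(bundle, "tfm_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(stack = file.path(dir, "stressed.tif"),
             reference = file.path(dir, "reference.tif"),
             mask = file.path(dir, "roi_mask.tif"),
             truth = file.path(dir, "ground_truth.json"))
  norm01 <- function(m) pmin(pmax(m / max(abs(m), 1), 0), 1)
  tiff::writeTIFF(lapply(bundle$frames, norm01), paths["stack"],
                  bits.per.sample = 32L)
  tiff::writeTIFF(norm01(bundle$reference), paths["reference"],
                  bits.per.sample = 32L)
  tiff::writeTIFF((bundle$roi) * 1.0, paths["mask"], bits.per.sample = 8L)
  p <- bundle$params
  jsonlite::write_json(
    list(pixel_size_um = p$pixel_size,
         image_shape = p$image_shape,
         material = unclass(p$material),
         patches = p$traction_patches,
         patch_net_force_nN = patch_net_force(p$traction_patches),
         n_frames = bundle$n_frames,
         seed = p$seed),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
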