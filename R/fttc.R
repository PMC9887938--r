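#' Elastic substrate material parameters
#'
#' Polyacrylamide TFM substrates are characterised by their shear modulus G'
#' (the quantity rheometers report); the Young's modulus used by the
#' half-space Green's function follows as E = 2 G' (1 + nu). The default
#' Poisson ratio 0.5 treats the hydrogel as incompressible.
#'
#' @param shear_modulus shear modulus G' in Pa
#' @param poisson_ratio Poisson's ratio in [0, 0.5]
#' @return object of class `material_params` with fields `shear_modulus`,
#'   `poisson_ratio`, `young_modulus`
#' @export
material_params <- function(shear_modulus, poisson_ratio = 0.5) {
  if (!is.finite(shear_modulus) || shear_modulus <= 0)
    stop("shear_modulus must be > 0")
  if (!is.finite(poisson_ratio) || poisson_ratio < 0 || poisson_ratio > 0.5)
    stop("poisson_ratio must be in [0, 0.5]")
  structure(list(shear_modulus = shear_modulus,
                 poisson_ratio = poisson_ratio,
                 young_modulus = young_from_shear(shear_modulus, poisson_ratio)),
            class = "material_params")
}

#' Substrate stiffness presets
#'
#' The hydrogel families used for the two cell types: fibroblast gels at
#' 0.1, 1 and 10 kPa and neuronal gels at 0.1, 0.3 and 1 kPa (shear
#' modulus G').
#'
#' @param label one of "0.1kPa", "0.3kPa", "1kPa", "10kPa"
#' @param poisson_ratio Poisson's ratio (default 0.5)
#' @return a [material_params()]
#' @export
material_preset <- function(label, poisson_ratio = 0.5) {
  presets <- c("0.1kPa" = 100, "0.3kPa" = 300, "1kPa" = 1000, "10kPa" = 10000)
  if (!label %in% names(presets))
    stop("unknown substrate label: ", label,
         " (known: ", paste(names(presets), collapse = ", "), ")")
  material_params(presets[[label]], poisson_ratio)
}

#' Construct a 2-D vector field on a regular grid
#'
#' Shared container for displacement fields (components in um) and traction
#' fields (components in Pa). Matrices are indexed `[row, col]` with row = y
#' increasing downward and col = x increasing rightward (image convention);
#' `x` and `y` are the physical grid coordinates in um.
#'
#' @param x,y strictly increasing, uniformly spaced grid coordinates (um)
#' @param fx,fy component matrices, dim = c(length(y), length(x))
#' @param unit "um" for displacement, "Pa" for traction
#' @param valid optional logical matrix marking trustworthy nodes
#' @param meta optional list of provenance metadata (material, lambda, ...)
#' @return object of class `vector_field`
#' @export
vector_field <- function(x, y, fx, fy, unit = c("um", "Pa"),
                         valid = NULL, meta = list()) {
  unit <- match.arg(unit)
  stopifnot(is.matrix(fx), is.matrix(fy), all(dim(fx) == dim(fy)),
            nrow(fx) == length(y), ncol(fx) == length(x))
  for (g in list(x, y)) {
    if (length(g) > 1) {
      d <- diff(g)
      if (any(d <= 0) || diff(range(d)) > 1e-9 * mean(d))
        stop("grid coordinates must be strictly increasing and uniform")
    }
  }
  if (is.null(valid)) valid <- matrix(TRUE, nrow(fx), ncol(fx))
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 fx = fx, fy = fy, unit = unit,
                 valid = valid, meta = meta),
            class = "vector_field")
}

#' @export
print.vector_field <- function(x, ...) {
  cat(sprintf("vector_field [%s]: %d x %d grid, spacing %.4g um, max |f| = %.4g\n",
              x$unit, nrow(x$fx), ncol(x$fx), grid_spacing(x),
              max(sqrt(x$fx^2 + x$fy^2))))
  invisible(x)
}

#' Grid spacing of a vector field in um
#' @param field a `vector_field`
#' @return scalar spacing (grids are square by construction in this package)
#' @export
grid_spacing <- function(field) {
  if (length(field$x) > 1) mean(diff(field$x)) else mean(diff(field$y))
}

# angular wavenumbers (rad/um) in FFT order for an n-point grid of spacing d
fft_wavenumbers <- function(n, d) {
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n]
  2 * pi * k / (n * d)
}

# Boussinesq half-space Green's tensor in Fourier space, evaluated on the
# full 2-D FFT grid. Returns the three independent entries (symmetric 2x2
# per mode); the k = 0 entry is set to zero (handled by callers).
#   G(k) = (2 (1+nu) / (E k^3)) [ (1-nu) k^2 + nu ky^2,  -nu kx ky
#                                 -nu kx ky,             (1-nu) k^2 + nu kx^2 ]
green_tensor <- function(nrow_, ncol_, d, material) {
  kx <- fft_wavenumbers(ncol_, d)
  ky <- fft_wavenumbers(nrow_, d)
  KX <- matrix(kx, nrow_, ncol_, byrow = TRUE)
  KY <- matrix(ky, nrow_, ncol_)
  K2 <- KX^2 + KY^2
  K <- sqrt(K2)
  E <- material$young_modulus
  nu <- material$poisson_ratio
  pref <- 2 * (1 + nu) / (E * K^3)
  gxx <- pref * ((1 - nu) * K2 + nu * KY^2)
  gyy <- pref * ((1 - nu) * K2 + nu * KX^2)
  gxy <- pref * (-nu * KX * KY)
  gxx[1, 1] <- 0; gyy[1, 1] <- 0; gxy[1, 1] <- 0
  list(gxx = gxx, gyy = gyy, gxy = gxy, K = K)
}

fft2 <- function(m) stats::fft(m)
ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

#' Surface displacement of an elastic half-space under a traction field
#'
#' Solves the forward Boussinesq problem in Fourier space: each spatial
#' frequency of the displacement is the Green's tensor times the traction
#' mode, u~(k) = G~(k) T~(k). The traction must be balanced (zero mean
#' in each component): the k = 0 mode of the Boussinesq operator is
#' unbounded, so a nonzero net force has no periodic solution.
#'
#' Padding policy: the spectral solve treats the field as periodic. With
#' the default `pad = 1` this is exactly the operator [fttc_traction()]
#' inverts, so forward-then-inverse is an identity at lambda = 0; the
#' periodicity assumption requires the source region to sit comfortably
#' inside the grid (a warning is issued when its support fills more than
#' three quarters of the field). `pad > 1`
#' zero-pads the traction to `pad` times the grid before transforming and
#' crops back, approximating an isolated source on an infinite half-space --
#' useful for forward modelling, but deliberately NOT the operator the
#' inverse assumes (the slowly decaying Boussinesq tail makes the two
#' differ near the boundary).
#'
#' @param traction a `vector_field` in Pa
#' @param material a [material_params()]
#' @param pad integer padding factor >= 1 (default 1, periodic)
#' @param on_unbalanced "error" (default) rejects a nonzero-mean traction;
#'   "project" removes the mean (with a warning) before solving
#' @param balance_tol relative imbalance (|mean T| / mean |T|) below which
#'   the residual mean -- discretization leakage of an intentionally
#'   balanced field -- is zeroed without comment (default 1e-3)
#' @return a `vector_field` of displacements in um on the same grid
#' @export
forward_displacement <- function(traction, material, pad = 1,
                                 on_unbalanced = c("error", "project"),
                                 balance_tol = 1e-3) {
  stopifnot(inherits(traction, "vector_field"), traction$unit == "Pa",
            inherits(material, "material_params"))
  on_unbalanced <- match.arg(on_unbalanced)
  tx <- traction$fx; ty <- traction$fy
  scale <- max(mean(abs(tx)), mean(abs(ty)), .Machine$double.eps)
  if (max(abs(mean(tx)), abs(mean(ty))) > balance_tol * scale) {
    if (on_unbalanced == "error")
      stop("unbalanced traction: nonzero k = 0 mode (net force) unsupported")
    warning("projecting out nonzero mean traction before forward solve")
  }
  tx <- tx - mean(tx); ty <- ty - mean(ty)
  pad <- as.integer(pad)
  stopifnot(pad >= 1)
  if (pad == 1) {
    mag <- sqrt(tx^2 + ty^2)
    hot <- which(mag > 0.01 * max(mag, .Machine$double.eps), arr.ind = TRUE)
    if (nrow(hot) > 0 &&
        (diff(range(hot[, 1])) + 1 > 0.75 * nrow(tx) ||
         diff(range(hot[, 2])) + 1 > 0.75 * ncol(tx)))
      warning("traction support fills most of the grid: periodicity assumption questionable")
  }
  nr <- nrow(tx); nc <- ncol(tx)
  NR <- nr * pad; NC <- nc * pad
  TX <- matrix(0, NR, NC); TY <- matrix(0, NR, NC)
  TX[1:nr, 1:nc] <- tx; TY[1:nr, 1:nc] <- ty
  d <- grid_spacing(traction)
  G <- green_tensor(NR, NC, d, material)
  TXh <- fft2(TX); TYh <- fft2(TY)
  UXh <- G$gxx * TXh + G$gxy * TYh
  UYh <- G$gxy * TXh + G$gyy * TYh
  ux <- Re(ifft2(UXh))[1:nr, 1:nc]
  uy <- Re(ifft2(UYh))[1:nr, 1:nc]
  vector_field(traction$x, traction$y, ux, uy, unit = "um",
               meta = list(material = material, pad = pad))
}

#' Reconstruct traction from a displacement field (regularized FTTC)
#'
#' Fourier-transform traction cytometry: per spatial frequency, the 2x2
#' Boussinesq relation is inverted with Tikhonov regularization,
#' T~ = (G~' G~ + (lambda s)^2 I)^{-1} G~' u~, where s is the largest
#' singular value of the Green's operator over all modes, so that `lambda`
#' is dimensionless (0 = plain inverse, valid on noise-free data). The zero
#' frequency (mean) traction is forced to 0: the net force of a periodic
#' displacement field is unobservable, and cell tractions must balance.
#' Invalid displacement nodes are filled by local interpolation first.
#'
#' @param displacement a `vector_field` in um
#' @param material a [material_params()]
#' @param lambda dimensionless regularization parameter (>= 0), or "auto" /
#'   "lcurve" to select it with [choose_lambda()] (discrepancy principle or
#'   L-curve corner respectively)
#' @return a `vector_field` in Pa; `meta` records material and lambda
#' @export
fttc_traction <- function(displacement, material, lambda = 0) {
  stopifnot(inherits(displacement, "vector_field"),
            displacement$unit == "um",
            inherits(material, "material_params"))
  if (!any(displacement$valid)) stop("all displacement nodes invalid")
  displacement <- fill_invalid(displacement)
  if (is.character(lambda)) {
    lambda <- choose_lambda(displacement, material,
                            method = if (lambda == "lcurve") "lcurve"
                                     else "discrepancy")$lambda
  }
  stopifnot(is.numeric(lambda), lambda >= 0)
  ux <- displacement$fx; uy <- displacement$fy
  d <- grid_spacing(displacement)
  G <- green_tensor(nrow(ux), ncol(ux), d, material)
  UXh <- fft2(ux); UYh <- fft2(uy)
  # largest singular value of G over modes: for the Boussinesq tensor this is
  # (1+nu)... attained at the smallest nonzero k; compute numerically
  smax <- max(eigen_green_max(G))
  l2 <- (lambda * smax)^2
  # per-mode solve of the symmetric 2x2 system (A + l2 I) T = G' u with
  # A = G' G; everything elementwise
  a11 <- G$gxx^2 + G$gxy^2 + l2
  a12 <- G$gxy * (G$gxx + G$gyy)
  a22 <- G$gyy^2 + G$gxy^2 + l2
  b1 <- G$gxx * UXh + G$gxy * UYh
  b2 <- G$gxy * UXh + G$gyy * UYh
  det <- a11 * a22 - a12^2
  det[det == 0] <- Inf  # only the k=0 mode (G = 0, l2 = 0): forces T = 0
  TXh <- (a22 * b1 - a12 * b2) / det
  TYh <- (a11 * b2 - a12 * b1) / det
  TXh[1, 1] <- 0; TYh[1, 1] <- 0
  tx <- Re(ifft2(TXh)); ty <- Re(ifft2(TYh))
  vector_field(displacement$x, displacement$y, tx, ty, unit = "Pa",
               meta = list(material = material, lambda = lambda))
}

# largest eigenvalue of the (symmetric, positive) Green's tensor per mode
eigen_green_max <- function(G) {
  tr <- G$gxx + G$gyy
  disc <- sqrt(pmax((G$gxx - G$gyy)^2 + 4 * G$gxy^2, 0))
  (tr + disc) / 2
}

# replace invalid nodes by the mean of valid neighbours (iterated until
# filled); used before the FFT which needs a complete grid
fill_invalid <- function(field) {
  if (all(field$valid)) return(field)
  fx <- field$fx; fy <- field$fy; ok <- field$valid
  fx[!ok] <- NA; fy[!ok] <- NA
  for (iter in 1:100) {
    if (!anyNA(fx)) break
    bad <- which(is.na(fx), arr.ind = TRUE)
    for (j in seq_len(nrow(bad))) {
      r <- bad[j, 1]; c <- bad[j, 2]
      rs <- max(1, r - 1):min(nrow(fx), r + 1)
      cs <- max(1, c - 1):min(ncol(fx), c + 1)
      nx <- fx[rs, cs]; ny <- fy[rs, cs]
      if (any(!is.na(nx))) {
        fx[r, c] <- mean(nx, na.rm = TRUE)
        fy[r, c] <- mean(ny, na.rm = TRUE)
      }
    }
  }
  field$fx <- fx; field$fy <- fy
  field$valid <- matrix(TRUE, nrow(fx), ncol(fx))
  field
}

#' Estimate the displacement noise level of a field
#'
#' Robust white-noise floor estimate from first differences along both grid
#' directions: for a smooth field plus i.i.d. noise the differences are
#' noise-dominated, and MAD(diff) / (0.6745 sqrt(2)) estimates the per-node
#' noise SD. The two components are pooled.
#'
#' @param displacement a `vector_field` in um
#' @return estimated noise SD per component, um
#' @export
estimate_noise_sd <- function(displacement) {
  est1 <- function(m) {
    d <- c(diff(m), diff(t(m)))
    stats::median(abs(d - stats::median(d))) / (0.6745 * sqrt(2))
  }
  (est1(displacement$fx) + est1(displacement$fy)) / 2
}

#' Select the FTTC regularization parameter
#'
#' Two data-driven heuristics over a log grid of candidate `lambdas`, both
#' based on the residual norm ||G t_lambda - u|| (RMS over nodes, both
#' components pooled) and the solution norm ||t_lambda||:
#'
#' * `"discrepancy"` (default): pick the lambda whose residual is closest
#'   to the noise floor sqrt(2) sigma_n, with sigma_n estimated by
#'   [estimate_noise_sd()] (Morozov's discrepancy principle). The default
#'   grid spans 1e-4 to 1 (19 points).
#' * `"lcurve"`: the corner of the L-curve in log-log coordinates by the
#'   triangle method (maximum perpendicular distance from the chord joining
#'   the curve's endpoints); default grid 1e-4 to 1e-1 (11 points). Kept as
#'   an alternative: for smooth traction fields its corner sits at the
#'   noise-floor elbow and systematically under-regularizes.
#'
#' @param displacement a `vector_field` in um
#' @param material a [material_params()]
#' @param method "discrepancy" (default) or "lcurve"
#' @param lambdas candidate values; default depends on method (see above)
#' @param noise_sd noise SD in um for the discrepancy principle; estimated
#'   from the field when NULL
#' @return list with `lambda` (chosen), `table` (lambda, residual_norm,
#'   solution_norm), `noise_sd` (used, or NA)
#' @export
choose_lambda <- function(displacement, material,
                          method = c("discrepancy", "lcurve"),
                          lambdas = NULL, noise_sd = NULL) {
  method <- match.arg(method)
  if (is.null(lambdas))
    lambdas <- if (method == "discrepancy") 10^seq(-4, 0, length.out = 19)
               else 10^seq(-4, -1, length.out = 11)
  displacement <- fill_invalid(displacement)
  res <- vapply(lambdas, function(l) {
    tr <- fttc_traction(displacement, material, lambda = l)
    # support check is meaningless on reconstructed (noise-bearing) fields
    fwd <- suppressWarnings(forward_displacement(tr, material, pad = 1))
    c(resid = sqrt(mean((fwd$fx - displacement$fx)^2 +
                          (fwd$fy - displacement$fy)^2)),
      sol = sqrt(mean(tr$fx^2 + tr$fy^2)))
  }, c(resid = 0, sol = 0))
  if (method == "discrepancy") {
    if (is.null(noise_sd)) noise_sd <- estimate_noise_sd(displacement)
    target <- sqrt(2) * noise_sd
    pick <- which.min(abs(log(pmax(res["resid", ], .Machine$double.xmin)) -
                            log(max(target, .Machine$double.xmin))))
  } else {
    lr <- log10(pmax(res["resid", ], .Machine$double.xmin))
    ls <- log10(pmax(res["sol", ], .Machine$double.xmin))
    a <- c(lr[1], ls[1]); b <- c(lr[length(lr)], ls[length(ls)])
    ab <- (b - a) / sqrt(sum((b - a)^2))
    dist <- abs((lr - a[1]) * ab[2] - (ls - a[2]) * ab[1])
    pick <- which.max(dist)
    noise_sd <- NA_real_
  }
  list(lambda = lambdas[pick],
       table = data.frame(lambda = lambdas,
                          residual_norm = res["resid", ],
                          solution_norm = res["sol", ]),
       noise_sd = noise_sd)
}

#' Average traction fields over time
#'
#' Componentwise arithmetic mean of per-frame reconstructions on identical
#' grids (12 frames for neurons, 5 for fibroblasts in the default protocol).
#'
#' @param fields list of `vector_field`s with identical grids, units and
#'   provenance
#' @return a `vector_field`; `meta$n_frames` records the count
#' @export
time_average <- function(fields) {
  stopifnot(length(fields) >= 1)
  ref <- fields[[1]]
  for (f in fields) {
    stopifnot(inherits(f, "vector_field"))
    if (!isTRUE(all.equal(f$x, ref$x)) || !isTRUE(all.equal(f$y, ref$y)) ||
        f$unit != ref$unit)
      stop("mismatched grids or units in time_average")
  }
  fx <- Reduce(`+`, lapply(fields, `[[`, "fx")) / length(fields)
  fy <- Reduce(`+`, lapply(fields, `[[`, "fy")) / length(fields)
  meta <- ref$meta
  meta$n_frames <- length(fields)
  vector_field(ref$x, ref$y, fx, fy, unit = ref$unit, meta = meta)
}

#' Region-of-interest mask aligned to a field grid
#'
#' @param mask logical matrix, same dim as the field components
#' @param label optional label (e.g. "growth_cone")
#' @return object of class `roi_mask`
#' @export
roi_mask <- function(mask, label = "roi") {
  stopifnot(is.logical(mask), is.matrix(mask))
  structure(list(mask = mask, label = label), class = "roi_mask")
}

# accept a roi_mask or a bare logical matrix; check shape and non-emptiness
as_roi <- function(roi, field) {
  m <- if (inherits(roi, "roi_mask")) roi$mask else roi
  stopifnot(is.logical(m), is.matrix(m))
  if (!all(dim(m) == dim(field$fx)))
    stop("ROI mask shape does not match field grid")
  if (!any(m)) stop("empty ROI")
  m
}

#' Net force over a region of interest
#'
#' Integrates the traction over the ROI, F = sum(T) * dA with dA the grid
#' cell area, and converts Pa um^2 to nN (1 Pa um^2 = 1e-3 nN). For a
#' neuronal growth cone this net force approximates the tension the growth
#' cone exerts on its axon.
#'
#' @param traction a `vector_field` in Pa
#' @param roi a [roi_mask()] or logical matrix matching the grid
#' @return named numeric: `Fx_nN`, `Fy_nN`, `Fmag_nN`
#' @examples
#' # uniform 100 Pa over 100 um^2 integrates to 10 nN
#' @export
net_force <- function(traction, roi) {
  stopifnot(inherits(traction, "vector_field"), traction$unit == "Pa")
  m <- as_roi(roi, traction)
  dA <- grid_spacing(traction)^2
  fx <- sum(traction$fx[m]) * dA
  fy <- sum(traction$fy[m]) * dA
  c(Fx_nN = pa_um2_to_nN(fx), Fy_nN = pa_um2_to_nN(fy),
    Fmag_nN = pa_um2_to_nN(sqrt(fx^2 + fy^2)))
}

#' Scalar traction summaries over a region of interest
#'
#' Mean and 90th-percentile traction magnitude over the ROI; when the
#' matched displacement field is supplied, also the strain energy
#' U = 1/2 sum(T . u) dA in fJ.
#'
#' @param traction a `vector_field` in Pa
#' @param roi a [roi_mask()] or logical matrix
#' @param displacement optional matching `vector_field` in um
#' @return named numeric: `mean_stress_Pa`, `p90_stress_Pa`, and
#'   `strain_energy_fJ` when displacement is given
#' @export
traction_summary <- function(traction, roi, displacement = NULL) {
  stopifnot(inherits(traction, "vector_field"), traction$unit == "Pa")
  m <- as_roi(roi, traction)
  mag <- sqrt(traction$fx^2 + traction$fy^2)
  out <- c(mean_stress_Pa = mean(mag[m]),
           p90_stress_Pa = as.numeric(stats::quantile(mag[m], 0.9)))
  if (!is.null(displacement)) {
    stopifnot(inherits(displacement, "vector_field"),
              displacement$unit == "um",
              all(dim(displacement$fx) == dim(traction$fx)))
    dA <- grid_spacing(traction)^2
    u <- 0.5 * sum((traction$fx[m] * displacement$fx[m] +
                      traction$fy[m] * displacement$fy[m])) * dA
    out <- c(out, strain_energy_fJ = pa_um3_to_fJ(u))
  }
  out
}
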