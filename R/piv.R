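#' Bead-image displacement by windowed cross-correlation (PIV)
#'
#' Estimates the substrate displacement between a reference bead image
#' (relaxed gel) and a stressed frame. The images are divided into square
#' interrogation windows; in each, the normalized cross-correlation between
#' the demeaned reference and stressed windows is computed by FFT and the
#' correlation peak located with subpixel precision by a three-point
#' Gaussian fit along each axis. Windows whose correlation peak is weak are
#' masked invalid; vectors failing the normalized-median outlier test are
#' replaced by the median of their neighbours.
#'
#' Image convention: matrices `[row, col]`, x = column index increasing
#' rightward, y = row index increasing downward; the sign convention is
#' stressed minus reference (a feature moving right gives positive u).
#'
#' @param reference,stressed numeric image matrices of identical shape
#' @param window interrogation window size in px (power of two, >= 16;
#'   default 32)
#' @param overlap window overlap fraction in [0, 0.9] (default 0.75)
#' @param pixel_size image pixel size in um
#' @param min_peak minimum normalized correlation peak below which a window
#'   is marked invalid (default 0.3)
#' @param median_threshold normalized-median test threshold (default 2)
#' @return a [vector_field()] of displacements in um; `valid` marks windows
#'   with a usable correlation peak, `meta` records window/overlap and the
#'   displacement in px (`ux_px`, `uy_px`)
#' @export
piv_displacement <- function(reference, stressed, window = 32,
                             overlap = 0.75, pixel_size = 0.1,
                             min_peak = 0.3, median_threshold = 2) {
  stopifnot(is.matrix(reference), is.matrix(stressed))
  if (!all(dim(reference) == dim(stressed)))
    stop("reference and stressed images differ in shape")
  window <- as.integer(window)
  if (window < 16 || bitwAnd(window, window - 1L) != 0L)
    stop("window must be a power of two >= 16")
  stopifnot(overlap >= 0, overlap <= 0.9, pixel_size > 0)
  step <- max(1L, as.integer(round(window * (1 - overlap))))
  nr <- nrow(reference); nc <- ncol(reference)
  if (nr < window || nc < window) stop("image smaller than one window")
  row0 <- seq(1L, nr - window + 1L, by = step)
  col0 <- seq(1L, nc - window + 1L, by = step)
  ny <- length(row0); nx <- length(col0)
  ux <- matrix(NA_real_, ny, nx); uy <- matrix(NA_real_, ny, nx)
  valid <- matrix(FALSE, ny, nx)
  half <- window %/% 2L
  warned <- FALSE
  # circular cross-correlation R(s) = sum_x A(x) B(x + s) and its integer
  # peak as a signed lag; returns NULL for featureless windows / weak peaks
  xcorr_peak <- function(A, B) {
    A <- A - mean(A); B <- B - mean(B)
    na <- sqrt(sum(A^2)); nb <- sqrt(sum(B^2))
    if (na == 0 || nb == 0) return(NULL)
    R <- Re(stats::fft(Conj(stats::fft(A)) * stats::fft(B),
                       inverse = TRUE)) / length(A)
    pk <- which(R == max(R), arr.ind = TRUE)[1, ]
    if (max(R) / (na * nb) < min_peak) return(NULL)
    dy <- pk[1] - 1L; if (dy > half) dy <- dy - window
    dx <- pk[2] - 1L; if (dx > half) dx <- dx - window
    list(R = R, pk = pk, dy = dy, dx = dx)
  }
  for (i in seq_len(ny)) {
    rs <- row0[i]:(row0[i] + window - 1L)
    for (j in seq_len(nx)) {
      cs <- col0[j]:(col0[j] + window - 1L)
      A <- reference[rs, cs]
      p1 <- xcorr_peak(A, stressed[rs, cs])
      if (is.null(p1)) next
      if (abs(p1$dx) >= half || abs(p1$dy) >= half) next  # wrapped: unusable
      # second pass with the stressed window offset by the integer shift:
      # recentres the peak near zero lag, removing the window-truncation
      # bias of the one-pass subpixel estimate
      dy0 <- 0L; dx0 <- 0L; p <- p1
      if (p1$dy != 0L || p1$dx != 0L) {
        rs2 <- rs + p1$dy; cs2 <- cs + p1$dx   # offset the stressed window
        rs3 <- rs - p1$dy; cs3 <- cs - p1$dx   # or the reference window
        p2 <- NULL
        if (rs2[1] >= 1L && rs2[window] <= nr &&
            cs2[1] >= 1L && cs2[window] <= nc) {
          p2 <- xcorr_peak(A, stressed[rs2, cs2])
        } else if (rs3[1] >= 1L && rs3[window] <= nr &&
                   cs3[1] >= 1L && cs3[window] <= nc) {
          p2 <- xcorr_peak(reference[rs3, cs3], stressed[rs, cs])
        }
        if (!is.null(p2) && abs(p2$dx) < half && abs(p2$dy) < half) {
          dy0 <- p1$dy; dx0 <- p1$dx; p <- p2
        }
      }
      sub <- gauss3_subpixel(p$R, p$pk[1], p$pk[2], window)
      ux[i, j] <- dx0 + p$dx + sub[2]
      uy[i, j] <- dy0 + p$dy + sub[1]
      valid[i, j] <- TRUE
      if (!warned && max(abs(ux[i, j]), abs(uy[i, j])) > window / 4) {
        warning("displacement exceeds 1/4 of the interrogation window")
        warned <- TRUE
      }
    }
  }
  flt <- median_filter_vectors(ux, uy, valid, median_threshold)
  xs <- (col0 + half - 1) * pixel_size  # window centres, 0-based px -> um
  ys <- (row0 + half - 1) * pixel_size
  vector_field(xs, ys, flt$ux * pixel_size, flt$uy * pixel_size,
               unit = "um", valid = valid,
               meta = list(window = window, overlap = overlap,
                           pixel_size = pixel_size,
                           ux_px = flt$ux, uy_px = flt$uy,
                           n_outliers = flt$n_outliers))
}

# 3-point Gaussian subpixel interpolation around the (circular) peak of R;
# falls back to a parabolic fit when neighbours are non-positive
gauss3_subpixel <- function(R, pr, pc, n) {
  wrap <- function(i) ((i - 1L) %% n) + 1L
  off <- function(c0, cm, cp) {
    if (cm > 0 && cp > 0 && c0 > 0 &&
        (log(cm) + log(cp) - 2 * log(c0)) < 0) {
      (log(cm) - log(cp)) / (2 * (log(cm) + log(cp) - 2 * log(c0)))
    } else {
      den <- cm + cp - 2 * c0
      if (den >= 0) 0 else (cm - cp) / (2 * den)
    }
  }
  c0 <- R[pr, pc]
  dr <- off(c0, R[wrap(pr - 1L), pc], R[wrap(pr + 1L), pc])
  dc <- off(c0, R[pr, wrap(pc - 1L)], R[pr, wrap(pc + 1L)])
  c(max(-1, min(1, dr)), max(-1, min(1, dc)))
}

# normalized median test (universal outlier detection): residual of each
# vector against the median of its 8-neighbourhood, normalized by the median
# absolute neighbour fluctuation; outliers replaced by the neighbour median
median_filter_vectors <- function(ux, uy, valid, threshold, eps = 0.1) {
  ny <- nrow(ux); nx <- ncol(ux)
  n_out <- 0L
  ux2 <- ux; uy2 <- uy
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    if (!valid[i, j]) next
    rs <- max(1, i - 1):min(ny, i + 1)
    cs <- max(1, j - 1):min(nx, j + 1)
    nbx <- ux[rs, cs]; nby <- uy[rs, cs]
    nbv <- valid[rs, cs]
    nbv[rs == i & rep(cs == j, each = length(rs))] <- FALSE  # exclude self
    selm <- nbv & !is.na(nbx)
    if (sum(selm) < 3) next
    mx <- stats::median(nbx[selm]); my <- stats::median(nby[selm])
    rmx <- stats::median(abs(nbx[selm] - mx))
    rmy <- stats::median(abs(nby[selm] - my))
    r <- sqrt((ux[i, j] - mx)^2 + (uy[i, j] - my)^2) /
      (sqrt(rmx^2 + rmy^2) + eps)
    if (r > threshold) {
      ux2[i, j] <- mx; uy2[i, j] <- my
      n_out <- n_out + 1L
    }
  }
  # invalid windows: fill from neighbour medians so the grid is complete
  ux2[!valid] <- NA; uy2[!valid] <- NA
  list(ux = ux2, uy = uy2, n_outliers = n_out)
}

#' Subtract rigid drift estimated from cell-free regions
#'
#' Estimates stage/reference-frame drift as the median displacement over the
#' complement of the cell mask and subtracts it from the whole field.
#'
#' @param displacement a `vector_field` in um
#' @param cell_mask logical matrix on the field grid, TRUE inside the cell
#' @return drift-corrected `vector_field`; `meta$drift_um` records the
#'   subtracted vector
#' @export
correct_drift <- function(displacement, cell_mask) {
  stopifnot(inherits(displacement, "vector_field"))
  m <- !cell_mask & displacement$valid
  if (!any(m)) stop("no valid cell-free nodes to estimate drift from")
  drift <- c(stats::median(displacement$fx[m], na.rm = TRUE),
             stats::median(displacement$fy[m], na.rm = TRUE))
  displacement$fx <- displacement$fx - drift[1]
  displacement$fy <- displacement$fy - drift[2]
  displacement$meta$drift_um <- drift
  displacement
}
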