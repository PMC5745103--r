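## Rigid-body inter-channel registration (dominated by the axial offsets
## caused by sample-arm length mismatch), B-scan flattening to the ILM,
## and volume fusion with surface re-warping.

#' Rigid transform
#'
#' @param dz Axial shift in pixels (positive = towards larger row index).
#' @param dx Lateral shift in pixels.
#' @param theta Rotation in degrees about the image centre (|theta| <= 5).
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(dz = 0, dx = 0, theta = 0) {
  if (abs(theta) > 5) stop("rigid registration is fine alignment: |theta| <= 5 deg")
  structure(list(dz = dz, dx = dx, theta = theta), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: dz %.3f px, dx %.3f px, theta %.3f deg\n",
              x$dz, x$dx, x$theta))
  invisible(x)
}

## Bilinear sampling of img at fractional (rows, cols); outside -> fill.
#' @keywords internal
bilinear_sample <- function(img, rows, cols, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  val <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    out <- rep(fill, length(r))
    out[ok] <- img[cbind(r[ok], c[ok])]
    out
  }
  (1 - fr) * (1 - fc) * val(r0, c0) +
    (1 - fr) * fc * val(r0, c0 + 1) +
    fr * (1 - fc) * val(r0 + 1, c0) +
    fr * fc * val(r0 + 1, c0 + 1)
}

#' Apply a rigid transform to a B-scan
#'
#' Rotates about the image centre by `theta`, then translates by
#' `(dz, dx)`. Resampling is bilinear (inverse mapping); out-of-field
#' pixels are filled with the background value 0 so downstream windows
#' near edges are visibly empty rather than biased.
#'
#' @param image Numeric matrix.
#' @param transform A [rigid_transform()].
#' @param fill Fill value for out-of-field pixels.
#' @return Transformed matrix, same dimensions.
#' @export
apply_rigid <- function(image, transform, fill = 0) {
  stopifnot(inherits(transform, "rigid_transform"))
  nr <- nrow(image); nc <- ncol(image)
  if (transform$theta == 0 &&
      transform$dz == round(transform$dz) && transform$dx == round(transform$dx)) {
    out <- shift_rows(image, transform$dz, fill)
    dx <- as.integer(round(transform$dx))
    if (dx != 0) out <- t(apply(out, 1, shift_vec, dz = dx, fill = fill))
    return(out)
  }
  th <- transform$theta * pi / 180
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  g <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  ## inverse map: undo translation, then rotate by -theta about centre
  yr <- g$r - transform$dz - cr
  yc <- g$c - transform$dx - cc
  sr <- cos(th) * yr - sin(th) * yc + cr
  sc <- sin(th) * yr + cos(th) * yc + cc
  matrix(bilinear_sample(image, sr, sc, fill), nr, nc)
}

## Best integer translation of mov against ref by FFT cross-correlation,
## restricted to |dz| <= dz_max, |dx| <= dx_max; returns list(dz, dx,
## score) with quadratic sub-pixel refinement.
#' @keywords internal
xcorr_translation <- function(ref, mov, dz_max = 100L, dx_max = 20L) {
  nr <- nrow(ref); nc <- ncol(ref)
  r0 <- ref - mean(ref); m0 <- mov - mean(mov)
  C <- Re(stats::fft(stats::fft(r0) * Conj(stats::fft(m0)), inverse = TRUE)) / length(r0)
  ## C[(u mod nr)+1, (v mod nc)+1] = sum ref(r,c) mov(r-u, c-v)
  dz_max <- min(dz_max, nr %/% 2 - 1L); dx_max <- min(dx_max, nc %/% 2 - 1L)
  us <- seq.int(-dz_max, dz_max); vs <- seq.int(-dx_max, dx_max)
  sub <- C[(us %% nr) + 1L, (vs %% nc) + 1L, drop = FALSE]
  i <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  du <- us[i[1]]; dv <- vs[i[2]]
  off_u <- subpixel_offset(sub[, i[2]], i[1])
  off_v <- subpixel_offset(sub[i[1], ], i[2])
  list(dz = du + off_u, dx = dv + off_v, score = sub[i[1], i[2]])
}

#' Estimate the rigid transform aligning one B-scan to another
#'
#' Exhaustive FFT cross-correlation over translation, repeated over a
#' small grid of rotation angles with quadratic refinement of the best
#' angle. Returns the transform that, applied to `moving` with
#' [apply_rigid()], best aligns it to `reference` — for an image shifted
#' axially by +7 px the estimate is dz = -7.
#'
#' @param reference,moving Same-size linear-intensity matrices.
#' @param dz_max,dx_max Translation search ranges (pixels).
#' @param theta_max Angular search half-range, degrees (0 disables the
#'   rotation search).
#' @param theta_step Angular search step, degrees.
#' @return A [rigid_transform()].
#' @export
estimate_rigid <- function(reference, moving, dz_max = 100L, dx_max = 20L,
                           theta_max = 2, theta_step = 1) {
  stopifnot(identical(dim(reference), dim(moving)))
  if (stats::sd(reference) == 0 || stats::sd(moving) == 0)
    stop("no-content error: flat image cannot be registered")
  thetas <- if (theta_max > 0) seq(-theta_max, theta_max, by = theta_step) else 0
  if (!0 %in% thetas) thetas <- sort(c(thetas, 0))
  fits <- lapply(thetas, function(th) {
    m <- if (th == 0) moving else
      apply_rigid(moving, rigid_transform(0, 0, th))
    xcorr_translation(reference, m, dz_max, dx_max)
  })
  scores <- vapply(fits, `[[`, numeric(1), "score")
  i <- which.max(scores)
  th <- thetas[i]
  if (length(thetas) > 2 && i > 1 && i < length(thetas))
    th <- th + theta_step * subpixel_offset(scores, i)
  rigid_transform(dz = fits[[i]]$dz, dx = fits[[i]]$dx, theta = th)
}

#' Register channels 2 and 3 to channel 1
#'
#' Estimates one rigid transform per moving channel on the central
#' B-scan and applies it to every B-scan of that channel. Image
#' dimensions never change.
#'
#' @param stack An [mdoct_stack()].
#' @param ... Passed to [estimate_rigid()].
#' @return The registered stack, with attribute-free element
#'   `transforms`: list of the two estimated [rigid_transform()]s
#'   (channels 2 and 3).
#' @export
register_triplet <- function(stack, ...) {
  stopifnot(inherits(stack, "mdoct_stack"))
  nb <- dim(stack$channels[[1]])[3]
  mid <- (nb + 1L) %/% 2L
  ref <- get_bscan(stack, 1L, mid)
  transforms <- vector("list", 2)
  out <- stack
  for (c in 2:3) {
    tf <- estimate_rigid(ref, get_bscan(stack, c, mid), ...)
    transforms[[c - 1]] <- tf
    for (j in seq_len(nb))
      out$channels[[c]][, , j] <- apply_rigid(get_bscan(stack, c, j), tf)
  }
  out$registered <- TRUE
  out$transforms <- transforms
  out
}

#' Flatten a B-scan to its ILM
#'
#' Shifts each A-scan axially (integer shifts) so the ILM comes to lie
#' on a common row — the median ILM row.
#'
#' @param bscan Linear-intensity matrix.
#' @param ilm Per-A-scan ILM rows.
#' @return List with `image`, `shifts` (applied per column; negate to
#'   invert) and `target_row`.
#' @export
flatten_bscan <- function(bscan, ilm) {
  stopifnot(ncol(bscan) == length(ilm))
  if (any(ilm < 1 | ilm > nrow(bscan))) stop("boundary out of image range")
  target <- round(stats::median(ilm))
  shifts <- as.integer(target - round(ilm))
  out <- bscan
  for (j in which(shifts != 0L)) out[, j] <- shift_vec(bscan[, j], shifts[j])
  list(image = out, shifts = shifts, target_row = target)
}

#' Undo a flattening
#' @param bscan Flattened matrix.
#' @param shifts Shifts returned by [flatten_bscan()].
#' @return Unflattened matrix.
#' @export
unflatten_bscan <- function(bscan, shifts) {
  out <- bscan
  for (j in which(shifts != 0L)) out[, j] <- shift_vec(bscan[, j], -shifts[j])
  out
}

#' Fuse three registered volumes on a common flattened surface
#'
#' Flattens every B-scan of each channel to that channel's own ILM,
#' fuses per voxel (mean or max), then re-warps the fused volume with
#' channel 1's shifts so the surface regains channel 1's (realistic)
#' shape.
#'
#' @param stack A registered [mdoct_stack()].
#' @param ilm_maps List of three `ascans x bscans` ILM matrices (one per
#'   channel), e.g. from [segment_stack()] per channel.
#' @param mode `"mean"` or `"max"`.
#' @return List with `volume` (array `depth x ascans x bscans`) and
#'   `ilm` (channel 1's ILM map, the fused surface).
#' @export
fuse_volume <- function(stack, ilm_maps, mode = c("mean", "max")) {
  mode <- match.arg(mode)
  stopifnot(inherits(stack, "mdoct_stack"), length(ilm_maps) == 3)
  if (!stack$registered) stop("stack must be registered before fusion")
  d <- dim(stack$channels[[1]])
  for (m in ilm_maps) if (!all(dim(m) == d[2:3])) stop("dimension mismatch")
  vol <- array(0, d)
  for (j in seq_len(d[3])) {
    flats <- vector("list", 3)
    sh1 <- NULL
    for (c in 1:3) {
      f <- flatten_bscan(get_bscan(stack, c, j), ilm_maps[[c]][, j])
      flats[[c]] <- f$image
      if (c == 1) sh1 <- f$shifts
    }
    fused <- if (mode == "mean") (flats[[1]] + flats[[2]] + flats[[3]]) / 3
             else pmax(flats[[1]], flats[[2]], flats[[3]])
    vol[, , j] <- unflatten_bscan(fused, sh1)
  }
  list(volume = vol, ilm = ilm_maps[[1]])
}
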