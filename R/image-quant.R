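#' Simulate a bimodal intensity image
#'
#' A 2D image with a recorded true foreground mask: foreground pixels at
#' `fg_mean`, background at `bg_mean`, plus optional Gaussian noise.
#' With `noise_sd = 0` the image has exactly two distinct values.
#'
#' @param shape integer length-2 (rows, cols).
#' @param foreground_fraction fraction of pixels in the foreground.
#' @param fg_mean,bg_mean class means; `fg_mean` must exceed `bg_mean`.
#' @param noise_sd additive Gaussian noise sd.
#' @param seed RNG seed.
#' @return list with `image` (matrix) and `mask` (logical matrix, TRUE =
#'   foreground).
#' @export
simulateImage <- function(shape = c(64L, 64L), foreground_fraction = 0.25,
                          fg_mean = 200, bg_mean = 10, noise_sd = 5,
                          seed = 1L) {
    if (fg_mean <= bg_mean) stopf("fg_mean must exceed bg_mean")
    if (foreground_fraction < 0 || foreground_fraction > 1)
        stopf("foreground_fraction must lie in [0, 1]")
    withSeed(seed, {
        n <- prod(shape)
        n_fg <- round(foreground_fraction * n)
        mask <- matrix(FALSE, shape[1], shape[2])
        mask[sample(n, n_fg)] <- TRUE
        img <- matrix(bg_mean, shape[1], shape[2])
        img[mask] <- fg_mean
        if (noise_sd > 0) img <- img + stats::rnorm(n, 0, noise_sd)
        list(image = img, mask = mask)
    })
}

# Yen's entropic-correlation criterion on a normalized histogram p over
# bins 1..B, evaluated at split t (bins <= t = background):
#   crit(t) = 2 log(P1 (1 - P1)) - log(sum_{i<=t} p_i^2) - log(sum_{i>t} p_i^2)
# Splits with P1 in {0, 1} carry no information and are excluded (-Inf).
.yenCriterion <- function(p) {
    P1 <- cumsum(p)
    P1sq <- cumsum(p^2)
    P2sq <- rev(cumsum(rev(p^2)))     # sum over i >= t
    B <- length(p)
    t <- seq_len(B - 1L)
    crit <- 2 * log(P1[t] * (1 - P1[t])) - log(P1sq[t]) - log(P2sq[t + 1L])
    crit[P1[t] <= 0 | P1[t] >= 1 | P1sq[t] <= 0 | P2sq[t + 1L] <= 0] <- -Inf
    crit
}

#' Yen automatic threshold of an intensity image
#'
#' Builds an `n_bins` histogram over the image's intensity range and
#' returns the threshold maximizing Yen's entropic correlation criterion
#' over all split points. The threshold is the centre of the last
#' background bin, so the split convention is: pixels strictly above the
#' threshold are foreground. Ties are broken toward the lower threshold.
#'
#' @param image numeric matrix (or array) of intensities with at least
#'   two distinct values.
#' @param n_bins histogram bins (default 256).
#' @return the threshold value (numeric scalar).
#' @export
yenThreshold <- function(image, n_bins = 256L) {
    v <- as.vector(image)
    if (any(!is.finite(v))) stopf("image contains non-finite values")
    rng <- range(v)
    if (diff(rng) == 0)
        stopf("degenerate image: constant intensity, no threshold exists")
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    h <- tabulate(pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE),
                            1L), n_bins), nbins = n_bins)
    p <- h / sum(h)
    crit <- .yenCriterion(p)
    t <- which.max(crit)               # first occurrence = lower threshold
    centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
    centers[t]
}

#' Fraction of pixels above a threshold
#'
#' The positive-area statistic for thresholded micrographs: the fraction
#' of pixels strictly above the threshold, per field, and the mean over
#' fields. With a pixel size, the absolute positive area is also returned.
#'
#' @param image numeric matrix, or a list of matrices (one per
#'   high-power field).
#' @param threshold intensity threshold.
#' @param pixel_size optional pixel area (e.g. um^2) for absolute area.
#' @return for a single image, a list with `fraction` (and `area` if
#'   `pixel_size` given); for a list of fields, additionally `per_field`
#'   and `mean_fraction`.
#' @export
positiveFraction <- function(image, threshold, pixel_size = NULL) {
    one <- function(img) mean(as.vector(img) > threshold)
    if (is.list(image)) {
        per <- vapply(image, one, numeric(1))
        out <- list(per_field = per, mean_fraction = mean(per),
                    fraction = mean(per))
        if (!is.null(pixel_size))
            out$area <- vapply(image, function(i)
                sum(as.vector(i) > threshold) * pixel_size, numeric(1))
        return(out)
    }
    out <- list(fraction = one(image))
    if (!is.null(pixel_size))
        out$area <- sum(as.vector(image) > threshold) * pixel_size
    out
}

#' Simulate a CT volume in Hounsfield units
#'
#' A 3D grid with a mineralized inclusion at `bone_hu` inside a soft
#' tissue background at `tissue_hu`, plus Gaussian noise.
#'
#' @param shape integer length-3 dims.
#' @param bone_fraction fraction of voxels in the inclusion.
#' @param bone_hu,tissue_hu class means (HU).
#' @param noise_sd additive noise sd (HU).
#' @param seed RNG seed.
#' @return list with `volume` (3D array) and `mask` (true inclusion).
#' @export
simulateVolume <- function(shape = c(32L, 32L, 32L), bone_fraction = 0.1,
                           bone_hu = 2000, tissue_hu = 50, noise_sd = 100,
                           seed = 1L) {
    withSeed(seed, {
        n <- prod(shape)
        mask <- array(FALSE, shape)
        mask[sample(n, round(bone_fraction * n))] <- TRUE
        vol <- array(tissue_hu, shape)
        vol[mask] <- bone_hu
        if (noise_sd > 0) vol <- vol + stats::rnorm(n, 0, noise_sd)
        list(volume = vol, mask = mask)
    })
}

#' Mineralized-tissue volume above a Hounsfield threshold
#'
#' Counts voxels at or above the HU threshold (the threshold is the
#' minimum included density) times the voxel volume; optionally normalized
#' by mean cortical thickness.
#'
#' @param volume 3D numeric array of HU values.
#' @param hu_threshold inclusion threshold (e.g. 800, 1250 or 1800).
#' @param voxel_volume voxel volume in mm^3.
#' @param cortical_thickness_mm optional mean cortical thickness (mm).
#' @return list with `volume_mm3` and, when thickness is given,
#'   `normalized_mm3_per_mm`.
#' @export
ctVolume <- function(volume, hu_threshold, voxel_volume,
                     cortical_thickness_mm = NULL) {
    if (voxel_volume <= 0) stopf("voxel volume must be positive")
    v <- sum(volume >= hu_threshold) * voxel_volume
    out <- list(volume_mm3 = v)
    if (!is.null(cortical_thickness_mm)) {
        if (cortical_thickness_mm <= 0)
            stopf("cortical thickness must be positive")
        out$normalized_mm3_per_mm <- v / cortical_thickness_mm
    }
    out
}
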