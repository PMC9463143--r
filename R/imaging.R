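#' Normalized 2-D Gaussian convolution kernel
#'
#' Kernel of size `2*ceiling(3*sigma)+1`, normalized to unit sum.
#' @param sigma Gaussian standard deviation (pixels).
#' @return Square numeric matrix.
#' @export
gaussian_kernel <- function(sigma) {
  stopifnot(sigma > 0)
  r <- ceiling(3 * sigma)
  x <- (-r):r
  k <- exp(-outer(x^2, x^2, "+") / (2 * sigma^2))
  k / sum(k)
}

as_slices <- function(stack) {
  if (is.matrix(stack)) list(stack)
  else if (length(dim(stack)) == 3L)
    lapply(seq_len(dim(stack)[3]), function(z) stack[, , z])
  else stop("image stack must be a 2-D matrix or 3-D array")
}

from_slices <- function(slices, stack) {
  if (is.matrix(stack)) slices[[1]]
  else array(unlist(slices), dim = dim(stack))
}

#' Difference-of-Gaussians band-pass filter
#'
#' Per 2-D slice: Gaussian blur at `sigma_small` minus Gaussian blur at
#' `sigma_large` (circular boundary), giving a positive response at
#' punctate structures and rejecting constant background. Linear in the
#' input.
#'
#' @param stack 2-D matrix or 3-D array (y, x, z).
#' @param sigma_small,sigma_large Gaussian sigmas in pixels; must satisfy
#'   `0 < sigma_small < sigma_large`. Defaults 1 and 4.
#' @return Filtered stack of the same shape.
#' @export
dog_filter <- function(stack, sigma_small = 1, sigma_large = 4) {
  if (!(sigma_small > 0 && sigma_large > 0 && sigma_small < sigma_large))
    stop("require 0 < sigma_small < sigma_large")
  ks <- gaussian_kernel(sigma_small)
  kl <- gaussian_kernel(sigma_large)
  sl <- lapply(as_slices(stack), function(m) {
    EBImage::filter2(m, ks, boundary = "circular") -
      EBImage::filter2(m, kl, boundary = "circular")
  })
  from_slices(sl, stack)
}

#' Uniform threshold mask
#'
#' Voxels strictly above `threshold` are foreground. The threshold used is
#' recorded on the result so quantifications stay traceable.
#'
#' @param stack 2-D matrix or 3-D array.
#' @param threshold Finite numeric threshold.
#' @return Logical array of the same shape with attribute `threshold`.
#' @export
threshold_mask <- function(stack, threshold) {
  stopifnot(is.finite(threshold))
  m <- stack > threshold
  attr(m, "threshold") <- threshold
  m
}

#' Colocalization fraction of two thresholded channels
#'
#' The number of thresholded voxels of the query channel that overlap
#' thresholded voxels of the reference channel, divided by all thresholded
#' query voxels, computed over the full stack. Undefined (NA) when the
#' query mask is empty.
#'
#' @param mask_query,mask_reference Logical arrays of identical shape.
#' @return Fraction in \[0, 1\], or `NA_real_` for an empty query mask.
#' @export
colocalization_fraction <- function(mask_query, mask_reference) {
  if (!identical(dim(mask_query), dim(mask_reference)))
    stop("masks must have identical shape")
  nq <- sum(mask_query)
  if (nq == 0L) {
    warning("empty query mask: colocalization undefined")
    return(NA_real_)
  }
  sum(mask_query & mask_reference) / nq
}

#' Label connected components (8-connectivity) in a binary 2-D mask
#'
#' Two-pass labelling with diagonal adjacency, so touching puncta merge
#' into one object.
#'
#' @param mask Logical or 0/1 matrix.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components_8 <- function(mask) {
  m <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  lab <- matrix(0L, nrow(m), ncol(m))
  nxt <- 0L
  nr <- nrow(m); nc <- ncol(m)
  idx <- which(m)
  for (p in idx) {
    if (lab[p] != 0L) next
    nxt <- nxt + 1L
    queue <- p
    lab[p] <- nxt
    while (length(queue)) {
      q <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((q - 1L) %% nr) + 1L
      cc <- ((q - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; c2 <- cc + dc
        if (rr < 1L || rr > nr || c2 < 1L || c2 > nc) next
        q2 <- (c2 - 1L) * nr + rr
        if (m[q2] && lab[q2] == 0L) {
          lab[q2] <- nxt
          queue <- c(queue, q2)
        }
      }
    }
  }
  lab
}

#' Puncta counts, density, sizes and intensities in a region of interest
#'
#' Connected components (2-D, 8-connectivity, per slice) of the thresholded
#' mask restricted to the ROI are the puncta. Density is the punctum count
#' divided by the ROI area.
#'
#' @param mask Logical 2-D matrix or 3-D array (thresholded image).
#' @param intensity Matching intensity stack for integrated intensities.
#' @param roi Logical 2-D matrix (applied to every slice), or `NULL` for
#'   the full field.
#' @param roi_area ROI area in the caller's units; defaults to the ROI
#'   pixel count.
#' @return list of class `puncta_stats`: `count`, `area`, `density`,
#'   `sizes` (pixels per punctum), `intensities` (integrated intensity per
#'   punctum).
#' @export
puncta_metrics <- function(mask, intensity, roi = NULL, roi_area = NULL) {
  slices <- as_slices(mask)
  int_slices <- as_slices(intensity)
  dm <- dim(slices[[1]])
  if (is.null(roi)) roi <- matrix(TRUE, dm[1], dm[2])
  if (!identical(dim(roi), dm)) stop("ROI outside image bounds")
  if (!any(roi)) stop("empty ROI")
  if (is.null(roi_area)) roi_area <- sum(roi)
  sizes <- numeric(0); intens <- numeric(0)
  for (z in seq_along(slices)) {
    lab <- label_components_8(slices[[z]] & roi)
    k <- max(lab)
    if (k > 0L) {
      sizes <- c(sizes, tabulate(lab[lab > 0L], nbins = k))
      intens <- c(intens, as.numeric(
        rowsum(as.numeric(int_slices[[z]][lab > 0L]),
               group = lab[lab > 0L])))
    }
  }
  structure(list(count = length(sizes), area = roi_area,
                 density = length(sizes) / roi_area,
                 sizes = sizes, intensities = intens),
            class = "puncta_stats")
}
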