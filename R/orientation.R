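#' Primary diffusion orientation field
#'
#' Produces the unit primary-peak vector field used by the cosine-similarity
#' analysis. Either an externally supplied peak volume (grid x 3 array, e.g.
#' read from file) is validated and normalised, or the field falls back to
#' the principal eigenvector of a per-voxel tensor field (grid x 6 upper
#' triangle layout, as produced by [fit_dti()]). Vectors are
#' sign-canonicalised (first nonzero component positive); zero-norm peaks are
#' excluded (set `NA`).
#'
#' @param tensor_field Optional grid x 6 tensor array.
#' @param peaks Optional grid x 3 peak array.
#' @param mask Logical array of voxels to process.
#' @returns Grid x 3 array of unit vectors with a `provenance` attribute.
#' @export
primary_peak <- function(tensor_field = NULL, peaks = NULL, mask) {
  if (is.null(tensor_field) == is.null(peaks))
    stop("provide exactly one of tensor_field or peaks")
  d <- dim(mask)
  out <- array(NA_real_, c(d, 3))
  idx <- which(mask)
  if (!is.null(peaks)) {
    m <- matrix(NA_real_, length(idx), 3)
    for (a in 1:3) m[, a] <- (peaks[, , , a])[idx]
    prov <- "fODF-peak1"
  } else {
    m <- matrix(NA_real_, length(idx), 3)
    for (v in seq_along(idx)) {
      t6 <- vapply(1:6, function(c6) (tensor_field[, , , c6])[idx[v]], 0)
      if (anyNA(t6)) next
      m[v, ] <- tensor_metrics(tensor_from_6(t6))$e1
    }
    prov <- "DTI-e1"
  }
  nrm <- sqrt(rowSums(m^2))
  bad <- !is.finite(nrm) | nrm < 1e-12
  m[bad, ] <- NA_real_
  m[!bad, ] <- m[!bad, , drop = FALSE] / nrm[!bad]
  for (v in which(!bad)) m[v, ] <- canonical_sign(m[v, ])
  for (a in 1:3) {
    comp <- array(NA_real_, d)
    comp[idx] <- m[, a]
    out[, , , a] <- comp
  }
  attr(out, "provenance") <- prov
  out
}

#' Voxel-wise cosine-similarity orientation maps
#'
#' For each anatomical axis, the absolute normalised inner product between
#' the primary diffusion orientation and the Laplace-coordinate gradient:
#' `|u . v| / (|u| |v|)`, in `[0, 1]`. 0 means the two vectors are
#' orthogonal, 1 parallel (or antiparallel — the absolute value makes the
#' metric sign-invariant). Voxels where either field has zero norm are
#' excluded.
#'
#' @param peaks Grid x 3 primary orientation field ([primary_peak()]).
#' @param grads Named list of grid x 3 gradient fields, typically
#'   `list(AP = ..., PD = ..., IO = ...)` from [gradient_field()].
#' @param mask Logical array of voxels to process.
#' @returns Named list of scalar arrays: `long_axis`, `tangential`, `radial`
#'   for the AP, PD, IO axes respectively (only those axes supplied).
#' @export
cosine_similarity_maps <- function(peaks, grads, mask) {
  out_names <- c(AP = "long_axis", PD = "tangential", IO = "radial")
  idx <- which(mask)
  p <- matrix(NA_real_, length(idx), 3)
  for (a in 1:3) p[, a] <- (peaks[, , , a])[idx]
  pn <- sqrt(rowSums(p^2))
  res <- list()
  for (ax in names(grads)) {
    g <- matrix(NA_real_, length(idx), 3)
    for (a in 1:3) g[, a] <- (grads[[ax]][, , , a])[idx]
    gn <- sqrt(rowSums(g^2))
    val <- abs(rowSums(p * g)) / (pn * gn)
    val[!is.finite(val)] <- NA_real_
    arr <- array(NA_real_, dim(mask))
    arr[idx] <- val
    res[[out_names[[ax]] %||% ax]] <- arr
  }
  res
}

#' Cosine similarity of two vectors
#'
#' The scalar form of the orientation metric: `|u . v| / (|u| |v|)`.
#' @param u,v Numeric 3-vectors (any nonzero length).
#' @returns Value in `[0, 1]`.
#' @examples
#' cosine_similarity(c(1, 0, 0), c(0, 1, 0))  # orthogonal -> 0
#' cosine_similarity(c(0, 0, 1), c(0, 0, 1))  # parallel -> 1
#' @export
cosine_similarity <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12) stop("zero-norm input vector")
  abs(sum(u * v)) / (nu * nv)
}
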