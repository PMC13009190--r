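#' Multi-shell diffusion acquisition scheme
#'
#' Bundles shell b-values, per-shell gradient direction counts, unit gradient
#' directions and pulsed-gradient timings into a validated scheme object.
#' Units follow the diffusion-MRI convention used throughout the package:
#' b-values in ms/um^2, diffusivities in um^2/ms, pulse timings in ms.
#'
#' @param bvalues Numeric vector of shell b-values (ms/um^2), including 0.
#' @param n_dirs_per_shell Integer vector, one count per shell.
#' @param directions Optional matrix (n_volumes x 3) of unit directions, in
#'   shell order. If `NULL`, near-uniform directions are generated per shell
#'   from a Fibonacci sphere lattice (b = 0 volumes get a dummy +z direction).
#' @param delta Gradient pulse duration (ms). Must satisfy `delta < Delta`.
#' @param Delta Gradient pulse separation (ms).
#' @returns An object of class `acq_scheme`: a list with elements `bvalues`,
#'   `n_dirs_per_shell`, `shell` (shell index per volume), `b` (b-value per
#'   volume), `directions`, `delta`, `Delta`, `n_volumes`.
#' @examples
#' sch <- default_scheme()
#' sch$n_volumes
#' @export
acquisition_scheme <- function(bvalues, n_dirs_per_shell, directions = NULL,
                               delta = 7, Delta = 24) {
  stopifnot(length(bvalues) == length(n_dirs_per_shell))
  if (any(bvalues < 0)) stop("all b-values must be >= 0")
  if (any(n_dirs_per_shell < 1)) stop("each shell needs at least one volume")
  if (!(delta < Delta)) stop("delta must be smaller than Delta")
  shell <- rep(seq_along(bvalues), n_dirs_per_shell)
  b <- bvalues[shell]
  n_vol <- length(shell)
  if (is.null(directions)) {
    directions <- do.call(rbind, lapply(seq_along(bvalues), function(s) {
      n <- n_dirs_per_shell[s]
      if (bvalues[s] == 0) {
        matrix(rep(c(0, 0, 1), n), ncol = 3, byrow = TRUE)
      } else {
        fibonacci_hemisphere(n)
      }
    }))
  } else {
    directions <- as.matrix(directions)
    if (nrow(directions) != n_vol || ncol(directions) != 3)
      stop("directions must be an n_volumes x 3 matrix")
    nrm <- sqrt(rowSums(directions^2))
    if (any(abs(nrm - 1) > 1e-6))
      stop("all gradient directions must have unit norm (tolerance 1e-6)")
  }
  structure(
    list(bvalues = bvalues, n_dirs_per_shell = as.integer(n_dirs_per_shell),
         shell = shell, b = b, directions = directions,
         delta = delta, Delta = Delta, n_volumes = n_vol),
    class = "acq_scheme")
}

#' @rdname acquisition_scheme
#' @details `default_scheme()` reproduces the 6-shell protocol used throughout
#'   the package: b = 0 (14 volumes), 0.5 (30), 1.2 (30), 2.4 (60), 4.0 (60),
#'   6.0 (60) ms/um^2, with delta = 7 ms and Delta = 24 ms.
#' @export
default_scheme <- function(delta = 7, Delta = 24) {
  acquisition_scheme(bvalues = c(0, 0.5, 1.2, 2.4, 4.0, 6.0),
                     n_dirs_per_shell = c(14L, 30L, 30L, 60L, 60L, 60L),
                     delta = delta, Delta = Delta)
}

# Near-uniform unit vectors from the spherical Fibonacci lattice, mapped to a
# hemisphere-symmetric layout (antipodal pairs carry the same diffusion
# weighting, so the hemisphere restriction is conventional).
fibonacci_hemisphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  v <- cbind(r * cos(phi), r * sin(phi), z)
  v / sqrt(rowSums(v^2))
}

#' @export
print.acq_scheme <- function(x, ...) {
  cat("<acq_scheme> ", x$n_volumes, " volumes, shells b = ",
      paste(x$bvalues, collapse = "/"), " ms/um^2 (",
      paste(x$n_dirs_per_shell, collapse = "/"),
      " vols), delta = ", x$delta, " ms, Delta = ", x$Delta, " ms\n", sep = "")
  invisible(x)
}

#' Write / read a scheme as FSL-style plain-text files
#'
#' `write_scheme()` writes `<prefix>.bval` (one row of b-values) and
#' `<prefix>.bvec` (three rows of direction components) plus
#' `<prefix>.timing` (delta, Delta). `read_scheme()` reads them back.
#'
#' @param scheme An `acq_scheme`.
#' @param prefix File path prefix.
#' @returns `write_scheme()` the prefix, invisibly; `read_scheme()` an
#'   `acq_scheme`.
#' @export
write_scheme <- function(scheme, prefix) {
  writeLines(paste(format(scheme$b, trim = TRUE), collapse = " "),
             paste0(prefix, ".bval"))
  m <- t(scheme$directions)
  writeLines(apply(m, 1, function(r) paste(format(r, trim = TRUE), collapse = " ")),
             paste0(prefix, ".bvec"))
  writeLines(paste(scheme$delta, scheme$Delta), paste0(prefix, ".timing"))
  invisible(prefix)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(prefix) {
  b <- scan(paste0(prefix, ".bval"), quiet = TRUE)
  v <- t(as.matrix(utils::read.table(paste0(prefix, ".bvec"))))
  tm <- scan(paste0(prefix, ".timing"), quiet = TRUE)
  shells <- unique(b)
  # regroup volumes by first appearance of each b-value
  ord <- order(match(b, shells))
  acquisition_scheme(bvalues = shells,
                     n_dirs_per_shell = as.integer(table(factor(b, levels = shells))),
                     directions = v[ord, , drop = FALSE],
                     delta = tm[1], Delta = tm[2])
}
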