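#' Assign ground-truth microstructure to a domain for one participant
#'
#' Evaluates the per-parcel linear age/sex model of an effect specification
#' at this participant's age and sex, adds per-voxel Gaussian residuals,
#' clips to physical bounds (logging the clip count) and derives the simplex
#' signal fractions. The orientation field is coherent: the stick mean
#' direction follows one anatomical axis of the domain's true coordinates.
#'
#' @param domain A [generate_domain()] result.
#' @param participant One-row data frame with `age` (years) and `sex`
#'   (`"F"`/`"M"`), e.g. a row of [generate_cohort()].
#' @param effects Effect-spec tibble (see [default_effect_spec()]); must
#'   cover every subfield parcel for every parameter it mentions.
#' @param mu_axis Which axis the stick orientation field follows
#'   (`"AP"`, `"PD"` or `"IO"`).
#' @param residual_scope `"voxel"` (default): independent Gaussian residuals
#'   per voxel; `"parcel"`: one residual per parcel, shared by its voxels —
#'   the reduced-scale representation of between-participant biological
#'   variability on small test domains.
#' @param seed Integer seed for the residual draws.
#' @returns Object of class `ground_truth_field`: arrays over the grid for
#'   `f_ec`, `f_in` (raw fractions), `fneurite`, `fsoma`, `fextracellular`
#'   (derived, summing to 1 on the mask), `r_s`, `kappa`, `d_in`, `d_ec`,
#'   `mu` (grid x 3), `tensor` (grid x 6, row-major upper triangle
#'   xx,yy,zz,xy,xz,yz of the effective low-b tensor), plus `n_clipped` and
#'   the participant row.
#' @export
assign_ground_truth <- function(domain, participant, effects,
                                mu_axis = c("AP", "PD", "IO"),
                                residual_scope = c("voxel", "parcel"),
                                seed = 1L) {
  stopifnot(inherits(domain, "hipp_domain"))
  mu_axis <- match.arg(mu_axis)
  residual_scope <- match.arg(residual_scope)
  age_c <- attr(effects, "age_center") %||% 13.5
  ap_gradient <- isTRUE(attr(effects, "ap_gradient"))
  parcels <- subfield_names()
  need <- unique(effects$parameter)
  cover <- tidyr::expand_grid(parcel = parcels, parameter = need)
  miss <- dplyr::anti_join(cover, effects, by = c("parcel", "parameter"))
  if (nrow(miss) > 0)
    stop("effect spec does not cover all parcels for: ",
         paste(unique(miss$parameter), collapse = ", "))

  male <- as.integer(participant$sex == "M")
  dage <- participant$age - age_c
  mask <- domain$mask
  sf <- domain$subfield
  # anterior-loaded weights per long-axis bin (uncus ... tail)
  ap_weights <- c(1, 0.75, 0.5, 0.25, 0)
  bounds <- list(f_ec = c(0, 1), f_soma = c(0, 1), r_s = c(0.5, 12),
                 kappa = c(0, 64), d_in = c(0.1, 3), d_ec = c(0.1, 3))

  n_clipped <- 0L
  fields <- list()
  withr_seed(seed, {
    for (p in need) {
      eff <- effects[effects$parameter == p, ]
      eff <- eff[match(parcels, eff$parcel), ]
      slope <- eff$slope_age + eff$slope_age_sex * male
      arr <- array(NA_real_, domain$grid_shape)
      idx <- which(mask)
      parc <- sf[idx]
      slope_vox <- slope[parc]
      if (ap_gradient) slope_vox <- slope_vox * ap_weights[domain$longaxis[idx]]
      resid <- if (residual_scope == "voxel") {
        rnorm(length(idx), sd = eff$residual_sd[parc])
      } else {
        rnorm(length(parcels), sd = eff$residual_sd)[parc]
      }
      vals <- eff$intercept[parc] + slope_vox * dage +
        eff$offset_sex[parc] * male + resid
      b <- bounds[[p]]
      if (!is.null(b)) {
        clip <- vals < b[1] | vals > b[2]
        n_clipped <- n_clipped + sum(clip)
        vals <- pmin(pmax(vals, b[1]), b[2])
      }
      arr[idx] <- vals
      fields[[p]] <- arr
    }
  })

  # the generator parametrises the reported (derived) fractions directly:
  # fextracellular = f_ec, fsoma = f_soma (capped onto the simplex),
  # fneurite = 1 - f_ec - f_soma; the raw intraneurite fraction of the
  # cellular signal follows as f_in = fneurite / (1 - f_ec)
  fe_v <- fields$f_ec[mask]
  fs_v <- fields$f_soma[mask]
  over <- fs_v > 1 - fe_v
  n_clipped <- n_clipped + sum(over)
  fs_v <- pmin(fs_v, 1 - fe_v)
  fn_v <- 1 - fe_v - fs_v
  fin_v <- ifelse(fe_v < 1, fn_v / (1 - fe_v), 0)
  der <- tibble::tibble(fneurite = fn_v, fsoma = fs_v, fextracellular = fe_v)
  fneurite <- fsoma <- fextra <- f_in <- array(NA_real_, domain$grid_shape)
  fneurite[mask] <- fn_v
  fsoma[mask] <- fs_v
  fextra[mask] <- fe_v
  f_in[mask] <- fin_v
  fields$f_soma[mask] <- fs_v

  mu <- orientation_field(domain, mu_axis)
  tensor <- effective_tensor(fields, der, mu, mask, domain$grid_shape)

  structure(list(f_ec = fields$f_ec, f_soma = fields$f_soma, f_in = f_in,
                 fneurite = fneurite, fsoma = fsoma, fextracellular = fextra,
                 r_s = fields$r_s, kappa = fields$kappa,
                 d_in = fields$d_in, d_ec = fields$d_ec,
                 mu = mu, tensor = tensor, mask = mask,
                 grid_shape = domain$grid_shape, n_clipped = n_clipped,
                 participant = participant, mu_axis = mu_axis),
            class = "ground_truth_field")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# unit orientation field along one anatomical axis, from the analytic
# true-coordinate gradient (normalised; constant for a rectangular slab)
orientation_field <- function(domain, axis = "AP") {
  coord <- switch(axis, AP = domain$true_coords$u,
                  PD = domain$true_coords$v, IO = domain$true_coords$w)
  g <- finite_diff_gradient(coord, domain$mask, domain$voxel_size)
  n <- sqrt(g[, , , 1]^2 + g[, , , 2]^2 + g[, , , 3]^2)
  n[n == 0] <- NA
  for (a in 1:3) g[, , , a] <- g[, , , a] / n
  # voxels pinched to a single layer along some axis have an undefined
  # finite-difference direction; give them the mean field orientation so the
  # generated field stays coherent and defined on the whole mask
  idx <- which(domain$mask)
  bad <- idx[is.na(n[idx])]
  if (length(bad)) {
    m <- vapply(1:3, function(a) mean((g[, , , a])[idx], na.rm = TRUE), 0)
    m <- m / sqrt(sum(m^2))
    for (a in 1:3) {
      sl <- g[, , , a]
      sl[bad] <- m[a]
      g[, , , a] <- sl
    }
  }
  g
}

# effective low-b tensor of the compartment mixture:
# D = f_ec d_ec I + fneurite d_in mu mu' (soma contributes ~0 apparent)
effective_tensor <- function(fields, der, mu, mask, grid_shape) {
  tens <- array(NA_real_, c(grid_shape, 6))
  idx <- which(mask)
  iso <- fields$f_ec[idx] * fields$d_ec[idx]
  ax <- der$fneurite * fields$d_in[idx]
  m <- matrix(NA_real_, length(idx), 3)
  for (a in 1:3) m[, a] <- (mu[, , , a])[idx]
  comp <- cbind(iso + ax * m[, 1]^2, iso + ax * m[, 2]^2, iso + ax * m[, 3]^2,
                ax * m[, 1] * m[, 2], ax * m[, 1] * m[, 3], ax * m[, 2] * m[, 3])
  for (c6 in 1:6) {
    sl <- array(NA_real_, grid_shape)
    sl[idx] <- comp[, c6]
    tens[, , , c6] <- sl
  }
  tens
}

tensor_from_6 <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3, 3)
}

#' Parcel-mean ground-truth table
#'
#' Averages a ground-truth field within parcels, yielding the table used to
#' verify injected age slopes by ordinary least squares.
#'
#' @param field A [assign_ground_truth()] result.
#' @param domain The domain the field was generated on.
#' @param parameters Which parameter arrays to average.
#' @param parcellation `"subfield"` or `"longaxis"`.
#' @returns Tibble with columns `parcel`, `parameter`, `value` plus the
#'   participant columns.
#' @export
ground_truth_parcel_means <- function(field, domain,
                                      parameters = c("fneurite", "fsoma",
                                                     "fextracellular", "r_s",
                                                     "kappa"),
                                      parcellation = c("subfield", "longaxis")) {
  parcellation <- match.arg(parcellation)
  lab <- if (parcellation == "subfield") domain$subfield else domain$longaxis
  lev <- if (parcellation == "subfield") subfield_names() else longaxis_names()
  idx <- which(domain$mask)
  out <- purrr::map_dfr(parameters, function(p) {
    vals <- field[[p]][idx]
    tibble::tibble(parcel = lev,
                   parameter = p,
                   value = as.numeric(tapply(vals, factor(lab[idx], levels = seq_along(lev)), mean)))
  })
  dplyr::bind_cols(out, field$participant[rep(1, nrow(out)), c("participant", "age", "sex", "hemisphere")])
}
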