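# Condensate density estimation: "seamless assembling" (upper bound; the
# condensate is as dense as the average fiber) and explicit "random
# docking" of rigid fibers into a 200-nm sphere (lower bound).

#' Seamless-assembly condensate density (upper bound)
#'
#' With no space between fibers the condensate density equals the average
#' density of the fibers themselves.
#'
#' @param fiber_metrics list of results from [fiber_metrics()] or
#'   [wlc_metrics()] (each carrying `ncp_density_uM`).
#' @return list of class `nuca_density`: `mode = "seamless"`,
#'   `bound = "upper"`, `value_uM`.
#' @export
seamless_density <- function(fiber_metrics) {
  if (!length(fiber_metrics)) stop("empty fiber list")
  vals <- vapply(fiber_metrics, function(fm) fm$ncp_density_uM, numeric(1))
  structure(list(mode = "seamless", bound = "upper", value_uM = mean(vals),
                 n_fibers = length(vals)), class = "nuca_density")
}

#' Randomly dock fibers into a spherical condensate (lower bound)
#'
#' Fibers are treated as rigid bodies whose excluded volume is the union of
#' spheres at the NCP centers; each fiber's envelope radius is half a draw
#' from the condition's (i, i+2) center-spacing distribution, clamped to at
#' least the unit sphere radius. Fibers are placed sequentially with
#' uniform random rotation and center, rejecting placements that leave the
#' 200-nm sphere or overlap a placed fiber; docking stops at the first
#' fiber that cannot be placed within the attempt budget.
#'
#' @param fibers list of `nuca_fiber`.
#' @param sphere_diameter_nm condensate diameter (default 200).
#' @param spacing_nm list(mean, sd) of the inter-fiber NCP spacing
#'   distribution in nm (e.g. the measured i,i+2 distance).
#' @param rng_seed integer seed.
#' @param attempts placement attempts per fiber (default 1000).
#' @return object of class `nuca_condensate`: `placements` (fiber id,
#'   rotation, translation, envelope radius), `centers_nm` (all placed NCP
#'   centers), `sphere_diameter_nm`, `total_ncp`, `concentration_uM`.
#' @export
random_dock <- function(fibers, sphere_diameter_nm = 200,
                        spacing_nm = list(mean = 26.5, sd = 3),
                        rng_seed = 1L, attempts = 1000L) {
  if (!length(fibers)) stop("empty fiber list")
  set.seed(as.integer(rng_seed %% 2147483647))
  r_sph <- sphere_diameter_nm / 2
  placed_centers <- NULL
  placed_radii <- numeric(0)
  placements <- list()
  for (fid in seq_along(fibers)) {
    fib <- fibers[[fid]]
    cen0 <- sweep(fib$centers / 10, 2, colMeans(fib$centers / 10))  # nm
    r_env <- max(fib$radius_A / 10,
                 stats::rnorm(1, spacing_nm$mean, spacing_nm$sd) / 2)
    ok <- FALSE
    for (a in seq_len(attempts)) {
      R <- random_rotation()
      # uniform center in the sphere
      repeat {
        ctr <- stats::runif(3, -r_sph, r_sph)
        if (sum(ctr^2) <= r_sph^2) break
      }
      cen <- sweep(cen0 %*% t(R), 2, ctr, "+")
      if (max(rowSums(cen^2)) > r_sph^2) next
      if (!is.null(placed_centers)) {
        d2 <- cross_dist2(cen, placed_centers)
        lim <- outer(rep(r_env, nrow(cen)), placed_radii, "+")
        if (any(d2 < lim^2)) next
      }
      placed_centers <- rbind(placed_centers, cen)
      placed_radii <- c(placed_radii, rep(r_env, nrow(cen)))
      placements[[length(placements) + 1L]] <-
        list(fiber = fid, rotation = R, translation = ctr,
             envelope_radius_nm = r_env, n_ncp = nrow(cen))
      ok <- TRUE
      break
    }
    if (!ok) break   # stop at the first fiber that cannot be placed
  }
  if (!length(placements))
    stop("no fiber could be placed in the sphere")
  total <- sum(vapply(placements, function(p) p$n_ncp, numeric(1)))
  vol <- (4 / 3) * pi * r_sph^3
  structure(list(placements = placements, centers_nm = placed_centers,
                 sphere_diameter_nm = sphere_diameter_nm,
                 total_ncp = total,
                 concentration_uM = UM_PER_COUNT_PER_NM3 * total / vol),
            class = "nuca_condensate")
}

#' Concentration of a docked condensate
#'
#' Total placed NCPs over the full sphere volume, in micromolar.
#'
#' @param model a `nuca_condensate`.
#' @return concentration in uM.
#' @export
condensate_concentration <- function(model) {
  vol <- (4 / 3) * pi * (model$sphere_diameter_nm / 2)^3
  UM_PER_COUNT_PER_NM3 * model$total_ncp / vol
}

#' Export a condensate (placements as JSON, centers as pseudo-atom PDB)
#'
#' @param model a `nuca_condensate` (or a slab crop of one).
#' @param json_path,pdb_path output paths; either may be `NULL` to skip.
#' @return invisibly, the paths written.
#' @export
write_condensate <- function(model, json_path = NULL, pdb_path = NULL) {
  if (!is.null(json_path)) {
    obj <- list(sphere_diameter_nm = model$sphere_diameter_nm,
                total_ncp = model$total_ncp,
                concentration_uM = condensate_concentration(model),
                placements = lapply(model$placements, function(p)
                  list(fiber = p$fiber, rotation = p$rotation,
                       translation = p$translation,
                       envelope_radius_nm = p$envelope_radius_nm,
                       n_ncp = p$n_ncp)))
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = I(17))
  }
  if (!is.null(pdb_path))
    centers_pseudo_pdb(model$centers_nm * 10, pdb_path,
                       "nucarray condensate export (coordinates Angstrom)")
  invisible(c(json_path, pdb_path))
}

#' Crop a z-slab from a condensate for visualization
#'
#' @param model a `nuca_condensate`.
#' @param z0_nm lower z bound of the slab.
#' @param thickness_nm slab thickness (default 25).
#' @return the model restricted to NCP centers with
#'   `z in [z0, z0 + thickness)`.
#' @export
slab_crop <- function(model, z0_nm, thickness_nm = 25) {
  if (thickness_nm <= 0) stop("thickness must be > 0")
  keep <- model$centers_nm[, 3] >= z0_nm &
    model$centers_nm[, 3] < z0_nm + thickness_nm
  out <- model
  out$centers_nm <- model$centers_nm[keep, , drop = FALSE]
  out$total_ncp <- sum(keep)
  out$slab <- c(z0_nm, z0_nm + thickness_nm)
  out
}
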