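# Seeded generator of ground-truthed organoid / tumor-cell 3D scenes and
# rendered two-channel image stacks emulating a cleared-organoid confocal
# acquisition (85 optical sections, 3 um z-step by default).

#' Specify the depth distribution of tumor cells below the organoid surface
#'
#' @param law one of `"exponential"`, `"gamma"`, `"fixed"`.
#' @param scale scale in micrometres (exponential, gamma).
#' @param shape gamma shape.
#' @param values numeric vector of fixed depths (law = "fixed"); positive =
#'   inside the organoid, negative = outside the shell.
#' @return a classed depth-law specification.
#' @export
depth_law <- function(law = c("exponential", "gamma", "fixed"),
                      scale = 15, shape = 2, values = NULL) {
  if (is.character(law) && !law[1] %in% c("exponential", "gamma", "fixed"))
    stopf("unknown depth_law '%s' (use exponential, gamma or fixed)", law[1])
  law <- match.arg(law)
  if (law == "fixed" && is.null(values))
    stopf("depth_law 'fixed' needs a 'values' vector")
  structure(list(law = law, scale = scale, shape = shape, values = values),
            class = "depth_law")
}

draw_depths <- function(dl, n) {
  switch(dl$law,
    exponential = stats::rexp(n, rate = 1 / dl$scale),
    gamma = stats::rgamma(n, shape = dl$shape, scale = dl$scale),
    fixed = {
      if (length(dl$values) != n)
        stopf("fixed depth_law has %d values but %d tumor cells requested",
              length(dl$values), n)
      as.numeric(dl$values)
    })
}

# Uniform directions on the unit sphere.
runif_sphere <- function(n) {
  z <- stats::runif(n, -1, 1)
  t <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(t), y = r * sin(t), z = z)
}

#' Generate a ground-truthed organoid / tumor scene
#'
#' The organoid is modeled as a sphere (analytic oracle for every downstream
#' geometric quantity). Nuclei fill the organoid volume; each tumor cell is
#' placed at radial distance `organoid_radius - depth` along a random
#' direction, where depth is drawn from `depth_law`. Negative depths place
#' cells outside the shell.
#'
#' @param organoid_radius radius in micrometres.
#' @param n_nuclei number of organoid nuclei to render in the nuclear
#'   channel; `NULL` (default) picks a density of 0.7 nuclei per 1000 um^3
#'   (about 11 um center-to-center spacing, i.e. densely packed tissue).
#' @param n_tumor number of tumor cells.
#' @param depth_law a [depth_law()] object (or list coerced to one).
#' @param seed integer seed; equal seeds give bit-identical scenes.
#' @param center organoid center, micrometres.
#' @param shrinkage scalar tissue-shrinkage factor applied to all
#'   coordinates (cleared tissue shrinks during dehydration; default 1 = no
#'   shrinkage).
#' @param organoid_id,group labels carried into the truth table.
#' @return an `organoid_scene` with fields `center`, `radius`,
#'   `nucleus_positions`, `tumor_positions`, `tumor_true_depth`, `seed`.
#' @export
generate_scene <- function(organoid_radius, n_nuclei = NULL, n_tumor = 150,
                           depth_law = invadR::depth_law("exponential", scale = 15),
                           seed = 1L, center = c(0, 0, 0), shrinkage = 1,
                           organoid_id = "org1", group = "control") {
  if (!inherits(depth_law, "depth_law")) depth_law <- do.call(invadR::depth_law, depth_law)
  if (organoid_radius <= 0) stopf("organoid_radius must be > 0")
  n_nuclei <- n_nuclei %||% round(0.7e-3 * 4 / 3 * pi * organoid_radius^3)
  if (!is_count(n_nuclei) || !is_count(n_tumor)) stopf("counts must be >= 0")
  with_seed(seed, {
    # nuclei uniform in the ball
    nr <- organoid_radius * stats::runif(n_nuclei)^(1 / 3)
    nuc <- runif_sphere(n_nuclei) * nr
    nuc <- sweep(nuc, 2, center, "+")
    depth <- draw_depths(depth_law, n_tumor)
    tr <- organoid_radius - depth
    tum <- runif_sphere(n_tumor) * tr
    tum <- sweep(tum, 2, center, "+")
    if (shrinkage != 1) {
      nuc <- sweep(sweep(nuc, 2, center), 2, rep(shrinkage, 3), "*")
      nuc <- sweep(nuc, 2, center, "+")
      tum <- sweep(sweep(tum, 2, center), 2, rep(shrinkage, 3), "*")
      tum <- sweep(tum, 2, center, "+")
      depth <- depth * shrinkage
      organoid_radius <- organoid_radius * shrinkage
    }
    structure(list(center = center, radius = organoid_radius,
                   nucleus_positions = nuc, tumor_positions = tum,
                   tumor_true_depth = depth, seed = seed,
                   organoid_id = organoid_id, group = group),
              class = "organoid_scene")
  })
}

#' @export
print.organoid_scene <- function(x, ...) {
  cat(sprintf("organoid_scene '%s' (group %s): R = %g um, %d nuclei, %d tumor cells\n",
              x$organoid_id, x$group, x$radius,
              nrow(x$nucleus_positions), nrow(x$tumor_positions)))
  invisible(x)
}

#' Imaging parameters for stack rendering
#'
#' Defaults mirror the acquisition: 85 optical sections at a 3 um z-step
#' (total z-distance 255 um), 10x objective scale in xy.
#'
#' @param n_slices number of optical sections.
#' @param z_step z spacing, micrometres.
#' @param xy_pixel xy pixel size, micrometres.
#' @param fov_xy field of view in xy, micrometres (NULL = sized to the scene).
#' @param blob_sigma rendered cell size (Gaussian sigma), micrometres.
#' @param noise_model list with `poisson_scale` (0 = noise-free),
#'   `background` (constant offset) and `seed`.
#' @return an `imaging_params` list.
#' @export
imaging_params <- function(n_slices = 85, z_step = 3, xy_pixel = 1.2,
                           fov_xy = NULL, blob_sigma = 4,
                           noise_model = list(poisson_scale = 0,
                                              background = 0, seed = 1L)) {
  if (!is_count(n_slices) || n_slices < 1) stopf("n_slices must be >= 1")
  if (z_step <= 0) stopf("z_step must be > 0")
  structure(list(n_slices = as.integer(n_slices), z_step = z_step,
                 xy_pixel = xy_pixel, fov_xy = fov_xy, blob_sigma = blob_sigma,
                 noise_model = noise_model),
            class = "imaging_params")
}

#' Construct a calibrated two-channel voxel stack
#'
#' @param nuclear,tumor numeric 3D arrays (x, y, z), identical dimensions.
#' @param spacing named numeric `c(x=, y=, z=)` voxel spacing in micrometres.
#' @param origin physical position (um) of the center of voxel (1,1,1).
#' @return a `voxel_stack`.
#' @export
voxel_stack <- function(nuclear, tumor, spacing, origin = c(0, 0, 0)) {
  if (!identical(dim(nuclear), dim(tumor)))
    stopf("nuclear and tumor channels must share dimensions")
  if (any(nuclear < 0) || any(tumor < 0)) stopf("intensities must be >= 0")
  spacing <- unname(as.numeric(spacing))
  structure(list(nuclear = nuclear, tumor = tumor,
                 spacing = spacing, origin = unname(as.numeric(origin))),
            class = "voxel_stack")
}

#' @export
print.voxel_stack <- function(x, ...) {
  d <- dim(x$nuclear)
  cat(sprintf("voxel_stack: %d x %d x %d voxels, spacing (%g, %g, %g) um, total z %g um\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              stack_total_z(x)))
  invisible(x)
}

#' Total z-distance of a stack
#'
#' Reported as `n_slices * z_step` (85 sections at 3 um = 255 um).
#'
#' @param stack a `voxel_stack`.
#' @return total z extent in micrometres.
#' @export
stack_total_z <- function(stack) dim(stack$nuclear)[3] * stack$spacing[3]

# Add a separable Gaussian blob to `arr` (in place value, returned).
add_blob <- function(arr, pos_vox, sigma_vox, amplitude) {
  d <- dim(arr)
  rng <- lapply(1:3, function(ax) {
    lo <- max(1L, floor(pos_vox[ax] - 4 * sigma_vox[ax]))
    hi <- min(d[ax], ceiling(pos_vox[ax] + 4 * sigma_vox[ax]))
    if (lo > hi) return(NULL)
    lo:hi
  })
  if (any(vapply(rng, is.null, logical(1)))) return(arr)
  g <- lapply(1:3, function(ax)
    exp(-0.5 * ((rng[[ax]] - pos_vox[ax]) / sigma_vox[ax])^2))
  blob <- amplitude * (g[[1]] %o% g[[2]] %o% g[[3]])
  arr[rng[[1]], rng[[2]], rng[[3]]] <- arr[rng[[1]], rng[[2]], rng[[3]]] + blob
  arr
}

#' Render a scene into a two-channel voxel stack
#'
#' Each nucleus / tumor cell becomes a Gaussian blob in its channel; optional
#' Poisson shot noise and constant background. Cells outside the field of
#' view are clipped with a warning; the clipped count is stored in
#' `attr(stack, "n_clipped")`.
#'
#' @param scene an `organoid_scene`.
#' @param params an [imaging_params()] list.
#' @return a `voxel_stack`; `stack_total_z()` reports `n_slices * z_step`.
#' @export
render_stack <- function(scene, params = imaging_params()) {
  fov <- params$fov_xy %||% (2 * (scene$radius + 4 * params$blob_sigma + 10))
  nx <- ny <- max(8L, ceiling(fov / params$xy_pixel))
  nz <- params$n_slices
  spacing <- c(params$xy_pixel, params$xy_pixel, params$z_step)
  # center the organoid in the field of view
  origin <- c(scene$center[1] - (nx - 1) / 2 * spacing[1],
              scene$center[2] - (ny - 1) / 2 * spacing[2],
              scene$center[3] - (nz - 1) / 2 * spacing[3])
  nuc_arr <- array(0, c(nx, ny, nz))
  tum_arr <- array(0, c(nx, ny, nz))
  sigma_vox <- params$blob_sigma / spacing

  to_vox <- function(p) sweep(sweep(p, 2, origin), 2, spacing, "/") + 1
  render_channel <- function(arr, pos, amplitude) {
    if (is.null(pos) || nrow(pos) == 0L) return(list(arr = arr, clipped = 0L))
    pv <- to_vox(pos)
    d <- dim(arr)
    ok <- pv[, 1] >= 1 & pv[, 1] <= d[1] & pv[, 2] >= 1 & pv[, 2] <= d[2] &
          pv[, 3] >= 1 & pv[, 3] <= d[3]
    for (i in which(ok)) arr <- add_blob(arr, pv[i, ], sigma_vox, amplitude)
    list(arr = arr, clipped = sum(!ok))
  }
  rn <- render_channel(nuc_arr, scene$nucleus_positions, 180)
  rt <- render_channel(tum_arr, scene$tumor_positions, 200)
  n_clipped <- rn$clipped + rt$clipped
  if (n_clipped > 0)
    warnf("%d cell(s) outside the field of view were clipped", n_clipped)

  nm <- params$noise_model
  nuc_arr <- rn$arr; tum_arr <- rt$arr
  if ((nm$poisson_scale %||% 0) > 0) {
    with_seed(nm$seed %||% 1L, {
      s <- nm$poisson_scale
      nuc_arr <- array(stats::rpois(length(nuc_arr),
                                    (nuc_arr + (nm$background %||% 0)) * s) / s,
                       dim(nuc_arr))
      tum_arr <- array(stats::rpois(length(tum_arr),
                                    (tum_arr + (nm$background %||% 0)) * s) / s,
                       dim(tum_arr))
    })
  } else {
    nuc_arr <- nuc_arr + (nm$background %||% 0)
    tum_arr <- tum_arr + (nm$background %||% 0)
  }
  st <- voxel_stack(nuc_arr, tum_arr, spacing, origin)
  attr(st, "n_clipped") <- n_clipped
  st
}

#' Ground-truth distance table for a scene
#'
#' One row per tumor cell with the true signed depth below the organoid
#' surface; the oracle against which measured distances are validated.
#'
#' @param scene an `organoid_scene`.
#' @return a `data.frame` with columns `organoid_id`, `group`, `cell_id`,
#'   `x`, `y`, `z`, `distance_um` (true signed depth, + = inside).
#' @export
scene_to_truth_table <- function(scene) {
  n <- nrow(scene$tumor_positions)
  data.frame(
    organoid_id = rep(scene$organoid_id, n),
    group = rep(scene$group, n),
    cell_id = if (n) paste0(scene$organoid_id, "_c", seq_len(n)) else character(0),
    x = scene$tumor_positions[, 1][seq_len(n)],
    y = scene$tumor_positions[, 2][seq_len(n)],
    z = scene$tumor_positions[, 3][seq_len(n)],
    distance_um = scene$tumor_true_depth[seq_len(n)],
    stringsAsFactors = FALSE)
}

#' Write a scene's truth table and parameter sidecar
#'
#' @param scene an `organoid_scene`.
#' @param csv_path output CSV (one row per tumor cell).
#' @param json_path optional JSON sidecar with generator parameters.
#' @return `csv_path`, invisibly.
#' @export
write_scene_csv <- function(scene, csv_path, json_path = NULL) {
  utils::write.csv(scene_to_truth_table(scene), csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(organoid_id = scene$organoid_id,
                              group = scene$group, radius_um = scene$radius,
                              center_um = scene$center, seed = scene$seed,
                              n_nuclei = nrow(scene$nucleus_positions),
                              n_tumor = nrow(scene$tumor_positions)),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
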