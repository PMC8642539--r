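# End-to-end commands for both arms of the analysis, driven by a validated
# configuration list (or YAML file). Every run writes a JSON manifest
# recording the parameters and package version so the outputs can be
# reproduced exactly.

organoid_config_defaults <- function() list(
  arm = "organoid",
  n_organoids_per_group = 3L,
  n_tumor = 150L,
  n_nuclei = 3000L,
  organoid_radius = 100,
  groups = c("control", "treated"),
  depth_scale = c(control = 20, treated = 10),
  reference_group = "control",
  detail_um = 25,
  spot_diameter_um = 10,
  n_blank = 50L,
  xy_pixel = 4,
  n_slices = 85L,
  z_step = 3,
  mode = "image",            # "image" = render + reconstruct; "truth" = use
                             # generator ground truth distances directly
  seed = 1L)

sc_config_defaults <- function() list(
  arm = "singlecell",
  n_cells = 2000L,
  n_genes = 1200L,
  species_mix = 0.85,
  ambient_rate = 0.05,
  species_threshold_pct = 90,
  min_genes = 200L,
  max_genes = 6000L,
  max_mito_pct = 10,
  fold_effect = 4,
  fc_thresh = 0.23,
  p_thresh = 1e-8,
  arms = c("DMSO", "treated"),
  seed = 1L)

#' Validate a pipeline configuration against its defaults
#'
#' Unknown keys are an error (listing the offending keys); missing keys take
#' the defaults, which carry the workflow's stated parameter values
#' (25 um surface detail, 10 um spots, 50 blank slices, 200/6000/10% QC,
#' 0.23 / 1e-8 volcano thresholds).
#'
#' @param config named list (or path to a YAML file).
#' @param arm `"organoid"` or `"singlecell"`.
#' @return the completed configuration list.
#' @export
validate_config <- function(config, arm = c("organoid", "singlecell")) {
  arm <- match.arg(arm)
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  defaults <- if (arm == "organoid") organoid_config_defaults() else
    sc_config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  out <- utils::modifyList(defaults, config)
  out$arm <- arm
  out
}

write_manifest <- function(config, out_dir, extra = list()) {
  manifest <- c(list(package = "invadR",
                     version = as.character(utils::packageVersion("invadR")),
                     config = config), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the organoid invasion pipeline end to end
#'
#' Generates seeded synthetic organoid scenes for each group (treatment
#' scales the invasion-depth distribution), quantifies cell-to-surface
#' distances (either through full rendering + surface reconstruction +
#' spot detection, or directly from generator ground truth), and computes
#' the invasion statistics: min-normalized distances, reference-group Q3
#' invasion threshold, per-organoid invading counts, and the group test on
#' per-organoid invading-cell counts (t test for 2 groups, ANOVA + Tukey
#' HSD for more; Tukey pairs are also reported for 2 groups).
#'
#' @param config configuration list or YAML path; see
#'   [validate_config()].
#' @param out_dir output directory.
#' @return invisibly, a list with `distances`, `summary`, `group_test`,
#'   `counts`; CSV/JSON outputs and a manifest are written to `out_dir`.
#' @export
run_organoid_pipeline <- function(config = list(), out_dir) {
  cfg <- validate_config(config, "organoid")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tables <- list()
  meshes <- list()
  org_summary <- list()
  idx <- 0L
  for (g in cfg$groups) {
    for (i in seq_len(cfg$n_organoids_per_group)) {
      idx <- idx + 1L
      org_id <- sprintf("%s_org%d", g, i)
      seed_i <- cfg$seed * 1000L + idx
      scene <- generate_scene(cfg$organoid_radius,
                              n_nuclei = cfg$n_nuclei, n_tumor = cfg$n_tumor,
                              depth_law = depth_law("exponential",
                                                    scale = cfg$depth_scale[[g]]),
                              seed = seed_i, organoid_id = org_id, group = g)
      if (cfg$mode == "truth") {
        tables[[org_id]] <- scene_to_truth_table(scene)
      } else {
        params <- imaging_params(n_slices = cfg$n_slices, z_step = cfg$z_step,
                                 xy_pixel = cfg$xy_pixel)
        stack <- render_stack(scene, params)
        stack <- pad_stack(stack, cfg$n_blank)
        m1 <- reconstruct_surface(stack, detail_um = cfg$detail_um)
        m2 <- outside_mask_resurface(stack, m1)
        spots <- detect_spots(stack, diameter_um = cfg$spot_diameter_um)
        tables[[org_id]] <- shortest_distance(spots, m2, organoid_id = org_id,
                                              group = g)
        meshes[[org_id]] <- m2
        org_summary[[org_id]] <- data.frame(
          organoid_id = org_id, group = g, n_cells = nrow(spots$positions),
          volume_um3 = mesh_volume(m2), area_um2 = mesh_area(m2))
        write_mesh(m2, file.path(out_dir, paste0(org_id, "_surface.obj")))
      }
    }
  }
  distances <- normalize_distances(do.call(rbind, c(tables,
                                                    make.row.names = FALSE)))
  summ <- invasion_summary(distances, cfg$reference_group)
  counts <- summ$per_organoid
  count_groups <- split(counts$n_invading, counts$group)
  group_test <- if (length(count_groups) == 2) {
    gt <- compare_multi_groups(count_groups)   # k = 2 Tukey = pooled t test
    gt
  } else compare_multi_groups(count_groups)

  write_distance_csv(distances, file.path(out_dir, "distances.csv"))
  utils::write.csv(counts, file.path(out_dir, "invasion_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(threshold_um = summ$threshold_um,
                            reference_group = summ$reference_group),
                       file.path(out_dir, "invasion_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(group_test$pairwise,
                   file.path(out_dir, "group_test.csv"), row.names = FALSE)
  if (length(org_summary))
    utils::write.csv(do.call(rbind, org_summary),
                     file.path(out_dir, "organoid_summary.csv"),
                     row.names = FALSE)
  kde <- kde_profile(distances)
  utils::write.csv(kde, file.path(out_dir, "kde_profiles.csv"),
                   row.names = FALSE)
  write_manifest(cfg, out_dir)
  invisible(list(distances = distances, summary = summ,
                 group_test = group_test, counts = counts, meshes = meshes))
}

#' Run the single-cell pipeline end to end
#'
#' Generates a seeded barnyard capture and a two-arm cycle cohort,
#' assigns species, applies the detected-gene / mitochondrial QC filter,
#' scores S and G2M modules, bins phases, computes arm-wise phase and
#' cluster proportion shifts, and classifies a rank-sum + Bonferroni DE
#' table of the planted marker genes into volcano categories.
#'
#' @param config configuration list or YAML path; see
#'   [validate_config()].
#' @param out_dir output directory.
#' @return invisibly, a list with `species_annotation`, `annotation`,
#'   `phase_shift`, `cluster_shift`, `volcano`; CSVs and a manifest are
#'   written to `out_dir`.
#' @export
run_sc_pipeline <- function(config = list(), out_dir) {
  cfg <- validate_config(config, "singlecell")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  design_bar <- sc_design(n_cells = cfg$n_cells, n_genes = cfg$n_genes,
                          species_mix = cfg$species_mix,
                          ambient_rate = cfg$ambient_rate,
                          fold_effect = cfg$fold_effect, seed = cfg$seed)
  barn <- generate_barnyard(design_bar)
  spec_ann <- species_assign(barn, cfg$species_threshold_pct)

  design_cyc <- sc_design(n_cells = cfg$n_cells, n_genes = cfg$n_genes,
                          fold_effect = cfg$fold_effect,
                          seed = cfg$seed + 1L)
  cohort <- generate_cycle_cohort(design_cyc, arms = cfg$arms)
  keep <- qc_filter(cohort, cfg$min_genes, cfg$max_genes, cfg$max_mito_pct)
  cohort_f <- subset_cells(cohort, keep)
  ann <- score_cell_cycle(cohort_f, seed = cfg$seed)
  phase_shift <- proportion_shift(ann, "phase", arms = cfg$arms)
  ann$cluster <- ann$true_cluster
  cluster_shift <- proportion_shift(ann, "cluster", arms = cfg$arms)

  marker_genes <- cohort_f$features$gene[cohort_f$features$program == "marker"]
  de <- rank_sum_de(cohort_f, arms = cfg$arms, genes = marker_genes)
  volcano <- volcano_classify(de, cfg$fc_thresh, cfg$p_thresh)

  utils::write.csv(spec_ann, file.path(out_dir, "species_annotation.csv"),
                   row.names = FALSE)
  utils::write.csv(ann, file.path(out_dir, "cell_annotation.csv"),
                   row.names = FALSE)
  utils::write.csv(phase_shift, file.path(out_dir, "phase_shift.csv"),
                   row.names = FALSE)
  utils::write.csv(cluster_shift, file.path(out_dir, "cluster_shift.csv"),
                   row.names = FALSE)
  utils::write.csv(volcano, file.path(out_dir, "volcano.csv"),
                   row.names = FALSE)
  utils::write.csv(tabulate_arms(ann), file.path(out_dir, "arm_counts.csv"),
                   row.names = FALSE)
  write_manifest(cfg, out_dir)
  invisible(list(species_annotation = spec_ann, annotation = ann,
                 phase_shift = phase_shift, cluster_shift = cluster_shift,
                 volcano = volcano))
}
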