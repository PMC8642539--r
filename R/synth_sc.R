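# Seeded generator of dual-species droplet UMI count matrices with planted
# cell-cycle states, clusters and treatment-arm proportion shifts, emulating
# a PDX single-cell capture (~10,000 cells per sample target).

#' Cell-cycle signature gene lists
#'
#' The 43 S-phase and 54 G2M-phase signature genes (Tirosh-style lists)
#' shipped with the package; used both by the generator (as the planted
#' programs) and by [module_score()].
#'
#' @return a list with character vectors `S` and `G2M`.
#' @export
cell_cycle_genes <- function() {
  path <- system.file("extdata", "cell_cycle_genes.tsv", package = "invadR")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  list(S = tab$gene[tab$phase == "S"], G2M = tab$gene[tab$phase == "G2M"])
}

#' Design of a synthetic single-cell experiment
#'
#' Defaults emulate the in vivo capture: ~10,000 cells per treatment arm,
#' droplet UMI counts sampled negative-binomially, log-normal library sizes,
#' a small ambient cross-species contamination fraction, and a planted
#' G1-ward proportion shift in the treated arm.
#'
#' @param n_cells cells per arm.
#' @param n_genes genes per species panel (background genes; programs and
#'   markers are added on top for the human panel).
#' @param species_mix fraction of barcodes that are human tumor cells.
#' @param ambient_rate fraction of each cell's UMIs drawn from the other
#'   species' ambient pool (in `[0, 0.5)`).
#' @param phase_proportions list with per-arm named vectors over
#'   `G1`, `S`, `G2M`, each summing to 1.
#' @param n_clusters number of planted expression clusters.
#' @param fold_effect fold-change applied to S-program genes in S cells and
#'   G2M-program genes in G2M cells.
#' @param marker_fold fold-change of cluster marker genes in their cluster.
#' @param n_markers marker genes per cluster.
#' @param libsize_meanlog,libsize_sdlog log-normal library-size parameters.
#' @param dispersion negative-binomial size parameter (larger = closer to
#'   Poisson).
#' @param mito_rate_mult rate multiplier for the 13 mitochondrial genes.
#' @param seed integer seed.
#' @return an `sc_design` list.
#' @export
sc_design <- function(n_cells = 10000, n_genes = 2000, species_mix = 0.85,
                      ambient_rate = 0.05,
                      phase_proportions = list(
                        arm1 = c(G1 = 0.55, S = 0.25, G2M = 0.20),
                        arm2 = c(G1 = 0.70, S = 0.17, G2M = 0.13)),
                      n_clusters = 3, fold_effect = 4, marker_fold = 3,
                      n_markers = 20,
                      libsize_meanlog = log(5000), libsize_sdlog = 0.3,
                      dispersion = 10, mito_rate_mult = 3, seed = 1L) {
  if (any(vapply(phase_proportions, function(p) abs(sum(p) - 1) > 1e-8,
                 logical(1))))
    stopf("phase proportions must sum to 1 per arm")
  if (ambient_rate < 0 || ambient_rate >= 0.5)
    stopf("ambient_rate must be in [0, 0.5)")
  structure(mget(names(formals())), class = "sc_design")
}

# Feature table for the two-species panel. The human panel carries the
# packaged S/G2M signature genes, per-cluster marker genes and 13
# mitochondrial genes; everything else is tagged background.
build_features <- function(design) {
  cc <- cell_cycle_genes()
  n_mito <- 13L
  mito <- sprintf("MT-GENE%02d", seq_len(n_mito))
  markers <- unlist(lapply(seq_len(design$n_clusters), function(k)
    sprintf("MARK%d_%02d", k, seq_len(design$n_markers))))
  n_bg <- max(0L, design$n_genes - length(cc$S) - length(cc$G2M) -
                length(mito) - length(markers))
  bg <- sprintf("HUM%04d", seq_len(n_bg))
  hum <- data.frame(
    gene = c(cc$S, cc$G2M, markers, mito, bg),
    species = "human",
    mito = c(rep(FALSE, length(cc$S) + length(cc$G2M) + length(markers)),
             rep(TRUE, n_mito), rep(FALSE, n_bg)),
    program = c(rep("S", length(cc$S)), rep("G2M", length(cc$G2M)),
                rep("marker", length(markers)),
                rep("background", n_mito + n_bg)),
    cluster = c(rep(NA_integer_, length(cc$S) + length(cc$G2M)),
                rep(seq_len(design$n_clusters), each = design$n_markers),
                rep(NA_integer_, n_mito + n_bg)),
    stringsAsFactors = FALSE)
  mou <- data.frame(
    gene = sprintf("mm-Gene%04d", seq_len(design$n_genes)),
    species = "mouse", mito = FALSE, program = "background",
    cluster = NA_integer_, stringsAsFactors = FALSE)
  rbind(hum, mou)
}

# Per-gene baseline relative rates (log-normal), with the mito multiplier.
base_rates <- function(features) {
  r <- stats::rlnorm(nrow(features), meanlog = 0, sdlog = 1)
  r
}

# NB sampling of a genes x cells block given per-cell expected totals and a
# genes x cells relative-rate structure encoded as baseline rates plus
# per-cell multiplier sets. Returns a sparse dgCMatrix.
sample_counts <- function(rate_mat, size) {
  mu <- rate_mat
  cnt <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu), size = size),
                nrow(mu), ncol(mu))
  methods::as(methods::as(Matrix::Matrix(cnt, sparse = TRUE), "generalMatrix"),
              "CsparseMatrix")
}

#' Generate a dual-species barnyard count matrix
#'
#' Human cells draw `1 - ambient_rate` of their UMIs from human genes and
#' `ambient_rate` from the mouse ambient pool (and vice versa); counts are
#' negative-binomial around the rate structure. Planted truth (species per
#' barcode) is stored alongside the counts.
#'
#' @param design an [sc_design()].
#' @return an `sc_counts` list: `counts` (sparse genes x cells), `features`
#'   data frame (gene, species, mito, program), `barcodes` data frame
#'   (barcode, arm, true_species, true_phase, true_cluster).
#' @export
generate_barnyard <- function(design = sc_design()) {
  with_seed(design$seed, {
    features <- build_features(design)
    n <- design$n_cells
    n_hum <- round(n * design$species_mix)
    true_species <- c(rep("human", n_hum), rep("mouse", n - n_hum))
    lib <- stats::rlnorm(n, design$libsize_meanlog, design$libsize_sdlog)
    r <- base_rates(features)
    r[features$mito] <- r[features$mito] * design$mito_rate_mult
    hu <- features$species == "human"
    r_h <- r * hu / sum(r[hu])
    r_m <- r * (!hu) / sum(r[!hu])
    amb <- design$ambient_rate
    own <- ifelse(true_species == "human", 1, 0)
    # genes x cells expected counts
    mu <- outer(r_h, lib * ((1 - amb) * own + amb * (1 - own))) +
          outer(r_m, lib * ((1 - amb) * (1 - own) + amb * own))
    counts <- sample_counts(mu, design$dispersion)
    barcodes <- data.frame(
      barcode = sprintf("BC%05d", seq_len(n)), arm = NA_character_,
      true_species = true_species, true_phase = NA_character_,
      true_cluster = NA_integer_, stringsAsFactors = FALSE)
    rownames(counts) <- features$gene
    colnames(counts) <- barcodes$barcode
    structure(list(counts = counts, features = features, barcodes = barcodes,
                   design = design),
              class = "sc_counts")
  })
}

#' Generate a two-arm cohort with planted cell-cycle phases and clusters
#'
#' Human cells only (post species-separation stage of the pipeline). Each
#' cell's phase is drawn from its arm's phase proportions; S cells have
#' their S-program gene rates multiplied by `fold_effect`, G2M cells
#' likewise; cluster markers are elevated `marker_fold`-fold in their
#' cluster. The planted labels are stored per barcode.
#'
#' @param design an [sc_design()].
#' @param arms character names of the two arms.
#' @return an `sc_counts` object with truth columns filled in.
#' @export
generate_cycle_cohort <- function(design = sc_design(),
                                  arms = c("DMSO", "treated")) {
  cc <- cell_cycle_genes()
  if (length(intersect(cc$S, cc$G2M)))
    stopf("S and G2M program gene lists overlap")
  with_seed(design$seed, {
    features <- build_features(design)
    features <- features[features$species == "human", , drop = FALSE]
    r0 <- base_rates(features)
    r0[features$mito] <- r0[features$mito] * design$mito_rate_mult
    phases <- c("G1", "S", "G2M")
    per_arm <- lapply(seq_along(arms), function(ai) {
      n <- design$n_cells
      props <- design$phase_proportions[[ai]][phases]
      phase <- sample(phases, n, replace = TRUE, prob = props)
      cluster <- sample.int(design$n_clusters, n, replace = TRUE)
      lib <- stats::rlnorm(n, design$libsize_meanlog, design$libsize_sdlog)
      rates <- matrix(r0, nrow(features), n)
      s_rows <- features$program == "S"
      g_rows <- features$program == "G2M"
      rates[s_rows, phase == "S"] <- rates[s_rows, phase == "S"] * design$fold_effect
      rates[g_rows, phase == "G2M"] <- rates[g_rows, phase == "G2M"] * design$fold_effect
      for (k in seq_len(design$n_clusters)) {
        m_rows <- features$program == "marker" & features$cluster == k
        rates[m_rows, cluster == k] <- rates[m_rows, cluster == k] * design$marker_fold
      }
      mu <- sweep(rates, 2, lib / colSums(rates), "*")
      counts <- sample_counts(mu, design$dispersion)
      list(counts = counts, phase = phase, cluster = cluster)
    })
    counts <- do.call(cbind, lapply(per_arm, `[[`, "counts"))
    n <- design$n_cells
    barcodes <- data.frame(
      barcode = sprintf("BC%05d", seq_len(length(arms) * n)),
      arm = rep(arms, each = n),
      true_species = "human",
      true_phase = unlist(lapply(per_arm, `[[`, "phase")),
      true_cluster = unlist(lapply(per_arm, `[[`, "cluster")),
      stringsAsFactors = FALSE)
    rownames(counts) <- features$gene
    colnames(counts) <- barcodes$barcode
    structure(list(counts = counts, features = features, barcodes = barcodes,
                   design = design),
              class = "sc_counts")
  })
}

#' @export
print.sc_counts <- function(x, ...) {
  cat(sprintf("sc_counts: %d genes x %d cells (%.2f%% nonzero)\n",
              nrow(x$counts), ncol(x$counts),
              100 * Matrix::nnzero(x$counts) / prod(dim(x$counts))))
  invisible(x)
}

#' Write an sc_counts object as MTX + feature / barcode TSVs
#'
#' Layout mirrors the droplet-pipeline convention: `matrix.mtx`,
#' `features.tsv` (gene, species, mito, program), `barcodes.tsv`, plus a
#' `truth.csv` sidecar with the planted labels.
#'
#' @param x an `sc_counts` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(x$features[, c("gene", "species", "mito", "program")],
                     file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(x$barcodes$barcode, file.path(dir, "barcodes.tsv"))
  utils::write.csv(x$barcodes, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read an sc_counts object written by [write_count_matrix()]
#'
#' @param dir directory containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv` (and optionally `truth.csv`).
#' @return an `sc_counts` object.
#' @export
read_count_matrix <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  features <- utils::read.delim(file.path(dir, "features.tsv"),
                                header = FALSE, stringsAsFactors = FALSE,
                                col.names = c("gene", "species", "mito",
                                              "program"))
  features$mito <- as.logical(features$mito)
  bcs <- readLines(file.path(dir, "barcodes.tsv"))
  truth_path <- file.path(dir, "truth.csv")
  barcodes <- if (file.exists(truth_path)) {
    utils::read.csv(truth_path, stringsAsFactors = FALSE)
  } else {
    data.frame(barcode = bcs, arm = NA_character_,
               true_species = NA_character_, true_phase = NA_character_,
               true_cluster = NA_integer_, stringsAsFactors = FALSE)
  }
  rownames(counts) <- features$gene
  colnames(counts) <- bcs
  structure(list(counts = counts, features = features, barcodes = barcodes,
                 design = NULL),
            class = "sc_counts")
}
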