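# Defined single-cell computations: barnyard species assignment, QC
# filtering, cell-cycle module scoring and phase binning, arm-wise
# proportion shifts, and volcano-category classification.

#' Per-barcode QC and species metrics
#'
#' @param x an `sc_counts` object.
#' @return a `data.frame`: `barcode`, `n_umi`, `n_genes_detected`,
#'   `pct_mito`, `pct_human`, `pct_mouse`, plus truth columns carried over.
#' @export
cell_metrics <- function(x) {
  cs <- Matrix::colSums(x$counts)
  ng <- Matrix::colSums(x$counts > 0)
  if (!"mito" %in% names(x$features)) stopf("features lack a 'mito' flag")
  mito <- Matrix::colSums(x$counts[x$features$mito, , drop = FALSE])
  hum <- Matrix::colSums(x$counts[x$features$species == "human", , drop = FALSE])
  out <- data.frame(
    barcode = colnames(x$counts) %||% sprintf("BC%05d", seq_along(cs)),
    n_umi = as.numeric(cs), n_genes_detected = as.numeric(ng),
    pct_mito = ifelse(cs > 0, 100 * mito / cs, 0),
    pct_human = ifelse(cs > 0, 100 * hum / cs, 0),
    stringsAsFactors = FALSE)
  out$pct_mouse <- 100 - out$pct_human
  merge_cols <- intersect(c("arm", "true_species", "true_phase",
                            "true_cluster"), names(x$barcodes))
  out[merge_cols] <- x$barcodes[match(out$barcode, x$barcodes$barcode),
                                merge_cols]
  out
}

#' Assign barcodes to a species from cross-species UMI fractions
#'
#' A barcode is called human when at least `threshold_pct` of its UMIs fall
#' on human-tagged genes, mouse when at least `threshold_pct` fall on mouse
#' genes, and ambiguous otherwise (ambiguous barcodes are excluded
#' downstream). Optionally the threshold call is refined by 2-means
#' clustering on the human fraction.
#'
#' @param x an `sc_counts` object (features must carry species tags).
#' @param threshold_pct percent UMI cutoff (default 90).
#' @param refine also run 2-means clustering on `pct_human` and relabel
#'   non-ambiguous cells by their cluster.
#' @return [cell_metrics()] table with an added `species` column
#'   (`"human"`, `"mouse"`, `"ambiguous"`).
#' @export
species_assign <- function(x, threshold_pct = 90, refine = FALSE) {
  if (!"species" %in% names(x$features) ||
      all(is.na(x$features$species)))
    stopf("features carry no species tags")
  met <- cell_metrics(x)
  species <- rep("ambiguous", nrow(met))
  species[met$pct_human >= threshold_pct] <- "human"
  species[met$pct_mouse >= threshold_pct] <- "mouse"
  if (refine && length(unique(met$pct_human)) > 1) {
    km <- stats::kmeans(met$pct_human, centers = 2)
    hum_clus <- which.max(km$centers)
    refined <- ifelse(km$cluster == hum_clus, "human", "mouse")
    keep_ambig <- species == "ambiguous"
    species <- refined
    species[keep_ambig] <- "ambiguous"
  }
  met$species <- species
  met
}

#' QC-filter barcodes on detected genes and mitochondrial fraction
#'
#' Retains a cell iff `min_genes <= n_genes_detected <= max_genes` and
#' `pct_mito <= max_mito_pct`: the discard rules are strict ("less than 200
#' or more than 6000 detected genes, or more than 10% mitochondrial"), so
#' boundary cells are retained.
#'
#' @param x an `sc_counts` object or a [cell_metrics()] table.
#' @param min_genes,max_genes detected-gene bounds (defaults 200, 6000).
#' @param max_mito_pct mitochondrial percentage bound (default 10).
#' @return character vector of retained barcodes.
#' @export
qc_filter <- function(x, min_genes = 200, max_genes = 6000,
                      max_mito_pct = 10) {
  met <- if (inherits(x, "sc_counts")) cell_metrics(x) else x
  keep <- met$n_genes_detected >= min_genes &
          met$n_genes_detected <= max_genes &
          met$pct_mito <= max_mito_pct
  met$barcode[keep]
}

#' Subset an sc_counts object to a set of barcodes
#'
#' @param x an `sc_counts` object.
#' @param barcodes barcodes to keep.
#' @return the subset `sc_counts`.
#' @export
subset_cells <- function(x, barcodes) {
  idx <- match(barcodes, colnames(x$counts))
  if (anyNA(idx)) stopf("%d barcode(s) not present", sum(is.na(idx)))
  structure(list(counts = x$counts[, idx, drop = FALSE],
                 features = x$features,
                 barcodes = x$barcodes[match(barcodes, x$barcodes$barcode), ,
                                       drop = FALSE],
                 design = x$design),
            class = "sc_counts")
}

#' Log-normalize counts (counts-per-10k, log1p)
#'
#' @param x an `sc_counts` object or sparse genes x cells matrix.
#' @param scale_factor library-size target (default 1e4).
#' @return sparse genes x cells matrix of log-normalized expression.
#' @export
normalize_log1p <- function(x, scale_factor = 1e4) {
  m <- if (inherits(x, "sc_counts")) x$counts else x
  cs <- Matrix::colSums(m)
  cs[cs == 0] <- 1
  norm <- m %*% Matrix::Diagonal(x = scale_factor / cs)
  norm@x <- log1p(norm@x)
  rownames(norm) <- rownames(m)
  colnames(norm) <- colnames(m)
  norm
}

#' Expression-program module score with binned control genes
#'
#' Per cell: mean log-normalized expression of the program genes minus the
#' mean of a control set, where `n_ctrl` control genes are drawn (per
#' program gene) from the same average-expression bin of all genes. This is
#' the standard binned-control scoring scheme for cell-cycle signatures.
#'
#' @param norm log-normalized genes x cells matrix (see
#'   [normalize_log1p()]).
#' @param program_genes character vector of program gene names; genes absent
#'   from the panel are dropped with a warning.
#' @param n_bins number of average-expression bins (default 24).
#' @param n_ctrl control genes drawn per program gene (default 100).
#' @param seed integer seed making the control draw reproducible.
#' @param exclude genes barred from the control pools (default: the program
#'   genes themselves; pass the union of all scored signatures when scoring
#'   several related programs so one program cannot serve as another's
#'   control).
#' @return numeric per-cell score vector.
#' @export
module_score <- function(norm, program_genes, n_bins = 24, n_ctrl = 100,
                         seed = 1L, exclude = program_genes) {
  present <- intersect(program_genes, rownames(norm))
  if (length(present) == 0) stopf("no program genes present in the panel")
  if (length(present) < length(program_genes))
    warnf("%d program gene(s) absent from the panel were dropped",
          length(program_genes) - length(present))
  avg <- Matrix::rowMeans(norm)
  n_bins <- min(n_bins, length(unique(avg)))
  bins <- cut(rank(avg, ties.method = "first"), breaks = n_bins,
              labels = FALSE)
  names(bins) <- rownames(norm)
  ctrl_sets <- with_seed(seed, {
    lapply(present, function(g) {
      pool <- names(bins)[bins == bins[g]]
      pool <- setdiff(pool, c(g, exclude))
      if (length(pool) == 0) pool <- setdiff(names(bins), c(present, exclude))
      if (length(pool) <= n_ctrl) pool else sample(pool, n_ctrl)
    })
  })
  # each program gene contributes the mean of its own matched controls, so
  # the control distribution mirrors the program's expression-bin profile
  w <- numeric(nrow(norm))
  names(w) <- rownames(norm)
  for (cs in ctrl_sets) w[cs] <- w[cs] + 1 / (length(present) * length(cs))
  used <- w > 0
  prog_mean <- Matrix::colMeans(norm[present, , drop = FALSE])
  ctrl_mean <- as.numeric(w[used] %*% norm[used, , drop = FALSE])
  as.numeric(prog_mean - ctrl_mean)
}

#' Bin cells into cell-cycle phases from S and G2M scores
#'
#' Cells with both scores at or below zero are assigned to G1 (the "lower
#' G2M and S scores" rule); otherwise the phase of the larger score wins,
#' with equal positive scores breaking to S.
#'
#' @param s_score,g2m_score numeric score vectors.
#' @return character vector in `{"G1", "S", "G2M"}`.
#' @export
assign_phase <- function(s_score, g2m_score) {
  ifelse(s_score <= 0 & g2m_score <= 0, "G1",
         ifelse(s_score >= g2m_score, "S", "G2M"))
}

#' Score cells and assign phases in one call
#'
#' @param x an `sc_counts` object.
#' @param s_genes,g2m_genes program gene lists (default: the packaged
#'   signatures).
#' @param n_bins,n_ctrl,seed see [module_score()].
#' @return annotation `data.frame` with `barcode`, `s_score`, `g2m_score`,
#'   `phase` and truth columns.
#' @export
score_cell_cycle <- function(x, s_genes = cell_cycle_genes()$S,
                             g2m_genes = cell_cycle_genes()$G2M,
                             n_bins = 24, n_ctrl = 100, seed = 1L) {
  norm <- normalize_log1p(x)
  both <- union(s_genes, g2m_genes)
  s <- module_score(norm, s_genes, n_bins, n_ctrl, seed = seed,
                    exclude = both)
  g <- module_score(norm, g2m_genes, n_bins, n_ctrl, seed = seed + 1L,
                    exclude = both)
  ann <- data.frame(barcode = colnames(x$counts), s_score = s, g2m_score = g,
                    phase = assign_phase(s, g), stringsAsFactors = FALSE)
  merge_cols <- intersect(c("arm", "true_species", "true_phase",
                            "true_cluster"), names(x$barcodes))
  ann[merge_cols] <- x$barcodes[match(ann$barcode, x$barcodes$barcode),
                                merge_cols]
  ann
}

#' Per-category proportion shift between two treatment arms
#'
#' @param annotation data frame with an `arm` column and the category
#'   column.
#' @param category column to tabulate (`"phase"` or `"cluster"`, or any
#'   label column).
#' @param arms length-2 character: reference arm first; the delta is
#'   arm2 - arm1, in percentage points.
#' @return a `data.frame`: `category`, `pct_arm1`, `pct_arm2`, `delta_pct`.
#' @export
proportion_shift <- function(annotation, category = "phase",
                             arms = NULL) {
  if (!"arm" %in% names(annotation)) stopf("annotation lacks an 'arm' column")
  arms <- arms %||% unique(annotation$arm)
  if (length(arms) != 2) stopf("exactly two arms are required")
  a1 <- annotation[annotation$arm == arms[1], category]
  a2 <- annotation[annotation$arm == arms[2], category]
  if (length(a1) == 0 || length(a2) == 0)
    stopf("arm '%s' has no cells", arms[which(c(length(a1), length(a2)) == 0)[1]])
  cats <- sort(unique(c(a1, a2)))
  p1 <- 100 * as.numeric(table(factor(a1, cats))) / length(a1)
  p2 <- 100 * as.numeric(table(factor(a2, cats))) / length(a2)
  data.frame(category = cats, pct_arm1 = p1, pct_arm2 = p2,
             delta_pct = p2 - p1, stringsAsFactors = FALSE)
}

#' Tabulate pass-filter cells per arm
#'
#' Small report-aggregation helper: per-arm cell counts and their total.
#'
#' @param annotation data frame with an `arm` column (one row per
#'   pass-filter cell).
#' @return a `data.frame` with columns `arm`, `n_cells`; the summed total is
#'   stored in `attr(, "total")` and appended as a `"total"` row.
#' @export
tabulate_arms <- function(annotation) {
  tab <- table(annotation$arm)
  out <- data.frame(arm = names(tab), n_cells = as.integer(tab),
                    stringsAsFactors = FALSE)
  total <- sum(out$n_cells)
  out <- rbind(out, data.frame(arm = "total", n_cells = total))
  attr(out, "total") <- total
  out
}

#' Bonferroni correction over all tested features
#'
#' @param p raw p-values.
#' @param m number of features tested (default `length(p)`); the correction
#'   multiplies by the full feature count, capped at 1.
#' @return corrected p-values.
#' @export
bonferroni_correct <- function(p, m = length(p)) pmin(1, p * m)

#' Classify volcano-plot records
#'
#' Up: `log2fc > fc_thresh` and `p_bonferroni < p_thresh`; down:
#' `log2fc < -fc_thresh` and `p_bonferroni < p_thresh`; otherwise ns.
#' Inequalities are strict, so boundary values are non-significant.
#'
#' @param records data frame with `gene`, `log2fc`, `p_bonferroni`.
#' @param fc_thresh log2 fold-change threshold (default 0.23).
#' @param p_thresh corrected p threshold (default 1e-8, reading the
#'   "10e-9" convention literally; set 1e-9 if the tighter reading is
#'   wanted).
#' @return `records` with an added `category` factor in
#'   `{"up", "down", "ns"}`.
#' @export
volcano_classify <- function(records, fc_thresh = 0.23, p_thresh = 1e-8) {
  cat_ <- rep("ns", nrow(records))
  sig <- records$p_bonferroni < p_thresh
  cat_[sig & records$log2fc > fc_thresh] <- "up"
  cat_[sig & records$log2fc < -fc_thresh] <- "down"
  records$category <- factor(cat_, levels = c("up", "down", "ns"))
  records
}

#' Rank-sum differential expression reference generator
#'
#' A simple per-gene Wilcoxon rank-sum comparison of log-normalized
#' expression between two arms with full-feature Bonferroni correction.
#' Meant to produce (log2fc, p) tables for synthetic-data tests of the
#' volcano classifier; it is not a model-based DE engine.
#'
#' @param x an `sc_counts` object with an `arm` column in `barcodes`.
#' @param arms length-2 character, reference arm first.
#' @param genes optional subset of genes to test (Bonferroni still uses the
#'   full feature count).
#' @return data frame: `gene`, `log2fc` (arm2 vs arm1, log2 of mean
#'   normalized-count ratio with a pseudocount), `p_raw`, `p_bonferroni`.
#' @export
rank_sum_de <- function(x, arms = NULL, genes = NULL) {
  arms <- arms %||% unique(stats::na.omit(x$barcodes$arm))
  if (length(arms) != 2) stopf("exactly two arms are required")
  norm <- normalize_log1p(x)
  in1 <- x$barcodes$arm[match(colnames(norm), x$barcodes$barcode)] == arms[1]
  in2 <- x$barcodes$arm[match(colnames(norm), x$barcodes$barcode)] == arms[2]
  genes <- genes %||% rownames(norm)
  m_features <- nrow(norm)
  res <- do.call(rbind, lapply(genes, function(g) {
    v1 <- as.numeric(norm[g, in1]); v2 <- as.numeric(norm[g, in2])
    p <- if (length(unique(c(v1, v2))) < 2) 1 else
      suppressWarnings(stats::wilcox.test(v2, v1)$p.value)
    lfc <- log2((mean(expm1(v2)) + 1) / (mean(expm1(v1)) + 1))
    data.frame(gene = g, log2fc = lfc, p_raw = p, stringsAsFactors = FALSE)
  }))
  res$p_bonferroni <- bonferroni_correct(res$p_raw, m = m_features)
  res
}
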