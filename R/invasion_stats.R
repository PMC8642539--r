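# Statistics on distance tables: per-organoid min-normalization, the
# reference-group third-quartile invasion threshold, invading-cell counts,
# stacked KDE depth profiles, and the group tests used on the figures
# (unpaired two-tailed t test; one-way ANOVA with Tukey HSD post-hoc).

#' Min-normalize distances per organoid
#'
#' Sets the minimum distance of each organoid to 0 (the figures' axis
#' convention); the raw column is retained.
#'
#' @param table a distance table with columns `organoid_id` and
#'   `distance_um`.
#' @return the table with an added `normalized_distance_um` column.
#' @export
normalize_distances <- function(table) {
  if (!all(c("organoid_id", "distance_um") %in% names(table)))
    stopf("distance table needs 'organoid_id' and 'distance_um' columns")
  if (nrow(table) == 0) {
    table$normalized_distance_um <- numeric(0)
    return(table)
  }
  mins <- tapply(table$distance_um, table$organoid_id, min)
  table$normalized_distance_um <-
    table$distance_um - as.numeric(mins[as.character(table$organoid_id)])
  table
}

#' Invasion threshold: mean reference-group third quartile
#'
#' For each organoid in the reference group, the third quartile (Q3,
#' linear-interpolation / type-7 quantile by default) of its normalized
#' distances is computed; the threshold is the unweighted mean of these Q3
#' values.
#'
#' @param table a distance table (normalized with [normalize_distances()]
#'   unless `use_normalized = FALSE`).
#' @param reference_group group label defining the threshold (e.g. the
#'   vehicle arm or the early timepoint).
#' @param use_normalized use `normalized_distance_um` (default) or raw
#'   `distance_um`.
#' @param quantile_type passed to [stats::quantile()] (default 7).
#' @return threshold in micrometres.
#' @export
invasion_threshold <- function(table, reference_group,
                               use_normalized = TRUE, quantile_type = 7) {
  col <- if (use_normalized) "normalized_distance_um" else "distance_um"
  if (use_normalized && !col %in% names(table))
    table <- normalize_distances(table)
  ref <- table[table$group == reference_group, , drop = FALSE]
  if (nrow(ref) == 0)
    stopf("reference group '%s' not found in the distance table", reference_group)
  q3 <- tapply(ref[[col]], droplevels(factor(ref$organoid_id)),
               stats::quantile, probs = 0.75, type = quantile_type,
               names = FALSE)
  mean(as.numeric(q3))
}

#' Count invading cells per organoid and group
#'
#' A cell is invading when its distance strictly exceeds the threshold.
#'
#' @param table a distance table with a `normalized_distance_um` column
#'   (added automatically if missing).
#' @param threshold invasion threshold in micrometres.
#' @param use_normalized count on normalized (default) or raw distances.
#' @return a `data.frame` with `organoid_id`, `group`, `n_cells`,
#'   `n_invading`.
#' @export
count_invading <- function(table, threshold, use_normalized = TRUE) {
  col <- if (use_normalized) "normalized_distance_um" else "distance_um"
  if (use_normalized && !col %in% names(table))
    table <- normalize_distances(table)
  sp <- split(table, paste(table$group, table$organoid_id, sep = "\r"))
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(organoid_id = d$organoid_id[1], group = d$group[1],
               n_cells = nrow(d),
               n_invading = sum(d[[col]] > threshold),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$group, out$organoid_id), , drop = FALSE]
}

#' Invasion summary for a distance table
#'
#' Bundles the reference-group threshold with per-organoid Q3 values,
#' cell counts and invading-cell counts.
#'
#' @inheritParams invasion_threshold
#' @return a list of class `invasion_summary`: `threshold_um`,
#'   `reference_group`, `per_organoid` data frame.
#' @export
invasion_summary <- function(table, reference_group,
                             use_normalized = TRUE, quantile_type = 7) {
  if (use_normalized && !"normalized_distance_um" %in% names(table))
    table <- normalize_distances(table)
  thr <- invasion_threshold(table, reference_group, use_normalized,
                            quantile_type)
  counts <- count_invading(table, thr, use_normalized)
  col <- if (use_normalized) "normalized_distance_um" else "distance_um"
  q3 <- vapply(seq_len(nrow(counts)), function(i) {
    d <- table[table$organoid_id == counts$organoid_id[i] &
               table$group == counts$group[i], col]
    stats::quantile(d, 0.75, type = quantile_type, names = FALSE)
  }, numeric(1))
  counts$q3_um <- q3
  structure(list(threshold_um = thr, reference_group = reference_group,
                 per_organoid = counts),
            class = "invasion_summary")
}

#' @export
print.invasion_summary <- function(x, ...) {
  cat(sprintf("invasion_summary: threshold %.4g um (mean Q3 of group '%s')\n",
              x$threshold_um, x$reference_group))
  print(x$per_organoid)
  invisible(x)
}

#' Per-organoid kernel density profiles of invasion depth
#'
#' Gaussian-kernel density of each organoid's distances, evaluated on a
#' shared grid and renormalized to unit trapezoid area so the curves can be
#' stacked.
#'
#' @param x numeric vector of distances, or a distance table (then one curve
#'   per organoid).
#' @param bandwidth `"scott"` (Scott's rule, [stats::bw.nrd()]) or a numeric
#'   bandwidth in micrometres.
#' @param n grid points.
#' @param use_normalized for tables, which column to profile.
#' @return a `data.frame` with columns `organoid_id` (absent for a plain
#'   vector), `x`, `density`.
#' @export
kde_profile <- function(x, bandwidth = "scott", n = 512,
                        use_normalized = TRUE) {
  if (is.data.frame(x)) {
    col <- if (use_normalized) "normalized_distance_um" else "distance_um"
    if (use_normalized && !col %in% names(x)) x <- normalize_distances(x)
    sp <- split(x[[col]], x$organoid_id)
    rng <- range(x[[col]])
    pad <- 3 * max(vapply(sp, function(v)
      if (length(unique(v)) > 1) stats::bw.nrd(v) else
        if (is.numeric(bandwidth)) bandwidth else 1, numeric(1)))
    out <- do.call(rbind, lapply(names(sp), function(id) {
      cv <- kde_curve(sp[[id]], bandwidth, n, from = rng[1] - pad,
                      to = rng[2] + pad)
      cbind(organoid_id = id, cv)
    }))
    rownames(out) <- NULL
    return(out)
  }
  kde_curve(x, bandwidth, n)
}

kde_curve <- function(v, bandwidth, n, from = NULL, to = NULL) {
  if (length(v) == 0) stopf("kde_profile: empty input")
  if (length(unique(v)) < 2) {
    if (!is.numeric(bandwidth))
      stopf("kde_profile: degenerate input (a single distinct value) needs a numeric bandwidth")
    h <- bandwidth
    from <- from %||% (min(v) - 4 * h); to <- to %||% (max(v) + 4 * h)
    g <- seq(from, to, length.out = n)
    dens <- stats::dnorm(g, mean = v[1], sd = h)
  } else {
    bw <- if (is.numeric(bandwidth)) bandwidth else stats::bw.nrd(v)
    from <- from %||% (min(v) - 3 * bw); to <- to %||% (max(v) + 3 * bw)
    kd <- stats::density(v, bw = bw, n = n, from = from, to = to)
    g <- kd$x; dens <- kd$y
  }
  area <- sum(diff(g) * (dens[-1] + dens[-length(dens)]) / 2)
  data.frame(x = g, density = dens / area)
}

#' Unpaired two-sample t test (two-tailed)
#'
#' Student's pooled-variance test by default (the captions say "t test"
#' without qualification); set `welch = TRUE` for the unequal-variance
#' variant. Identical constant groups return p = 1 with a `degenerate` flag.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param welch use the Welch variant.
#' @return a `group_result` list: `test`, `statistic`, `p_value`, `stars`,
#'   `degenerate`.
#' @export
compare_two_groups <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    stopf("both groups need n >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(structure(list(test = "t_two_sample", statistic = 0,
                            p_value = 1, stars = p_stars(1),
                            degenerate = TRUE),
                       class = "group_result"))
    }
    return(structure(list(test = "t_two_sample", statistic = Inf,
                          p_value = 0, stars = p_stars(0), degenerate = TRUE),
                     class = "group_result"))
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  structure(list(test = "t_two_sample",
                 statistic = unname(tt$statistic),
                 p_value = tt$p.value, stars = p_stars(tt$p.value),
                 degenerate = FALSE),
            class = "group_result")
}

#' One-way ANOVA with Tukey HSD post-hoc
#'
#' F statistic and p-value from the one-way decomposition of sums of
#' squares; per-pair adjusted p-values from the studentized-range
#' distribution with N - k error degrees of freedom (Tukey-Kramer for
#' unequal group sizes).
#'
#' @param groups a named list of numeric vectors (>= 2 groups, each n >= 2),
#'   or a numeric vector with `labels`.
#' @param labels optional group labels when `groups` is a vector.
#' @return a `group_result` list with `test = "anova_tukey"`, `statistic`
#'   (F), `p_value`, and `pairwise` data frame (`pair`, `mean_diff`,
#'   `adjusted_p`, `stars`).
#' @export
compare_multi_groups <- function(groups, labels = NULL) {
  if (!is.list(groups)) {
    if (is.null(labels)) stopf("supply a named list or values + labels")
    groups <- split(as.numeric(groups), labels)
  }
  k <- length(groups)
  if (k < 2) stopf("need >= 2 groups")
  n_i <- vapply(groups, length, integer(1))
  if (any(n_i < 2)) stopf("every group needs n >= 2")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  m_i <- vapply(groups, mean, numeric(1))
  gm <- mean(x)
  ssb <- sum(n_i * (m_i - gm)^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  df1 <- k - 1; df2 <- N - k
  mse <- ssw / df2
  f <- if (ssw == 0) {
    if (ssb == 0) 0 else Inf
  } else (ssb / df1) / mse
  p <- if (is.infinite(f)) 0 else if (f == 0 && ssw == 0) 1 else
    stats::pf(f, df1, df2, lower.tail = FALSE)

  pairs <- utils::combn(names(groups), 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    diff <- m_i[g2] - m_i[g1]
    se <- sqrt(mse / 2 * (1 / n_i[g1] + 1 / n_i[g2]))
    adj_p <- if (se == 0) {
      if (diff == 0) 1 else 0
    } else stats::ptukey(abs(diff) / se, nmeans = k, df = df2,
                         lower.tail = FALSE)
    data.frame(pair = paste(g2, g1, sep = "-"),
               mean_diff = unname(diff), adjusted_p = unname(adj_p),
               stars = p_stars(adj_p), stringsAsFactors = FALSE)
  }))
  structure(list(test = "anova_tukey", statistic = unname(f), p_value = p,
                 pairwise = pairwise),
            class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("group_result [%s]: statistic = %.4g, p = %.3g (%s)\n",
              x$test, x$statistic, x$p_value, p_stars(x$p_value)))
  if (!is.null(x$pairwise)) print(x$pairwise)
  invisible(x)
}

#' Plot stacked per-organoid KDE depth profiles
#'
#' Unit-area curves drawn cumulatively (each organoid's density stacked on
#' the previous), the usual presentation of invasion-depth profiles.
#'
#' @param kde a [kde_profile()] table with an `organoid_id` column.
#' @param path optional PNG path; NULL draws on the current device.
#' @param main plot title.
#' @return invisibly, the matrix of stacked curves.
#' @export
plot_kde_profiles <- function(kde, path = NULL, main = "Invasion depth") {
  ids <- unique(kde$organoid_id)
  g <- kde$x[kde$organoid_id == ids[1]]
  curves <- vapply(ids, function(id) kde$density[kde$organoid_id == id],
                   numeric(length(g)))
  stacked <- apply(curves, 1, cumsum)
  if (!is.null(path)) grDevices::png(path, width = 800, height = 500)
  cols <- grDevices::hcl.colors(length(ids), "Zissou 1", alpha = 0.6)
  plot(range(g), c(0, max(stacked)), type = "n",
       xlab = "normalized distance to organoid surface (um)",
       ylab = "stacked density", main = main)
  for (i in rev(seq_along(ids))) {
    ys <- if (length(ids) == 1) stacked else stacked[i, ]
    graphics::polygon(c(g, rev(g)), c(ys, rep(0, length(g))),
                      col = cols[i], border = NA)
  }
  if (!is.null(path)) grDevices::dev.off()
  invisible(stacked)
}
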