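# One-way permutational ANOVA machinery on Euclidean distances.
#
# The pseudo-F is computed from the partition of the squared Euclidean
# distance matrix: SS_total = sum_{i<j} d2_ij / N, SS_within summed per group
# with its own n_g, SS_among = SS_total - SS_within, and
# F = (SS_among / (a - 1)) / (SS_within / (N - a)). For univariate responses
# this equals the classical one-way ANOVA F exactly.

permanova_ss <- function(D2, idx_by_group) {
  N <- nrow(D2)
  ss_tot <- sum(D2) / (2 * N)
  ss_w <- 0
  for (idx in idx_by_group)
    ss_w <- ss_w + sum(D2[idx, idx]) / (2 * length(idx))
  c(among = ss_tot - ss_w, within = ss_w, total = ss_tot)
}

pseudo_f <- function(D2, groups) {
  idx <- split(seq_along(groups), groups)
  ss <- permanova_ss(D2, idx)
  a <- length(idx); N <- nrow(D2)
  (ss[["among"]] / (a - 1)) / (ss[["within"]] / (N - a))
}

# Enumerate all distinct assignments of N observations to groups of the given
# sizes; returns a list of index-vectors-per-group lists.
enumerate_assignments <- function(sizes) {
  recurse <- function(avail, sizes) {
    if (length(sizes) == 1L) return(list(list(avail)))
    # groups are labelled (fixed factor), so every choice of members counts
    picks <- combn(length(avail), sizes[1L])
    do.call(c, lapply(seq_len(ncol(picks)), function(j) {
      chosen <- avail[picks[, j]]
      lapply(recurse(avail[-picks[, j]], sizes[-1L]),
             function(r) c(list(chosen), r))
    }))
  }
  recurse(seq_len(sum(sizes)), sizes)
}

n_arrangements <- function(sizes) {
  exp(lfactorial(sum(sizes)) - sum(lfactorial(sizes)))
}

#' One-way PERMANOVA on Euclidean distances
#'
#' Permutational analysis of variance for a single fixed factor, on the
#' Euclidean distance matrix of a univariate or multivariate response. The
#' pseudo-F partitions among- versus within-group sums of squared distances
#' with the usual degrees of freedom; for a univariate response it equals the
#' classical one-way ANOVA F. Significance is assessed by unrestricted
#' permutation of observations: when the number of distinct group assignments
#' is at most `exhaustive_limit` the full set is enumerated and
#' `p = #(F_perm >= F_obs) / #arrangements` (the identity included);
#' otherwise `n_permutations` random permutations are drawn and
#' `p = (#(F_perm >= F_obs) + 1) / (n_permutations + 1)`, which keeps p above
#' zero and makes the observed statistic part of its own reference set.
#'
#' @param y numeric vector, or matrix with one observation per row.
#' @param groups factor (or coercible) of group labels; at least two groups,
#'   each with at least two observations.
#' @param n_permutations random permutations when exhaustive enumeration is
#'   not used (default 9999).
#' @param seed integer seed making the permutation p-value reproducible.
#' @param exhaustive_limit enumerate all arrangements when their count is at
#'   most this (default 10000).
#' @param pairwise also run all two-group comparisons, reporting the pseudo-t
#'   (square root of the two-group pseudo-F) and its permutation p-value.
#' @param p_adjust_method multiplicity correction for the pairwise p-values
#'   (default `"none"`, matching uncorrected reporting; any
#'   [stats::p.adjust()] method).
#' @return Object of class `"permanova"`: `statistic` (pseudo-F), `df`,
#'   `ss` (among/within/total), `p_value`, `n_permutations` (arrangements
#'   actually used), `exhaustive`, and a `pairwise` data.frame.
#' @seealso [permdisp()]
#' @export
permanova_oneway <- function(y, groups, n_permutations = 9999, seed = NULL,
                             exhaustive_limit = 10000, pairwise = TRUE,
                             p_adjust_method = "none") {
  y <- as.matrix(y)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop("need at least two groups", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 2L))
    stop("group(s) of size 1 cannot be tested: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  if (nrow(y) != length(groups)) stop("response/group length mismatch")
  D2 <- as.matrix(dist(y))^2
  if (sum(D2) < 1e-24) {
    # all observations identical: no variation to partition
    return(structure(list(statistic = 0, df = c(among = nlevels(groups) - 1L,
                                                within = length(groups) -
                                                  nlevels(groups)),
                          ss = c(among = 0, within = 0, total = 0),
                          p_value = 1, n_permutations = 0L,
                          exhaustive = FALSE, degenerate = TRUE,
                          pairwise = NULL, seed = seed),
                     class = "permanova"))
  }
  f_obs <- pseudo_f(D2, groups)
  # a perfectly separated grouping gives SS_within = 0 and a legitimate
  # infinite pseudo-F; compare without tolerance then
  tol <- if (is.finite(f_obs)) 1e-12 * max(1, abs(f_obs)) else 0

  n_arr <- n_arrangements(as.integer(sizes))
  exhaustive <- is.finite(n_arr) && n_arr <= exhaustive_limit
  if (exhaustive) {
    assigns <- enumerate_assignments(as.integer(sizes))
    f_perm <- vapply(assigns, function(a) {
      ss <- permanova_ss(D2, a)
      (ss[["among"]] / (length(a) - 1)) / (ss[["within"]] / (nrow(D2) - length(a)))
    }, 0)
    p <- sum(f_perm >= f_obs - tol) / length(f_perm)
    n_used <- length(f_perm)
  } else {
    n_used <- n_permutations
    f_perm <- with_seed(seed, {
      vapply(seq_len(n_permutations), function(i) {
        pseudo_f(D2, groups[sample.int(length(groups))])
      }, 0)
    })
    p <- (sum(f_perm >= f_obs - tol) + 1) / (n_permutations + 1)
  }

  pw <- NULL
  if (pairwise && nlevels(groups) > 2L) {
    combos <- combn(levels(groups), 2L)
    pw <- do.call(rbind, lapply(seq_len(ncol(combos)), function(j) {
      sel <- groups %in% combos[, j]
      sub <- permanova_oneway(y[sel, , drop = FALSE], groups[sel],
                              n_permutations = n_permutations,
                              seed = derive_seed(seed, j),
                              exhaustive_limit = exhaustive_limit,
                              pairwise = FALSE)
      data.frame(group1 = combos[1L, j], group2 = combos[2L, j],
                 pseudo_t = sqrt(sub$statistic), pseudo_F = sub$statistic,
                 p = sub$p_value, n_permutations = sub$n_permutations,
                 exhaustive = sub$exhaustive)
    }))
    pw$p_adjusted <- stats::p.adjust(pw$p, method = p_adjust_method)
  }

  structure(list(statistic = unname(f_obs),
                 df = c(among = nlevels(groups) - 1L,
                        within = length(groups) - nlevels(groups)),
                 ss = permanova_ss(D2, split(seq_along(groups), groups)),
                 p_value = unname(p), n_permutations = n_used,
                 exhaustive = exhaustive, degenerate = FALSE, pairwise = pw,
                 seed = seed),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("One-way PERMANOVA (Euclidean distances)\n")
  if (isTRUE(x$degenerate)) {
    cat("  degenerate: all observations identical; F = 0, p = 1\n")
    return(invisible(x))
  }
  cat(sprintf("  pseudo-F = %.4g on df %d, %d;  p(perm) = %.4g  (%s, %d %s)\n",
              x$statistic, x$df[1L], x$df[2L], x$p_value,
              if (x$exhaustive) "exhaustive" else "sampled",
              x$n_permutations,
              if (x$exhaustive) "arrangements" else "permutations"))
  if (!is.null(x$pairwise)) {
    cat("  pairwise (pseudo-t, uncorrected p unless adjusted):\n")
    print(x$pairwise, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' PERMDISP: permutation test of homogeneity of dispersions
#'
#' Computes each observation's Euclidean distance to its group centroid and
#' tests group differences in those distances with the one-way pseudo-F (for
#' univariate distances, the classical ANOVA F), with significance by
#' permutation of the distance values across groups. When all distances are
#' (numerically) identical the test is degenerate: F is reported as 0 with
#' p = 1 and `degenerate = TRUE`.
#'
#' @inheritParams permanova_oneway
#' @return Object of class `"permdisp"`: `statistic` (dispersion F),
#'   `p_value`, `distances`, `group_means` (mean distance-to-centroid per
#'   group), `degenerate`, `n_permutations`, `exhaustive`, and optionally a
#'   `pairwise` table.
#' @export
permdisp <- function(y, groups, n_permutations = 9999, seed = NULL,
                     exhaustive_limit = 10000, pairwise = FALSE) {
  y <- as.matrix(y)
  groups <- droplevels(as.factor(groups))
  sizes <- table(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(sizes < 2L))
    stop("group(s) of size 1 cannot be tested: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  cent <- apply(y, 2L, function(col) tapply(col, groups, mean))
  cent <- matrix(cent, nrow = nlevels(groups))
  dists <- sqrt(rowSums((y - cent[as.integer(groups), , drop = FALSE])^2))
  gmean <- tapply(dists, groups, mean)
  gmean <- setNames(as.numeric(gmean), names(gmean))
  if (max(dists) - min(dists) < 1e-12 * max(1, max(abs(dists)))) {
    return(structure(list(statistic = 0, p_value = 1, distances = dists,
                          group_means = gmean,
                          degenerate = TRUE, n_permutations = 0L,
                          exhaustive = FALSE, pairwise = NULL),
                     class = "permdisp"))
  }
  pm <- permanova_oneway(dists, groups, n_permutations = n_permutations,
                         seed = seed, exhaustive_limit = exhaustive_limit,
                         pairwise = FALSE)
  pw <- NULL
  if (pairwise && nlevels(groups) > 2L) {
    combos <- combn(levels(groups), 2L)
    pw <- do.call(rbind, lapply(seq_len(ncol(combos)), function(j) {
      sel <- groups %in% combos[, j]
      sub <- permdisp(y[sel, , drop = FALSE], groups[sel],
                      n_permutations = n_permutations,
                      seed = derive_seed(seed, 100 + j),
                      exhaustive_limit = exhaustive_limit)
      data.frame(group1 = combos[1L, j], group2 = combos[2L, j],
                 dispersion_F = sub$statistic, p = sub$p_value)
    }))
  }
  structure(list(statistic = pm$statistic, p_value = pm$p_value,
                 distances = dists, group_means = gmean,
                 degenerate = FALSE, n_permutations = pm$n_permutations,
                 exhaustive = pm$exhaustive, pairwise = pw),
            class = "permdisp")
}

#' @export
print.permdisp <- function(x, ...) {
  cat("PERMDISP (distances to group centroids)\n")
  if (x$degenerate) {
    cat("  degenerate: all distances identical; F = 0, p = 1\n")
  } else {
    cat(sprintf("  F = %.4g;  p(perm) = %.4g  (%d %s)\n", x$statistic,
                x$p_value, x$n_permutations,
                if (x$exhaustive) "arrangements" else "permutations"))
  }
  invisible(x)
}

#' Normalize profile variables across stations
#'
#' Centers each depth-bin variable to mean 0 and scales it to unit SD across
#' stations (the usual normalization before a multivariate analysis mixing
#' scales). Variables with zero SD carry no information and are dropped with a
#' warning; the count of dropped columns is kept as an attribute.
#'
#' @param m numeric matrix, stations in rows, depth-bin variables in columns.
#' @return The normalized matrix (possibly fewer columns), with attribute
#'   `dropped` naming removed zero-variance columns.
#' @export
normalize_profiles <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least two stations", call. = FALSE)
  sds <- apply(m, 2L, sd)
  drop <- !is.finite(sds) | sds == 0
  if (any(drop))
    warning(sum(drop), " zero-variance profile column(s) dropped",
            call. = FALSE)
  out <- scale(m[, !drop, drop = FALSE])
  attr(out, "dropped") <- colnames(m)[drop] %||% which(drop)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Aggregate per-image SPI measurements to station scale
#'
#' Station-scale averages and standard deviations (sample SD, n - 1
#' denominator) of the univariate metrics and of each 5 mm profile bin, the SD
#' serving as a proxy for within-station spatial heterogeneity. Images whose
#' live/dead ratio is undefined (no dead maerl) are excluded from the ratio
#' mean/SD with their count logged in the output.
#'
#' @param image_metrics data.frame with one row per image: `station`,
#'   `rugosity`, `penetration_cm`, `live_dead_ratio`, `ratio_defined`.
#' @param image_profiles data.frame with one row per image x bin: `station`,
#'   `image`, `depth_from_cm`, `pct_live`, `pct_dead`, `pct_interstice`.
#' @param station_table data.frame: `station`, `pressure` (times fully
#'   dredged) and optionally `group` (else derived with [assign_groups()]).
#' @param max_depth_cm profile depth window retained (default 10, i.e. 20
#'   bins at 5 mm).
#' @param bin_cm profile bin size (default 0.5).
#' @return Object of class `"station_summary"`: `metrics` (one row per
#'   station: group, pressure, n_images, mean and sd of rugosity,
#'   penetration, ratio, and `n_ratio_excluded`), and `profiles`, a list with
#'   `mean` and `sd` sub-lists of station x bin matrices for `live`, `dead`
#'   and `interstice`. Stations with fewer than two images are dropped from
#'   SD columns (NA) and flagged.
#' @export
aggregate_stations <- function(image_metrics, image_profiles, station_table,
                               max_depth_cm = 10, bin_cm = 0.5) {
  stopifnot(all(c("station", "pressure") %in% names(station_table)))
  if (is.null(station_table$group)) {
    station_table$group <- assign_groups(station_table$pressure)
  } else if (!is.factor(station_table$group) &&
             all(station_table$group %in% c("Control", "Moderate", "High"))) {
    station_table$group <- factor(station_table$group,
                                  levels = c("Control", "Moderate", "High"))
  }
  stations <- station_table$station

  msd <- function(v) {
    v <- v[!is.na(v)]
    c(mean = if (length(v)) mean(v) else NA_real_,
      sd = if (length(v) > 1L) sd(v) else NA_real_)
  }
  metrics <- do.call(rbind, lapply(stations, function(s) {
    d <- image_metrics[image_metrics$station == s, , drop = FALSE]
    r <- d$live_dead_ratio[d$ratio_defined]
    rug <- msd(d$rugosity); pen <- msd(d$penetration_cm); rat <- msd(r)
    data.frame(station = s, n_images = nrow(d),
               rugosity_mean = rug[1L], rugosity_sd = rug[2L],
               penetration_mean = pen[1L], penetration_sd = pen[2L],
               ratio_mean = rat[1L], ratio_sd = rat[2L],
               n_ratio_excluded = sum(!d$ratio_defined))
  }))
  metrics <- merge(station_table[, c("station", "pressure", "group")], metrics,
                   by = "station", sort = FALSE)

  n_bins <- round(max_depth_cm / bin_cm)
  depth_bins <- (seq_len(n_bins) - 1L) * bin_cm
  prof_mats <- function(col, fun) {
    m <- matrix(NA_real_, length(stations), n_bins,
                dimnames = list(as.character(stations),
                                sprintf("d%.1fcm", depth_bins)))
    for (si in seq_along(stations)) {
      d <- image_profiles[image_profiles$station == stations[si], ]
      for (bi in seq_len(n_bins)) {
        v <- d[[col]][abs(d$depth_from_cm - depth_bins[bi]) < bin_cm / 2]
        v <- v[!is.na(v)]
        m[si, bi] <- if (fun == "mean" && length(v)) mean(v)
          else if (fun == "sd" && length(v) > 1L) sd(v) else NA_real_
      }
    }
    m
  }
  profiles <- list(
    mean = list(live = prof_mats("pct_live", "mean"),
                dead = prof_mats("pct_dead", "mean"),
                interstice = prof_mats("pct_interstice", "mean")),
    sd = list(live = prof_mats("pct_live", "sd"),
              dead = prof_mats("pct_dead", "sd"),
              interstice = prof_mats("pct_interstice", "sd")))
  structure(list(metrics = metrics, profiles = profiles,
                 bin_cm = bin_cm, max_depth_cm = max_depth_cm),
            class = "station_summary")
}

#' @export
print.station_summary <- function(x, ...) {
  cat(sprintf("station summary: %d stations, %d profile bins (0-%g cm)\n",
              nrow(x$metrics), ncol(x$profiles$mean$live), x$max_depth_cm))
  print(head(x$metrics, 10), digits = 3, row.names = FALSE)
  if (nrow(x$metrics) > 10) cat("  ...\n")
  invisible(x)
}
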