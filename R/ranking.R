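# Tournament ranking: two-round z-scores with outlier exclusion, the
# weighted composite score, cumulative group ranking, best-model counts,
# enrichment testing and heatmap ordering.

# Metric orientations in the composite: these three are "lower is better"
# and are negated before z-scoring.
LOWER_BETTER <- c("clash", "sidechain_dev", "backbone_dev")

#' Two-round z-scores with outlier exclusion
#'
#' Lower-is-better values are negated first. Round 1 computes z-scores from
#' the mean and population standard deviation over all values; values with
#' z below -2 are excluded as outliers, the statistics are recomputed over
#' the survivors, and final z-scores are assigned to all entries (including
#' the excluded ones) from the recomputed statistics. A zero standard
#' deviation yields all-zero z-scores.
#'
#' @param raw Named numeric vector (one value per group).
#' @param orientation `"higher"` or `"lower"` (is better).
#' @param outlier_cut Round-1 exclusion threshold, default -2.
#' @return Named z-score vector over all input groups.
#' @export
two_round_z <- function(raw, orientation = c("higher", "lower"),
                        outlier_cut = mc_defaults()$z_outlier_cut) {
  orientation <- match.arg(orientation)
  v <- as.numeric(raw)
  names(v) <- names(raw)
  if (sum(!is.na(v)) < 2) {
    warning("fewer than 2 values; all z set to 0")
    return(setNames(rep(0, length(v)), names(v)))
  }
  if (orientation == "lower") v <- -v
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  ok <- !is.na(v)
  s1 <- pop_sd(v[ok])
  z1 <- if (s1 > 0) (v - mean(v[ok])) / s1 else rep(0, length(v))
  keep <- ok & !(z1 < outlier_cut)
  s2 <- pop_sd(v[keep])
  z2 <- if (s2 > 0) (v - mean(v[keep])) / s2 else rep(0, length(v))
  z2[!ok] <- NA
  setNames(z2, names(raw))
}

#' Weighted composite score from per-metric z-scores
#'
#' S = (1/16)(z_LDDT + z_CADaa + z_SG + z_sidechain)
#'   + (1/12)(z_clash + z_backbone + z_DipDiff)
#'   + (1/4)(z_GDT_HA + z_ASE [+ z_reLLG]).
#' All component z-scores are already oriented (higher = better). Missing
#' components contribute 0 with a warning; the weights are not
#' renormalised, so the 10-metric total weight is 1.25 and the 9-metric
#' total 1.
#'
#' @param z Named numeric vector with names among `lddt`, `cad_aa`, `sg`,
#'   `sidechain_dev`, `clash`, `backbone_dev`, `dipdiff`, `gdt_ha`, `ase`,
#'   `rellg`.
#' @param include_rellg Include the reLLG term (requires `z["rellg"]`).
#' @return The composite score S.
#' @export
composite <- function(z, include_rellg = FALSE) {
  w <- mc_defaults()$composite_weights
  g1 <- c("lddt", "cad_aa", "sg", "sidechain_dev")
  g2 <- c("clash", "backbone_dev", "dipdiff")
  g3 <- c("gdt_ha", "ase")
  if (include_rellg) g3 <- c(g3, "rellg")
  need <- c(g1, g2, g3)
  miss <- setdiff(need, names(z)[!is.na(z)])
  if (length(miss)) {
    warning("missing metric z-scores set to 0: ", paste(miss, collapse = ", "))
    z[miss] <- 0
  }
  z[is.na(z)] <- 0
  unname(w["group1"] * sum(z[g1]) + w["group2"] * sum(z[g2]) +
         w["group3"] * sum(z[g3]))
}

#' Per-EU z-scores and composites for a long-form score table
#'
#' Applies [two_round_z()] per EU and metric (over each group's model-1
#' value) and combines the z-scores into the composite S per group and EU.
#'
#' @param scores Long-form data frame `eu_id, group, metric, value`
#'   (model-1 values).
#' @param include_rellg Passed to [composite()].
#' @return Data frame `eu_id, group, S` plus a `z` attribute with the
#'   per-metric z tables.
#' @export
eu_composites <- function(scores, include_rellg = FALSE) {
  stopifnot(all(c("eu_id", "group", "metric", "value") %in% names(scores)))
  out <- list()
  ztabs <- list()
  for (e in unique(scores$eu_id)) {
    se <- scores[scores$eu_id == e, , drop = FALSE]
    groups <- unique(se$group)
    zmat <- matrix(NA_real_, length(groups), 0, dimnames = list(groups, NULL))
    for (m in unique(se$metric)) {
      sm <- se[se$metric == m, , drop = FALSE]
      raw <- setNames(rep(NA_real_, length(groups)), groups)
      raw[sm$group] <- sm$value
      zc <- suppressWarnings(two_round_z(
        raw, orientation = if (m %in% LOWER_BETTER) "lower" else "higher"))
      zmat <- cbind(zmat, setNames(data.frame(zc), m)[[1]])
      colnames(zmat)[ncol(zmat)] <- m
    }
    ztabs[[e]] <- zmat
    S <- vapply(groups, function(g) {
      suppressWarnings(composite(zmat[g, ], include_rellg = include_rellg))
    }, numeric(1))
    out[[e]] <- data.frame(eu_id = e, group = groups, S = S,
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  attr(res, "z") <- ztabs
  res
}

#' Cumulative group ranking from per-EU composite scores
#'
#' Each group's total is the sum over EUs of max(S, 0): only positive
#' contributions count, so one disastrous model cannot erase good work
#' elsewhere. Groups attempting fewer than `min_eus` EUs are dropped.
#' Ties share the better rank.
#'
#' @param composites Data frame `eu_id, group, S` (missing rows = not
#'   attempted).
#' @param min_eus Participation threshold, default 10.
#' @return `mc_ranking` data frame: group, n_eus, total, rank.
#' @export
rank_groups <- function(composites, min_eus = mc_defaults()$min_eus) {
  stopifnot(all(c("eu_id", "group", "S") %in% names(composites)))
  if (!nrow(composites)) stop("empty score table")
  ok <- !is.na(composites$S)
  composites <- composites[ok, , drop = FALSE]
  tot <- tapply(pmax(composites$S, 0), composites$group, sum)
  n_eus <- tapply(composites$eu_id, composites$group, function(x) length(unique(x)))
  out <- data.frame(group = names(tot), n_eus = as.integer(n_eus[names(tot)]),
                    total = as.numeric(tot), stringsAsFactors = FALSE)
  out <- out[out$n_eus >= min_eus, , drop = FALSE]
  if (!nrow(out)) stop("no group passes the participation threshold")
  out <- out[order(-out$total), , drop = FALSE]
  out$rank <- rank(-out$total, ties.method = "min")
  rownames(out) <- NULL
  class(out) <- c("mc_ranking", "data.frame")
  out
}

#' Best-model counts per group
#'
#' For each EU the strictly best score earns one count; ties split the
#' credit 1/k among the tied groups.
#'
#' @param scores Data frame `eu_id, group, value` (one row per group and
#'   EU; higher is better).
#' @return Named numeric vector of counts per group (sums to the EU count).
#' @export
best_model_counts <- function(scores) {
  stopifnot(all(c("eu_id", "group", "value") %in% names(scores)))
  counts <- setNames(rep(0, length(unique(scores$group))), unique(scores$group))
  for (e in unique(scores$eu_id)) {
    se <- scores[scores$eu_id == e & !is.na(scores$value), , drop = FALSE]
    if (!nrow(se)) next
    best <- se$group[se$value == max(se$value)]
    counts[best] <- counts[best] + 1 / length(best)
  }
  counts
}

#' Fisher's exact test (two-sided) by hypergeometric enumeration
#'
#' Enumerates all 2x2 tables with the observed margins and sums the
#' probabilities of tables no more likely than the observed one.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_enrichment <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0), all(tab == round(tab)))
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  k_obs <- tab[1, 1]
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(ks, c1, n - c1, r1)
  p_obs <- stats::dhyper(k_obs, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Ward clustering order for score heatmaps
#'
#' Missing entries are imputed by column means for the distance computation
#' only; all-missing rows or columns are dropped with a warning. Ward
#' linkage on Euclidean distances gives row and column leaf orders for
#' heatmap layout.
#'
#' @param mat Numeric matrix (e.g. groups x EUs of GDT_TS), may contain NA.
#' @return List: `row_order`, `col_order`, `row_linkage`, `col_linkage`
#'   (hclust objects or NULL when a dimension has fewer than 2 entries).
#' @export
ward_order <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 1 || ncol(mat) < 1) stop("need at least one row and column")
  bad_row <- rowSums(!is.na(mat)) == 0
  bad_col <- colSums(!is.na(mat)) == 0
  if (any(bad_row) || any(bad_col)) {
    warning("dropping all-missing rows/columns")
    mat <- mat[!bad_row, !bad_col, drop = FALSE]
  }
  imp <- mat
  for (j in seq_len(ncol(imp))) {
    cm <- mean(imp[, j], na.rm = TRUE)
    imp[is.na(imp[, j]), j] <- cm
  }
  cluster_dim <- function(m) {
    if (nrow(m) < 2) return(list(order = seq_len(nrow(m)), linkage = NULL))
    hc <- stats::hclust(stats::dist(m), method = "ward.D2")
    list(order = hc$order, linkage = hc)
  }
  rows <- cluster_dim(imp)
  cols <- cluster_dim(t(imp))
  list(row_order = rows$order, col_order = cols$order,
       row_linkage = rows$linkage, col_linkage = cols$linkage)
}
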