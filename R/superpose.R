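# Rigid superposition metrics: GDT_TS / GDT_HA via a seeded iterative
# inlier search, and per-residue sequence-dependent distances under the
# 4 A superposition that feed the local-error analyses.

# Matched Calpha coordinate pairs of a correspondence map, in target order.
matched_ca <- function(map) {
  tt <- residue_table(map$target)
  mt <- residue_table(map$model)
  ti <- tt$ca[match(map$pairs$t_key, tt$key)]
  mi <- mt$ca[match(map$pairs$m_key, mt$key)]
  ok <- !is.na(ti) & !is.na(mi)
  list(t = atom_xyz(map$target, ti[ok]), m = atom_xyz(map$model, mi[ok]),
       keys = map$pairs$t_key[ok])
}

# Maximal-inlier search at one distance threshold: superpositions seeded
# from every contiguous window of lengths 3, 5, 7 and the full chain, each
# iterated {fit on inliers -> recompute inliers} to a fixed point. Short
# chains (<= 12 residues) additionally seed from every residue triple,
# which makes the search exact with respect to triple seeding there.
# Returns the best inlier set (ties broken by lower inlier RMSD).
gdt_search <- function(txyz, mxyz, threshold, max_iter = 20) {
  n <- nrow(txyz)
  seeds <- list(seq_len(n))
  for (w in c(3, 5, 7)) {
    if (n >= w) for (s in seq_len(n - w + 1)) seeds[[length(seeds) + 1]] <- s:(s + w - 1)
  }
  if (n <= 12) {
    tri <- utils::combn(n, 3)
    for (ci in seq_len(ncol(tri))) seeds[[length(seeds) + 1]] <- tri[, ci]
  }
  best <- list(count = -1L, rmsd = Inf, sup = NULL, inliers = integer(0))
  for (seed in seeds) {
    inliers <- seed
    prev <- integer(0)
    for (it in seq_len(max_iter)) {
      if (length(inliers) < 3) break
      sup <- tryCatch(kabsch(txyz[inliers, , drop = FALSE],
                             mxyz[inliers, , drop = FALSE]),
                      error = function(e) NULL)
      if (is.null(sup)) break
      d <- sqrt(rowSums((apply_superposition(sup, mxyz) - txyz)^2))
      new_in <- which(d <= threshold)
      if (length(new_in) >= 3) {
        fit_sup <- tryCatch(kabsch(txyz[new_in, , drop = FALSE],
                                   mxyz[new_in, , drop = FALSE]),
                            error = function(e) NULL)
        if (is.null(fit_sup)) fit_sup <- sup  # collinear inliers: keep seed fit
        dd <- sqrt(rowSums((apply_superposition(fit_sup, mxyz) - txyz)^2))
        r_in <- sqrt(mean(dd[new_in]^2))
        if (length(new_in) > best$count ||
            (length(new_in) == best$count && r_in < best$rmsd)) {
          best <- list(count = length(new_in), rmsd = r_in, sup = fit_sup,
                       inliers = new_in)
        }
      }
      if (identical(new_in, inliers) || identical(new_in, prev) ||
          length(new_in) < 3) break
      prev <- inliers
      inliers <- new_in
    }
  }
  if (best$count < 0) {
    # no threshold-satisfying triple: fall back to the global fit, 0 inliers
    sup <- kabsch(txyz, mxyz)
    best <- list(count = 0L, rmsd = sup$rmsd, sup = sup, inliers = integer(0))
  }
  best
}

#' Global Distance Test score
#'
#' GDT_TS (thresholds 1, 2, 4, 8 A) or GDT_HA (0.5, 1, 2, 4 A): for each
#' threshold the maximal fraction of Calpha pairs simultaneously
#' superposable within it, averaged and scaled to 0-100. The denominator is
#' the number of target residues in the map's frame, so unmatched target
#' residues count as failures. The superposition found at the 4 A threshold
#' is kept as the final superposition and yields per-residue distances.
#'
#' @param map An `mc_map` (at least 3 matched Calpha pairs).
#' @param mode `"TS"` or `"HA"`.
#' @return `mc_gdt` object: `score` (0-100), `per_threshold_fraction`,
#'   `final_superposition`, `residue_distances` (named by target residue
#'   key; `NA` for unmatched residues).
#' @export
gdt <- function(map, mode = c("TS", "HA")) {
  mode <- match.arg(mode)
  thresholds <- if (mode == "TS") mc_defaults()$gdt_ts_thresholds
                else mc_defaults()$gdt_ha_thresholds
  ca <- matched_ca(map)
  if (nrow(ca$t) < 3) stop("gdt needs at least 3 matched Calpha pairs")
  n_frame <- length(map$frame_keys)
  fr <- numeric(length(thresholds))
  names(fr) <- as.character(thresholds)
  final <- NULL
  for (i in seq_along(thresholds)) {
    res <- gdt_search(ca$t, ca$m, thresholds[i])
    fr[i] <- res$count / n_frame
    if (thresholds[i] == 4) final <- res$sup
  }
  if (is.null(final)) final <- gdt_search(ca$t, ca$m, 4)$sup
  d <- sqrt(rowSums((apply_superposition(final, ca$m) - ca$t)^2))
  rd <- rep(NA_real_, n_frame)
  names(rd) <- map$frame_keys
  rd[ca$keys] <- d
  structure(list(mode = mode, per_threshold_fraction = fr,
                 score = 100 * mean(fr), final_superposition = final,
                 residue_distances = rd),
            class = "mc_gdt")
}

#' @export
print.mc_gdt <- function(x, ...) {
  cat(sprintf("<GDT_%s = %.2f | fractions: %s>\n", x$mode, x$score,
              paste(sprintf("%sA %.2f", names(x$per_threshold_fraction),
                            x$per_threshold_fraction), collapse = ", ")))
  invisible(x)
}

#' Per-residue sequence-dependent superposition distances
#'
#' Calpha-Calpha distance per target residue under the superposition that
#' maximises the number of pairs within 4 A (the GDT search at that
#' threshold); unmatched residues are `NA`. These distances drive the
#' error-region and B-factor analyses.
#'
#' @param map An `mc_map`.
#' @return Named numeric vector over the map's target frame.
#' @export
lga_distances <- function(map) {
  gdt(map, "TS")$residue_distances
}
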