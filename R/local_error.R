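# Local error versus structural context: crystal symmetry-mate expansion,
# residue/region interface labelling, error-region detection from rolling
# superposition distances, and B-factor error binning.

# Orthogonalisation matrix of a unit cell (a along x, b in the xy plane).
orth_matrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; c_ <- cell[3]
  al <- deg2rad(cell[4]); be <- deg2rad(cell[5]); ga <- deg2rad(cell[6])
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
            2 * cos(al) * cos(be) * cos(ga))
  matrix(c(a, b * cos(ga), c_ * cos(be),
           0, b * sin(ga), c_ * (cos(al) - cos(be) * cos(ga)) / sin(ga),
           0, 0, c_ * v / sin(ga)), 3, 3, byrow = TRUE)
}

# Tabulated space-group operators (fractional rotation | translation).
# Unknown symbols fall back to the identity with a warning.
SG_OPS <- list(
  "P 1" = list(list(R = diag(3), t = c(0, 0, 0))),
  "P 1 21 1" = list(
    list(R = diag(3), t = c(0, 0, 0)),
    list(R = diag(c(-1, 1, -1)), t = c(0, 0.5, 0))),
  "P 21 21 21" = list(
    list(R = diag(3), t = c(0, 0, 0)),
    list(R = diag(c(-1, -1, 1)), t = c(0.5, 0, 0.5)),
    list(R = diag(c(-1, 1, -1)), t = c(0, 0.5, 0.5)),
    list(R = diag(c(1, -1, -1)), t = c(0.5, 0.5, 0))),
  "C 1 2 1" = list(
    list(R = diag(3), t = c(0, 0, 0)),
    list(R = diag(c(-1, 1, -1)), t = c(0, 0, 0)),
    list(R = diag(3), t = c(0.5, 0.5, 0)),
    list(R = diag(c(-1, 1, -1)), t = c(0.5, 0.5, 0)))
)
SG_OPS[["P 21"]] <- SG_OPS[["P 1 21 1"]]
SG_OPS[["C 2"]] <- SG_OPS[["C 1 2 1"]]

#' Expand a crystal structure into neighbouring symmetry mates
#'
#' Applies the space-group operators combined with unit-cell translations
#' in {-1, 0, 1}^3 and keeps every non-identity copy with any atom within
#' `radius` of the asymmetric unit.
#'
#' @param target An `mc_structure` with cell and space group.
#' @param radius Retention distance (A), default 10.
#' @return List of `mc_structure` symmetry mates (possibly empty).
#' @export
expand_lattice <- function(target, radius = mc_defaults()$context_radius) {
  if (is.null(target$cell)) {
    warning("no crystal cell; lattice context unavailable")
    return(list())
  }
  sg <- target$space_group %||% "P 1"
  ops <- SG_OPS[[sg]]
  if (is.null(ops)) {
    warning("space group '", sg, "' not tabulated; using identity operator only")
    ops <- SG_OPS[["P 1"]]
  }
  om <- orth_matrix(target$cell)
  omi <- solve(om)
  xyz <- atom_xyz(target)
  frac <- t(omi %*% t(xyz))
  mates <- list()
  shifts <- expand.grid(-1:1, -1:1, -1:1)
  for (oi in seq_along(ops)) {
    op <- ops[[oi]]
    f1 <- sweep(frac %*% t(op$R), 2, op$t, "+")
    for (s in seq_len(nrow(shifts))) {
      sh <- as.numeric(shifts[s, ])
      if (oi == 1 && all(sh == 0)) next  # identity copy
      f2 <- sweep(f1, 2, sh, "+")
      x2 <- t(om %*% t(f2))
      if (fields_mindist2(xyz, x2) <= radius^2) {
        mate <- target
        mate$atoms[, c("x", "y", "z")] <- x2
        mate$id <- sprintf("%s_sym%d_%d%d%d", target$id, oi, sh[1], sh[2], sh[3])
        mates[[length(mates) + 1]] <- mate
      }
    }
  }
  mates
}

# Calpha coordinates and keys of a structure.
ca_coords <- function(x) {
  rt <- residue_table(x)
  ok <- !is.na(rt$ca)
  list(xyz = atom_xyz(x, rt$ca[ok]), keys = rt$key[ok],
       chain = rt$chain[ok], resno = rt$resno[ok])
}

count_within <- function(from_xyz, to_xyz, radius) {
  if (is.null(to_xyz) || !nrow(to_xyz)) return(rep(0L, nrow(from_xyz)))
  d2 <- outer(rowSums(from_xyz^2), rowSums(to_xyz^2), "+") -
    2 * from_xyz %*% t(to_xyz)
  rowSums(d2 <= radius^2 + 1e-9)
}

#' Structural context of each target residue
#'
#' Counts, per residue, the Calpha neighbours within 10 A that belong to a
#' symmetry mate, another chain, or (when domain ranges are supplied) a
#' different domain. A residue is labelled `lattice` with at least 3 such
#' lattice contacts, else `chain`, else `domain`, else `none`.
#'
#' @param target An `mc_structure` (the full entry, all chains).
#' @param mates Output of [expand_lattice()]; computed when `NULL`.
#' @param domains Optional list of data frames (`chain`, `start`, `end`),
#'   one per domain.
#' @param radius Contact radius (A), default 10.
#' @param min_contacts Contact-count threshold, default 3.
#' @return Data frame: key, n_lattice, n_chain, n_domain, label.
#' @export
residue_context <- function(target, mates = NULL, domains = NULL,
                            radius = mc_defaults()$context_radius,
                            min_contacts = mc_defaults()$context_min_contacts) {
  if (is.null(mates)) {
    mates <- if (!is.null(target$cell)) expand_lattice(target, radius) else list()
  }
  ca <- ca_coords(target)
  lat_xyz <- if (length(mates)) {
    do.call(rbind, lapply(mates, function(m) ca_coords(m)$xyz))
  } else NULL
  n_lat <- count_within(ca$xyz, lat_xyz, radius)
  n_chain <- integer(length(ca$keys))
  for (ch in unique(ca$chain)) {
    own <- ca$chain == ch
    n_chain[own] <- count_within(ca$xyz[own, , drop = FALSE],
                                 ca$xyz[!own, , drop = FALSE], radius)
  }
  n_dom <- integer(length(ca$keys))
  if (!is.null(domains) && length(domains) > 1) {
    dom_of <- rep(NA_integer_, length(ca$keys))
    for (d in seq_along(domains)) {
      rg <- domains[[d]]
      for (r in seq_len(nrow(rg))) {
        hit <- ca$chain == rg$chain[r] & ca$resno >= rg$start[r] &
          ca$resno <= rg$end[r]
        dom_of[hit] <- d
      }
    }
    for (i in seq_along(ca$keys)) {
      if (is.na(dom_of[i])) next
      other <- which(!is.na(dom_of) & dom_of != dom_of[i] & ca$chain == ca$chain[i])
      if (length(other)) {
        n_dom[i] <- count_within(ca$xyz[i, , drop = FALSE],
                                 ca$xyz[other, , drop = FALSE], radius)
      }
    }
  }
  label <- ifelse(n_lat >= min_contacts, "lattice",
           ifelse(n_chain >= min_contacts, "chain",
           ifelse(n_dom >= min_contacts, "domain", "none")))
  data.frame(key = ca$keys, n_lattice = n_lat, n_chain = n_chain,
             n_domain = n_dom, label = label, stringsAsFactors = FALSE)
}

# Centred rolling mean, window truncated at the ends; NA values propagate
# as NA positions (they break runs downstream).
rolling_mean <- function(x, window) {
  n <- length(x)
  half <- (window - 1) %/% 2
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(x[i])) next
    w <- x[max(1, i - half):min(n, i + half)]
    out[i] <- mean(w, na.rm = TRUE)
  }
  out
}

#' Detect contiguous high-error regions
#'
#' A five-residue-window rolling mean of the per-residue superposition
#' distance is computed (window truncated at chain ends; absent residues
#' break runs); error regions are the maximal runs of at least `min_len`
#' consecutive residues whose rolling mean is at least `cut`.
#'
#' @param residue_distances Named vector from [lga_distances()] (NA =
#'   absent residue).
#' @param window Rolling window, default 5.
#' @param min_len Minimum region length, default 3.
#' @param cut Rolling-mean threshold (A), default 3.
#' @return Data frame: start, end (positions), start_key, end_key, length,
#'   mean_rolling_distance. Zero rows when no region qualifies.
#' @export
error_regions <- function(residue_distances,
                          window = mc_defaults()$region_window,
                          min_len = mc_defaults()$region_min_len,
                          cut = mc_defaults()$region_cut) {
  x <- as.numeric(residue_distances)
  keys <- names(residue_distances) %||% as.character(seq_along(x))
  roll <- rolling_mean(x, window)
  hot <- !is.na(roll) & roll >= cut
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values & r$lengths >= min_len)
  if (!length(keep)) {
    return(data.frame(start = integer(0), end = integer(0),
                      start_key = character(0), end_key = character(0),
                      length = integer(0), mean_rolling_distance = numeric(0)))
  }
  data.frame(start = starts[keep], end = ends[keep],
             start_key = keys[starts[keep]], end_key = keys[ends[keep]],
             length = r$lengths[keep],
             mean_rolling_distance = vapply(keep, function(j) {
               mean(roll[starts[j]:ends[j]])
             }, numeric(1)),
             stringsAsFactors = FALSE)
}

#' Structural context label of an error region
#'
#' Over the region's residues, the mean number of neighbour Calphas within
#' 10 A in each context class is computed; the region is labelled `lattice`
#' if its mean is at least 0.5, else `chain`, else `domain`, else `none`.
#'
#' @param region One row of [error_regions()] output (uses `start_key` /
#'   `end_key`), or a vector of residue keys.
#' @param target Full target `mc_structure`.
#' @param mates Symmetry mates from [expand_lattice()].
#' @param domains Optional domain ranges (see [residue_context()]).
#' @param radius Contact radius (A), default 10.
#' @param density Mean-neighbour threshold, default 0.5.
#' @return One of `"lattice"`, `"chain"`, `"domain"`, `"none"`.
#' @export
region_context <- function(region, target, mates = NULL, domains = NULL,
                           radius = mc_defaults()$context_radius,
                           density = mc_defaults()$region_density) {
  ctx <- residue_context(target, mates = mates, domains = domains,
                         radius = radius)
  keys <- if (is.character(region)) region else {
    i1 <- match(region$start_key, ctx$key)
    i2 <- match(region$end_key, ctx$key)
    ctx$key[i1:i2]
  }
  sel <- ctx[ctx$key %in% keys, , drop = FALSE]
  if (!nrow(sel)) return("none")
  if (mean(sel$n_lattice) >= density) "lattice"
  else if (mean(sel$n_chain) >= density) "chain"
  else if (mean(sel$n_domain) >= density) "domain"
  else "none"
}

#' Mean residue error by normalised B-factor bin
#'
#' Restricted to model-1 submissions with GDT_TS above the quality filter,
#' residue B-factors are z-normalised within each target, pooled, and split
#' into 10 equal-count bins; the mean residue error is reported per bin.
#'
#' @param residues Data frame with one row per residue observation:
#'   `target_id`, `b` (target B-factor), `error` (residue distance, A) and
#'   `gdt_ts` (the model's score).
#' @param n_bins Number of bins, default 10.
#' @param gdt_ts_filter Model quality filter, default 80 (strictly above).
#' @return Data frame: bin, n, mean_b_norm, mean_error.
#' @export
bfactor_bins <- function(residues, n_bins = 10,
                         gdt_ts_filter = mc_defaults()$gdt_ts_quality_filter) {
  stopifnot(all(c("target_id", "b", "error", "gdt_ts") %in% names(residues)))
  res <- residues[residues$gdt_ts > gdt_ts_filter & !is.na(residues$error), ,
                  drop = FALSE]
  if (!nrow(res)) stop("no qualifying model residues (GDT_TS filter)")
  zb <- stats::ave(res$b, res$target_id, FUN = function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
  ord_rank <- rank(zb, ties.method = "first")  # stable order on ties
  bin <- ceiling(ord_rank * n_bins / length(zb))
  data.frame(bin = sort(unique(bin)),
             n = as.integer(table(bin)),
             mean_b_norm = as.numeric(tapply(zb, bin, mean)),
             mean_error = as.numeric(tapply(res$error, bin, mean)))
}
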