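# Superposition-free and local-environment metrics: LDDT, Sphere-Grinder,
# a sampling-based contact-area-difference (CAD) surrogate, DipDiff, and a
# heavy-atom clash surrogate.

# Atom-level correspondence: rows of target and model atom tables matched
# by name within mapped residue pairs. Pairs with differing residue types
# are matched on backbone atoms only.
matched_atom_rows <- function(map) {
  ta <- map$target$atoms
  ma <- map$model$atoms
  tk <- res_key(ta)
  mk <- res_key(ma)
  bb <- c("N", "CA", "C", "O")
  out_t <- integer(0); out_m <- integer(0)
  for (i in seq_len(nrow(map$pairs))) {
    ti <- which(tk == map$pairs$t_key[i])
    mi <- which(mk == map$pairs$m_key[i])
    tn <- ta$elety[ti]; mn <- ma$elety[mi]
    if (!map$pairs$same_type[i]) { ti <- ti[tn %in% bb]; tn <- ta$elety[ti] }
    hit <- match(tn, mn)
    ok <- !is.na(hit)
    out_t <- c(out_t, ti[ok])
    out_m <- c(out_m, mi[hit[ok]])
  }
  data.frame(t_row = out_t, m_row = out_m,
             t_key = tk[out_t], stringsAsFactors = FALSE)
}

#' Local Distance Difference Test
#'
#' Superposition-free agreement of all-atom distance maps. Reference
#' distances are all heavy-atom pairs in the target between distinct
#' residues with separation at most `radius`. A reference distance is
#' preserved at a threshold when the model reproduces it within that
#' threshold; pairs involving an unmatched model atom count as violated.
#' The per-residue value is the mean preserved fraction over thresholds
#' among that residue's reference distances; residues entirely absent from
#' the model score 0.
#'
#' @param map An `mc_map`.
#' @param radius Inclusion radius (A), default 15.
#' @param thresholds Distance-difference thresholds (A).
#' @return `mc_lddt`: `global` in [0, 1], `per_residue` named over the
#'   target frame.
#' @export
lddt <- function(map, radius = mc_defaults()$lddt_radius,
                 thresholds = mc_defaults()$lddt_thresholds) {
  amap <- matched_atom_rows(map)
  ta <- map$target$atoms
  tk <- res_key(ta)
  in_frame <- tk %in% map$frame_keys
  ti <- which(in_frame)
  txyz <- atom_xyz(map$target, ti)
  n <- length(ti)
  if (n < 2) stop("lddt needs at least 2 matched residues")
  dt <- as.matrix(stats::dist(txyz))
  keys <- tk[ti]
  ref <- which(upper.tri(dt) & dt <= radius &
               outer(keys, keys, "!=") , arr.ind = TRUE)
  if (!nrow(ref)) stop("no reference distances within the radius")
  # model coordinates aligned to target frame atoms (NA when unmatched)
  midx <- amap$m_row[match(ti, amap$t_row)]
  mxyz <- matrix(NA_real_, n, 3)
  okm <- !is.na(midx)
  mxyz[okm, ] <- atom_xyz(map$model, midx[okm])
  d_target <- dt[ref]
  d_model <- sqrt(rowSums((mxyz[ref[, 1], , drop = FALSE] -
                           mxyz[ref[, 2], , drop = FALSE])^2))
  dd <- abs(d_model - d_target)  # NA when an endpoint is unmatched
  pres <- vapply(thresholds, function(th) {
    p <- dd < th
    p[is.na(p)] <- FALSE
    p
  }, logical(nrow(ref)))
  frac <- rowMeans(pres)
  k1 <- keys[ref[, 1]]; k2 <- keys[ref[, 2]]
  per_res <- tapply(c(frac, frac), c(k1, k2), mean)
  out <- rep(NA_real_, length(map$frame_keys))
  names(out) <- map$frame_keys
  out[names(per_res)] <- as.numeric(per_res)
  # residues absent from the model score 0 by convention
  unmatched <- setdiff(map$frame_keys, map$pairs$t_key)
  out[unmatched] <- 0
  structure(list(global = mean(out, na.rm = TRUE), per_residue = out,
                 radius = radius, thresholds = thresholds),
            class = "mc_lddt")
}

#' @export
print.mc_lddt <- function(x, ...) {
  cat(sprintf("<LDDT global %.3f over %d residues (radius %g A)>\n",
              x$global, length(x$per_residue), x$radius))
  invisible(x)
}

#' Sphere-Grinder local environment score
#'
#' For each target residue, all matched heavy-atom pairs whose target atom
#' lies within `radius` of the residue's Calpha are locally superposed; the
#' score is the percentage of residues whose local RMSD is at most
#' `rmsd_cut`. Residues with fewer than 3 local atoms pass trivially.
#'
#' @param map An `mc_map`.
#' @param radius Sphere radius (A), default 6.
#' @param rmsd_cut Local RMSD cutoff (A), default 2.
#' @return Score in [0, 100].
#' @export
sphere_grinder <- function(map, radius = mc_defaults()$sg_radius,
                           rmsd_cut = mc_defaults()$sg_rmsd_cut) {
  amap <- matched_atom_rows(map)
  if (!nrow(amap)) stop("no matched atoms")
  txyz <- atom_xyz(map$target, amap$t_row)
  mxyz <- atom_xyz(map$model, amap$m_row)
  rt <- residue_table(map$target)
  rt <- rt[rt$key %in% map$frame_keys & !is.na(rt$ca), , drop = FALSE]
  pass <- logical(nrow(rt))
  for (i in seq_len(nrow(rt))) {
    ca <- atom_xyz(map$target, rt$ca[i])
    sel <- which(sqrt(rowSums(sweep(txyz, 2, ca)^2)) <= radius)
    if (length(sel) < 3) { pass[i] <- TRUE; next }
    sup <- kabsch(txyz[sel, , drop = FALSE], mxyz[sel, , drop = FALSE])
    pass[i] <- sup$rmsd <= rmsd_cut
  }
  100 * mean(pass)
}

# Residue-residue contact areas by sphere-surface sampling: each sample
# point on an atom's solvent-extended sphere is assigned to the nearest
# other atom whose extended sphere contains it; cross-residue assignments
# accumulate area. Deterministic golden-spiral point set.
contact_areas <- function(xyz, radii, reskeys, samples_per_atom = 256,
                          probe = 1.4) {
  n <- nrow(xyz)
  pts0 <- sphere_points(samples_per_atom)
  rext <- radii + probe
  all_keys <- character(0)
  all_area <- numeric(0)
  for (a in seq_len(n)) {
    nb <- which(sqrt(rowSums(sweep(xyz, 2, xyz[a, ])^2)) <= rext[a] + max(rext))
    nb <- setdiff(nb, a)
    if (!length(nb)) next
    p <- sweep(pts0 * rext[a], 2, xyz[a, ], "+")
    # distance of each point to each neighbour's extended surface
    nxyz <- xyz[nb, , drop = FALSE]
    d <- sqrt(outer(rowSums(p^2), rowSums(nxyz^2), "+") - 2 * p %*% t(nxyz))
    d <- sweep(d, 2, rext[nb])
    best <- max.col(-d, ties.method = "first")
    inside <- d[cbind(seq_len(nrow(d)), best)] < 0
    owner <- nb[best]
    cross <- inside & (reskeys[owner] != reskeys[a])
    if (!any(cross)) next
    ap <- 4 * pi * rext[a]^2 / samples_per_atom
    k1 <- reskeys[a]; k2 <- reskeys[owner[cross]]
    keys <- ifelse(k1 < k2, paste(k1, k2, sep = "~"), paste(k2, k1, sep = "~"))
    all_keys <- c(all_keys, keys)
    all_area <- c(all_area, rep(ap, length(keys)))
  }
  if (!length(all_keys)) return(list())
  as.list(tapply(all_area, all_keys, sum))
}

#' All-atom contact-area-difference score (sampling surrogate)
#'
#' Residue-residue contact surface areas are estimated by sampling each
#' atom's solvent-extended sphere; the score compares model areas with
#' target areas over the target's contacts using the truncated-difference
#' form 1 - sum(min(|A_model - A_target|, A_target)) / sum(A_target).
#'
#' @param map An `mc_map`.
#' @param samples_per_atom Sphere sample count per atom (default 256).
#' @return Score in [0, 1].
#' @export
cad_aa <- function(map, samples_per_atom = 256) {
  ta <- map$target$atoms
  tk <- res_key(ta)
  keep <- tk %in% map$frame_keys
  at <- contact_areas(atom_xyz(map$target)[keep, , drop = FALSE],
                      vdw_radius(ta$elesy[keep]), tk[keep],
                      samples_per_atom = samples_per_atom)
  if (!length(at)) stop("no residue contacts in the target")
  amap <- matched_atom_rows(map)
  ma <- map$model$atoms
  am <- contact_areas(atom_xyz(map$model, amap$m_row),
                      vdw_radius(ma$elesy[amap$m_row]),
                      amap$t_key,  # model residues labelled by target key
                      samples_per_atom = samples_per_atom)
  tot <- 0; diff <- 0
  for (key in names(at)) {
    a_t <- at[[key]]
    a_m <- am[[key]] %||% 0
    tot <- tot + a_t
    diff <- diff + min(abs(a_m - a_t), a_t)
  }
  1 - diff / tot
}

#' DipDiff neighbour-distance agreement
#'
#' For each pair of consecutive matched residues, the four distances
#' {CAi-CAi+1, CAi-Oi+1, Oi-CAi+1, Oi-Oi+1} are compared between model and
#' target; each pair scores max(0, 1 - meanDelta / tolerance), averaged and
#' scaled to 0-100 (higher is better).
#'
#' @param map An `mc_map`.
#' @param tolerance Deviation (A) at which a pair's score reaches 0.
#' @return Score in [0, 100].
#' @export
dipdiff <- function(map, tolerance = 1) {
  rt <- residue_table(map$target)
  rm_ <- residue_table(map$model)
  rt <- rt[rt$key %in% map$frame_keys, , drop = FALSE]
  get_atoms <- function(struct, key, names_) {
    idx <- which(res_key(struct$atoms) == key)
    an <- struct$atoms$elety[idx]
    if (!all(names_ %in% an)) return(NULL)
    atom_xyz(struct, idx[match(names_, an)])
  }
  scores <- numeric(0)
  for (i in seq_len(nrow(rt) - 1)) {
    if (rt$chain[i + 1] != rt$chain[i] || rt$resno[i + 1] != rt$resno[i] + 1) next
    k1 <- rt$key[i]; k2 <- rt$key[i + 1]
    j1 <- match(k1, map$pairs$t_key); j2 <- match(k2, map$pairs$t_key)
    if (is.na(j1) || is.na(j2)) next
    t1 <- get_atoms(map$target, k1, c("CA", "O"))
    t2 <- get_atoms(map$target, k2, c("CA", "O"))
    m1 <- get_atoms(map$model, map$pairs$m_key[j1], c("CA", "O"))
    m2 <- get_atoms(map$model, map$pairs$m_key[j2], c("CA", "O"))
    if (is.null(t1) || is.null(t2) || is.null(m1) || is.null(m2)) next
    dt <- c(vnorm(t1[1, ] - t2[1, ]), vnorm(t1[1, ] - t2[2, ]),
            vnorm(t1[2, ] - t2[1, ]), vnorm(t1[2, ] - t2[2, ]))
    dm <- c(vnorm(m1[1, ] - m2[1, ]), vnorm(m1[1, ] - m2[2, ]),
            vnorm(m1[2, ] - m2[1, ]), vnorm(m1[2, ] - m2[2, ]))
    dev <- mean(abs(dm - dt))
    scores <- c(scores, max(0, 1 - dev / tolerance))
  }
  if (!length(scores)) stop("no eligible neighbouring residue pairs")
  100 * mean(scores)
}

# Atom index pairs within 3 bonds of each other (bonded, 1-3 and 1-4),
# from standard residue topology plus peptide links. 1-4 pairs are governed
# by torsional geometry, not van der Waals packing: ideal backbones place
# O(i)-CA(i+1) and C(i)-C(i+1) inside the raw overlap cut, so counting them
# would flag perfect geometry.
excluded_pairs <- function(x) {
  a <- x$atoms
  k <- res_key(a)
  rt <- residue_table(x)
  adj <- vector("list", nrow(a))
  add_bond <- function(i, j) {
    adj[[i]] <<- c(adj[[i]], j)
    adj[[j]] <<- c(adj[[j]], i)
  }
  for (r in seq_len(nrow(rt))) {
    idx <- which(k == rt$key[r])
    an <- a$elety[idx]
    bonds <- c(BACKBONE_BONDS, SIDECHAIN_BONDS[[rt$type[r]]])
    for (b in bonds) {
      i <- match(b[1], an); j <- match(b[2], an)
      if (!is.na(i) && !is.na(j)) add_bond(idx[i], idx[j])
    }
    if (r < nrow(rt) && rt$chain[r + 1] == rt$chain[r] &&
        rt$resno[r + 1] == rt$resno[r] + 1) {
      idx2 <- which(k == rt$key[r + 1])
      i <- match("C", an); j <- match("N", a$elety[idx2])
      if (!is.na(i) && !is.na(j)) add_bond(idx[i], idx2[j])
    }
  }
  pairs <- new.env(parent = emptyenv())
  mark <- function(i, j) {
    key <- if (i < j) paste(i, j) else paste(j, i)
    pairs[[key]] <- TRUE
  }
  for (i in seq_along(adj)) {
    for (j in adj[[i]]) {
      if (j > i) mark(i, j)
      for (l in adj[[j]]) {
        if (l == i) next
        mark(i, l)  # 1-3 via j
        for (m in adj[[l]]) if (m != i && m != j) mark(i, m)  # 1-4
      }
    }
  }
  ls(pairs)
}

#' Heavy-atom clash surrogate score
#'
#' Counts unordered non-bonded heavy-atom pairs (pairs within 3 bonds by
#' standard residue topology and peptide links excluded) whose van der
#' Waals overlap is at least `overlap_cut`, reported per 1000 atoms (lower
#' is better), in the spirit of the MolProbity clashscore but without
#' hydrogens.
#'
#' @param model An `mc_structure`.
#' @param overlap_cut Overlap threshold (A), default 0.4.
#' @return Clashes per 1000 atoms.
#' @export
clash_score <- function(model, overlap_cut = mc_defaults()$clash_overlap_cut) {
  a <- model$atoms
  n <- nrow(a)
  if (n < 2) stop("clash_score needs at least 2 atoms")
  xyz <- atom_xyz(model)
  rad <- vdw_radius(a$elesy)
  d <- as.matrix(stats::dist(xyz))
  lim <- outer(rad, rad, "+") - overlap_cut
  cand <- which(upper.tri(d) & d <= lim, arr.ind = TRUE)
  if (!nrow(cand)) return(0)
  excl <- excluded_pairs(model)
  keys <- paste(cand[, 1], cand[, 2])
  clashes <- sum(!(keys %in% excl))
  1000 * clashes / n
}
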