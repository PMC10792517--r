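# Backbone and side-chain dihedral analyses, chi-angle accuracy (AAA),
# Shrake-Rupley solvent accessibility, surface/buried partition, and a
# lightweight phi/psi secondary-structure composition label.

#' Backbone and side-chain torsion angles
#'
#' Phi/psi from consecutive backbone atoms (absent at chain termini) and
#' chi1-chi4 from the canonical atom quadruples per residue type; missing
#' atoms yield absent angles.
#'
#' @param x An `mc_structure`.
#' @return `mc_torsions`: named `phi` and `psi` vectors (degrees) and a
#'   `chi` list, all keyed by residue.
#' @export
torsions <- function(x) {
  rt <- residue_table(x)
  k <- res_key(x$atoms)
  getp <- function(ri, name) {
    idx <- which(k == rt$key[ri])
    j <- match(name, x$atoms$elety[idx])
    if (is.na(j)) return(NULL)
    as.numeric(x$atoms[idx[j], c("x", "y", "z")])
  }
  n <- nrow(rt)
  phi <- psi <- rep(NA_real_, n)
  names(phi) <- names(psi) <- rt$key
  chi <- vector("list", n)
  names(chi) <- rt$key
  consec <- function(i, j) {
    rt$chain[i] == rt$chain[j] && rt$resno[j] == rt$resno[i] + 1
  }
  for (i in seq_len(n)) {
    Ni <- getp(i, "N"); CAi <- getp(i, "CA"); Ci <- getp(i, "C")
    if (i > 1 && consec(i - 1, i)) {
      Cp <- getp(i - 1, "C")
      if (!is.null(Cp) && !is.null(Ni) && !is.null(CAi) && !is.null(Ci)) {
        phi[i] <- dihedral(Cp, Ni, CAi, Ci)
      }
    }
    if (i < n && consec(i, i + 1)) {
      Nn <- getp(i + 1, "N")
      if (!is.null(Ni) && !is.null(CAi) && !is.null(Ci) && !is.null(Nn)) {
        psi[i] <- dihedral(Ni, CAi, Ci, Nn)
      }
    }
    quads <- CHI_ATOMS[[rt$type[i]]]
    if (length(quads)) {
      vals <- rep(NA_real_, length(quads))
      for (q in seq_along(quads)) {
        ps <- lapply(quads[[q]], function(nm) getp(i, nm))
        if (any(vapply(ps, is.null, TRUE))) next
        ang <- dihedral(ps[[1]], ps[[2]], ps[[3]], ps[[4]])
        if (is.na(ang)) warning("degenerate (collinear) chi geometry in ", rt$key[i])
        vals[q] <- ang
      }
      chi[[i]] <- vals
    }
  }
  structure(list(phi = phi, psi = psi, chi = chi), class = "mc_torsions")
}

# Circular chi difference with the 180-degree flip minimisation applied to
# chemically symmetric terminal dihedrals.
chi_differences <- function(restype, chi_t, chi_m,
                            equivalence = CHI_SYMMETRIC) {
  nq <- min(length(chi_t), length(chi_m))
  if (!nq) return(numeric(0))
  d <- circ_diff(chi_t[seq_len(nq)], chi_m[seq_len(nq)])
  sym <- equivalence[restype]
  if (!is.na(sym) && sym <= nq) {
    d[sym] <- min(d[sym], circ_diff(chi_t[sym] + 180, chi_m[sym]))
  }
  d
}

#' Backbone and side-chain dihedral deviation
#'
#' Backbone deviation: mean over residues of the RMS of the circular phi
#' and psi differences. Side-chain deviation: mean over residues (with at
#' least one comparable chi) of the RMS circular chi difference, after the
#' chemical-equivalence flip minimisation. Both are 0 for identical
#' structures; lower is better.
#'
#' @param map An `mc_map`.
#' @return List with `backbone_dev` and `sidechain_dev` (degrees).
#' @export
torsion_dev <- function(map) {
  tt <- torsions(map$target)
  mt <- torsions(map$model)
  bb <- numeric(0); sc <- numeric(0)
  for (i in seq_len(nrow(map$pairs))) {
    tk <- map$pairs$t_key[i]; mk <- map$pairs$m_key[i]
    dphi <- if (!is.na(tt$phi[tk]) && !is.na(mt$phi[mk]))
      circ_diff(tt$phi[tk], mt$phi[mk]) else NA
    dpsi <- if (!is.na(tt$psi[tk]) && !is.na(mt$psi[mk]))
      circ_diff(tt$psi[tk], mt$psi[mk]) else NA
    dv <- c(dphi, dpsi)
    if (any(!is.na(dv))) bb <- c(bb, sqrt(mean(dv[!is.na(dv)]^2)))
    if (map$pairs$same_type[i]) {
      ct <- tt$chi[[tk]]; cm <- mt$chi[[mk]]
      if (length(ct) && length(cm)) {
        d <- chi_differences(map$pairs$t_type[i], ct, cm)
        d <- d[!is.na(d)]
        if (length(d)) sc <- c(sc, sqrt(mean(d^2)))
      }
    }
  }
  if (!length(bb) && !length(sc)) stop("no comparable angles")
  list(backbone_dev = if (length(bb)) mean(bb) else NA_real_,
       sidechain_dev = if (length(sc)) mean(sc) else NA_real_)
}

#' Side-chain chi-angle accuracy (AAA)
#'
#' Per residue, the percentage of its chi angles within `tol` degrees
#' (circular) of the reference, taking for each chemically symmetric
#' terminal dihedral the minimum over the 180-degree flip. The mean over
#' residues is the structure-level score.
#'
#' @param map An `mc_map`.
#' @param tol Tolerance in degrees, default 40.
#' @param equivalence Named integer vector: residue type -> index of its
#'   symmetric terminal chi.
#' @return List: `per_residue` (named percentages) and `mean`.
#' @export
aaa_score <- function(map, tol = mc_defaults()$chi_tolerance,
                      equivalence = CHI_SYMMETRIC) {
  tt <- torsions(map$target)
  mt <- torsions(map$model)
  per <- numeric(0)
  for (i in seq_len(nrow(map$pairs))) {
    if (!map$pairs$same_type[i]) next
    ct <- tt$chi[[map$pairs$t_key[i]]]
    cm <- mt$chi[[map$pairs$m_key[i]]]
    if (!length(ct) || !length(cm)) next
    d <- chi_differences(map$pairs$t_type[i], ct, cm, equivalence)
    d <- d[!is.na(d)]
    if (!length(d)) next
    per[map$pairs$t_key[i]] <- 100 * mean(d <= tol)
  }
  list(per_residue = per,
       mean = if (length(per)) mean(per) else NA_real_)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Numerical SASA over heavy atoms (vdW radii plus probe), summed per
#' residue.
#'
#' @param x An `mc_structure`.
#' @param probe Probe radius (A), default 1.4.
#' @param n_points Sphere sample points per atom.
#' @return Named per-residue SASA (A^2).
#' @export
sasa <- function(x, probe = mc_defaults()$sasa_probe, n_points = 192) {
  a <- x$atoms
  xyz <- atom_xyz(x)
  rad <- vdw_radius(a$elesy) + probe
  n <- nrow(a)
  pts0 <- sphere_points(n_points)
  atom_area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(sqrt(rowSums(sweep(xyz, 2, xyz[i, ])^2)) < rad[i] + max(rad))
    nb <- setdiff(nb, i)
    p <- sweep(pts0 * rad[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      acc <- acc & (rowSums(sweep(p, 2, xyz[j, ])^2) > rad[j]^2)
      if (!any(acc)) break
    }
    atom_area[i] <- 4 * pi * rad[i]^2 * sum(acc) / n_points
  }
  k <- res_key(a)
  v <- tapply(atom_area, k, sum)
  out <- as.numeric(v[unique(k)])
  names(out) <- unique(k)
  out
}

#' Surface classification by relative accessibility
#'
#' Relative SASA against theoretical Gly-X-Gly maxima; a residue is surface
#' when its relative accessibility exceeds 20%.
#'
#' @param x An `mc_structure`.
#' @param threshold Relative-SASA surface cutoff (default 0.20, strict).
#' @param ... Passed to [sasa()].
#' @return Data frame: key, sasa, rel_sasa, is_surface.
#' @export
surface_classification <- function(x, threshold = mc_defaults()$rel_sasa_surface,
                                   ...) {
  s <- sasa(x, ...)
  rt <- residue_table(x)
  ref <- MAX_SASA[rt$type[match(names(s), rt$key)]]
  rel <- as.numeric(s) / as.numeric(ref)
  data.frame(key = names(s), sasa = as.numeric(s), rel_sasa = rel,
             is_surface = rel > threshold, stringsAsFactors = FALSE)
}

#' Mean side-chain accuracy over surface and buried residues
#'
#' Surface classification is computed on the full target chain (before any
#' EU restriction); AAA is then averaged separately over surface and
#' non-surface residues of the mapped model. Targets with no buried
#' residues return `NA` for the buried mean.
#'
#' @param target Full-chain target `mc_structure`.
#' @param best_model_map `mc_map` of the model to assess (typically the
#'   top model by GDT_HA).
#' @param ... Passed to [aaa_score()].
#' @return List: `surface_mean_aaa`, `buried_mean_aaa` (NA if no buried
#'   residues with side chains).
#' @export
surface_partition_aaa <- function(target, best_model_map, ...) {
  cls <- surface_classification(target)
  aaa <- aaa_score(best_model_map, ...)$per_residue
  surf_keys <- cls$key[cls$is_surface]
  bur_keys <- cls$key[!cls$is_surface]
  sv <- aaa[names(aaa) %in% surf_keys]
  bv <- aaa[names(aaa) %in% bur_keys]
  list(surface_mean_aaa = if (length(sv)) mean(sv) else NA_real_,
       buried_mean_aaa = if (length(bv)) mean(bv) else NA_real_)
}

# Per-residue H/E/coil assignment from phi/psi boxes, requiring runs >= 3.
ss_assign <- function(x) {
  to <- torsions(x)
  h <- !is.na(to$phi) & !is.na(to$psi) &
    to$phi >= -100 & to$phi <= -30 & to$psi >= -80 & to$psi <= -5
  e <- !is.na(to$phi) & !is.na(to$psi) &
    to$phi >= -180 & to$phi <= -45 &
    ((to$psi >= 90 & to$psi <= 180) | (to$psi >= -180 & to$psi <= -170))
  ss <- ifelse(h, "H", ifelse(e, "E", "C"))
  # enforce minimum run length 3
  r <- rle(ss)
  r$values[r$lengths < 3 & r$values != "C"] <- "C"
  inverse.rle(r)
}

#' Secondary-structure composition label
#'
#' Residues are assigned helix/strand/coil from phi/psi regions (runs of at
#' least 3 required); the label follows the fraction of helix among regular
#' (H+E) residues: all-alpha (100%), mostly-alpha (>65%), mixed,
#' mostly-beta (>65% strand), all-beta (100% strand).
#'
#' @param x An `mc_structure`.
#' @return One of `"all-alpha"`, `"mostly-alpha"`, `"mixed"`,
#'   `"mostly-beta"`, `"all-beta"`.
#' @export
ss_composition <- function(x) {
  ss <- ss_assign(x)
  reg <- ss[ss %in% c("H", "E")]
  if (!length(reg)) {
    warning("no regular secondary structure; labelling mixed")
    return("mixed")
  }
  fa <- mean(reg == "H")
  if (fa == 1) "all-alpha"
  else if (fa > 0.65) "mostly-alpha"
  else if (fa == 0) "all-beta"
  else if (fa < 0.35) "mostly-beta"
  else "mixed"
}
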