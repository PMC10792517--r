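# Synthetic targets and predictions: an internal-coordinate peptide builder
# (ideal bond lengths/angles), rigid/noise/chi perturbations, emulated
# pLDDT confidence, toy P1 crystal lattices, and multi-group ensembles with
# planted skill. These stand in for real model/target pairs so that every
# analysis stage can be exercised end to end.

# Ideal backbone geometry (A / degrees).
BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
                ang_ca_c_o = 120.8, omega = 180,
                cb_len = 1.53, ang_n_ca_cb = 110.5, tau_c_n_ca_cb = -120)

# Side-chain z-matrices. Each entry: atom, reference atoms (A, B, C for the
# torsion path A-B-C-atom), bond length, bond angle B-C-atom, and torsion:
# either a number (degrees) or list(chi = k, offset = o) meaning chi_k + o.
SC_ZMAT <- list(
  GLY = list(),
  ALA = list(),
  SER = list(list("OG", c("N", "CA", "CB"), 1.417, 110.8, list(chi = 1, offset = 0))),
  LEU = list(
    list("CG", c("N", "CA", "CB"), 1.530, 116.3, list(chi = 1, offset = 0)),
    list("CD1", c("CA", "CB", "CG"), 1.530, 110.5, list(chi = 2, offset = 0)),
    list("CD2", c("CA", "CB", "CG"), 1.530, 110.5, list(chi = 2, offset = 120))),
  ASP = list(
    list("CG", c("N", "CA", "CB"), 1.520, 113.8, list(chi = 1, offset = 0)),
    list("OD1", c("CA", "CB", "CG"), 1.250, 118.3, list(chi = 2, offset = 0)),
    list("OD2", c("CA", "CB", "CG"), 1.250, 118.3, list(chi = 2, offset = 180))),
  GLU = list(
    list("CG", c("N", "CA", "CB"), 1.520, 113.8, list(chi = 1, offset = 0)),
    list("CD", c("CA", "CB", "CG"), 1.520, 113.8, list(chi = 2, offset = 0)),
    list("OE1", c("CB", "CG", "CD"), 1.250, 118.3, list(chi = 3, offset = 0)),
    list("OE2", c("CB", "CG", "CD"), 1.250, 118.3, list(chi = 3, offset = 180))),
  PHE = list(
    list("CG", c("N", "CA", "CB"), 1.500, 113.8, list(chi = 1, offset = 0)),
    list("CD1", c("CA", "CB", "CG"), 1.390, 120.0, list(chi = 2, offset = 0)),
    list("CD2", c("CA", "CB", "CG"), 1.390, 120.0, list(chi = 2, offset = 180)),
    list("CE1", c("CB", "CG", "CD1"), 1.390, 120.0, 180),
    list("CE2", c("CB", "CG", "CD2"), 1.390, 120.0, 180),
    list("CZ", c("CG", "CD1", "CE1"), 1.390, 120.0, 0)),
  TYR = list(
    list("CG", c("N", "CA", "CB"), 1.500, 113.8, list(chi = 1, offset = 0)),
    list("CD1", c("CA", "CB", "CG"), 1.390, 120.0, list(chi = 2, offset = 0)),
    list("CD2", c("CA", "CB", "CG"), 1.390, 120.0, list(chi = 2, offset = 180)),
    list("CE1", c("CB", "CG", "CD1"), 1.390, 120.0, 180),
    list("CE2", c("CB", "CG", "CD2"), 1.390, 120.0, 180),
    list("CZ", c("CG", "CD1", "CE1"), 1.390, 120.0, 0),
    list("OH", c("CD1", "CE1", "CZ"), 1.380, 120.0, 180)),
  ARG = list(
    list("CG", c("N", "CA", "CB"), 1.520, 114.0, list(chi = 1, offset = 0)),
    list("CD", c("CA", "CB", "CG"), 1.520, 111.3, list(chi = 2, offset = 0)),
    list("NE", c("CB", "CG", "CD"), 1.460, 112.0, list(chi = 3, offset = 0)),
    list("CZ", c("CG", "CD", "NE"), 1.330, 124.2, list(chi = 4, offset = 0)),
    list("NH1", c("CD", "NE", "CZ"), 1.330, 120.0, 0),
    list("NH2", c("CD", "NE", "CZ"), 1.330, 120.0, 180)),
  HIS = list(
    list("CG", c("N", "CA", "CB"), 1.500, 113.8, list(chi = 1, offset = 0)),
    list("ND1", c("CA", "CB", "CG"), 1.380, 122.7, list(chi = 2, offset = 0)),
    list("CE1", c("CB", "CG", "ND1"), 1.320, 108.0, 180),
    list("NE2", c("CG", "ND1", "CE1"), 1.320, 108.0, 0),
    list("CD2", c("ND1", "CE1", "NE2"), 1.360, 108.0, 0))
)

SYNTH_ALPHABET <- c("ALA", "GLY", "LEU", "ASP", "GLU", "PHE", "TYR",
                    "ARG", "SER", "HIS")

# Candidate rotamers (degrees) per residue type, tried in order; the first
# clash-free candidate against the already-built structure is kept.
ROTAMER_SETS <- list(
  SER = list(-65, 180, 62),
  LEU = list(c(-65, 175), c(180, 65), c(-172, 145)),
  ASP = list(c(-70, -20), c(180, 20), c(-170, 40), c(62, -10)),
  GLU = list(c(-65, 180, -25), c(180, 180, 0), c(-67, -65, -40), c(62, 180, -10)),
  PHE = list(c(-65, 90), c(180, 80), c(62, 90), c(-65, -30)),
  TYR = list(c(-65, 90), c(180, 80), c(62, 90), c(-65, -30)),
  ARG = list(c(-65, 180, 180, 180), c(180, 180, 180, 180),
             c(-177, 65, 180, 180), c(62, 180, 65, 85)),
  HIS = list(c(-65, -80), c(180, 60), c(-177, 100), c(62, -75))
)
DEFAULT_CHI <- lapply(ROTAMER_SETS, `[[`, 1)

element_of <- function(name) substr(gsub("[0-9]", "", name), 1, 1)

#' Build an ideal-geometry peptide from internal coordinates
#'
#' Constructs a full heavy-atom single-chain structure from backbone
#' (phi, psi) and side-chain chi angles using standard bond lengths and
#' angles; omega is fixed trans (180 degrees). Deterministic.
#'
#' @param sequence Character vector of 3-letter residue codes, or a single
#'   one-letter string. Supported types: Ala, Gly, Leu, Asp, Glu, Phe, Tyr,
#'   Arg, Ser, His.
#' @param phi,psi Numeric vectors (degrees), recycled; phi of the first and
#'   psi of the last residue are only used to place terminal atoms.
#' @param chi List (one numeric vector per residue) of chi angles; `NULL`
#'   entries are assigned the first clash-free candidate from a small
#'   rotamer set (deterministic).
#' @param chain Chain identifier.
#' @param id Structure id.
#' @param role `"target"` or `"prediction"`.
#' @return An `mc_structure`.
#' @examples
#' helix <- build_peptide(strrep("A", 12), phi = -57, psi = -47)
#' @export
build_peptide <- function(sequence, phi = -57, psi = -47, chi = NULL,
                          chain = "A", id = "synth", role = "target") {
  if (length(sequence) == 1 && !sequence %in% AA3) {
    letters1 <- strsplit(sequence, "")[[1]]
    sequence <- names(AA1)[match(letters1, AA1)]
    if (anyNA(sequence)) stop("unknown one-letter residue code")
  }
  if (!all(sequence %in% names(SC_ZMAT))) {
    stop("unsupported residue type(s): ",
         paste(setdiff(sequence, names(SC_ZMAT)), collapse = " "))
  }
  n <- length(sequence)
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  g <- BB_GEOM
  rows <- list()
  add <- function(resno, resid, name, xyz) {
    rows[[length(rows) + 1]] <<- data.frame(
      type = "ATOM", eleno = length(rows) + 1, elety = name, alt = "",
      resid = resid, chain = chain, resno = resno, insert = "",
      x = xyz[1], y = xyz[2], z = xyz[3], o = 1, b = 0,
      elesy = element_of(name), stringsAsFactors = FALSE)
  }
  # backbone N, CA, C for every residue
  bb <- vector("list", n)
  N <- c(0, 0, 0)
  CA <- c(g$n_ca, 0, 0)
  th <- deg2rad(180 - g$ang_n_ca_c)
  C <- CA + g$ca_c * c(cos(th), sin(th), 0)
  bb[[1]] <- list(N = N, CA = CA, C = C)
  for (i in seq_len(n - 1)) {
    p <- bb[[i]]
    Nn <- place_atom(p$N, p$CA, p$C, g$c_n, g$ang_ca_c_n, psi[i])
    CAn <- place_atom(p$CA, p$C, Nn, g$n_ca, g$ang_c_n_ca, g$omega)
    Cn <- place_atom(p$C, Nn, CAn, g$ca_c, g$ang_n_ca_c, phi[i + 1])
    bb[[i + 1]] <- list(N = Nn, CA = CAn, C = Cn)
  }
  # pass 1: backbone (N, CA, C, O) and CB everywhere
  base_pos <- vector("list", n)
  for (i in seq_len(n)) {
    p <- bb[[i]]
    pos <- list(N = p$N, CA = p$CA, C = p$C,
                O = place_atom(p$N, p$CA, p$C, g$c_o, g$ang_ca_c_o,
                               psi[i] + 180))
    if (sequence[i] != "GLY") {
      pos$CB <- place_atom(p$C, p$N, p$CA, g$cb_len, g$ang_n_ca_cb,
                           g$tau_c_n_ca_cb)
    }
    base_pos[[i]] <- pos
  }
  # environment the side chains must avoid: backbone/CB of every residue,
  # plus side chains already placed
  env_xyz <- do.call(rbind, lapply(seq_len(n), function(i) {
    do.call(rbind, base_pos[[i]])
  }))
  env_res <- rep(seq_len(n), vapply(base_pos, length, 1L))
  env_rad <- vdw_radius(element_of(unlist(lapply(base_pos, names))))
  place_sidechain <- function(i, chis) {
    pos <- base_pos[[i]]
    out <- list()
    for (row in SC_ZMAT[[sequence[i]]]) {
      tau <- row[[5]]
      if (is.list(tau)) {
        if (tau$chi > length(chis)) stop("missing chi", tau$chi, " for ", sequence[i])
        tau <- chis[tau$chi] + tau$offset
      }
      xyz <- place_atom(pos[[row[[2]][1]]], pos[[row[[2]][2]]],
                        pos[[row[[2]][3]]], row[[3]], row[[4]], tau)
      pos[[row[[1]]]] <- xyz
      out[[row[[1]]]] <- xyz
    }
    out
  }
  # worst vdW overlap of candidate side-chain atoms against the current
  # environment (other residues only; own backbone contacts are governed
  # by the fixed internal geometry)
  worst_overlap <- function(i, sc) {
    if (!length(sc)) return(-Inf)
    sxyz <- do.call(rbind, sc)
    srad <- vdw_radius(element_of(names(sc)))
    other <- env_res != i
    d <- sqrt(outer(rowSums(sxyz^2), rowSums(env_xyz[other, , drop = FALSE]^2), "+") -
              2 * sxyz %*% t(env_xyz[other, , drop = FALSE]))
    max(outer(srad, env_rad[other], "+") - d)
  }
  for (i in seq_len(n)) {
    restype <- sequence[i]
    if (length(SC_ZMAT[[restype]])) {
      if (!is.null(chi) && !is.null(chi[[i]])) {
        sc <- place_sidechain(i, chi[[i]])
      } else {
        cands <- ROTAMER_SETS[[restype]]
        sc <- NULL; best <- Inf
        for (cand in cands) {
          sci <- place_sidechain(i, cand)
          ov <- worst_overlap(i, sci)
          if (ov < best) { best <- ov; sc <- sci }
          if (ov < 0.35) break  # clash-free with margin; keep it
        }
      }
      if (length(sc)) {
        env_xyz <- rbind(env_xyz, do.call(rbind, sc))
        env_res <- c(env_res, rep(i, length(sc)))
        env_rad <- c(env_rad, vdw_radius(element_of(names(sc))))
      }
    } else sc <- list()
    pos <- base_pos[[i]]
    add(i, restype, "N", pos$N)
    add(i, restype, "CA", pos$CA)
    add(i, restype, "C", pos$C)
    add(i, restype, "O", pos$O)
    if (!is.null(pos$CB)) add(i, restype, "CB", pos$CB)
    for (nm in names(sc)) add(i, restype, nm, sc[[nm]])
  }
  atoms <- do.call(rbind, rows)
  new_structure(atoms, id = id, role = role)
}

# Distal atom names rotated by a change in chi_k of a residue type:
# atoms connected to the axis' far atom without passing through the near one.
chi_distal_atoms <- function(restype, k) {
  quad <- CHI_ATOMS[[restype]][[k]]
  bonds <- c(BACKBONE_BONDS, SIDECHAIN_BONDS[[restype]])
  adj <- list()
  for (b in bonds) {
    adj[[b[1]]] <- c(adj[[b[1]]], b[2])
    adj[[b[2]]] <- c(adj[[b[2]]], b[1])
  }
  seen <- c(quad[2], quad[3])  # block traversal back through the axis
  frontier <- quad[3]
  out <- character(0)
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier])), seen)
    out <- c(out, nxt)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  out
}

# Rotate one residue's chi_k to a new value (degrees), in place.
set_chi <- function(x, key, k, new_value) {
  idx <- which(res_key(x$atoms) == key)
  restype <- x$atoms$resid[idx[1]]
  quad <- CHI_ATOMS[[restype]][[k]]
  an <- x$atoms$elety[idx]
  if (!all(quad %in% an)) return(x)
  p <- lapply(quad, function(nm) as.numeric(x$atoms[idx[match(nm, an)], c("x", "y", "z")]))
  cur <- dihedral(p[[1]], p[[2]], p[[3]], p[[4]])
  if (is.na(cur)) return(x)
  distal <- chi_distal_atoms(restype, k)
  rot_idx <- idx[an %in% distal]
  if (!length(rot_idx)) return(x)
  R <- rotation_about_axis(p[[3]] - p[[2]], new_value - cur)
  xyz <- as.matrix(x$atoms[rot_idx, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, p[[2]])
  xyz <- t(R %*% t(xyz))
  xyz <- sweep(xyz, 2, p[[2]], "+")
  x$atoms[rot_idx, c("x", "y", "z")] <- xyz
  x
}

#' Perturb a target into a synthetic prediction
#'
#' Applies, in order: rigid transforms of residue segments, per-residue
#' Gaussian coordinate noise whose sigma may be coupled to the target's
#' normalised B-factor, and random re-sampling of side-chain chi angles.
#' Seeded and reproducible.
#'
#' @param target An `mc_structure`.
#' @param global_sigma Gaussian noise sigma (A).
#' @param segment_transforms List of `list(start, end, angle, axis,
#'   translation)`: residues (by number) rotated about their centroid and
#'   translated.
#' @param chi_resample_prob Probability that each chi angle is replaced by a
#'   uniform draw from (-180, 180].
#' @param bfactor_coupling Coupling c in sigma_i = global_sigma * (1 + c *
#'   zB_i), where zB is the per-structure z-scored residue B-factor
#'   (negative sigmas floored at 0).
#' @param seed Integer seed.
#' @return A prediction `mc_structure`.
#' @export
perturb <- function(target, global_sigma = 0, segment_transforms = list(),
                    chi_resample_prob = 0, bfactor_coupling = 0, seed = 1) {
  x <- target
  x$role <- "prediction"
  x$cell <- NULL
  x$space_group <- NULL
  set.seed(seed)
  rt <- residue_table(x)
  for (tr in segment_transforms) {
    sel <- which(x$atoms$resno >= tr$start & x$atoms$resno <= tr$end)
    if (!length(sel)) stop("segment transform range outside target")
    xyz <- as.matrix(x$atoms[sel, c("x", "y", "z")])
    cen <- colMeans(xyz)
    R <- if (!is.null(tr$angle) && tr$angle != 0)
      rotation_about_axis(tr$axis %||% c(0, 0, 1), tr$angle) else diag(3)
    xyz <- sweep(t(R %*% t(sweep(xyz, 2, cen))), 2, cen + (tr$translation %||% c(0, 0, 0)), "+")
    x$atoms[sel, c("x", "y", "z")] <- xyz
  }
  if (global_sigma > 0) {
    sig_res <- rep(global_sigma, nrow(rt))
    if (bfactor_coupling > 0) {
      bres <- tapply(target$atoms$b, res_key(target$atoms), mean)[rt$key]
      zb <- if (stats::sd(bres) > 0) (bres - mean(bres)) / stats::sd(bres) else rep(0, length(bres))
      sig_res <- pmax(0, global_sigma * (1 + bfactor_coupling * zb))
    }
    sig_atom <- sig_res[match(res_key(x$atoms), rt$key)]
    n <- nrow(x$atoms)
    x$atoms$x <- x$atoms$x + stats::rnorm(n, 0, sig_atom)
    x$atoms$y <- x$atoms$y + stats::rnorm(n, 0, sig_atom)
    x$atoms$z <- x$atoms$z + stats::rnorm(n, 0, sig_atom)
  }
  if (chi_resample_prob > 0) {
    for (i in seq_len(nrow(rt))) {
      restype <- rt$type[i]
      nchi <- length(CHI_ATOMS[[restype]])
      if (!nchi) next
      for (k in seq_len(nchi)) {
        if (stats::runif(1) < chi_resample_prob) {
          x <- set_chi(x, rt$key[i], k, stats::runif(1, -180, 180))
        }
      }
    }
  }
  x
}

#' Wrap a structure in a toy P1 crystal cell
#'
#' Attaches a P1 cell and space group so lattice analyses (symmetry-mate
#' expansion, interface contexts) can run. Errors if any ±1 cell translate
#' of the chain would clash sterically with the original (heavy atoms
#' closer than 3 A).
#'
#' @param target An `mc_structure`.
#' @param cell Numeric 6-vector (a, b, c, alpha, beta, gamma).
#' @return The structure with `cell`/`space_group` set and role `"target"`.
#' @export
make_lattice <- function(target, cell = c(30, 30, 30, 90, 90, 90)) {
  x <- target
  x$cell <- cell
  x$space_group <- "P 1"
  x$role <- "target"
  om <- orth_matrix(cell)
  xyz <- atom_xyz(x)
  for (sh in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    tvec <- as.numeric(om %*% sh)
    d2 <- fields_mindist2(xyz, sweep(xyz, 2, tvec, "+"))
    if (d2 < 9) stop("overlapping copies: chain does not fit the cell")
  }
  x
}

# min squared distance between two point sets (chunked to bound memory)
fields_mindist2 <- function(a, b) {
  best <- Inf
  step <- 500
  for (i in seq(1, nrow(a), by = step)) {
    ii <- i:min(i + step - 1, nrow(a))
    d2 <- outer(rowSums(a[ii, , drop = FALSE]^2), rowSums(b^2), "+") -
      2 * a[ii, , drop = FALSE] %*% t(b)
    best <- min(best, min(d2))
  }
  best
}

#' Emulate predictor confidence from actual local accuracy
#'
#' Sets the prediction's B-factor column to its actual per-residue LDDT
#' (scaled to 0-100) plus Gaussian noise, clipped to [0, 100] and broadcast
#' to all atoms of the residue.
#'
#' @param prediction,target `mc_structure` objects.
#' @param noise_sigma Gaussian sigma on the 0-100 scale.
#' @param seed Integer seed.
#' @return The prediction with confidence written into the B column.
#' @export
emulate_plddt <- function(prediction, target, noise_sigma = 0, seed = 1) {
  map <- map_residues(target, prediction)
  lr <- lddt(map)
  set.seed(seed)
  per_res <- 100 * lr$per_residue
  noise <- stats::rnorm(length(per_res), 0, noise_sigma)
  val <- pmin(100, pmax(0, per_res + noise))
  names(val) <- names(lr$per_residue)
  # carry values over to model residues via the map
  mk <- prediction$atoms |> res_key()
  mres <- map$pairs$m_key[match(names(val), map$pairs$t_key)]
  b <- rep(50, nrow(prediction$atoms))
  hit <- match(mk, mres)
  b[!is.na(hit)] <- val[hit[!is.na(hit)]]
  prediction$atoms$b <- b
  prediction
}

#' Generate a multi-group synthetic prediction ensemble
#'
#' Builds one target peptide per EU and, for each group x EU, five perturbed
#' models whose noise scale is set by the group's planted skill
#' (sigma = sigma_max * (1 - skill), jittered per model; model 1 is drawn
#' from the same distribution, so self-ranking is uninformative by
#' construction). Confidence is emulated from actual LDDT. A truth table
#' records the planted skills.
#'
#' @param n_groups,n_eus Ensemble dimensions.
#' @param skills Numeric vector in [0, 1], one per group (default evenly
#'   spaced, distinct).
#' @param models_per_group Models per group and EU (default 5).
#' @param missing_rate Per-group probability of skipping an EU.
#' @param sigma_max Noise sigma (A) for a skill-0 group.
#' @param eu_length Residues per EU peptide.
#' @param plddt_noise Sigma of the confidence emulation noise (0-100 scale).
#' @param seed Integer seed; the whole tree is reproducible from it.
#' @param out_dir Optional directory: when given, targets and models are
#'   written as PDB trees with an EU table and truth-table TSVs.
#' @return List with `targets` (per EU), `eus` (table), `models` (nested
#'   list `[[eu]][[group]]` of length-5 model lists), `truth` (group skills).
#' @export
make_ensemble <- function(n_groups = 10, n_eus = 20, skills = NULL,
                          models_per_group = 5, missing_rate = 0,
                          sigma_max = 4, eu_length = 16, plddt_noise = 5,
                          seed = 1, out_dir = NULL) {
  set.seed(seed)
  if (is.null(skills)) skills <- seq(0.05, 0.95, length.out = n_groups)
  stopifnot(length(skills) == n_groups, all(skills >= 0 & skills <= 1))
  groups <- sprintf("G%03d", seq_len(n_groups))
  eus <- sprintf("E%03d", seq_len(n_eus))
  targets <- list()
  eu_rows <- list()
  for (e in seq_len(n_eus)) {
    seqv <- sample(SYNTH_ALPHABET, eu_length, replace = TRUE)
    # helix body, a two-residue loop, and a short strand tail for
    # secondary-structure variety (junction torsions chosen clash-free)
    nst <- max(0, round(eu_length / 4))
    nh <- eu_length - nst - 2
    phi <- c(rep(-57, nh), -60, -90, rep(-120, nst))
    psi <- c(rep(-47, nh), 120, 150, rep(135, nst))
    tg <- build_peptide(seqv, phi = phi, psi = psi, id = eus[e], role = "target")
    # synthetic B-factors: gamma-distributed, per-residue, scaled per target
    bres <- stats::rgamma(eu_length, shape = 2, scale = stats::runif(1, 5, 15))
    tg$atoms$b <- bres[match(res_key(tg$atoms), residue_table(tg)$key)]
    targets[[eus[e]]] <- tg
    eu_rows[[e]] <- data.frame(target_id = eus[e], eu_id = eus[e],
                               selection = sprintf("A:1-%d", eu_length),
                               difficulty = sample(c("TBM-easy", "TBM-hard", "FM"), 1),
                               taxonomy = "Synthetic", stringsAsFactors = FALSE)
  }
  eu_tab <- do.call(rbind, eu_rows)
  eu_tab$ranges <- lapply(eu_tab$selection, parse_selection)
  models <- list()
  for (e in eus) {
    models[[e]] <- list()
    for (gi in seq_len(n_groups)) {
      if (stats::runif(1) < missing_rate) next
      sig0 <- sigma_max * (1 - skills[gi])
      ms <- list()
      for (m in seq_len(models_per_group)) {
        sig <- sig0 * stats::runif(1, 0.7, 1.3)
        sd_seed <- sample.int(.Machine$integer.max, 1)
        pred <- perturb(targets[[e]], global_sigma = sig,
                        chi_resample_prob = min(1, sig / 8), seed = sd_seed)
        pred <- emulate_plddt(pred, targets[[e]], noise_sigma = plddt_noise,
                              seed = sd_seed + 1L)
        pred$id <- sprintf("%s_%s_%d", groups[gi], e, m)
        pred$role <- "prediction"
        ms[[m]] <- pred
      }
      models[[e]][[groups[gi]]] <- ms
    }
  }
  truth <- data.frame(group = groups, skill = skills, stringsAsFactors = FALSE)
  out <- list(targets = targets, eus = eu_tab, models = models, truth = truth,
              groups = groups)
  if (!is.null(out_dir)) write_ensemble(out, out_dir)
  out
}

# Write an ensemble as a PDB tree with EU and truth TSVs (the manifest).
write_ensemble <- function(ens, out_dir) {
  dir.create(file.path(out_dir, "targets"), recursive = TRUE, showWarnings = FALSE)
  for (e in names(ens$targets)) {
    write_structure(ens$targets[[e]], file.path(out_dir, "targets", paste0(e, ".pdb")))
  }
  utils::write.table(ens$eus[, c("target_id", "eu_id", "selection", "difficulty",
                                 "taxonomy")],
                     file.path(out_dir, "eus.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ens$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (e in names(ens$models)) {
    for (g in names(ens$models[[e]])) {
      d <- file.path(out_dir, "models", e, g)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      for (m in seq_along(ens$models[[e]][[g]])) {
        write_structure(ens$models[[e]][[g]][[m]],
                        file.path(d, sprintf("model_%d.pdb", m)))
      }
    }
  }
  invisible(out_dir)
}
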