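# Catalytic-site accuracy: all-atom RMSD of the site residues under a
# site-only least-squares fit, minimised over chemical-equivalence flips.

# All combinations of flip states for the flippable residues of a site.
flip_combinations <- function(flippable) {
  if (!length(flippable)) return(list(logical(0)))
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(flippable)))
  lapply(seq_len(nrow(grid)), function(i) as.logical(grid[i, ]))
}

# Atom names of a residue after applying (or not) its 180-degree flip.
flipped_names <- function(names_, restype, flip) {
  if (!flip) return(names_)
  swaps <- FLIP_SWAPS[[restype]]
  out <- names_
  for (sw in swaps) {
    out[names_ == sw[1]] <- sw[2]
    out[names_ == sw[2]] <- sw[1]
  }
  out
}

#' Catalytic-site all-atom RMSD
#'
#' Fits the model's site heavy atoms onto the target's by least squares
#' (site atoms only) and reports the RMSD, minimised over every
#' combination of 180-degree terminal-dihedral flips of the site's
#' chemically symmetric residues (Asp, Glu, Phe, Tyr; His optionally).
#' Models at or below the GDT_HA filter are excluded, as are models with a
#' site residue missing.
#'
#' @param map An `mc_map` covering the site residues.
#' @param site Data frame `chain, resno` (optionally `restype`) of the
#'   catalytic residues (2-6 of them) in target numbering.
#' @param gdt_ha The model's GDT_HA; computed from the map when `NULL`.
#' @param gdt_ha_filter Exclusion threshold, default 30 (strictly above
#'   passes).
#' @param his_flip Also allow His ring flips.
#' @return List: `rmsd` (A, or NA), `status` (`"ok"`, `"excluded_gdt"`,
#'   `"excluded_missing"`), `gdt_ha`.
#' @export
site_rmsd <- function(map, site, gdt_ha = NULL,
                      gdt_ha_filter = mc_defaults()$gdt_ha_site_filter,
                      his_flip = FALSE) {
  stopifnot(all(c("chain", "resno") %in% names(site)))
  if (nrow(site) < 2 || nrow(site) > 6) stop("a site has 2-6 residues")
  if (is.null(gdt_ha)) gdt_ha <- gdt(map, "HA")$score
  if (gdt_ha <= gdt_ha_filter) {
    return(list(rmsd = NA_real_, status = "excluded_gdt", gdt_ha = gdt_ha))
  }
  rt <- residue_table(map$target)
  keys <- character(nrow(site))
  for (i in seq_len(nrow(site))) {
    j <- which(rt$chain == site$chain[i] & rt$resno == site$resno[i])
    if (!length(j)) stop("site residue not present in target: ",
                         site$chain[i], site$resno[i])
    keys[i] <- rt$key[j[1]]
  }
  pr <- map$pairs[match(keys, map$pairs$t_key), , drop = FALSE]
  if (anyNA(pr$m_key) || !all(pr$same_type)) {
    return(list(rmsd = NA_real_, status = "excluded_missing", gdt_ha = gdt_ha))
  }
  tk <- res_key(map$target$atoms)
  mk <- res_key(map$model$atoms)
  equiv <- names(FLIP_SWAPS)
  if (!his_flip) equiv <- setdiff(equiv, "HIS")
  flippable <- which(pr$t_type %in% equiv)
  best <- Inf
  for (combo in flip_combinations(flippable)) {
    txyz <- NULL; mxyz <- NULL
    ok <- TRUE
    for (i in seq_len(nrow(pr))) {
      ti <- which(tk == pr$t_key[i])
      mi <- which(mk == pr$m_key[i])
      mn <- map$model$atoms$elety[mi]
      fi <- match(i, flippable)
      if (!is.na(fi) && combo[fi]) mn <- flipped_names(mn, pr$t_type[i], TRUE)
      hit <- match(map$target$atoms$elety[ti], mn)
      use <- !is.na(hit)
      if (sum(use) < 1) { ok <- FALSE; break }
      txyz <- rbind(txyz, atom_xyz(map$target, ti[use]))
      mxyz <- rbind(mxyz, atom_xyz(map$model, mi[hit[use]]))
    }
    if (!ok || nrow(txyz) < 3) next
    sup <- kabsch(txyz, mxyz)
    if (sup$rmsd < best) best <- sup$rmsd
  }
  if (!is.finite(best)) {
    return(list(rmsd = NA_real_, status = "excluded_missing", gdt_ha = gdt_ha))
  }
  list(rmsd = best, status = "ok", gdt_ha = gdt_ha)
}
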