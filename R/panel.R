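# One-call metric panel for a target/model pair, and ensemble scoring into
# the long-form table the ranking consumes.

#' Compute GDT_TS and GDT_HA together
#'
#' Runs the threshold searches once over the union of the TS and HA
#' threshold sets and assembles both scores, plus the per-residue distances
#' under the shared 4 A superposition.
#'
#' @param map An `mc_map`.
#' @return List: `gdt_ts`, `gdt_ha`, `residue_distances`.
#' @export
gdt_both <- function(map) {
  ca <- matched_ca(map)
  if (nrow(ca$t) < 3) stop("gdt needs at least 3 matched Calpha pairs")
  n_frame <- length(map$frame_keys)
  d <- mc_defaults()
  thr <- sort(unique(c(d$gdt_ts_thresholds, d$gdt_ha_thresholds)))
  fr <- setNames(numeric(length(thr)), as.character(thr))
  final <- NULL
  for (i in seq_along(thr)) {
    res <- gdt_search(ca$t, ca$m, thr[i])
    fr[i] <- res$count / n_frame
    if (thr[i] == 4) final <- res$sup
  }
  dd <- sqrt(rowSums((apply_superposition(final, ca$m) - ca$t)^2))
  rd <- rep(NA_real_, n_frame)
  names(rd) <- map$frame_keys
  rd[ca$keys] <- dd
  list(gdt_ts = 100 * mean(fr[as.character(d$gdt_ts_thresholds)]),
       gdt_ha = 100 * mean(fr[as.character(d$gdt_ha_thresholds)]),
       residue_distances = rd)
}

#' Full metric panel for one model
#'
#' Computes every component metric for a target/model correspondence:
#' LDDT (0-1), the CAD surrogate (0-1), Sphere-Grinder (0-100),
#' side-chain and backbone dihedral deviations (degrees, lower better),
#' the clash surrogate (per 1000 atoms, lower better), DipDiff (0-100),
#' GDT_HA, GDT_TS (0-100) and, when the model carries confidence, ASE
#' (0-100).
#'
#' @param map An `mc_map`.
#' @param with_ase Compute ASE from the model's B-column confidence.
#' @param cad_samples Sphere samples per atom for the CAD surrogate.
#' @return Named numeric vector.
#' @export
metric_vector <- function(map, with_ase = TRUE, cad_samples = 64) {
  g <- gdt_both(map)
  l <- lddt(map)
  td <- torsion_dev(map)
  out <- c(lddt = l$global,
           cad_aa = cad_aa(map, samples_per_atom = cad_samples),
           sg = sphere_grinder(map),
           sidechain_dev = td$sidechain_dev,
           clash = clash_score(map$model),
           backbone_dev = td$backbone_dev,
           dipdiff = dipdiff(map),
           gdt_ha = g$gdt_ha,
           gdt_ts = g$gdt_ts)
  if (with_ase) {
    conf <- extract_confidence(map$model, "residue")
    pl <- conf[map$pairs$m_key]
    names(pl) <- map$pairs$t_key
    out["ase"] <- ase(pl, l$per_residue)$ase
  }
  out
}

#' Score an ensemble into a long-form metric table
#'
#' Runs the metric panel over every group's model 1 (or all models) for
#' every EU of a synthetic ensemble, yielding the `eu_id, group, model,
#' metric, value` table consumed by [eu_composites()] and
#' [model1_best_fraction()].
#'
#' @param ens Output of [make_ensemble()].
#' @param models `"model1"` or `"all"`.
#' @param metrics Optional subset of metric names to keep.
#' @param cad_samples Passed to [metric_vector()].
#' @return Long-form data frame.
#' @export
score_ensemble <- function(ens, models = c("model1", "all"), metrics = NULL,
                           cad_samples = 64) {
  models <- match.arg(models)
  rows <- list()
  for (e in names(ens$models)) {
    tg <- ens$targets[[e]]
    for (g in names(ens$models[[e]])) {
      idx <- if (models == "model1") 1L else seq_along(ens$models[[e]][[g]])
      for (m in idx) {
        map <- map_residues(tg, ens$models[[e]][[g]][[m]])
        v <- metric_vector(map, cad_samples = cad_samples)
        if (!is.null(metrics)) v <- v[names(v) %in% metrics]
        rows[[length(rows) + 1]] <- data.frame(
          eu_id = e, group = g, model = m, metric = names(v),
          value = as.numeric(v), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
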