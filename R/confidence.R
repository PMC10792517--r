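# Self-assessment accuracy: agreement of predicted confidence with actual
# local accuracy (ASE), and how often a group's model 1 is its best model.

#' Accuracy Self Estimate (ASE)
#'
#' Agreement between predicted confidence (pLDDT, 0-100) and actual LDDT
#' (0-1): 100 * (1 - mean |plddt/100 - lddt|). 100 means perfect
#' self-assessment. When both vectors are named, they are matched by
#' residue key.
#'
#' @param predicted_plddt Per-residue pLDDT (0-100).
#' @param actual_lddt Per-residue LDDT in [0, 1].
#' @return `mc_ase`: `ase` in [0, 100] and `n_compared`.
#' @export
ase <- function(predicted_plddt, actual_lddt) {
  if (!is.null(names(predicted_plddt)) && !is.null(names(actual_lddt))) {
    common <- intersect(names(predicted_plddt), names(actual_lddt))
    predicted_plddt <- predicted_plddt[common]
    actual_lddt <- actual_lddt[common]
  }
  ok <- !is.na(predicted_plddt) & !is.na(actual_lddt)
  if (!any(ok)) stop("no residues with both predicted and actual values")
  val <- 100 * (1 - mean(abs(predicted_plddt[ok] / 100 - actual_lddt[ok])))
  structure(list(ase = val, n_compared = sum(ok)), class = "mc_ase")
}

#' @export
print.mc_ase <- function(x, ...) {
  cat(sprintf("<ASE %.2f over %d residues>\n", x$ase, x$n_compared))
  invisible(x)
}

#' Fraction of evaluation units where model 1 was the best model
#'
#' Per group, the percentage of attempted EUs on which model 1 achieved the
#' best quality score among that group's submissions; ties count in model
#' 1's favour (the predictor's stated confidence is honoured). Groups that
#' attempted fewer than half of the EUs are excluded, and alternate-
#' conformation EUs can be dropped. The random expectation with 5
#' exchangeable models is 20%.
#'
#' @param submissions Data frame with columns `group`, `eu_id`, `model`
#'   (integer, 1 = the group's top-ranked entry), `score` (higher better).
#' @param n_eus_total Total number of EUs (default: distinct `eu_id`s).
#' @param alt_conf_eus Optional EU ids to exclude.
#' @return Data frame: group, attempted, best_fraction (percent), sorted
#'   descending.
#' @export
model1_best_fraction <- function(submissions, n_eus_total = NULL,
                                 alt_conf_eus = NULL) {
  stopifnot(all(c("group", "eu_id", "model", "score") %in% names(submissions)))
  if (!is.null(alt_conf_eus)) {
    submissions <- submissions[!submissions$eu_id %in% alt_conf_eus, , drop = FALSE]
  }
  if (is.null(n_eus_total)) n_eus_total <- length(unique(submissions$eu_id))
  res <- list()
  for (g in unique(submissions$group)) {
    sg <- submissions[submissions$group == g, , drop = FALSE]
    eus <- unique(sg$eu_id)
    wins <- vapply(eus, function(e) {
      se <- sg[sg$eu_id == e, , drop = FALSE]
      m1 <- se$score[se$model == 1]
      length(m1) == 1 && m1 >= max(se$score)
    }, logical(1))
    res[[g]] <- data.frame(group = g, attempted = length(eus),
                           best_fraction = 100 * mean(wins),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out <- out[out$attempted >= n_eus_total / 2, , drop = FALSE]
  out[order(-out$best_fraction), , drop = FALSE]
}
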