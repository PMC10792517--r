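# Molecular-replacement model preparation: confidence-based trimming,
# coordinate-based rigid splitting, and the LLG points ranking (LLG values
# themselves are external inputs).

#' Trim low-confidence residues by first-atom pLDDT
#'
#' Removes every residue whose FIRST atom's B-column value is strictly
#' below the cutoff — deliberately the first atom, not the residue mean,
#' reproducing the preparation tool's behaviour on atomic-level pLDDTs.
#'
#' @param model A prediction `mc_structure` with pLDDT in the B column.
#' @param cutoff Confidence cutoff, default 70.
#' @return The trimmed `mc_structure`.
#' @export
trim_by_plddt <- function(model, cutoff = mc_defaults()$plddt_trim_cutoff) {
  k <- res_key(model$atoms)
  first <- !duplicated(k)
  keep_keys <- k[first][model$atoms$b[first] >= cutoff]
  if (!length(keep_keys)) stop("all residues fall below the confidence cutoff")
  model$atoms <- model$atoms[k %in% keep_keys, , drop = FALSE]
  model
}

# Sequential (BIRCH-style) leaf clustering of points: assign each point to
# the nearest existing centroid within threshold, else open a new cluster.
seq_cluster <- function(xyz, threshold) {
  cen <- matrix(numeric(0), 0, 3)
  size <- integer(0)
  lab <- integer(nrow(xyz))
  for (i in seq_len(nrow(xyz))) {
    if (nrow(cen)) {
      d <- sqrt(rowSums(sweep(cen, 2, xyz[i, ])^2))
      j <- which.min(d)
    } else d <- Inf
    if (length(d) && min(d) <= threshold) {
      lab[i] <- j
      cen[j, ] <- (cen[j, ] * size[j] + xyz[i, ]) / (size[j] + 1)
      size[j] <- size[j] + 1L
    } else {
      cen <- rbind(cen, xyz[i, ])
      size <- c(size, 1L)
      lab[i] <- nrow(cen)
    }
  }
  list(labels = lab, centroids = cen)
}

#' Split a model into k rigid pieces by Calpha clustering
#'
#' Incremental (BIRCH-style) clustering of Calpha coordinates. The distance
#' threshold starts at a quarter of the Calpha radius of gyration and is
#' tightened until at least k leaf clusters emerge; nearest centroids are
#' then merged down to exactly k. Sequence segments shorter than 3 residues
#' are reassigned to their flanking piece.
#'
#' @param model An `mc_structure`.
#' @param k Number of pieces, 2-4.
#' @return List: `pieces` (list of k `mc_structure`s) and `assignment`
#'   (integer per residue, in order).
#' @export
slice_rigid <- function(model, k) {
  if (k < 2 || k > 4) stop("k must be between 2 and 4")
  rt <- residue_table(model)
  if (nrow(rt) < k) stop("fewer residues than pieces")
  ca <- ca_coords(model)
  n <- nrow(ca$xyz)
  cen0 <- colMeans(ca$xyz)
  rg <- sqrt(mean(rowSums(sweep(ca$xyz, 2, cen0)^2)))
  thr <- rg / 4
  cl <- seq_cluster(ca$xyz, thr)
  while (max(cl$labels) < k && thr > 1e-3) {
    thr <- thr * 0.7
    cl <- seq_cluster(ca$xyz, thr)
  }
  lab <- cl$labels
  cen <- cl$centroids
  # agglomerate nearest centroids down to exactly k
  while (length(unique(lab)) > k) {
    ids <- sort(unique(lab))
    cmat <- t(vapply(ids, function(i) colMeans(ca$xyz[lab == i, , drop = FALSE]),
                     numeric(3)))
    d <- as.matrix(stats::dist(cmat))
    diag(d) <- Inf
    mi <- which(d == min(d), arr.ind = TRUE)[1, ]
    lab[lab == ids[mi[2]]] <- ids[mi[1]]
  }
  lab <- match(lab, sort(unique(lab)))
  # smoothing: sequence segments < 3 residues join their flanking piece
  repeat {
    r <- rle(lab)
    short <- which(r$lengths < 3)
    if (!length(short) || length(r$lengths) == 1) break
    j <- short[1]
    nb <- if (j == 1) 2 else j - 1
    r$values[j] <- r$values[nb]
    lab <- inverse.rle(r)
    if (length(unique(lab)) < k) break  # cannot smooth further without losing a piece
  }
  lab <- match(lab, unique(lab))
  pieces <- lapply(seq_len(max(lab)), function(p) {
    keys <- ca$keys[lab == p]
    pm <- model
    pm$atoms <- model$atoms[res_key(model$atoms) %in% keys, , drop = FALSE]
    pm$id <- sprintf("%s_piece%d", model$id, p)
    pm
  })
  list(pieces = pieces, assignment = lab)
}

#' LLG points ranking across targets
#'
#' Every group that attempted at least one target defines the points pool
#' x. On each target, groups are ranked by descending LLG and receive x,
#' x-1, ...; rows below the LLG threshold score 0, as do groups that did
#' not attempt the target. Tied LLGs share the higher points value.
#'
#' @param table Data frame `group, target, llg` (absent row or NA llg =
#'   not attempted).
#' @param llg_min Minimum LLG to score, default 60.
#' @return `data.frame(group, points)` sorted descending.
#' @export
llg_points <- function(table, llg_min = mc_defaults()$llg_min) {
  stopifnot(all(c("group", "target", "llg") %in% names(table)))
  att <- table[!is.na(table$llg), , drop = FALSE]
  if (!nrow(att)) stop("no attempted predictions in the table")
  groups <- unique(table$group)
  x <- length(unique(att$group))
  pts <- setNames(rep(0, length(groups)), groups)
  for (tg in unique(att$target)) {
    st <- att[att$target == tg, , drop = FALSE]
    st <- st[order(-st$llg), , drop = FALSE]
    # ties share the higher points value
    r <- rank(-st$llg, ties.method = "min")
    p <- pmax(x - r + 1, 0)
    p[st$llg < llg_min] <- 0
    pts[st$group] <- pts[st$group] + p
  }
  out <- data.frame(group = names(pts), points = as.numeric(pts),
                    stringsAsFactors = FALSE)
  out[order(-out$points), , drop = FALSE]
}
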