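# Shared fixtures and independent oracles. Fixtures are built in code;
# oracles are deliberately naive (brute force / enumeration) and stay
# independent of the implementation paths they check.

fx_helix <- function(n = 12, seq_ = NULL, ...) {
  if (is.null(seq_)) seq_ <- strrep("A", n)
  build_peptide(seq_, ...)
}

# Target plus a model that is a perturbed copy, with its residue map.
fx_pair <- function(n = 12, seq_ = NULL, sigma = 0, seed = 1, ...) {
  tg <- fx_helix(n, seq_)
  pm <- perturb(tg, global_sigma = sigma, seed = seed, ...)
  list(target = tg, model = pm, map = map_residues(tg, pm))
}

# Identity map: the model is the target re-labelled as a prediction.
fx_identity_map <- function(tg) {
  pm <- tg
  pm$role <- "prediction"
  pm$cell <- NULL
  pm$space_group <- NULL
  map_residues(tg, pm)
}

# Minimal hand-made structure from a table of (chain, resno, restype,
# atom name, x, y, z); single-atom residues allowed.
fx_raw_structure <- function(df, role = "target", b = 0) {
  atoms <- data.frame(type = "ATOM", eleno = seq_len(nrow(df)),
                      elety = df$elety, alt = "", resid = df$resid,
                      chain = df$chain, resno = df$resno, insert = "",
                      x = df$x, y = df$y, z = df$z, o = 1, b = b,
                      elesy = substr(gsub("[0-9]", "", df$elety), 1, 1),
                      stringsAsFactors = FALSE)
  modelcritic:::new_structure(atoms, id = "raw", role = role)
}

# Apply a fixed rigid transform to a structure (for invariance tests).
fx_rigid_copy <- function(x, angle = 35, axis = c(1, 2, 3), trans = c(5, -3, 2)) {
  R <- modelcritic:::rotation_about_axis(axis, angle)
  xyz <- as.matrix(x$atoms[, c("x", "y", "z")])
  x$atoms[, c("x", "y", "z")] <- sweep(t(R %*% t(xyz)), 2, trans, "+")
  x$role <- "prediction"
  x$cell <- NULL
  x
}

# --- Oracles -------------------------------------------------------------

# Exhaustive-seed GDT fraction at one threshold: superpositions seeded from
# every Calpha triple, iterated to a fixed point; best inlier count.
oracle_gdt_fraction <- function(txyz, mxyz, threshold, n_frame) {
  n <- nrow(txyz)
  best <- 0L
  combs <- utils::combn(n, 3)
  for (ci in seq_len(ncol(combs))) {
    inliers <- combs[, ci]
    for (it in 1:30) {
      sup <- tryCatch(kabsch(txyz[inliers, , drop = FALSE],
                             mxyz[inliers, , drop = FALSE]),
                      error = function(e) NULL)
      if (is.null(sup)) break
      d <- sqrt(rowSums((modelcritic:::apply_superposition(sup, mxyz) - txyz)^2))
      new_in <- which(d <= threshold)
      if (length(new_in) >= 3 && length(new_in) > best) best <- length(new_in)
      if (identical(new_in, inliers) || length(new_in) < 3) break
      inliers <- new_in
    }
  }
  best / n_frame
}

# Brute-force LDDT by direct pair enumeration over atom tables.
oracle_lddt_global <- function(map, radius = 15, thresholds = c(0.5, 1, 2, 4)) {
  ta <- map$target$atoms
  ma <- map$model$atoms
  tk <- modelcritic:::res_key(ta)
  mk <- modelcritic:::res_key(ma)
  frame <- map$frame_keys
  model_of <- function(key) map$pairs$m_key[match(key, map$pairs$t_key)]
  per_res <- sapply(frame, function(key) {
    fr <- c()
    for (i in which(tk %in% frame)) {
      if (tk[i] != key) next
      for (j in which(tk %in% frame)) {
        if (tk[j] == tk[i]) next
        dt <- sqrt(sum((ta[i, c("x", "y", "z")] - ta[j, c("x", "y", "z")])^2))
        if (dt > radius) next
        mi <- which(mk == model_of(tk[i]) & ma$elety == ta$elety[i])
        mj <- which(mk == model_of(tk[j]) & ma$elety == ta$elety[j])
        if (!length(mi) || !length(mj)) { fr <- c(fr, 0); next }
        dm <- sqrt(sum((ma[mi[1], c("x", "y", "z")] - ma[mj[1], c("x", "y", "z")])^2))
        fr <- c(fr, mean(abs(dm - dt) < thresholds))
      }
    }
    if (!length(fr)) NA_real_ else mean(fr)
  })
  per_res[!frame %in% map$pairs$t_key] <- 0
  mean(per_res, na.rm = TRUE)
}

# Two-sided Fisher p by explicit enumeration of all tables with the
# observed margins (probabilities from the hypergeometric density formula,
# built from factorials -- no shared code with the implementation).
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  lfac <- lfactorial
  ptab <- function(k) {
    exp(lfac(r1) + lfac(r2) + lfac(c1) + lfac(n - c1) - lfac(n) -
        lfac(k) - lfac(r1 - k) - lfac(c1 - k) - lfac(r2 - c1 + k))
  }
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(ks, ptab, numeric(1))
  p_obs <- ptab(tab[1, 1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
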