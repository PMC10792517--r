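test_that("LDDT is exact on identity and zero for missing residues", {
  tg <- fx_helix(8, "ALDEFYRS")
  m0 <- fx_identity_map(tg)
  r <- lddt(m0)
  expect_equal(r$global, 1.0)
  expect_true(all(r$per_residue == 1))
  # superposition-free: rigid motion changes nothing
  mm <- map_residues(tg, fx_rigid_copy(tg))
  expect_equal(lddt(mm)$global, 1.0, tolerance = 1e-9)
  # a residue deleted from the model scores 0
  partial <- tg
  k <- modelcritic:::res_key(partial$atoms)
  partial$atoms <- partial$atoms[k != "A|4|", ]
  partial$role <- "prediction"
  rp <- lddt(map_residues(tg, partial))
  expect_equal(unname(rp$per_residue["A|4|"]), 0)
  expect_lt(rp$global, 1)
})

test_that("LDDT equals the brute-force pair enumeration oracle", {
  set.seed(23)
  for (rep in 1:2) {
    pair <- fx_pair(n = 6, seq_ = "ALDEFY", sigma = 1.2, seed = 60 + rep)
    expect_equal(lddt(pair$map)$global, oracle_lddt_global(pair$map),
                 tolerance = 1e-10)
  }
})

test_that("Sphere-Grinder counts failing local environments", {
  tg <- fx_helix(20)
  expect_equal(sphere_grinder(fx_identity_map(tg)), 100)
  pm <- perturb(tg, segment_transforms = list(
    list(start = 8, end = 12, translation = c(10, 0, 0))), seed = 1)
  map <- map_residues(tg, pm)
  sg <- sphere_grinder(map)
  # independent count: residues whose 6 A target sphere mixes moved and
  # unmoved atoms get local RMSD > 2
  amap <- modelcritic:::matched_atom_rows(map)
  txyz <- modelcritic:::atom_xyz(map$target, amap$t_row)
  mxyz <- modelcritic:::atom_xyz(map$model, amap$m_row)
  rt <- modelcritic:::residue_table(tg)
  expected <- mean(sapply(seq_len(nrow(rt)), function(i) {
    ca <- modelcritic:::atom_xyz(tg, rt$ca[i])
    sel <- which(sqrt(rowSums(sweep(txyz, 2, ca)^2)) <= 6)
    if (length(sel) < 3) return(TRUE)
    kabsch(txyz[sel, , drop = FALSE], mxyz[sel, , drop = FALSE])$rmsd <= 2
  })) * 100
  expect_equal(sg, expected)
  expect_lt(sg, 100)
})

test_that("CAD surrogate spans its bounds and matches the truncated formula", {
  tg <- fx_helix(8, "ALDEFYRS")
  expect_equal(cad_aa(fx_identity_map(tg)), 1.0)
  # all contacts destroyed: residues pulled far apart one by one
  blown <- tg
  k <- modelcritic:::res_key(blown$atoms)
  for (i in 1:8) {
    sel <- k == paste0("A|", i, "|")
    blown$atoms$x[sel] <- blown$atoms$x[sel] + i * 100
  }
  blown$role <- "prediction"
  expect_equal(cad_aa(map_residues(tg, blown)), 0.0)
  # perturbed model: score equals the formula applied to measured areas
  pm <- perturb(tg, global_sigma = 1, seed = 5)
  map <- map_residues(tg, pm)
  got <- cad_aa(map, samples_per_atom = 64)
  at <- modelcritic:::contact_areas(
    modelcritic:::atom_xyz(tg), modelcritic:::vdw_radius(tg$atoms$elesy),
    modelcritic:::res_key(tg$atoms), 64)
  amap <- modelcritic:::matched_atom_rows(map)
  am <- modelcritic:::contact_areas(
    modelcritic:::atom_xyz(pm, amap$m_row),
    modelcritic:::vdw_radius(pm$atoms$elesy[amap$m_row]), amap$t_key, 64)
  tot <- 0; dv <- 0
  for (key in names(at)) {
    a_m <- if (is.null(am[[key]])) 0 else am[[key]]
    tot <- tot + at[[key]]
    dv <- dv + min(abs(a_m - at[[key]]), at[[key]])
  }
  expect_equal(got, 1 - dv / tot, tolerance = 1e-12)
  # sampling convergence: doubling the samples moves the score < 0.02
  expect_lt(abs(cad_aa(map, 128) - cad_aa(map, 64)), 0.02)
})

test_that("DipDiff maps mean deviation linearly onto 0-100", {
  tg <- fx_helix(6)
  expect_equal(dipdiff(fx_identity_map(tg)), 100)
  mm <- map_residues(tg, fx_rigid_copy(tg))
  expect_equal(dipdiff(mm), 100, tolerance = 1e-6)
  # against direct enumeration on a noisy model
  pm <- perturb(tg, global_sigma = 0.4, seed = 8)
  map <- map_residues(tg, pm)
  rt <- modelcritic:::residue_table(tg)
  grab <- function(x, key, nm) {
    idx <- which(modelcritic:::res_key(x$atoms) == key)
    as.matrix(x$atoms[idx[match(nm, x$atoms$elety[idx])], c("x", "y", "z")])
  }
  devs <- sapply(1:5, function(i) {
    t1 <- grab(tg, rt$key[i], c("CA", "O")); t2 <- grab(tg, rt$key[i + 1], c("CA", "O"))
    m1 <- grab(pm, rt$key[i], c("CA", "O")); m2 <- grab(pm, rt$key[i + 1], c("CA", "O"))
    dt <- c(dist(rbind(t1[1, ], t2[1, ])), dist(rbind(t1[1, ], t2[2, ])),
            dist(rbind(t1[2, ], t2[1, ])), dist(rbind(t1[2, ], t2[2, ])))
    dm <- c(dist(rbind(m1[1, ], m2[1, ])), dist(rbind(m1[1, ], m2[2, ])),
            dist(rbind(m1[2, ], m2[1, ])), dist(rbind(m1[2, ], m2[2, ])))
    mean(abs(dm - dt))
  })
  expect_equal(dipdiff(map), 100 * mean(pmax(0, 1 - devs)), tolerance = 1e-9)
  single <- build_peptide("A")
  expect_error(dipdiff(fx_identity_map(single)), "neighbouring")
})

test_that("clash surrogate counts true overlaps and respects topology", {
  # ideal helix: brute-force scan finds nothing beyond bonded geometry
  h <- fx_helix(12, "ALDEFYRSHGLL")
  expect_equal(clash_score(h), 0)
  # two non-bonded carbons 1.0 A apart: overlap 2.4, one clash in 2 atoms
  toy <- fx_raw_structure(data.frame(
    chain = "A", resno = c(1, 2), resid = "ALA", elety = c("CB", "CB"),
    x = c(0, 1), y = 0, z = 0))
  expect_equal(clash_score(toy), 500)
  # a bonded pair at covalent distance is excluded
  bonded <- fx_raw_structure(data.frame(
    chain = "A", resno = 1, resid = "ALA", elety = c("N", "CA"),
    x = c(0, 1.46), y = 0, z = 0))
  expect_equal(clash_score(bonded), 0)
})
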