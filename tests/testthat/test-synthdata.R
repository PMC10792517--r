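test_that("the ideal helix has alpha-helical hydrogen-bond geometry", {
  h <- build_peptide(strrep("A", 12), phi = -57, psi = -47)
  k <- modelcritic:::res_key(h$atoms)
  getp <- function(i, nm) {
    idx <- which(k == paste0("A|", i, "|"))
    as.numeric(h$atoms[idx[match(nm, h$atoms$elety[idx])], c("x", "y", "z")])
  }
  d <- sapply(1:8, function(i) modelcritic:::vnorm(getp(i, "O") - getp(i + 4, "N")))
  expect_true(all(d >= 2.7 & d <= 3.3))
  expect_equal(clash_score(h), 0)
  expect_error(build_peptide(c("ALA", "XYZ")), "unsupported")
})

test_that("requested chi angles survive the build and ideal structures are clean", {
  p <- build_peptide(c("LEU", "LEU"), chi = list(c(-60, 170), c(-60, 170)))
  to <- torsions(p)
  expect_equal(unname(to$chi[["A|1|"]][1]), -60, tolerance = 0.1)
  set.seed(61)
  for (i in 1:5) {
    sq <- sample(modelcritic:::SYNTH_ALPHABET, 14, TRUE)
    expect_equal(clash_score(build_peptide(sq)), 0, info = paste(sq, collapse = ""))
  }
})

test_that("a zero perturbation is the identity and transforms inject regions", {
  tg <- fx_helix(12)
  pm <- perturb(tg, seed = 5)
  expect_equal(pm$atoms$x, tg$atoms$x)
  map <- map_residues(tg, pm)
  expect_equal(gdt(map, "TS")$score, 100)
  expect_equal(lddt(map)$global, 1)
  # a translated segment becomes a detected error region
  tg40 <- fx_helix(40)
  pm40 <- perturb(tg40, segment_transforms = list(
    list(start = 20, end = 30, translation = c(10, 0, 0))), seed = 6)
  er <- error_regions(lga_distances(map_residues(tg40, pm40)))
  expect_gte(nrow(er), 1)
  rt <- modelcritic:::residue_table(tg40)
  covered <- any(er$start <= 30 & er$end >= 20)
  expect_true(covered)
  expect_error(perturb(tg, segment_transforms = list(
    list(start = 90, end = 95, translation = c(1, 0, 0))), seed = 1),
    "outside")
})

test_that("full chi resampling drives AAA to the uniform 2*tol/360 expectation", {
  set.seed(71)
  vals <- replicate(30, {
    tg <- build_peptide(c("GLY", "SER", "GLY", "SER", "GLY", "SER"),
                        chi = list(NULL, -65, NULL, 170, NULL, 60))
    pm <- perturb(tg, chi_resample_prob = 1, seed = sample.int(1e6, 1))
    aaa_score(map_residues(tg, pm))$mean
  })
  # single-chi residues, uniform resample: P(|delta| <= 40) = 80/360
  expect_equal(mean(vals), 100 * 80 / 360, tolerance = 0.15)
})

test_that("toy lattices are expandable and refuse overlapping cells", {
  # a thin extended chain in a tight cell packs against its own translates
  strand <- build_peptide(strrep("G", 12), phi = -120, psi = 135)
  tg <- make_lattice(strand, cell = c(45, 8, 30, 90, 90, 90))
  expect_equal(tg$space_group, "P 1")
  mates <- expand_lattice(tg)
  expect_gte(length(mates), 1)
  ctx <- residue_context(tg, mates = mates)
  expect_gte(max(ctx$n_lattice), 3)   # interface residues exist
  helix <- fx_helix(16)
  # the same chain in a much larger cell has no lattice context
  far <- make_lattice(helix, cell = c(200, 200, 200, 90, 90, 90))
  expect_equal(max(residue_context(far)$n_lattice), 0)
  # a 24 A helix cannot fit a 10 A cell without clashing into itself
  expect_error(make_lattice(helix, cell = c(10, 10, 10, 90, 90, 90)),
               "overlap")
})

test_that("emulated confidence tracks actual accuracy and degrades with noise", {
  tg <- fx_helix(12, "ALDEFYRSHGLL")
  pm <- perturb(tg, global_sigma = 1, seed = 8)
  exact <- emulate_plddt(pm, tg, noise_sigma = 0, seed = 9)
  map <- map_residues(tg, exact)
  conf <- extract_confidence(exact, "residue")
  lr <- lddt(map)
  pl <- conf[map$pairs$m_key]
  names(pl) <- map$pairs$t_key
  expect_equal(ase(pl, lr$per_residue)$ase, 100, tolerance = 1e-6)
  expect_true(all(conf >= 0 & conf <= 100))
  # expected ASE decreases as confidence noise grows
  set.seed(81)
  mean_ase <- sapply(c(0, 5, 15), function(sig) {
    mean(replicate(20, {
      noisy <- emulate_plddt(pm, tg, noise_sigma = sig,
                             seed = sample.int(1e6, 1))
      cf <- extract_confidence(noisy, "residue")[map$pairs$m_key]
      names(cf) <- map$pairs$t_key
      ase(cf, lr$per_residue)$ase
    }))
  })
  expect_true(all(diff(mean_ase) < 0))
})

test_that("ensembles are reproducible and enforce participation by construction", {
  e1 <- make_ensemble(n_groups = 2, n_eus = 2, skills = c(0.2, 0.8), seed = 3)
  e2 <- make_ensemble(n_groups = 2, n_eus = 2, skills = c(0.2, 0.8), seed = 3)
  expect_identical(e1$models[["E001"]][["G001"]][[1]]$atoms,
                   e2$models[["E001"]][["G001"]][[1]]$atoms)
  expect_equal(clash_score(e1$targets[["E001"]]), 0)
  # high missing rate drops a group below the 10-EU participation floor
  set.seed(91)
  em <- make_ensemble(n_groups = 2, n_eus = 14, skills = c(0.3, 0.9),
                      missing_rate = 0.9, seed = 13)
  attempts <- sapply(c("G001", "G002"), function(g) {
    sum(sapply(em$models, function(e) g %in% names(e)))
  })
  expect_true(any(attempts < 10))
  tab <- do.call(rbind, lapply(names(em$models), function(e) {
    gs <- names(em$models[[e]])
    if (!length(gs)) return(NULL)
    data.frame(eu_id = e, group = gs, S = 1)
  }))
  rk <- tryCatch(rank_groups(tab), error = function(e) NULL)
  kept <- if (is.null(rk)) character(0) else rk$group
  expect_true(all(attempts[kept] >= 10))
})

test_that("a two-group ensemble ranks the skilled group first", {
  ens <- make_ensemble(n_groups = 2, n_eus = 3, skills = c(0.1, 0.9), seed = 17)
  sc <- score_ensemble(ens)
  comp <- eu_composites(sc)
  rk <- rank_groups(comp, min_eus = 1)
  expect_equal(rk$group[1], "G002")
})
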