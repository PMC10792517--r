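test_that("lattice expansion keeps exactly the translates within reach", {
  helix <- fx_helix(16)          # ~18 A extent along each cell axis
  tg <- make_lattice(helix, cell = c(21, 21, 21, 90, 90, 90))
  mates <- expand_lattice(tg)
  # oracle: brute-force over all 26 unit translates
  om <- modelcritic:::orth_matrix(tg$cell)
  xyz <- modelcritic:::atom_xyz(tg)
  sh <- expand.grid(-1:1, -1:1, -1:1)
  sh <- sh[rowSums(abs(sh)) > 0, ]
  expected <- sum(apply(sh, 1, function(s) {
    x2 <- sweep(xyz, 2, as.numeric(om %*% as.numeric(s)), "+")
    modelcritic:::fields_mindist2(xyz, x2) <= 100
  }))
  expect_equal(length(mates), expected)
  expect_gte(length(mates), 2)   # at least the two axis neighbours
  # a huge cell leaves no mates; a prediction has no lattice at all
  far <- make_lattice(helix, cell = c(200, 200, 200, 90, 90, 90))
  expect_equal(length(expand_lattice(far)), 0)
  expect_warning(m0 <- expand_lattice(perturb(helix, seed = 1)), "no crystal cell")
  expect_equal(length(m0), 0)
})

test_that("residue context applies the 3-contact rule with precedence", {
  # single-atom residues at exact distances: 3 mates at 9.9 A -> lattice
  mk <- function(n, offs) fx_raw_structure(data.frame(
    chain = "A", resno = 1, resid = "GLY", elety = "CA",
    x = 0, y = 0, z = 0))
  target <- fx_raw_structure(data.frame(
    chain = "A", resno = 1, resid = "GLY", elety = "CA", x = 0, y = 0, z = 0))
  mate3 <- fx_raw_structure(data.frame(
    chain = "A", resno = 1:3, resid = "GLY", elety = "CA",
    x = c(9.9, 0, 0), y = c(0, 9.9, 0), z = c(0, 0, 9.9)))
  ctx3 <- residue_context(target, mates = list(mate3))
  expect_equal(ctx3$label, "lattice")
  expect_equal(ctx3$n_lattice, 3)
  mate2 <- mate3
  mate2$atoms <- mate2$atoms[1:2, ]
  expect_equal(residue_context(target, mates = list(mate2))$label, "none")
  # three other-chain neighbours and no lattice -> chain
  twochain <- fx_raw_structure(data.frame(
    chain = c("A", "B", "B", "B"), resno = c(1, 1, 2, 3), resid = "GLY",
    elety = "CA", x = c(0, 5, 0, 0), y = c(0, 0, 5, 0), z = c(0, 0, 0, 5)))
  ctx <- residue_context(twochain, mates = list())
  expect_equal(ctx$label[1], "chain")
  # precedence: a residue qualifying for lattice and chain reports lattice
  ctx_both <- residue_context(twochain, mates = list(mate3))
  expect_equal(ctx_both$label[1], "lattice")
})

test_that("error regions match the hand-computed rolling-mean boundaries", {
  d <- c(rep(0.5, 19), rep(10, 11), rep(0.5, 20))
  names(d) <- as.character(1:50)
  er <- error_regions(d)
  expect_equal(nrow(er), 1)
  expect_equal(er$start, 19)   # window 17-21 first reaches (3*0.5+2*10)/5
  expect_equal(er$end, 31)
  expect_gte(er$length, 3)
  # all-low distances produce nothing
  expect_equal(nrow(error_regions(rep(1, 30))), 0)
  # a one-residue dip whose rolling mean stays hot merges two runs
  d2 <- c(rep(0.5, 10), rep(10, 4), 0.5, rep(10, 4), rep(0.5, 10))
  er2 <- error_regions(d2)
  expect_equal(nrow(er2), 1)
  # idempotent under zero-error padding
  d3 <- c(rep(0, 7), d, rep(0, 7))
  er3 <- error_regions(d3)
  expect_equal(er3$end - er3$start, er$end - er$start)
  expect_equal(er3$start, er$start + 7)
  # absent residues break runs
  d4 <- d
  d4[25] <- NA
  er4 <- error_regions(d4)
  expect_equal(nrow(er4), 2)
  expect_true(all(er4$start != 25 & er4$end != 25))
  # self-audit: every reported region re-checks its defining inequalities
  roll <- modelcritic:::rolling_mean(d, 5)
  for (i in seq_len(nrow(er))) {
    expect_true(all(roll[er$start[i]:er$end[i]] >= 3))
  }
})

test_that("region context uses the 0.5 mean-neighbour rule", {
  # region of 2 residues, exactly 1 lattice neighbour total -> mean 0.5
  target <- fx_raw_structure(data.frame(
    chain = "A", resno = 1:2, resid = "GLY", elety = "CA",
    x = c(0, 50), y = 0, z = 0))
  mate <- fx_raw_structure(data.frame(
    chain = "A", resno = 1, resid = "GLY", elety = "CA", x = 5, y = 0, z = 0))
  lbl <- region_context(c("A|1|", "A|2|"), target, mates = list(mate))
  expect_equal(lbl, "lattice")   # mean exactly 0.5 qualifies
  expect_equal(region_context(c("A|2|"), target, mates = list(mate)), "none")
  # chain neighbours at 1 per residue, no lattice -> chain
  pairchain <- fx_raw_structure(data.frame(
    chain = c("A", "A", "B", "B"), resno = c(1, 2, 1, 2), resid = "GLY",
    elety = "CA", x = c(0, 4, 0, 4), y = c(0, 0, 3, 3), z = 0))
  expect_equal(region_context(c("A|1|", "A|2|"), pairchain, mates = list()),
               "chain")
})

test_that("B-factor bins are equal-sized and track coupled noise", {
  # degenerate: constant B within a target normalises to all-zero
  res0 <- data.frame(target_id = "T", b = 5, error = runif(30), gdt_ts = 90)
  b0 <- bfactor_bins(res0)
  expect_equal(sum(b0$n), 30)
  expect_true(max(b0$n) - min(b0$n) <= 1)
  # models failing the GDT_TS > 80 filter are ignored
  res_bad <- res0
  res_bad$gdt_ts <- 80
  expect_error(bfactor_bins(res_bad), "no qualifying")
  # error proportional to B gives strictly increasing bin means
  set.seed(51)
  res1 <- do.call(rbind, lapply(1:4, function(t) {
    b <- rgamma(50, 2, scale = 10)
    data.frame(target_id = paste0("T", t), b = b,
               error = 0.2 * b + rnorm(50, 0, 0.1), gdt_ts = 95)
  }))
  b1 <- bfactor_bins(res1)
  expect_true(all(diff(b1$mean_error) > 0))
  expect_true(max(b1$n) - min(b1$n) <= 1)
})
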