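test_that("structures round-trip through PDB preserving coordinates", {
  tg <- fx_helix(5, "ALDEF")
  tg$atoms$b <- seq_len(nrow(tg$atoms)) %% 90
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(tg, path)
  back <- read_structure(path, role = "target")
  expect_equal(nrow(back$atoms), nrow(tg$atoms))
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               as.matrix(tg$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(back$atoms$b, round(tg$atoms$b, 2), tolerance = 1e-6)
  expect_equal(back$atoms$elety, tg$atoms$elety)
})

test_that("CRYST1 cell and space group survive a write/read cycle", {
  tg <- make_lattice(fx_helix(6), cell = c(20, 20, 20, 90, 90, 90))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(tg, path)
  back <- read_structure(path)
  expect_equal(back$cell, c(20, 20, 20, 90, 90, 90))
  expect_equal(back$space_group, "P 1")
  # predictions do not carry a cell
  expect_null(perturb(tg, seed = 1)$cell)
})

test_that("parsing drops hydrogens/HETATM and resolves altlocs by occupancy", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.60 10.00           C",
    "ATOM      3  CA BALA A   1       1.500   0.100   0.000  0.40 10.00           C",
    "ATOM      4  C   ALA A   1       2.009   1.420   0.000  1.00 10.00           C",
    "ATOM      5  O   ALA A   1       1.251   2.390   0.000  1.00 10.00           O",
    "ATOM      6  H   ALA A   1       0.500   0.500   0.000  1.00 10.00           H",
    "HETATM    7  O   HOH A 101       9.000   9.000   9.000  1.00 20.00           O",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  x <- read_structure(path)
  expect_equal(nrow(x$atoms), 4)            # N, CA(A), C, O
  ca <- x$atoms[x$atoms$elety == "CA", ]
  expect_equal(ca$x, 1.458)                  # altloc A kept (occ 0.6)
  expect_false(any(x$atoms$elesy == "H"))
  expect_false(any(x$atoms$resid == "HOH"))
  expect_error(read_structure(withr::local_tempfile(fileext = ".pdb")),
               "not found")
})

test_that("residue mapping covers identity, renumbering and deletions", {
  tg <- fx_helix(10, "ALDEFYRSHG")
  m0 <- fx_identity_map(tg)
  expect_equal(m0$coverage, 1.0)

  shifted <- tg
  shifted$atoms$resno <- shifted$atoms$resno + 100
  shifted$role <- "prediction"
  m1 <- map_residues(tg, shifted)           # alignment fallback
  expect_equal(m1$coverage, 1.0)
  expect_true(all(m1$pairs$same_type))

  partial <- tg
  k <- modelcritic:::res_key(partial$atoms)
  partial$atoms <- partial$atoms[!k %in% c("A|3|", "A|7|"), ]
  partial$role <- "prediction"
  m2 <- map_residues(tg, partial)
  expect_equal(m2$coverage, 0.8)
})

test_that("EU restriction filters pairs and recomputes coverage", {
  tg <- fx_helix(20)
  map <- fx_identity_map(tg)
  eu_full <- list(ranges = data.frame(chain = "A", start = 1, end = 20))
  expect_equal(restrict_to_eu(map, eu_full)$coverage, 1.0)
  eu_half <- list(ranges = data.frame(chain = "A", start = 1, end = 10))
  r <- restrict_to_eu(map, eu_half)
  expect_equal(nrow(r$pairs), 10)
  expect_equal(length(r$frame_keys), 10)
  eu_bad <- list(ranges = data.frame(chain = "A", start = 100, end = 120))
  expect_error(restrict_to_eu(map, eu_bad), "no target residues")
  # restricting then mapping matches mapping then restricting
  pm <- perturb(tg, global_sigma = 1, seed = 3)
  m_then_r <- restrict_to_eu(map_residues(tg, pm), eu_half)
  expect_equal(sort(m_then_r$pairs$t_key),
               sort(map_residues(tg, pm)$pairs$t_key[1:10]))
})

test_that("EU tables parse the range syntax and vocabularies", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("target_id\teu_id\tselection\tdifficulty\ttaxonomy",
               "T1\tT1-D1\tA:1-10+A:15-20\tFM\tVirus"), path)
  tab <- read_eu_table(path)
  expect_equal(nrow(tab$ranges[[1]]), 2)
  expect_equal(tab$ranges[[1]]$end, c(10, 20))
  writeLines(c("target_id\teu_id\tselection\tdifficulty\ttaxonomy",
               "T1\tT1-D1\tA:1-10\tImpossible\tVirus"), path)
  expect_error(read_eu_table(path), "difficulty")
})

test_that("confidence extraction averages atoms and flags wrong scales", {
  tg <- fx_helix(3)
  pm <- perturb(tg, seed = 1)
  pm$atoms$b <- 90
  expect_equal(unname(extract_confidence(pm, "residue")), rep(90, 3))
  k <- modelcritic:::res_key(pm$atoms)
  pm$atoms$b[k == "A|2|"] <- c(60, 80, 100, 80, 80)[seq_len(sum(k == "A|2|"))]
  expect_equal(unname(extract_confidence(pm, "residue"))[2],
               mean(pm$atoms$b[k == "A|2|"]))
  pm$atoms$b <- 0.9   # pLDDT on the wrong (0-1) scale: passed through
  expect_warning(v <- extract_confidence(pm, "residue"), "off-scale")
  expect_equal(unname(v), rep(0.9, 3))
})

test_that("Neff/length matches clustering arithmetic", {
  msa10 <- rep(strrep("A", 100), 10)
  expect_equal(neff_per_length(msa10), 1 / 100)   # one cluster of 10
  expect_equal(neff_per_length(strrep("K", 50)), 1 / 50)  # singleton
  set.seed(9)
  alph <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")
  repeat {  # 5 mutually <80%-identical sequences of length 50
    seqs <- replicate(5, paste(sample(alph, 50, TRUE), collapse = ""))
    mats <- strsplit(seqs, "")
    ids <- outer(1:5, 1:5, Vectorize(function(i, j) mean(mats[[i]] == mats[[j]])))
    if (all(ids[upper.tri(ids)] < 0.8)) break
  }
  expect_equal(neff_per_length(seqs), 5 / 50)
  # monotone: lowering the threshold merges clusters, never splits them
  expect_lte(neff_per_length(seqs, identity_threshold = 0.05),
             neff_per_length(seqs, identity_threshold = 0.8))
  expect_error(neff_per_length(character(0)), "empty")
})
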