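test_that("two-round z excludes outliers then rescores everyone", {
  expect_warning(z1 <- two_round_z(c(a = 5)), "fewer than 2")
  expect_equal(unname(z1), 0)
  expect_equal(unname(two_round_z(c(4, 4, 4, 4))), rep(0, 4))
  # hand-worked case: -50 is a round-1 outlier (z about -2.2); the five
  # survivors have mean 10 and population sd sqrt(0.4)
  z <- two_round_z(c(g1 = 10, g2 = 11, g3 = 9, g4 = 10, g5 = 10, g6 = -50))
  expect_equal(unname(z[1:5]), c(0, 1, -1, 0, 0) / sqrt(0.4), tolerance = 1e-9)
  expect_lt(z["g6"], -90)
  # boundary case: z exactly -2 is not excluded (strictly-below rule)
  z2 <- two_round_z(c(10, 10, 10, 10, 0))
  expect_equal(unname(z2), c(0.5, 0.5, 0.5, 0.5, -2), tolerance = 1e-9)
  # location/scale equivariance
  v <- c(a = 3, b = 9, c = 5, d = 7, e = -20)
  expect_equal(two_round_z(2.5 * v + 11), two_round_z(v), tolerance = 1e-9)
  # lower-better metrics are negated before scoring
  expect_equal(two_round_z(v, "lower"), two_round_z(-v, "higher"))
})

test_that("the composite applies the 1/16, 1/12, 1/4 weight groups", {
  metrics <- c("lddt", "cad_aa", "sg", "sidechain_dev", "clash",
               "backbone_dev", "dipdiff", "gdt_ha", "ase", "rellg")
  z0 <- setNames(rep(0, 10), metrics)
  expect_equal(composite(z0, include_rellg = TRUE), 0)
  z1 <- setNames(rep(1, 10), metrics)
  expect_equal(composite(z1, include_rellg = TRUE), 4 / 16 + 3 / 12 + 3 / 4) # 1.25
  expect_equal(composite(z1[1:9], include_rellg = FALSE), 1.0)
  zg <- z0
  zg["gdt_ha"] <- 2
  expect_equal(composite(zg, include_rellg = TRUE), 0.5)
  # linear in each component with its group weight
  for (m in metrics) {
    zm <- z0; zm[m] <- 1
    w <- if (m %in% c("lddt", "cad_aa", "sg", "sidechain_dev")) 1 / 16
         else if (m %in% c("clash", "backbone_dev", "dipdiff")) 1 / 12 else 1 / 4
    expect_equal(composite(zm, include_rellg = TRUE), w)
  }
  expect_warning(composite(z1[1:5], include_rellg = FALSE), "missing")
})

test_that("group ranking floors contributions at zero and filters participation", {
  eus <- sprintf("E%03d", 1:112)
  tab <- rbind(
    data.frame(eu_id = eus, group = "Better", S = 1),
    data.frame(eu_id = eus, group = "Worse", S = 0.5),
    data.frame(eu_id = eus[1:9], group = "Dropout", S = 5))
  rk <- rank_groups(tab)
  expect_equal(rk$group[1], "Better")
  expect_false("Dropout" %in% rk$group)   # 9 of 112 EUs is below threshold
  # negative composites do not subtract
  tab2 <- rbind(
    data.frame(eu_id = eus[1:12], group = "A", S = c(rep(1, 11), -50)),
    data.frame(eu_id = eus[1:12], group = "B", S = rep(0.9, 12)))
  rk2 <- rank_groups(tab2)
  expect_equal(rk2$total[rk2$group == "A"], 11)
  expect_equal(rk2$group[1], "A")
  # adding an EU never lowers a total
  tab3 <- rbind(tab2, data.frame(eu_id = "E113", group = "A", S = -3))
  expect_equal(rank_groups(tab3)$total[rk2$group == "A"], 11)
  # ties share the better rank
  tie <- rbind(data.frame(eu_id = eus[1:10], group = "X", S = 1),
               data.frame(eu_id = eus[1:10], group = "Y", S = 1))
  expect_equal(rank_groups(tie)$rank, c(1, 1))
})

test_that("best-model counts give strict maxima full credit and split ties", {
  tab <- rbind(
    data.frame(eu_id = c("E1", "E2", "E3"), group = "A", value = c(90, 80, 70)),
    data.frame(eu_id = c("E1", "E2", "E3"), group = "B", value = c(80, 80, 60)))
  counts <- best_model_counts(tab)
  expect_equal(unname(counts["A"]), 1 + 0.5 + 1)
  expect_equal(unname(counts["B"]), 0.5)
  expect_equal(sum(counts), 3)  # conservation
})

test_that("Fisher enrichment reproduces the enrichment p-value of .001", {
  # 7 of 18 hard EUs viral versus 6 of 91 others
  tab <- matrix(c(7, 6, 11, 85), 2, 2)
  p <- fisher_enrichment(tab)
  expect_equal(round(p, 3), 0.001)
  expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  expect_equal(fisher_enrichment(matrix(c(5, 5, 5, 5), 2, 2)), 1.0)
  expect_equal(fisher_enrichment(matrix(c(0, 0, 3, 4), 2, 2)), 1)  # zero margin
  set.seed(31)
  for (i in 1:20) {
    t2 <- matrix(rpois(4, 6), 2, 2)
    expect_equal(fisher_enrichment(t2), oracle_fisher(t2), tolerance = 1e-12)
    # symmetric under simultaneous row and column swaps
    expect_equal(fisher_enrichment(t2), fisher_enrichment(t2[2:1, 2:1]))
  }
})

test_that("Ward ordering groups identical columns and planted blocks", {
  set.seed(41)
  m <- matrix(rnorm(60), 6, 10)
  m[, 4] <- m[, 9]  # identical columns must end up adjacent
  wo <- ward_order(m)
  pos <- match(c(4, 9), wo$col_order)
  expect_equal(abs(diff(pos)), 1)
  # two planted row blocks stay contiguous in leaf order
  blocks <- rbind(matrix(rnorm(40, 0), 4, 10), matrix(rnorm(40, 8), 4, 10))
  ro <- ward_order(blocks)$row_order
  pos14 <- sort(match(1:4, ro))
  expect_true(identical(pos14, 1:4) || identical(pos14, 5:8))
  # single row: only columns are ordered
  sr <- ward_order(matrix(1:5, 1, 5))
  expect_equal(sr$row_order, 1)
  expect_null(sr$row_linkage)
  # all-missing column dropped with warning
  m2 <- m; m2[, 2] <- NA
  expect_warning(ward_order(m2), "all-missing")
})
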