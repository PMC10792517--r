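#!/usr/bin/env Rscript
# Local error versus structural context: (a) residue error binned by
# per-target-normalised B-factor in high-quality models, (b) error-region
# detection, (c) crystal-lattice interface labelling on a toy P1 lattice
# with interface-localised noise.

suppressMessages(library(modelcritic))
set.seed(11)
dir.create("results", showWarnings = FALSE)

## (a) B-factor bins: coordinate noise coupled to the target B-factor
rows <- list()
for (t in 1:8) {
  sq <- sample(modelcritic:::SYNTH_ALPHABET, 40, TRUE)
  tg <- build_peptide(sq, id = sprintf("T%02d", t))
  bres <- rgamma(40, shape = 2, scale = 10)
  tg$atoms$b <- bres[match(modelcritic:::res_key(tg$atoms),
                           modelcritic:::residue_table(tg)$key)]
  pm <- perturb(tg, global_sigma = 0.5, bfactor_coupling = 0.8, seed = 100 + t)
  gb <- gdt_both(map_residues(tg, pm))
  rows[[t]] <- data.frame(target_id = tg$id, b = bres,
                          error = as.numeric(gb$residue_distances),
                          gdt_ts = gb$gdt_ts)
}
bins <- bfactor_bins(do.call(rbind, rows))
cat("Mean residue error by normalised-B bin (10 bins, low to high):\n")
print(round(bins$mean_error, 3))
cat("Monotone increase:", all(diff(bins$mean_error) > 0), "\n\n")
write.table(bins, "results/04_bfactor_bins.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

## (b, c) error regions and their lattice context: a straight 30-residue
## CA-trace rod whose chain ends touch the neighbouring cell translates.
## Noise injected at the ends should yield lattice-labelled regions;
## noise in the middle should not.
rod <- data.frame(chain = "A", resno = 1:30, resid = "GLY", elety = "CA",
                  x = 3.8 * (0:29), y = rep(c(0, 1), 15), z = 0)  # slight zig-zag
tg <- modelcritic:::new_structure(
  data.frame(type = "ATOM", eleno = 1:30, elety = "CA", alt = "",
             resid = "GLY", chain = "A", resno = 1:30, insert = "",
             x = rod$x, y = rod$y, z = rod$z, o = 1, b = 0, elesy = "C"),
  id = "rod")
tg <- make_lattice(tg, cell = c(115, 30, 30, 90, 90, 90))
mates <- expand_lattice(tg)
ctx <- residue_context(tg, mates = mates)
cat("Toy lattice:", length(mates), "mates; end residues with contacts:",
    paste(which(ctx$n_lattice >= 1), collapse = ","), "\n")

label_of_displaced <- function(start) {
  pm <- perturb(tg, segment_transforms = list(
    list(start = start, end = start + 4, translation = c(0, 0, 10))),
    seed = 600 + start)
  er <- error_regions(lga_distances(map_residues(tg, pm)))
  vapply(seq_len(nrow(er)), function(i) {
    region_context(ctx$key[er$start[i]:er$end[i]], tg, mates = mates)
  }, character(1))
}
at_iface <- unlist(lapply(c(1, 26), label_of_displaced))
control <- unlist(lapply(c(10, 13, 16), label_of_displaced))
frac <- function(x) if (length(x)) mean(x == "lattice") else NA
cat("Fraction of detected regions at a lattice interface:",
    "end-noise", round(frac(at_iface), 2),
    "vs mid-chain control", round(frac(control), 2), "\n")
write.table(data.frame(condition = c("interface_noise", "midchain_control"),
                       lattice_fraction = c(frac(at_iface), frac(control))),
            "results/04_region_context.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Wrote results/04_bfactor_bins.tsv, 04_region_context.tsv\n")
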