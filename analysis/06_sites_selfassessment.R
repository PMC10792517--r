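#!/usr/bin/env Rscript
# Functional-site accuracy and self-assessment: catalytic-site RMSD under
# chemical-equivalence flips across a noise ladder, surface/buried
# side-chain accuracy, and ASE / model-1-best statistics.

suppressMessages(library(modelcritic))
set.seed(9)
dir.create("results", showWarnings = FALSE)

## catalytic triad accuracy vs global accuracy across a noise ladder
triad <- build_peptide(c("SER", "GLY", "HIS", "GLY", "ASP", "GLY", "LEU",
                         "GLY", "TYR", "GLY"),
                       chi = list(-65, NULL, c(-65, -80), NULL, c(-70, -20),
                                  NULL, c(-65, 175), NULL, c(-65, 90), NULL))
site <- data.frame(chain = "A", resno = c(1, 3, 5))
rows <- list()
for (sig in c(0, 0.3, 0.6, 1, 1.5, 2.5)) {
  pm <- perturb(triad, global_sigma = sig, seed = round(1000 * sig) + 1)
  map <- map_residues(triad, pm)
  g <- gdt(map, "HA")$score
  r <- site_rmsd(map, site, gdt_ha = g)
  rows[[length(rows) + 1]] <- data.frame(
    sigma = sig, gdt_ha = round(g, 1),
    site_rmsd = round(r$rmsd, 3), status = r$status)
}
site_tab <- do.call(rbind, rows)
cat("Catalytic-site RMSD vs GDT_HA (GDT_HA <= 30 excluded):\n")
print(site_tab, row.names = FALSE)
write.table(site_tab, "results/06_site_rmsd.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

## surface vs buried side-chain accuracy for a mildly perturbed model
tg <- build_peptide(sample(modelcritic:::SYNTH_ALPHABET, 20, TRUE))
pm <- perturb(tg, chi_resample_prob = 0.4, seed = 77)
sp <- surface_partition_aaa(tg, map_residues(tg, pm))
cat(sprintf("\nMean AAA: surface %.1f%%, buried %s\n", sp$surface_mean_aaa,
            if (is.na(sp$buried_mean_aaa)) "absent (all-surface target)"
            else sprintf("%.1f%%", sp$buried_mean_aaa)))

## self-assessment: ASE degrades with confidence noise
base <- perturb(tg, global_sigma = 1, seed = 78)
map <- map_residues(tg, base)
lr <- lddt(map)
ase_tab <- do.call(rbind, lapply(c(0, 5, 15), function(sig) {
  noisy <- emulate_plddt(base, tg, noise_sigma = sig, seed = 79 + sig)
  conf <- extract_confidence(noisy, "residue")[map$pairs$m_key]
  names(conf) <- map$pairs$t_key
  data.frame(plddt_noise = sig, ase = round(ase(conf, lr$per_residue)$ase, 2))
}))
cat("\nASE vs confidence noise:\n")
print(ase_tab, row.names = FALSE)
write.table(ase_tab, "results/06_ase.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Wrote results/06_site_rmsd.tsv, 06_ase.tsv\n")
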