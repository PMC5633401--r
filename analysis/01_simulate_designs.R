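#!/usr/bin/env Rscript
# Generates the two simulated study designs the analyses run on and
# writes them as plain CSV under results/sim/:
#   - a full-sib cage design (169 families x 11 sibs spread over 3 cages
#     each; only offspring are phenotyped), with gene-dropped genotypes
#     on a 10,946-marker panel, QC'd by MAF >= 0.05;
#   - a six-generation pedigree of 1929 animals in 8 closed breeding
#     lines with the recent three generations (35%) genotyped.
# Everything downstream (02-04) reads these files, so the whole analysis
# is reproducible from here.

library(gconnect)

seed <- 1L
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## full-sib cage design -------------------------------------------------
mcfg <- sim_config(n_markers = 10946L, seed = seed)
md <- simulate_mice_design(mcfg)
geno <- gene_drop_genotypes(md$ped, mcfg)
# parents are not genotyped in this design
off <- as_genotype_table(geno$counts[md$units$id, ])
off <- filter_maf(off, 0.05)
cat(sprintf("cage design: %d offspring in %d cages, %d markers after QC\n",
            nrow(md$units), length(unique(md$units$unit)),
            ncol(off$counts)))

write_pedigree(md$ped, file.path(out, "mice_ped.csv"))
write_units(md$units, file.path(out, "mice_units.csv"))
write_genotypes(off, file.path(out, "mice_geno.csv"))

## multi-generation line design -----------------------------------------
ccfg <- sim_config(n_markers = 7250L, seed = seed + 7L)
cs <- simulate_cattle_design(ccfg)
cg <- gene_drop_genotypes(cs$ped, ccfg)
g22 <- filter_maf(as_genotype_table(cg$counts[cs$genotyped_ids, ]), 0.05)
cat(sprintf("line design: %d animals, %d genotyped (%.0f%%), %d markers after QC\n",
            nrow(cs$ped), length(cs$genotyped_ids),
            100 * length(cs$genotyped_ids) / nrow(cs$ped),
            ncol(g22$counts)))

write_pedigree(cs$ped, file.path(out, "cattle_ped.csv"))
write_genotypes(g22, file.path(out, "cattle_geno.csv"))
writeLines(cs$genotyped_ids, file.path(out, "cattle_genotyped_ids.txt"))

# an end-to-end phenotype set for the cage design (the connectedness
# statistics never read it; it documents the model the PEVs assume)
A <- numerator_relationship(md$ped)
ph <- simulate_phenotypes(A, md$units, h2 = 0.8, seed = seed)
utils::write.csv(ph, file.path(out, "mice_pheno.csv"), row.names = FALSE)
cat("wrote", out, "\n")
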