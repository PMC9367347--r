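#!/usr/bin/env Rscript
# Stage 1 -- synthetic study population.
#
# Builds the four-breed panel (Qinchuan 658, Fu 52, Yak 48, Chaidam 69;
# 827 females in total) with per-breed allele frequencies at the three
# KAT2B markers set to the published values, then lays the eight
# body-measure traits over it.  All traits are null except CCB, which
# carries a +0.8 cm effect for TT at g.T62131C -- a worked example of the
# kind of genotype effect the association stage is meant to find.
# Also synthesizes the allele-specific reference sequences each assay needs.

suppressPackageStartupMessages(library(cgassoc))
seed <- 1L
dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)

specs <- study_population_specs(seed)
assays <- kat2b_assays()
pop <- do.call(rbind, lapply(specs, simulate_population, markers = assays))
rownames(pop) <- NULL
message(sprintf("simulated %d individuals in %d breeds (%s)",
                nrow(pop), length(specs),
                paste(sprintf("%s n=%d", names(specs),
                              vapply(specs, `[[`, 1L, "n_individuals")),
                      collapse = ", ")))

ph <- default_phenotype_specs(
  marker = "g.T62131C",
  effects = list(CCB = c(CC = 0, TC = 0, TT = 0.8, CT = 0))
)
pop <- simulate_phenotypes(pop, ph, seed = seed + 1000L)
message(sprintf("phenotyped %d traits: %s", length(ph),
                paste(names(ph), collapse = ", ")))

refs <- lapply(assays, synthesize_reference, flank_padding = 150L,
               seed = seed + 2000L)
write_reference_fasta(refs, "results/sim/references.fa")
write_population_csv(pop, "results/sim/population.csv")
message("wrote results/sim/population.csv and results/sim/references.fa")
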