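#!/usr/bin/env Rscript
# Stage 2 -- in-silico PCR-RFLP genotyping.
#
# Amplifies each individual's two haplotype references with the assay
# primers, digests with HindIII (g.T61908C) or ApaI (g.T62131C, g.C73406T),
# pools the bands on a virtual gel lane and calls the genotype from the
# band pattern.  The calls are compared against the generating genotypes:
# the chain must be error-free by construction, so any mismatch would flag
# an implementation defect.

suppressPackageStartupMessages(library(cgassoc))

pop <- read_population_csv("results/sim/population.csv")
assays <- kat2b_assays()
fasta <- Biostrings::readDNAStringSet("results/sim/references.fa")
references <- lapply(assays, function(a) {
  keys <- paste0(a$marker_id, "_", c(a$cut_allele, a$uncut_allele))
  setNames(as.character(fasta[keys]), c(a$cut_allele, a$uncut_allele))
})

for (a in assays) {
  bands_cut <- digest(find_amplicon(references[[a$marker_id]][[a$cut_allele]],
                                    a$primers)$seq, a$enzyme)
  message(sprintf("%s: %d bp amplicon; allele %s digests to {%s} bp, allele %s is uncut",
                  a$marker_id, a$amplicon_length, a$cut_allele,
                  paste(unclass(bands_cut), collapse = ", "), a$uncut_allele))
}

pop <- rflp_genotype_population(pop, assays, references)
mismatch <- sum(vapply(names(assays), function(m) {
  sum(pop[[m]] != pop[[paste0(m, "_rflp")]])
}, integer(1)))
message(sprintf("genotyped %d individuals x %d markers: %d call mismatches",
                nrow(pop), length(assays), mismatch))
stopifnot(mismatch == 0L)

write_population_csv(pop, "results/sim/genotyped.csv")
write_genotypes_vcf(pop, assays, "results/sim/genotypes.vcf")
message("wrote results/sim/genotyped.csv and results/sim/genotypes.vcf")
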