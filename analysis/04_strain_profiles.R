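#!/usr/bin/env Rscript
# Strain-level SNV profiles of the simulated samples.
#
# Reads the per-site allele-count pileups from 02_simulate.R, calls
# per-sample alleles, builds the bi-allelic SNV catalog (prevalence
# > 5% of covered samples), and summarises strain-level diversity as
# the SNV fraction in coding genes plus shared-SNV Jaccard distances
# with their PCoA embedding.

library(dropstrain)
dir.create("results/strain", showWarnings = FALSE, recursive = TRUE)

pileup <- read_pileup("results/pipeline/pileup.tsv")
calls <- call_sites(pileup)          # defaults: depth >= 5, MAF >= 0.05
catalog <- build_catalog(calls)      # bi-allelic, prevalence > 5%
print(catalog)
write_tsv(as.data.frame(catalog$sites), "results/strain/snv_catalog.tsv")

fr <- suppressWarnings(snv_fraction(catalog, calls))
write_tsv(data.frame(species = rownames(fr), as.data.frame(fr),
                     check.names = FALSE),
          "results/strain/snv_fraction.tsv")
cat("\nSNV fraction in coding genes (per species x sample):\n")
print(round(fr, 4))

d <- shared_snv_jaccard(catalog)
write_distance(d, "results/strain/snv_jaccard.tsv")
ord <- pcoa(d, n_axes = 2)
write_tsv(data.frame(sample = rownames(ord$coordinates), ord$coordinates,
                     check.names = FALSE),
          "results/strain/pcoa_snv.tsv")

# do replicates of the same medium share more polymorphic sites?
med <- sub("_D[0-9]+$", "", rownames(d))
same <- d[outer(med, med, "==") & upper.tri(d)]
diff <- d[outer(med, med, "!=") & upper.tri(d)]
cat(sprintf("\nmean shared-SNV distance: within medium %.3f, between %.3f\n",
            mean(same), mean(diff)))
cat("wrote results/strain/\n")
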