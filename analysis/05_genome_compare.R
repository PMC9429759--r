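#!/usr/bin/env Rscript
# Comparative genomics of the simulated strain genomes.
#
# Reconstructs the strain genome sequences from the demo simulation and
# asks the species-delineation questions the droplet-derived MAGs raise:
# do strains of one species sit above the 95% ANI species threshold
# while different species fall below or fail to align at all; do TETRA
# correlations tell the same story; and how large is the core genome of
# a small ortholog clustering.

library(dropstrain)
dir.create("results/genomes", showWarnings = FALSE, recursive = TRUE)

cfg <- default_config()
cm <- make_community(n_species = cfg$n_species,
                     strains_per_species = cfg$strains_per_species,
                     media = cfg$media,
                     rare_strain_fraction = cfg$rare_strain_fraction,
                     seed = cfg$seed)
g <- make_strain_genomes(cm, genome_length = cfg$genome_length,
                         coding_fraction = cfg$coding_fraction,
                         divergence_rate = cfg$divergence_rate,
                         seed = cfg$seed)
seqs <- sapply(seq_len(nrow(cm$strains)), function(i)
  paste(strain_sequence(g, cm$strains$strain[i], cm$strains$species[i]),
        collapse = ""))
names(seqs) <- cm$strains$strain
write_fasta(seqs, "results/genomes/strain_genomes.fasta")

# ANI within species sp01 (three strains) and against one sp02 strain
panel <- c(cm$strains$strain[cm$strains$species == "sp01"],
           cm$strains$strain[cm$strains$species == "sp02"][1])
ani <- matrix(NA_real_, length(panel), length(panel),
              dimnames = list(panel, panel))
for (i in panel) for (j in panel)
  ani[i, j] <- if (i == j) 100 else anib(seqs[[i]], seqs[[j]])$ani
write_distance(ani, "results/genomes/ani_matrix.tsv")
cat("ANIb matrix (% identity; NA = no alignable fragments):\n")
print(round(ani, 2))
within <- ani[1:3, 1:3][upper.tri(matrix(0, 3, 3))]
cat(sprintf("within-species ANI %.2f-%.2f%% -> %s\n",
            min(within), max(within), classify_species(min(within))))
cat(sprintf("between-species fragments alignable: %s\n",
            ifelse(all(is.na(ani[4, 1:3])), "none (different species)",
                   "some")))

# TETRA correlations across all strains; NJ tree on 1 - r
sigs <- lapply(seqs, tetra_zscores)
r <- outer(seq_along(sigs), seq_along(sigs),
           Vectorize(function(i, j) tetra_correlation(sigs[[i]], sigs[[j]])))
dimnames(r) <- list(names(seqs), names(seqs))
write_distance(r, "results/genomes/tetra_correlation.tsv")
nw <- suppressWarnings(nj_tree(1 - r))
write_newick(nw, "results/genomes/tetra_nj.nwk")

# ortholog clustering of synthetic protein sets: a conserved core plus
# genome-specific accessory proteins
set.seed(derive_seed(cfg$seed, "ortholog_demo"))
aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
        "F", "P", "S", "T", "W", "Y", "V")
core_fam <- replicate(5, paste(sample(aa, 120, TRUE), collapse = ""))
mut_prot <- function(s, k) {
  x <- strsplit(s, "")[[1]]
  x[sample(length(x), k)] <- sample(aa, k, TRUE)
  paste(x, collapse = "")
}
prots <- lapply(1:4, function(gi) {
  acc <- replicate(sample(2:4, 1), paste(sample(aa, 100, TRUE), collapse = ""))
  ps <- c(vapply(core_fam, mut_prot, "", k = 6), acc)
  setNames(ps, sprintf("g%d_p%02d", gi, seq_along(ps)))
})
names(prots) <- paste0("genome", 1:4)
cl <- cluster_orthologs(prots)
write_tsv(cl$membership, "results/genomes/ortholog_clusters.tsv")
cat(sprintf("\northolog clusters: %d total, %d core (%.1f%% core fraction)\n",
            cl$n_clusters, cl$n_core, core_fraction(cl)))
cat("wrote results/genomes/\n")
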