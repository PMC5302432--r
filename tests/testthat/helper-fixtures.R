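# Small in-code fixtures shared across test files.

# Minimal 2-genotype x 1-environment x 2-replicate table with Fe only.
tiny_records <- function() {
  data.frame(genotype = c("A", "A", "B", "B"),
             group = "Cultivar",
             environment = "2012",
             replicate = c(1L, 2L, 1L, 2L),
             yield_kg_ha = c(3000, 5000, 3800, 3900),
             conc_Fe_mg_kg = c(40, 42, 45, 44),
             stringsAsFactors = FALSE)
}

# Balanced noise-free dataset with purely additive structure:
# yield_ij = 4000 + g_i + e_j, identical replicates, constant conc.
additive_met <- function(g = c(A = -300, B = 0, C = 300),
                         e = c(E1 = -200, E2 = 200), reps = 2,
                         conc = 40) {
  rows <- expand.grid(genotype = names(g), environment = names(e),
                      replicate = seq_len(reps), stringsAsFactors = FALSE)
  rows <- rows[order(rows$genotype, rows$environment, rows$replicate), ]
  rows$group <- "Cultivar"
  rows$yield_kg_ha <- 4000 + g[rows$genotype] + e[rows$environment]
  rows$conc_Fe_mg_kg <- conc
  met_dataset(rows)
}

# A mock AMMI fit with prescribed PC1 scores, for testing ranking logic in
# isolation from the decomposition.
mock_ammi_fit <- function(perf, pc1) {
  stopifnot(identical(names(perf), names(pc1)))
  gsc <- cbind(PC1 = pc1)
  rownames(gsc) <- names(pc1)
  structure(list(grand_mean = mean(perf),
                 genotype_effects = perf - mean(perf),
                 environment_effects = c(E1 = 0, E2 = 0),
                 lambdas = c(1),
                 genotype_scores = gsc,
                 environment_scores = cbind(PC1 = c(E1 = 1, E2 = -1)),
                 var_explained = 100, anova = NULL, trait = "yield"),
            class = "ammi_fit")
}
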