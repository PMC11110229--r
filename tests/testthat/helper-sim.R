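# Compact simulation settings for fast pipeline-level tests: a 2 x 60 kb
# nuclear genome with proportionally reduced feature and NUPT counts.
small_config <- function(seed = 1L, ...) {
  sim_config(
    seed = seed,
    plastid_length = 60000,
    plastid_genes = c(tRNA_plastid = 12, tRNA_mitochondrial = 2,
                      tRNA_nuclear = 2, rRNA_prokaryotic = 2,
                      rRNA_eukaryotic = 2, self_splicing_intron = 8,
                      regulatory_RNA = 1),
    plastid_gene_len = list(tRNA_plastid = c(70, 90),
                            tRNA_mitochondrial = c(70, 90),
                            tRNA_nuclear = c(70, 90),
                            rRNA_prokaryotic = c(800, 1500),
                            rRNA_eukaryotic = c(120, 1500),
                            self_splicing_intron = c(300, 600),
                            regulatory_RNA = c(150, 250)),
    n_chrom = 2L, chrom_length = 60000,
    n_genes = 24L, exons_per_gene = c(1L, 4L),
    exon_len = c(100, 300), intron_len = c(80, 300),
    n_te = 30L, te_len = c(150, 800),
    n_other_repeat = 12L, repeat_len = c(100, 300),
    nuclear_rna_counts = c(tRNA_nuclear = 8, tRNA_plastid = 10,
                           tRNA_mitochondrial = 4, rRNA_prokaryotic = 3,
                           rRNA_eukaryotic = 4, self_splicing_intron = 6,
                           regulatory_RNA = 3, spliceosomal_RNA = 2,
                           other_RNA = 2),
    episodes = list(I = list(n = 40L, mean = 82, sd = 3),
                    II = list(n = 160L, mean = 97, sd = 1.5)),
    frag_len = c(80, 250),
    n_terms = 8L,
    ...
  )
}

# one shared small bundle per test session
shared_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "nuptr-shared-bundle")
      cache <<- simulate_bundle(small_config(seed = 42L), dir)
    }
    cache
  }
})
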