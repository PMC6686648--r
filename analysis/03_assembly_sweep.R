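#!/usr/bin/env Rscript
# Step 3 -- splicing-graph assembly sweep.
#
# Builds one compacted de Bruijn (splicing-graph) assembly per (k, c)
# setting from the pooled QC'd reads and quantifies per-library node
# counts by k-mer plurality read assignment.  The sweep spans two k-mer
# lengths and two coverage cutoffs; note each simulated fragment
# contributes two perfectly overlapping mates, so cutoffs below ~4 would
# keep most singleton sequencing errors.

library(facpred)

design <- read.csv("results/library_design.csv")
reads <- lapply(design$library_id, function(lib) {
  c(read_fastq(file.path("results/fastq_qc", paste0(lib, "_1.fastq")))$seq,
    read_fastq(file.path("results/fastq_qc", paste0(lib, "_2.fastq")))$seq)
})
names(reads) <- design$library_id

grid <- unname(Map(assembly_params, c(25L, 25L, 31L, 31L), c(5L, 10L, 5L, 10L)))
assemblies <- sweep_assemblies(reads, grid)

dir.create("results/assemblies", showWarnings = FALSE)
for (nm in names(assemblies)) {
  asm <- assemblies[[nm]]
  write_assembly_fasta(asm, file.path("results/assemblies",
                                      paste0(nm, "_nodes.fasta")))
  write.csv(cbind(asm$nodes[c("node_id", "component_id", "n_kmers")],
                  asm$counts),
            file.path("results/assemblies", paste0(nm, "_counts.csv")),
            row.names = FALSE)
  write.table(asm$edges, file.path("results/assemblies",
                                   paste0(nm, "_edges.tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
  message(sprintf("%s: %d nodes in %d splicing graphs, %d edges, %d reads assigned",
                  nm, nrow(asm$nodes), length(unique(asm$nodes$component_id)),
                  nrow(asm$edges), sum(asm$counts)))
}
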