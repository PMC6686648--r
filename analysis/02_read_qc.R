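#!/usr/bin/env Rscript
# Step 2 -- read quality control.
#
# Drops read pairs in which either mate contains one of the four screened
# Illumina adapters (or a reverse complement), truncates each read at the
# first base with Phred quality <= 15, and removes pairs with a mate
# shorter than 20 bp after truncation.  Writes trimmed libraries and a
# per-library accounting table.

library(facpred)

design <- read.csv("results/library_design.csv")
dir.create("results/fastq_qc", showWarnings = FALSE)

stats <- list()
for (lib in design$library_id) {
  res <- qc_library(file.path("results/fastq", paste0(lib, "_1.fastq")),
                    file.path("results/fastq", paste0(lib, "_2.fastq")))
  write_fastq(res$mate1, file.path("results/fastq_qc", paste0(lib, "_1.fastq")))
  write_fastq(res$mate2, file.path("results/fastq_qc", paste0(lib, "_2.fastq")))
  stats[[lib]] <- cbind(library_id = lib, res$stats)
}
stats <- do.call(rbind, stats)
write.csv(stats, "results/qc_stats.csv", row.names = FALSE)

message(sprintf("QC kept %d of %d read pairs (%.2f%%); mean post-trim length %.1f bp",
                sum(stats$reads_out), sum(stats$reads_in),
                100 * sum(stats$reads_out) / sum(stats$reads_in),
                weighted.mean(stats$mean_length_out, stats$reads_out)))
message(sprintf("dropped: %d adapter pairs, %d short pairs",
                sum(stats$dropped_adapter), sum(stats$dropped_short)))
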