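#!/usr/bin/env Rscript
# Stage 6 -- Hardy-Weinberg genotype prediction.
#
# Takes the allele-class frequencies estimated by stage 3 in the
# homozygous wild-type setting, halves the wild-type frequency for a
# heterozygous mutant background (assigning the other half to the mutant
# allele, as in a P23H/+ cross), and predicts genotype frequencies by
# random pairing of alleles. The 86% -> 43% halving anchor is recomputed
# alongside the pipeline-estimated frequencies.

suppressPackageStartupMessages(library(hitiquant))

out_dir <- "results/genotype"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

## anchor arithmetic on the published frequencies
anchor <- heterozygote_adjust(c(wild_type = 0.86, hiti = 0.10, indel = 0.04),
                              mutant_label = "P23H")
message(sprintf("anchor: wild-type 86%% halves to %.0f%% (+%.0f%% P23H)",
                100 * anchor[["wild_type"]], 100 * anchor[["P23H"]]))

## pipeline-estimated allele classes from stage 3
es <- read.delim("results/quantify/edit_summary.tsv")
cls <- es[match(c("unmodified", "indel", "hiti"), es$class), ]
measured <- allele_freqs(c(
  wild_type = cls$pct[1] / 100,
  indel = cls$pct[2] / 100,
  hiti = cls$pct[3] / 100
))
adjusted <- heterozygote_adjust(measured, mutant_label = "P23H")
hw <- hw_genotypes(adjusted)
print(as.data.frame(hw), row.names = FALSE)
stopifnot(abs(sum(hw$freq) - 1) < 1e-9)

write.table(data.frame(allele = names(adjusted),
                       freq = as.numeric(adjusted)),
            file.path(out_dir, "adjusted_allele_freqs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_hw_table(hw, file.path(out_dir, "genotype_frequencies.tsv"))

# fraction of genotypes carrying at least one functional (hiti) allele
with_hiti <- sum(hw$freq[hw$allele1 == "hiti" | hw$allele2 == "hiti"])
message(sprintf("genotypes carrying >= 1 HITI-edited allele: %.2f%%",
                100 * with_hiti))
message("genotype tables written to ", out_dir)
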