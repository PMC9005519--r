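#!/usr/bin/env Rscript
# Stage 5 -- split-read integration detection.
#
# Runs the capture-seq procedure on the stage-2 reads: align every read to
# the donor insert with the strict preset, keep partial alignments, split
# them into insert portions (> 22 nt) and flank portions (> 30 nt),
# realign flanks against the AAV vector genome and every host chromosome,
# and tally the evidence per reference. Separately counts on-target
# integration as reads anchored on the first 10 nt of the insert that map
# to the cleavage region of the target gene.

source("analysis/00_scenario.R")

out_dir <- "results/integration"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

sc <- load_scenario()
core <- donor_core(sc$donor)
reads <- read_fastq("results/reads/capture.fastq")
genome <- read_fasta("results/reads/mock_genome.fa")
aav <- read_fasta("results/reads/aav_vector.fa")[[1]]
junctions <- read.delim("results/reads/true_junctions.tsv")

parts <- find_insert_reads(reads, core)
print(parts)
write_partition_fastas(parts,
                       file.path(out_dir, "insert_portions.fa"),
                       file.path(out_dir, "flank_portions.fa"))

tally <- realign_flanks(parts, c(vector = aav, genome))
print(as.data.frame(tally), row.names = FALSE)
message("ambiguous flanks: ", attr(tally, "n_ambiguous"),
        "; unaligned: ", attr(tally, "n_unaligned"))
out <- as.data.frame(tally)
out$ambiguous <- attr(tally, "n_ambiguous")
write.table(out, file.path(out_dir, "chromosome_tally.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# the decoys must not collect evidence; the target chromosome must
decoys <- grep("^chrD", out$reference)
stopifnot(sum(out$count[decoys]) <= 0.001 * nrow(reads))
stopifnot(out$count[out$reference == "chrT"] > 0)

## on-target counting at the cleavage region (cut +/- 40 nt)
cut_abs <- junctions$pos[1]
region <- c(cut_abs - 40L, cut_abs + 40L)
otf <- ontarget_insert_frequency(reads, core, genome[["chrT"]], region)
message(sprintf(
  "on-target: %d insert-anchored reads / %d reads over the cleavage region (%.1f%%)",
  otf$count, otf$denominator, 100 * otf$frequency))
write.table(data.frame(count = otf$count, denominator = otf$denominator,
                       frequency = otf$frequency,
                       region_start = region[1], region_end = region[2]),
            file.path(out_dir, "ontarget_frequency.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

## SAM export of the insert alignments for external inspection
aln <- align_batch(reads$seq, core, preset_strict())
aln$read_id <- reads$read_id
aln$seq <- reads$seq
write_sam(aln, "donor_core", nchar(core),
          file.path(out_dir, "insert_alignments.sam"))
message("integration outputs written to ", out_dir)
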