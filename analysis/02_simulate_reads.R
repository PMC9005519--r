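#!/usr/bin/env Rscript
# Stage 2 -- synthetic read sets.
#
# Simulates an edited-allele population for the designed locus/donor pair
# (retina-like outcome mixture: most alleles unmodified, HITI in ~5%, the
# rest NHEJ INDELs and rare inverted/vector events), then emulates the
# three sequencing designs: paired-end 150-nt dual-amplicon reads,
# single-end junction-amplicon reads trimmed 600->350 nt, and
# capture-style reads over a mock genome carrying the on-target
# integration plus episomal vector copies.

source("analysis/00_scenario.R")

SEED <- 20220413L
out_dir <- "results/reads"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

sc <- load_scenario()
mixture <- outcome_mixture(unmodified = 0.85, nhej_indel = 0.06,
                           precise_hiti = 0.04, imprecise_hiti = 0.01,
                           inverted_hiti = 0.02, vector_fragment = 0.02)
alleles <- simulate_alleles(sc$locus, sc$donor, mixture, n = 2000L,
                            seed = SEED)
message("allele population: ",
        paste(names(table(alleles$outcome)), table(alleles$outcome),
              collapse = ", "))

## dual-amplicon paired reads
design <- dual_amplicon_design(sc$locus, sc$donor)
amp_reads <- simulate_amplicon_reads(alleles, design$fwd, design$rev_primers,
                                     n_reads = 8000L, read_len = 150L,
                                     sub_error_rate = 0.001,
                                     seed = SEED + 1L)
write_fastq(amp_reads, file.path(out_dir, "amplicon.fastq"))
write_truth_tsv(amp_reads, file.path(out_dir, "amplicon_truth.tsv"))

## junction-amplicon reads (5' junction), trimmed 600 -> 350
jd <- junction_amplicon_design(sc$locus, sc$donor, "five")
j_alleles <- alleles[alleles$outcome %in%
                       c("precise_hiti", "imprecise_hiti"), , drop = FALSE]
jun_reads <- simulate_junction_reads(j_alleles, jd$fwd, jd$rev,
                                     n_reads = 2000L, raw_len = 600L,
                                     trimmed_len = 350L,
                                     sub_error_rate = 0.001,
                                     seed = SEED + 2L)
write_fastq(jun_reads, file.path(out_dir, "junction5.fastq"))
write_truth_tsv(jun_reads, file.path(out_dir, "junction5_truth.tsv"))

## capture-style reads over a mock genome with the on-target integration
host <- mock_host_genome(sc$locus, n_decoys = 2L, chrom_len = 3000L,
                         seed = SEED + 3L)
host <- integrate_donor(host, sc$locus, sc$donor)
aav <- mock_aav_genome(sc$donor, seed = SEED + 4L)
core_len <- nchar(donor_core(sc$donor))
roi <- data.frame(chrom = host$target_chrom, start = host$locus_offset,
                  end = host$locus_offset + nchar(sc$locus$ref) + core_len)
cap_reads <- simulate_capture_reads(host$genome, roi, n_reads = 1500L,
                                    read_len = 150L, enrichment_factor = 50,
                                    episome = as.character(aav),
                                    episome_copies = 3L,
                                    junctions = host$junctions,
                                    seed = SEED + 5L)
write_fastq(cap_reads, file.path(out_dir, "capture.fastq"))
write_truth_tsv(cap_reads, file.path(out_dir, "capture_truth.tsv"))
write_fasta(host$genome, file.path(out_dir, "mock_genome.fa"))
write_fasta(setNames(as.character(aav), "aav_vector"),
            file.path(out_dir, "aav_vector.fa"))
write.table(host$junctions, file.path(out_dir, "true_junctions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

writeLines(c(sprintf("seed\t%d", SEED),
             sprintf("n_alleles\t%d", nrow(alleles)),
             sprintf("mixture\t%s",
                     paste(sprintf("%s=%.3f", names(mixture), mixture),
                           collapse = ",")),
             sprintf("amplicon_reads\t%d", nrow(amp_reads)),
             sprintf("junction_reads\t%d", nrow(jun_reads)),
             sprintf("capture_reads\t%d", nrow(cap_reads)),
             sprintf("sub_error_rate\t%.4f", 0.001),
             sprintf("enrichment_factor\t%d", 50L)),
           file.path(out_dir, "params.tsv"))
message("read sets written to ", out_dir)
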