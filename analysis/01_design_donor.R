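#!/usr/bin/env Rscript
# Stage 1 -- donor design.
#
# Builds the analysis scenario: a 20-nt guide placed in a synthetic first-exon
# locus, and a promoterless HITI donor (inverted target sites | STOP x3
# frames | kozak START | DsRed-sized CDS | polyA | inverted target site).
# Validates the cassette and predicts the edited allele for both
# integration orientations, confirming the re-cleavage asymmetry that the
# inverted-site design exists to create.

suppressPackageStartupMessages(library(hitiquant))

SEED <- 20220412L
out_dir <- "results/design"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

set.seed(SEED)
bases <- c("A", "C", "G", "T")
protospacer <- paste(sample(bases, 20, replace = TRUE), collapse = "")
guide <- guide_spec(protospacer)
ref <- paste0(paste(sample(bases, 150, replace = TRUE), collapse = ""),
              protospacer, "AGG",
              paste(sample(bases, 150, replace = TRUE), collapse = ""))
locus <- place_guide(ref, guide)
message("guide placed on ", locus$strand, " strand, cut_pos ", locus$cut_pos)

# DsRed-sized payload (678-nt CDS)
payload <- paste0("ATG", paste(sample(bases, 675, replace = TRUE),
                               collapse = ""))
donor <- build_donor(guide, payload, start_type = "kozak", pam = "AGG")
val <- validate_donor(donor)
print(val)
stopifnot(attr(val, "ok"))

fw <- predict_integration(locus, donor, "forward")
iv <- predict_integration(locus, donor, "inverted")
message("forward integration: ", fw$recleavable_sites,
        " recleavable site(s); inverted: ", iv$recleavable_sites)
stopifnot(fw$recleavable_sites == 0L, iv$recleavable_sites == 2L)

write_fasta(setNames(as.character(locus$ref), "locus"),
            file.path(out_dir, "locus.fa"))
write_donor_fasta(donor, file.path(out_dir, "donor.fa"))
locus_to_bed(locus, chrom = "locus", path = file.path(out_dir, "guide.bed"))
writeLines(c(paste0("protospacer\t", protospacer),
             paste0("pam\tAGG"),
             paste0("cut_pos\t", locus$cut_pos),
             paste0("strand\t", locus$strand)),
           file.path(out_dir, "guide.tsv"))
write.table(data.frame(check = val$check, pass = val$pass, note = val$note),
            file.path(out_dir, "validation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(c(sprintf("seed\t%d", SEED),
             sprintf("payload_len\t%d", nchar(payload)),
             sprintf("donor_len\t%d", nchar(donor$seq)),
             sprintf("core_len\t%d", nchar(donor_core(donor)))),
           file.path(out_dir, "params.tsv"))
message("donor cassette: ", nchar(donor$seq), " nt (cap 2700); outputs in ",
        out_dir)
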