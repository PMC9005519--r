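# Rebuilds the locus/donor scenario from the stage-1 outputs so that later
# stages run off files, not in-memory state. Sourced by stages 02-06.

library(hitiquant)

load_scenario <- function(design_dir = "results/design") {
  stopifnot(dir.exists(design_dir))
  guide_tab <- read.delim(file.path(design_dir, "guide.tsv"), header = FALSE,
                          col.names = c("key", "value"))
  kv <- setNames(guide_tab$value, guide_tab$key)
  guide <- guide_spec(kv[["protospacer"]])
  ref <- read_fasta(file.path(design_dir, "locus.fa"))[[1]]
  locus <- place_guide(ref, guide)
  stopifnot(locus$cut_pos == as.integer(kv[["cut_pos"]]))

  parts <- read.delim(file.path(design_dir, "donor.parts.tsv"))
  donor_seq <- read_fasta(file.path(design_dir, "donor.fa"))[[1]]
  part_seq <- function(name) {
    row <- parts[parts$part == name, ]
    substr(donor_seq, row$start + 1L, row$end)
  }
  donor <- build_donor(guide, part_seq("payload"),
                       start_type = "kozak", pam = kv[["pam"]],
                       stop_cassette = part_seq("stop_cassette"),
                       start_seq = part_seq("start_element"),
                       polya = part_seq("polya"))
  stopifnot(as.character(donor$seq) == donor_seq)
  list(guide = guide, locus = locus, donor = donor)
}
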