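test_that("reads partition into insert-only, chimeric, discarded, non-insert", {
  set.seed(61)
  loc <- fix_locus()
  don <- fix_donor()
  core <- donor_core(don)
  host_flank <- rand_seq(400)

  r_inside <- substr(core, 51, 200)                       # wholly in donor
  # chimeras with a guaranteed mismatch at the junction so the donor match
  # cannot extend into the flank by chance
  r_chim <- paste0(substr(core, 1, 60),
                   rand_seq_mismatch(90, substr(core, 61, 61)))      # 60/90
  r_short_ins <- paste0(substr(core, 1, 20),
                        rand_seq_mismatch(130, substr(core, 21, 21)))
  r_host <- substr(host_flank, 51, 200)

  pp <- find_insert_reads(c(r_inside, r_chim, r_short_ins, r_host), core)
  expect_identical(pp$n_total, 4L)
  expect_length(pp$insert_only, 1L)
  expect_identical(nrow(pp$partitions), 1L)
  expect_identical(pp$partitions$insert_len, 60L)
  expect_identical(pp$partitions$flank_len, 90L)
  expect_length(pp$discarded, 1L)   # 20-nt insert portion fails > 22
  expect_length(pp$non_insert, 1L)
  # every read lands in exactly one bucket
  expect_identical(nrow(pp$partitions) + length(pp$insert_only) +
                     length(pp$discarded) + length(pp$non_insert), 4L)
})

test_that("the 22/30-nt thresholds are strict inequalities", {
  set.seed(62)
  don <- fix_donor()
  core <- donor_core(don)
  mk <- function(ins_len, flank_len) {
    paste0(substr(core, 1, ins_len),
           rand_seq_mismatch(flank_len, substr(core, ins_len + 1,
                                               ins_len + 1)))
  }
  at22 <- find_insert_reads(mk(22, 100), core)
  expect_identical(nrow(at22$partitions), 0L)   # 22 is not > 22
  at23 <- find_insert_reads(mk(23, 100), core)
  expect_identical(nrow(at23$partitions), 1L)
  at30 <- find_insert_reads(mk(60, 30), core)
  expect_identical(nrow(at30$partitions), 0L)   # 30 is not > 30
  at31 <- find_insert_reads(mk(60, 31), core)
  expect_identical(nrow(at31$partitions), 1L)
})

test_that("lowering the length thresholds never loses partitions", {
  set.seed(63)
  loc <- fix_locus()
  don <- fix_donor()
  core <- donor_core(don)
  flank <- rand_seq(300)
  reads <- vapply(1:60, function(k) {
    i <- sample(10:80, 1); f <- sample(10:80, 1)
    paste0(substr(core, 1, i), substr(flank, 1, f))
  }, character(1))
  n_default <- nrow(find_insert_reads(reads, core)$partitions)
  n_loose <- nrow(find_insert_reads(reads, core, min_insert = 10L,
                                    min_flank = 10L)$partitions)
  n_looser <- nrow(find_insert_reads(reads, core, min_insert = 0L,
                                     min_flank = 0L)$partitions)
  expect_gte(n_loose, n_default)
  expect_gte(n_looser, n_loose)
})

test_that("flank realignment recovers the integration chromosome", {
  loc <- fix_locus()
  don <- fix_donor()
  core <- donor_core(don)
  host <- mock_host_genome(loc, n_decoys = 2, chrom_len = 2000, seed = 64)
  host <- integrate_donor(host, loc, don)
  aav <- mock_aav_genome(don, seed = 1)
  roi <- data.frame(chrom = "chrT", start = host$locus_offset,
                    end = host$locus_offset + nchar(loc$ref) + nchar(core))
  caps <- simulate_capture_reads(host$genome, roi, 800,
                                 enrichment_factor = 50,
                                 episome = as.character(aav),
                                 episome_copies = 2,
                                 junctions = host$junctions, seed = 65)
  pp <- find_insert_reads(caps, core)
  expect_gt(nrow(pp$partitions), 0L)
  refs <- c(vector = as.character(aav), host$genome)
  tal <- realign_flanks(pp, refs)
  counts <- setNames(tal$count, tal$reference)
  # the true integration chromosome ranks first among host chromosomes and
  # decoys get zero (no spurious hits above 0.1% of inspected reads)
  expect_gt(counts[["chrT"]], 0L)
  expect_lte(counts[["chrD1"]] + counts[["chrD2"]],
             0.001 * nrow(caps))
  # episomal reads produce vector-assigned flanks, not host evidence
  expect_gt(counts[["vector"]], 0L)
})

test_that("episome-only capture yields vector flanks and zero host counts", {
  loc <- fix_locus()
  don <- fix_donor()
  core <- donor_core(don)
  host <- mock_host_genome(loc, n_decoys = 1, chrom_len = 1500, seed = 66)
  aav <- mock_aav_genome(don, seed = 1)
  roi <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0))
  caps <- simulate_capture_reads(host$genome, roi, 300,
                                 enrichment_factor = 1e6,
                                 episome = as.character(aav),
                                 episome_copies = 50, seed = 67)
  expect_true(all(caps$source_chrom == ".episome"))
  pp <- find_insert_reads(caps, core)
  tal <- realign_flanks(pp, c(vector = as.character(aav), host$genome))
  counts <- setNames(tal$count, tal$reference)
  expect_identical(sum(counts[names(host$genome)]), 0L)

  # empty partitions produce an all-zero tally
  empty <- find_insert_reads(substr(as.character(aav), 200, 340), core)
  tal0 <- realign_flanks(
    data.frame(read_id = character(0), flank_seq = character(0),
               stringsAsFactors = FALSE),
    c(vector = as.character(aav)))
  expect_identical(sum(tal0$count), 0L)
})

test_that("flank ties between references are excluded as ambiguous", {
  set.seed(68)
  don <- fix_donor()
  core <- donor_core(don)
  shared <- rand_seq(300)
  parts <- data.frame(read_id = "r1",
                      flank_seq = substr(shared, 1, 80),
                      stringsAsFactors = FALSE)
  tal <- realign_flanks(parts, c(refA = shared, refB = shared))
  expect_identical(sum(tal$count), 0L)
  expect_identical(attr(tal, "n_ambiguous"), 1L)
})

test_that("on-target counting anchors on the first 10 nt of the insert", {
  set.seed(69)
  loc <- fix_locus()
  don <- fix_donor()
  core <- donor_core(don)
  host <- mock_host_genome(loc, n_decoys = 0, chrom_len = 1500, seed = 70)
  host2 <- integrate_donor(host, loc, don)
  tgt <- host2$genome[["chrT"]]
  cl <- c(host$cut_abs - 40L, host$cut_abs + 40L)

  # read across the host -> insert 5' junction: covers insert start
  j5 <- host2$junctions$pos[1]
  r_anchor <- substr(tgt, j5 - 74, j5 + 75)
  # read in the insert interior mapped within the target gene region
  r_interior <- substr(tgt, j5 + 40, j5 + 189)
  # read far from the cleavage region
  r_far <- substr(tgt, 101, 250)
  otf <- ontarget_insert_frequency(c(r_anchor, r_interior, r_far), core,
                                   tgt, cl)
  expect_identical(otf$count, 1L)
  expect_identical(otf$denominator, 2L)  # anchor + interior overlap the region

  # an unedited locus yields zero anchored reads
  tgt0 <- host$genome[["chrT"]]
  r_wt <- substr(tgt0, host$cut_abs - 74, host$cut_abs + 75)
  otf0 <- ontarget_insert_frequency(r_wt, core, tgt0,
                                    c(host$cut_abs - 40L, host$cut_abs + 40L))
  expect_identical(otf0$count, 0L)
  expect_identical(otf0$denominator, 1L)

  expect_error(
    ontarget_insert_frequency(r_wt, core, tgt0, c(-5L, 4000L)),
    "outside"
  )
})

test_that("partition FASTA dumps mirror the two intermediate files", {
  set.seed(71)
  don <- fix_donor()
  core <- donor_core(don)
  reads <- paste0(substr(core, 1, 60),
                  rand_seq_mismatch(90, substr(core, 61, 61)))
  pp <- find_insert_reads(reads, core)
  fa1 <- tempfile(fileext = ".fa"); fa2 <- tempfile(fileext = ".fa")
  write_partition_fastas(pp, fa1, fa2)
  ins <- read_fasta(fa1); fl <- read_fasta(fa2)
  expect_identical(unname(nchar(ins)), 60L)
  expect_identical(unname(nchar(fl)), 90L)
})
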