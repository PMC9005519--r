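test_that("outcome_mixture validates fractions", {
  expect_error(outcome_mixture(unmodified = 0.5), "sum to 1")
  expect_error(outcome_mixture(unmodified = 1.2, nhej_indel = -0.2), ">= 0")
  m <- outcome_mixture(unmodified = 0.7, precise_hiti = 0.3)
  expect_s3_class(m, "outcome_mixture")
})

test_that("degenerate mixtures produce the promised allele populations", {
  loc <- fix_locus()
  don <- fix_donor()
  al_u <- simulate_alleles(loc, don, outcome_mixture(unmodified = 1), 100,
                          seed = 1)
  expect_identical(nrow(al_u), 100L)
  expect_true(all(al_u$seq == as.character(loc$ref)))

  al_p <- simulate_alleles(loc, don, outcome_mixture(precise_hiti = 1), 50,
                           seed = 2)
  fw <- predict_integration(loc, don, "forward")
  expect_true(all(al_p$seq == as.character(fw$edited_allele)))
  payload <- don$parts$payload
  hits <- lengths(gregexpr(payload, al_p$seq, fixed = TRUE))
  expect_true(all(hits == 1L))
})

test_that("simulation is byte-deterministic under a fixed seed", {
  loc <- fix_locus()
  don <- fix_donor()
  mix <- outcome_mixture(unmodified = 0.5, nhej_indel = 0.2,
                         precise_hiti = 0.1, imprecise_hiti = 0.1,
                         inverted_hiti = 0.05, vector_fragment = 0.05)
  run <- function() {
    al <- simulate_alleles(loc, don, mix, 300, seed = 33)
    d <- dual_amplicon_design(loc, don)
    rd <- simulate_amplicon_reads(al, d$fwd, d$rev_primers, 400,
                                  sub_error_rate = 0.002, seed = 34)
    fq <- tempfile(fileext = ".fastq")
    write_fastq(rd, fq)
    readBin(fq, "raw", file.info(fq)$size)
  }
  expect_identical(run(), run())
})

test_that("allele truth labels reproduce the sequence exactly", {
  loc <- fix_locus()
  don <- fix_donor()
  mix <- outcome_mixture(unmodified = 0.2, nhej_indel = 0.2,
                         precise_hiti = 0.15, imprecise_hiti = 0.15,
                         inverted_hiti = 0.15, vector_fragment = 0.15)
  al <- simulate_alleles(loc, don, mix, 400, seed = 35)
  ok <- vapply(seq_len(nrow(al)), function(i) {
    identical(rebuild_allele(loc, don, al[i, ]), al$seq[i])
  }, logical(1))
  expect_true(all(ok))
})

test_that("outcome fractions match the mixture within 3 binomial sd", {
  loc <- fix_locus()
  don <- fix_donor()
  mix <- outcome_mixture(unmodified = 0.55, nhej_indel = 0.25,
                         precise_hiti = 0.1, imprecise_hiti = 0.05,
                         inverted_hiti = 0.03, vector_fragment = 0.02)
  n <- 10000L
  al <- simulate_alleles(loc, don, mix, n, seed = 36)
  obs <- table(factor(al$outcome, levels = names(mix))) / n
  for (cls in names(mix)) {
    f <- mix[[cls]]
    tol <- 3 * sqrt(f * (1 - f) / n)
    expect_lt(abs(obs[[cls]] - f), tol + 1e-12)
  }
})

test_that("error-free amplicon reads are exact substrings, count as requested", {
  loc <- fix_locus()
  don <- fix_donor()
  al <- simulate_alleles(loc, don,
                         outcome_mixture(unmodified = 0.5, precise_hiti = 0.5),
                         500, seed = 37)
  d <- dual_amplicon_design(loc, don)
  rd <- simulate_amplicon_reads(al, d$fwd, d$rev_primers, 600, seed = 38)
  expect_identical(nrow(rd), 600L)
  expect_true(all(rd$mate %in% c(1L, 2L)))
  amp_refs <- c(d$wt_ref, d$hybrid_ref)
  ok <- vapply(seq_len(nrow(rd)), function(i) {
    s <- rd$seq[i]
    if (rd$mate[i] == 2L) s <- as.character(revcomp(s))
    any(vapply(amp_refs, function(a) grepl(s, a, fixed = TRUE), logical(1)))
  }, logical(1))
  expect_true(all(ok))
})

test_that("read share of the hybrid amplicon tracks the allele fraction", {
  loc <- fix_locus()
  don <- fix_donor()
  al <- simulate_alleles(loc, don,
                         outcome_mixture(unmodified = 0.95,
                                         precise_hiti = 0.05),
                         4000, seed = 39)
  f_true <- mean(al$outcome == "precise_hiti")
  d <- dual_amplicon_design(loc, don)
  n <- 10000L
  rd <- simulate_amplicon_reads(al, d$fwd, d$rev_primers, n, seed = 40)
  f_reads <- mean(rd$outcome == "precise_hiti")
  expect_lt(abs(f_reads - f_true), 3 * sqrt(f_true * (1 - f_true) / n))
})

test_that("primers absent from every allele raise an error", {
  loc <- fix_locus()
  don <- fix_donor()
  al <- simulate_alleles(loc, don, outcome_mixture(unmodified = 1), 20,
                         seed = 41)
  expect_error(
    simulate_amplicon_reads(al, "ACGTACGTACGTACGTACGT", "TTTTGGGGCCCCAAAATTTT",
                            100, seed = 1),
    "absent"
  )
})

test_that("junction reads are trimmed to 350 nt and match the precise reference", {
  loc <- fix_locus()
  don <- fix_donor()
  jd <- junction_amplicon_design(loc, don, "five")
  al <- simulate_alleles(loc, don, outcome_mixture(precise_hiti = 1), 100,
                         seed = 42)
  rd <- simulate_junction_reads(al, jd$fwd, jd$rev, 300, seed = 43)
  expect_identical(nrow(rd), 300L)
  expect_true(all(nchar(rd$seq) <= 350L))
  expect_true(all(vapply(rd$seq, function(s)
    grepl(s, jd$junction_ref, fixed = TRUE), logical(1))))
})

test_that("a planted 40-nt junction insertion appears in junction reads", {
  loc <- fix_locus()
  don <- fix_donor()
  jd <- junction_amplicon_design(loc, don, "five")
  m40 <- indel_model(type = "fixed", fixed_length = 40L, fixed_type = "I")
  al <- simulate_alleles(loc, don, outcome_mixture(imprecise_hiti = 1), 50,
                         model = m40,
                         junction_sites = c(five = 1, three = 0, both = 0),
                         seed = 44)
  expect_true(all(nchar(al$seq) == nchar(loc$ref) +
                    nchar(donor_core(don)) + 40L))
  rd <- simulate_junction_reads(al, jd$fwd, jd$rev, 100, seed = 45)
  a <- align_local(rd$seq[1], jd$junction_ref, preset_default())
  ev <- cigar_indels(a)
  expect_true(any(ev$type == "I" & ev$length == 40L))
})

test_that("capture sampling honors enrichment and integration truth", {
  loc <- fix_locus()
  don <- fix_donor()
  host <- mock_host_genome(loc, n_decoys = 2, chrom_len = 2000, seed = 46)
  roi <- data.frame(chrom = "chrT", start = host$locus_offset,
                    end = host$locus_offset + nchar(loc$ref))

  # infinite enrichment: every read starts within reach of the ROI
  caps_inf <- simulate_capture_reads(host$genome, roi, 200,
                                     enrichment_factor = Inf, seed = 47)
  expect_true(all(caps_inf$source_chrom == "chrT"))
  expect_true(all(caps_inf$source_start >= host$locus_offset - 150L &
                    caps_inf$source_start < host$locus_offset + nchar(loc$ref)))

  # no integration: no read spans a host/donor junction, and no read
  # contains donor-core sequence
  caps0 <- simulate_capture_reads(host$genome, roi, 400,
                                  enrichment_factor = 20,
                                  junctions = host$junctions, seed = 48)
  expect_identical(sum(caps0$spans_junction), 0L)
  pp0 <- find_insert_reads(caps0, donor_core(don))
  expect_identical(nrow(pp0$partitions), 0L)
  expect_length(pp0$insert_only, 0L)

  # with an on-target integration, chimeric reads span the cut
  host2 <- integrate_donor(host, loc, don)
  roi2 <- data.frame(chrom = "chrT", start = host$locus_offset,
                     end = host$locus_offset + nchar(loc$ref) +
                       nchar(donor_core(don)))
  caps1 <- simulate_capture_reads(host2$genome, roi2, 400,
                                  enrichment_factor = 20,
                                  junctions = host2$junctions, seed = 49)
  expect_gt(sum(caps1$spans_junction), 0L)
  expect_error(simulate_capture_reads(character(0), roi, 10, seed = 1),
               "empty genome")
})
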