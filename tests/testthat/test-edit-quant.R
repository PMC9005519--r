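# reads as plain character vectors exercise the sequence-level interface

test_that("windowed INDEL frequency counts only in-window events", {
  loc <- fix_locus()
  ref <- as.character(loc$ref)
  cut <- loc$cut_pos
  # 200-nt reads centered on the cut
  mk_read <- function(s) substr(s, cut - 99, cut + 100)

  reads <- rep(mk_read(ref), 100)
  es <- window_indel_frequency(reads, loc)
  expect_identical(es$n_assigned, 100L)
  expect_identical(es$pct_indel, 0)
  expect_identical(es$pct_unmodified, 100)

  # 10 reads with a 1-nt deletion at the cut
  del1 <- paste0(substr(ref, 1, cut), substr(ref, cut + 2, nchar(ref)))
  reads2 <- c(rep(mk_read(ref), 90), rep(mk_read(del1), 10))
  es2 <- window_indel_frequency(reads2, loc)
  expect_equal(es2$pct_indel, 10.0)
  expect_identical(es2$spectrum$signed_length, -1L)
  expect_equal(es2$spectrum$pct, 10.0)

  # deletion entirely 30 nt downstream of the cut: outside the 17-nt flank
  del_out <- paste0(substr(ref, 1, cut + 30), substr(ref, cut + 34, nchar(ref)))
  es3 <- window_indel_frequency(rep(mk_read(del_out), 20), loc)
  expect_identical(es3$pct_indel, 0)
  expect_identical(es3$pct_unmodified, 100)
})

test_that("reads not spanning the window are excluded from the denominator", {
  loc <- fix_locus()
  ref <- as.character(loc$ref)
  cut <- loc$cut_pos
  covering <- substr(ref, cut - 60, cut + 60)
  upstream_only <- substr(ref, 1, cut - 5)  # stops short of the window
  es <- window_indel_frequency(c(rep(covering, 30), rep(upstream_only, 10)),
                               loc)
  expect_identical(es$n_assigned, 30L)
  expect_identical(es$n_excluded, 10L)
  expect_error(window_indel_frequency(rep(upstream_only, 5), loc),
               "no read covers")
})

test_that("enlarging the window flank never decreases pct_indel", {
  loc <- fix_locus()
  don <- fix_donor()
  al <- simulate_alleles(loc, don,
                         outcome_mixture(unmodified = 0.6, nhej_indel = 0.4),
                         300, seed = 50)
  ref <- as.character(loc$ref)
  cut <- loc$cut_pos
  # full-span reads keep the denominator fixed across window sizes
  reads <- vapply(al$seq, function(s) s, character(1), USE.NAMES = FALSE)
  pcts <- vapply(c(2L, 5L, 10L, 17L, 25L), function(fl) {
    window_indel_frequency(reads, loc, window = window_spec(fl))$pct_indel
  }, numeric(1))
  expect_true(all(diff(pcts) >= 0))
})

test_that("dual-amplicon assignment separates wild-type, indel and HITI reads", {
  loc <- fix_locus()
  don <- fix_donor()
  d <- dual_amplicon_design(loc, don)

  al0 <- simulate_alleles(loc, don, outcome_mixture(unmodified = 1), 200,
                          seed = 51)
  rd0 <- simulate_amplicon_reads(al0, d$fwd, d$rev_primers, 500, seed = 52)
  es0 <- dual_amplicon_hiti(rd0, d$wt_ref, d$hybrid_ref, d$wt_cut_pos)
  expect_identical(es0$pct_hiti, 0)
  expect_identical(es0$pct_unmodified, 100)

  expect_error(dual_amplicon_hiti(rd0, d$wt_ref, d$wt_ref, d$wt_cut_pos),
               "identical")

  # a read matching both references equally (pure shared-primer prefix)
  shared <- substr(d$wt_ref, 1, 40)
  es_amb <- dual_amplicon_hiti(c(rep(substr(d$wt_ref, 1, 170), 10), shared),
                               d$wt_ref, d$hybrid_ref, d$wt_cut_pos)
  expect_identical(es_amb$n_ambiguous, 1L)
  expect_identical(es_amb$n_assigned, 10L)
})

test_that("classes partition the assigned reads exactly", {
  loc <- fix_locus()
  don <- fix_donor()
  d <- dual_amplicon_design(loc, don)
  mix <- outcome_mixture(unmodified = 0.6, nhej_indel = 0.2,
                         precise_hiti = 0.2)
  al <- simulate_alleles(loc, don, mix, 500, seed = 53)
  rd <- simulate_amplicon_reads(al, d$fwd, d$rev_primers, 2000, seed = 54)
  es <- dual_amplicon_hiti(rd, d$wt_ref, d$hybrid_ref, d$wt_cut_pos)
  expect_identical(es$n_unmodified + es$n_indel + es$n_hiti, es$n_assigned)
  expect_equal(es$pct_unmodified + es$pct_indel + es$pct_hiti, 100,
               tolerance = 1e-9)
})

test_that("the HITI estimator is consistent across mixture fractions", {
  loc <- fix_locus()
  don <- fix_donor()
  d <- dual_amplicon_design(loc, don)
  n_reads <- 10000L
  for (f in c(0.01, 0.05, 0.2)) {
    al <- simulate_alleles(loc, don,
                           outcome_mixture(unmodified = 1 - f,
                                           precise_hiti = f),
                           5000, seed = round(1000 * f))
    f_alleles <- mean(al$outcome == "precise_hiti")
    rd <- simulate_amplicon_reads(al, d$fwd, d$rev_primers, n_reads,
                                  seed = round(2000 * f))
    es <- dual_amplicon_hiti(rd, d$wt_ref, d$hybrid_ref, d$wt_cut_pos)
    tol <- 3 * sqrt(f_alleles * (1 - f_alleles) / n_reads) * 100
    expect_lt(abs(es$pct_hiti - 100 * f_alleles), tol,
              label = sprintf("f=%.2f: |%.3f - %.3f|", f, es$pct_hiti,
                              100 * f_alleles))
  }
})

test_that("junction species are grouped, thresholded inclusively, idempotently", {
  loc <- fix_locus()
  don <- fix_donor()
  jd <- junction_amplicon_design(loc, don, "five")

  alp <- simulate_alleles(loc, don, outcome_mixture(precise_hiti = 1), 100,
                          seed = 55)
  rdp <- simulate_junction_reads(alp, jd$fwd, jd$rev, 200, seed = 56)
  jr <- classify_junctions(rdp, jd$junction_ref, jd$junction_pos)
  expect_equal(jr$pct_precise, 100)
  expect_identical(nrow(jr$species), 0L)

  # 5% of alleles carry a +40 insertion at the 5' junction
  m40 <- indel_model(type = "fixed", fixed_length = 40L, fixed_type = "I")
  al40 <- simulate_alleles(loc, don,
                           outcome_mixture(precise_hiti = 0.95,
                                           imprecise_hiti = 0.05),
                           2000, model = m40,
                           junction_sites = c(five = 1, three = 0, both = 0),
                           seed = 57)
  f40 <- mean(al40$outcome == "imprecise_hiti")
  rd40 <- simulate_junction_reads(al40, jd$fwd, jd$rev, 3000, seed = 58)
  jr40 <- classify_junctions(rd40, jd$junction_ref, jd$junction_pos,
                             policy = threshold_policy("retina"))
  sp <- jr40$species
  expect_true(any(sp$type == "I" & sp$length == 40L))
  got <- sp$pct[sp$type == "I" & sp$length == 40L]
  expect_lt(abs(got - 100 * f40), 3 * sqrt(f40 * (1 - f40) / 3000) * 100)

  # inclusive threshold at the boundary and filter idempotence
  species <- data.frame(type = c("I", "D", "I"), length = c(40L, 3L, 7L),
                        signed_length = c(40L, -3L, 7L),
                        count = c(10L, 10L, 9L),
                        pct = c(0.10, 0.10, 0.09))
  pol <- threshold_policy("retina")
  kept <- apply_threshold(species, pol)
  expect_identical(nrow(kept), 2L)           # 0.10 kept (>=), 0.09 dropped
  expect_identical(apply_threshold(kept, pol), kept)
  pol_liver <- threshold_policy("liver")
  expect_identical(pol_liver$min_species_frequency, 0.5)
  expect_identical(nrow(apply_threshold(species, pol_liver)), 0L)
})

test_that("report tables carry one row per class and species", {
  loc <- fix_locus()
  don <- fix_donor()
  d <- dual_amplicon_design(loc, don)
  al <- simulate_alleles(loc, don,
                         outcome_mixture(unmodified = 0.7, nhej_indel = 0.1,
                                         precise_hiti = 0.2),
                         300, seed = 59)
  rd <- simulate_amplicon_reads(al, d$fwd, d$rev_primers, 1000, seed = 60)
  es <- dual_amplicon_hiti(rd, d$wt_ref, d$hybrid_ref, d$wt_cut_pos)
  tab <- report_table(es, sample = "s1")
  expect_identical(tab$class[1:3], c("unmodified", "indel", "hiti"))
  expect_equal(sum(tab$pct[1:3]), 100, tolerance = 1e-9)
})
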