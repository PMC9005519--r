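#' Editing-outcome mixture
#'
#' Fractions over the six allele outcome classes produced by Cas9 cleavage
#' in the presence of a HITI donor. Fractions must be non-negative and sum
#' to 1 (within 1e-9).
#'
#' @param unmodified,nhej_indel,precise_hiti,imprecise_hiti,inverted_hiti,vector_fragment
#'   Outcome fractions.
#' @return An `outcome_mixture` named numeric vector.
#' @export
outcome_mixture <- function(unmodified = 0, nhej_indel = 0, precise_hiti = 0,
                            imprecise_hiti = 0, inverted_hiti = 0,
                            vector_fragment = 0) {
  x <- c(unmodified = unmodified, nhej_indel = nhej_indel,
         precise_hiti = precise_hiti, imprecise_hiti = imprecise_hiti,
         inverted_hiti = inverted_hiti, vector_fragment = vector_fragment)
  if (any(x < 0)) stop("outcome_mixture: fractions must be >= 0",
                       call. = FALSE)
  if (abs(sum(x) - 1) > 1e-9) {
    stop("outcome_mixture: fractions must sum to 1 (got ", sum(x), ")",
         call. = FALSE)
  }
  structure(x, class = "outcome_mixture")
}

#' NHEJ INDEL length model
#'
#' Signed INDEL lengths for NHEJ repair and imprecise junctions. The
#' default is a truncated geometric length distribution over 1..50 nt with
#' a 3:1 deletion:insertion ratio, reflecting the small-deletion dominance
#' typical of Cas9 repair spectra; `type = "fixed"` produces a single
#' species (used to plant a known junction insertion such as the 40-nt one).
#'
#' @param type `"geometric"` or `"fixed"`.
#' @param p Geometric success parameter (mean length about `1/p`).
#' @param max_len Truncation bound (lengths are in 1..`max_len`).
#' @param del_prob Probability that an event is a deletion.
#' @param fixed_length,fixed_type For `type = "fixed"`: the single species.
#' @return An `indel_model` list.
#' @export
indel_model <- function(type = c("geometric", "fixed"), p = 0.2,
                        max_len = 50L, del_prob = 0.75,
                        fixed_length = 1L, fixed_type = c("D", "I")) {
  type <- match.arg(type)
  fixed_type <- match.arg(fixed_type)
  structure(list(type = type, p = p, max_len = as.integer(max_len),
                 del_prob = del_prob, fixed_length = as.integer(fixed_length),
                 fixed_type = fixed_type),
            class = "indel_model")
}

draw_indels <- function(model, n) {
  if (n == 0L) {
    return(data.frame(type = character(0), length = integer(0)))
  }
  if (model$type == "fixed") {
    return(data.frame(type = rep(model$fixed_type, n),
                      length = rep(model$fixed_length, n),
                      stringsAsFactors = FALSE))
  }
  len <- pmin(rgeom(n, model$p) + 1L, model$max_len)
  type <- ifelse(runif(n) < model$del_prob, "D", "I")
  data.frame(type = type, length = as.integer(len), stringsAsFactors = FALSE)
}

#' Mock AAV vector genome
#'
#' The donor cassette flanked by 145-nt ITR placeholders (canonical AAV
#' ITR length; the exact ITR sequence is irrelevant to integration
#' detection, only that vector-derived fragments carry non-host,
#' non-donor-core flanks).
#'
#' @param donor A `hiti_donor`.
#' @param itr_len ITR placeholder length (default 145).
#' @param seed RNG seed for the ITR placeholder bases.
#' @return A `nuc_seq` of the vector genome.
#' @export
mock_aav_genome <- function(donor, itr_len = 145L, seed = 1L) {
  if (!is.null(seed)) set.seed(seed)
  itr5 <- as.vector(unclass(random_nucseq(itr_len)))
  itr3 <- as.vector(unclass(random_nucseq(itr_len)))
  nuc_seq(paste0(itr5, as.vector(unclass(donor$seq)), itr3), id = "aav_vector")
}

# apply recorded events (sorted by position descending) to a base sequence;
# deletions remove [pos, pos+len), insertions place ins_seq starting at pos
apply_events <- function(seq, events) {
  for (ev in events) {
    n <- nchar(seq)
    if (ev$kind == "del") {
      seq <- paste0(substr(seq, 1L, ev$pos),
                    substr(seq, ev$pos + ev$len + 1L, n))
    } else {
      seq <- paste0(substr(seq, 1L, ev$pos), ev$ins,
                    substr(seq, ev$pos + 1L, n))
    }
  }
  seq
}

#' Simulate an edited-allele population
#'
#' Draws an outcome per allele from the mixture (multinomial, seeded) and
#' constructs the corresponding sequence:
#' \itemize{
#'   \item `unmodified`: the locus reference.
#'   \item `nhej_indel`: an INDEL from `model` centered at the cut.
#'   \item `precise_hiti`: [predict_integration()] forward allele.
#'   \item `imprecise_hiti`: forward allele with INDELs from `model` at the
#'     5', 3' or both junctions (probabilities 0.4/0.4/0.2).
#'   \item `inverted_hiti`: inverted-orientation allele.
#'   \item `vector_fragment`: a random fragment (50-500 nt, random strand)
#'     of the mock AAV genome ligated at the cut.
#' }
#' Every record stores its base form and event list so the sequence can be
#' re-derived exactly ([rebuild_allele()]).
#'
#' @param locus A `target_locus`.
#' @param donor A `hiti_donor`.
#' @param mixture An [outcome_mixture()].
#' @param n Number of alleles.
#' @param model An [indel_model()].
#' @param junction_sites For `imprecise_hiti`: which junctions may receive
#'   INDELs; a probability vector over `c(five, three, both)`.
#' @param vector_genome Mock AAV genome (`nuc_seq`); defaults to
#'   [mock_aav_genome()] of the donor.
#' @param seed RNG seed.
#' @return data.frame: `allele_id`, `outcome`, `seq`, `base` (ref / forward
#'   / inverted / the vector-fragment carrier), `events` (list column).
#' @export
simulate_alleles <- function(locus, donor, mixture, n,
                             model = indel_model(),
                             junction_sites = c(five = 0.4, three = 0.4,
                                                both = 0.2),
                             vector_genome = NULL, seed = NULL) {
  stopifnot(inherits(mixture, "outcome_mixture"), n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(vector_genome)) vector_genome <- mock_aav_genome(donor, seed = 1L)
  ref <- as.vector(unclass(locus$ref))
  cut <- locus$cut_pos
  fw <- predict_integration(locus, donor, "forward")
  iv <- predict_integration(locus, donor, "inverted")
  vec <- as.vector(unclass(vector_genome))

  outcomes <- sample(names(mixture), n, replace = TRUE, prob = mixture)
  seqs <- character(n)
  bases <- character(n)
  events <- vector("list", n)

  junction_event <- function(jpos, allele_len) {
    ev <- draw_indels(model, 1L)
    if (ev$type == "D") {
      pos <- max(0L, jpos - as.integer(ceiling(ev$length / 2)))
      pos <- min(pos, allele_len - ev$length)
      list(kind = "del", pos = pos, len = ev$length)
    } else {
      list(kind = "ins", pos = jpos,
           ins = as.vector(unclass(random_nucseq(ev$length))))
    }
  }

  for (i in seq_len(n)) {
    oc <- outcomes[i]
    evs <- list()
    if (oc == "unmodified") {
      base <- "ref"; s <- ref
    } else if (oc == "nhej_indel") {
      base <- "ref"
      evs <- list(junction_event(cut, nchar(ref)))
      s <- apply_events(ref, evs)
    } else if (oc == "precise_hiti") {
      base <- "forward"; s <- as.vector(unclass(fw$edited_allele))
    } else if (oc == "imprecise_hiti") {
      base <- "forward"
      s0 <- as.vector(unclass(fw$edited_allele))
      site <- sample(names(junction_sites), 1L, prob = junction_sites)
      jpos <- c(five = fw$core_start, three = fw$core_end)
      wanted <- if (site == "both") c("three", "five") else site
      # apply 3' first so 5' coordinates stay valid
      wanted <- wanted[order(match(wanted, c("three", "five")))]
      evs <- lapply(wanted, function(w) junction_event(jpos[[w]], nchar(s0)))
      s <- apply_events(s0, evs)
    } else if (oc == "inverted_hiti") {
      base <- "inverted"; s <- as.vector(unclass(iv$edited_allele))
    } else { # vector_fragment
      base <- "ref"
      frag_len <- sample(50:min(500L, nchar(vec)), 1L)
      start <- sample.int(nchar(vec) - frag_len + 1L, 1L)
      frag <- substr(vec, start, start + frag_len - 1L)
      if (runif(1) < 0.5) frag <- revcomp_chr(frag)
      evs <- list(list(kind = "ins", pos = cut, ins = frag))
      s <- apply_events(ref, evs)
    }
    seqs[i] <- s
    bases[i] <- base
    events[[i]] <- evs
  }

  out <- data.frame(
    allele_id = sprintf("allele_%05d", seq_len(n)),
    outcome = outcomes,
    seq = seqs,
    base = bases,
    stringsAsFactors = FALSE
  )
  out$events <- events
  attr(out, "locus") <- locus
  attr(out, "donor") <- donor
  class(out) <- c("allele_set", class(out))
  out
}

#' Re-derive an allele sequence from its recorded events
#'
#' Regenerates the base form (reference, forward or inverted integration)
#' from locus and donor, then re-applies the record's event list. Equals
#' the stored `seq` for every simulated allele (truth-label consistency).
#'
#' @param locus,donor As passed to [simulate_alleles()].
#' @param record One row of an `allele_set` (data.frame with `base` and
#'   `events`).
#' @return Character scalar.
#' @export
rebuild_allele <- function(locus, donor, record) {
  base <- switch(record$base,
    ref = as.vector(unclass(locus$ref)),
    forward = unclass(predict_integration(locus, donor, "forward")$edited_allele),
    inverted = unclass(predict_integration(locus, donor, "inverted")$edited_allele),
    stop("unknown base form: ", record$base)
  )
  as.vector(apply_events(base, record$events[[1]]))
}

# locate the amplicon cut out by a primer pair on one allele; returns
# c(start, end) 1-based inclusive or NULL. Multiple rev primers: the
# shortest product wins (PCR favors short amplicons; real assays'
# allele-specific primers are designed so that only one pair amplifies).
find_amplicon <- function(seq, fwd_primer, rev_primers) {
  f <- regexpr(fwd_primer, seq, fixed = TRUE)[1]
  if (f < 0L) return(NULL)
  best <- NULL
  for (rp in rev_primers) {
    site <- revcomp_chr(rp)
    m <- gregexpr(site, seq, fixed = TRUE)[[1]]
    m <- m[m > 0L & m >= f]
    if (!length(m)) next
    end <- min(m) + nchar(site) - 1L
    if (is.null(best) || end - f < best[2] - best[1]) best <- c(f, end)
  }
  best
}

add_sub_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    k <- stats::rbinom(1L, n, rate)
    if (k == 0L) return(s)
    pos <- sample.int(n, k)
    ch <- strsplit(s, "")[[1]]
    for (p in pos) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

const_qual <- function(seqs, q = 30L) {
  strrep(rawToChar(as.raw(33L + q)), nchar(seqs))
}

#' Simulate paired-end amplicon reads
#'
#' Amplicons are cut out of each allele by primer coordinates (shared
#' forward primer, one reverse primer per reference form); read pairs are
#' sampled from the amplicon ends in FR orientation with uniform
#' substitution errors. At `sub_error_rate = 0` every read is an exact
#' substring of its source amplicon. Alleles in which no primer pair finds
#' a product (e.g. a large deletion removed a primer site) are not
#' sampled; an error is raised if no allele at all yields an amplicon.
#'
#' @param alleles An `allele_set` from [simulate_alleles()].
#' @param fwd_primer Shared forward primer (top strand).
#' @param rev_primers Character vector of reverse primers (as written 5'->3'
#'   on the bottom strand), one per reference form.
#' @param n_reads Total reads to emit (even when `paired`).
#' @param read_len Read length (default 150).
#' @param paired Paired-end (default TRUE).
#' @param sub_error_rate Per-base substitution error rate.
#' @param seed RNG seed.
#' @return A `read_set` data.frame: `read_id`, `mate`, `seq`, `qual`,
#'   `source_allele`, `outcome`.
#' @export
simulate_amplicon_reads <- function(alleles, fwd_primer, rev_primers,
                                    n_reads, read_len = 150L, paired = TRUE,
                                    sub_error_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fwd_primer <- chr_seq(fwd_primer)
  rev_primers <- vapply(rev_primers, function(x) chr_seq(x),
                        character(1), USE.NAMES = FALSE)
  amps <- lapply(alleles$seq, find_amplicon, fwd_primer = fwd_primer,
                 rev_primers = rev_primers)
  ok <- !vapply(amps, is.null, logical(1))
  if (!any(ok)) {
    stop("simulate_amplicon_reads: primers absent from all alleles",
         call. = FALSE)
  }
  if (paired && n_reads %% 2L != 0L) {
    stop("simulate_amplicon_reads: n_reads must be even for paired output",
         call. = FALSE)
  }
  n_frag <- if (paired) n_reads %/% 2L else n_reads
  idx <- sample(which(ok), n_frag, replace = TRUE)

  amp_seq <- vapply(seq_along(idx), function(k) {
    i <- idx[k]
    substr(alleles$seq[i], amps[[i]][1], amps[[i]][2])
  }, character(1))

  r1 <- substr(amp_seq, 1L, read_len)
  if (paired) {
    alen <- nchar(amp_seq)
    r2 <- revcomp_chr(substr(amp_seq, pmax(1L, alen - read_len + 1L), alen))
    seqs <- c(rbind(r1, r2))
    mates <- rep(c(1L, 2L), n_frag)
    src <- rep(alleles$allele_id[idx], each = 2L)
    ocs <- rep(alleles$outcome[idx], each = 2L)
    ids <- sprintf("read_%06d/%d", rep(seq_len(n_frag), each = 2L), mates)
  } else {
    seqs <- r1
    mates <- rep(0L, n_frag)
    src <- alleles$allele_id[idx]
    ocs <- alleles$outcome[idx]
    ids <- sprintf("read_%06d", seq_len(n_frag))
  }
  seqs <- add_sub_errors(seqs, sub_error_rate)
  out <- data.frame(read_id = ids, mate = mates, seq = seqs,
                    qual = const_qual(seqs), source_allele = src,
                    outcome = ocs, stringsAsFactors = FALSE)
  class(out) <- c("read_set", class(out))
  out
}

#' Simulate junction-amplicon reads
#'
#' Single-end reads over one integration junction, generated at `raw_len`
#' from the forward-primer end of the junction amplicon and then truncated
#' to `trimmed_len`, emulating a 600-cycle run whose reads are trimmed to
#' 350 nt before alignment. All emitted reads have length <= `trimmed_len`.
#'
#' @param alleles An `allele_set`.
#' @param fwd_primer,rev_primer Junction primer pair.
#' @param n_reads Reads to emit.
#' @param raw_len,trimmed_len Raw and post-trim read lengths (600 / 350).
#' @param sub_error_rate Per-base substitution error rate.
#' @param seed RNG seed.
#' @return A `read_set` data.frame (single-end, `mate = 0`).
#' @export
simulate_junction_reads <- function(alleles, fwd_primer, rev_primer,
                                    n_reads, raw_len = 600L,
                                    trimmed_len = 350L, sub_error_rate = 0,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  reads <- simulate_amplicon_reads(
    alleles, fwd_primer, rev_primer, n_reads = n_reads,
    read_len = as.integer(raw_len), paired = FALSE,
    sub_error_rate = sub_error_rate, seed = NULL
  )
  reads$seq <- substr(reads$seq, 1L, trimmed_len)
  reads$qual <- substr(reads$qual, 1L, trimmed_len)
  reads
}

#' Mock host genome with an embedded target locus
#'
#' Builds `n_decoys + 1` random chromosomes and embeds the locus reference
#' midway into the target chromosome.
#'
#' @param locus A `target_locus`.
#' @param n_decoys Decoy chromosomes without any integration.
#' @param chrom_len Chromosome length (nt).
#' @param seed RNG seed.
#' @return List: `genome` (named character vector), `target_chrom`,
#'   `locus_offset` (0-based), `cut_abs` (absolute 0-based cut position).
#' @export
mock_host_genome <- function(locus, n_decoys = 2L, chrom_len = 3000L,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ref <- as.vector(unclass(locus$ref))
  stopifnot(chrom_len > nchar(ref))
  offset <- (chrom_len - nchar(ref)) %/% 2L
  chrT <- paste0(as.vector(unclass(random_nucseq(offset))), ref,
                 as.vector(unclass(random_nucseq(chrom_len - offset - nchar(ref)))))
  genome <- c(chrT = chrT)
  if (n_decoys > 0L) {
    for (k in seq_len(n_decoys)) {
      genome[paste0("chrD", k)] <- as.vector(unclass(random_nucseq(chrom_len)))
    }
  }
  list(genome = genome, target_chrom = "chrT",
       locus_offset = offset, cut_abs = offset + locus$cut_pos)
}

#' Integrate the donor core into a mock genome chromosome
#'
#' Replaces the embedded locus by its edited (forward-integration) allele
#' and records the absolute host/donor junction coordinates.
#'
#' @param host Result of [mock_host_genome()] (or a compatible list).
#' @param locus,donor As for [predict_integration()].
#' @param chrom Chromosome to edit (default the target chromosome).
#' @param offset 0-based offset of the locus on `chrom`.
#' @param orientation Integration orientation.
#' @return The `host` list with updated `genome` plus `junctions`
#'   (data.frame `chrom`, `pos` of the two host/donor boundaries, 0-based).
#' @export
integrate_donor <- function(host, locus, donor,
                            chrom = host$target_chrom,
                            offset = host$locus_offset,
                            orientation = "forward") {
  pred <- predict_integration(locus, donor, orientation)
  chr <- host$genome[[chrom]]
  ref_len <- nchar(locus$ref)
  edited <- paste0(substr(chr, 1L, offset),
                   as.vector(unclass(pred$edited_allele)),
                   substr(chr, offset + ref_len + 1L, nchar(chr)))
  host$genome[[chrom]] <- edited
  j <- data.frame(chrom = chrom,
                  pos = offset + c(pred$core_start, pred$core_end),
                  stringsAsFactors = FALSE)
  host$junctions <- rbind(host$junctions, j)
  host
}

#' Simulate capture-enriched reads
#'
#' Reads are drawn from the genome with start-position probability
#' proportional to `enrichment_factor` inside (or within one read length
#' of) the regions of interest and 1 elsewhere; `enrichment_factor = Inf`
#' restricts sampling to the enriched intervals. Episomal vector copies are
#' sampled as additional fully-enriched molecules, producing donor/vector
#' reads with no host flank. Chimeric host/donor reads arise naturally at
#' integration sites because the edited chromosome carries the donor core.
#'
#' @param genome Named character vector of chromosomes (integrations
#'   already applied, e.g. via [integrate_donor()]).
#' @param roi data.frame `chrom`, `start`, `end` (0-based half-open)
#'   regions of interest.
#' @param n_reads Reads to emit.
#' @param read_len Read length.
#' @param enrichment_factor Capture enrichment weight (default 50).
#' @param episome Optional episomal molecule sequence (the AAV genome).
#' @param episome_copies Number of episomal copies contributing mass.
#' @param sub_error_rate Per-base substitution error rate.
#' @param junctions Optional data.frame (`chrom`, `pos`) of true host/donor
#'   boundaries; used to label reads spanning a junction.
#' @param seed RNG seed.
#' @return A `read_set` data.frame with truth columns `source_chrom`,
#'   `source_start` (0-based; `NA` for episome reads), `spans_junction`.
#' @export
simulate_capture_reads <- function(genome, roi, n_reads, read_len = 150L,
                                   enrichment_factor = 50,
                                   episome = NULL, episome_copies = 0L,
                                   sub_error_rate = 0, junctions = NULL,
                                   seed = NULL) {
  if (length(genome) == 0L) {
    stop("simulate_capture_reads: empty genome", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  segs <- list() # per segment: chrom, lo, hi (0-based start range), weight
  for (chrom in names(genome)) {
    len <- nchar(genome[[chrom]])
    if (len < read_len) next
    nstart <- len - read_len + 1L
    r <- roi[roi$chrom == chrom, , drop = FALSE]
    enriched <- logical(nstart)
    if (nrow(r)) {
      for (k in seq_len(nrow(r))) {
        lo <- max(0L, r$start[k] - read_len + 1L)
        hi <- min(nstart - 1L, r$end[k] - 1L)
        if (hi >= lo) enriched[(lo + 1L):(hi + 1L)] <- TRUE
      }
    }
    rle_ <- rle(enriched)
    pos <- 0L
    for (k in seq_along(rle_$lengths)) {
      w <- if (rle_$values[k]) enrichment_factor else 1
      if (w > 0) {
        segs[[length(segs) + 1L]] <- list(chrom = chrom, lo = pos,
                                          hi = pos + rle_$lengths[k] - 1L,
                                          weight = w)
      }
      pos <- pos + rle_$lengths[k]
    }
  }
  if (!is.null(episome) && episome_copies > 0L) {
    ep <- chr_seq(episome)
    if (nchar(ep) >= read_len) {
      segs[[length(segs) + 1L]] <- list(
        chrom = ".episome", lo = 0L, hi = nchar(ep) - read_len,
        weight = enrichment_factor * episome_copies)
    }
  }
  if (!length(segs)) stop("simulate_capture_reads: no sampleable positions",
                          call. = FALSE)

  sizes <- vapply(segs, function(s) s$hi - s$lo + 1, numeric(1))
  w <- vapply(segs, function(s) s$weight, numeric(1)) * sizes
  if (any(is.infinite(w))) w <- ifelse(is.infinite(w), sizes, 0)
  seg_idx <- sample.int(length(segs), n_reads, replace = TRUE, prob = w)

  chroms <- character(n_reads); starts <- integer(n_reads)
  seqs <- character(n_reads); strands <- character(n_reads)
  for (i in seq_len(n_reads)) {
    s <- segs[[seg_idx[i]]]
    st <- if (s$hi > s$lo) s$lo + sample.int(s$hi - s$lo + 1L, 1L) - 1L else s$lo
    mol <- if (s$chrom == ".episome") chr_seq(episome) else genome[[s$chrom]]
    rd <- substr(mol, st + 1L, st + read_len)
    strand <- if (runif(1) < 0.5) "+" else "-"
    if (strand == "-") rd <- revcomp_chr(rd)
    chroms[i] <- s$chrom; starts[i] <- st; seqs[i] <- rd; strands[i] <- strand
  }
  seqs <- add_sub_errors(seqs, sub_error_rate)

  spans <- rep(FALSE, n_reads)
  if (!is.null(junctions) && nrow(junctions)) {
    for (k in seq_len(nrow(junctions))) {
      hit <- chroms == junctions$chrom[k] &
        starts < junctions$pos[k] & (starts + read_len) > junctions$pos[k]
      spans <- spans | hit
    }
  }
  out <- data.frame(
    read_id = sprintf("cap_%06d", seq_len(n_reads)),
    mate = 0L, seq = seqs, qual = const_qual(seqs),
    source_chrom = chroms, source_start = ifelse(chroms == ".episome",
                                                 NA_integer_, starts),
    strand = strands, spans_junction = spans,
    stringsAsFactors = FALSE
  )
  class(out) <- c("read_set", class(out))
  out
}

#' Read-set FASTQ and truth-table I/O
#'
#' `write_fastq` writes Phred+33 FASTQ (paired reads interleaved, mate in
#' the read name); `read_fastq` reads one back into a `read_set`-shaped
#' data.frame; `write_truth_tsv` stores the per-read truth columns.
#'
#' @param reads A `read_set` data.frame.
#' @param path Output path.
#' @return `path`, invisibly (`read_fastq`: a data.frame).
#' @export
write_fastq <- function(reads, path) {
  qs <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads$seq, reads$read_id)),
    Biostrings::PhredQuality(reads$qual)
  )
  # Biostrings notes that metadata columns are not serialized; expected here
  suppressWarnings(Biostrings::writeQualityScaledXStringSet(qs, path))
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(read_id = names(x), mate = 0L,
             seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname write_fastq
#' @export
write_truth_tsv <- function(reads, path) {
  keep <- intersect(c("read_id", "mate", "source_allele", "outcome",
                      "source_chrom", "source_start", "spans_junction"),
                    names(reads))
  write.table(reads[, keep, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
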