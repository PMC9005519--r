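#' Partition reads by donor (insert) content
#'
#' Aligns every read against the insert (donor) sequence with the strict
#' preset and partitions the read set:
#' \itemize{
#'   \item no-hit: `non_insert` reads;
#'   \item full-length alignment (total soft clip <= `full_clip_tol`):
#'     `insert_only` reads -- episomal/vector evidence, not chimeric;
#'   \item partial alignment: split into an insert portion (the aligned
#'     segment) and a flank portion (the larger soft clip). Kept as a
#'     partition only if the insert portion is longer than `min_insert`
#'     (22 nt) and the flank longer than `min_flank` (30 nt), both strict
#'     inequalities; otherwise `discarded`.
#' }
#' When a read is clipped on both sides the larger clip is taken as the
#' flank; the smaller clip is dropped.
#'
#' @param reads A `read_set` (or character vector).
#' @param insert Donor/insert sequence (length >= 50).
#' @param params An [align_params()]; default strict preset.
#' @param min_insert,min_flank Length thresholds (exclusive).
#' @param full_clip_tol Maximum total clip still counted as a full-length
#'   (non-chimeric) insert alignment.
#' @return A `read_partitions` list: `partitions` (data.frame `read_id`,
#'   `insert_seq`, `flank_seq`, `insert_len`, `flank_len`, `strand`,
#'   `insert_ref_start`, `insert_ref_end`, `covers_insert_start`),
#'   `insert_only`, `non_insert`, `discarded` (read ids), `n_total`.
#' @export
find_insert_reads <- function(reads, insert, params = preset_strict(),
                              min_insert = 22L, min_flank = 30L,
                              full_clip_tol = 5L) {
  insert <- chr_seq(insert, id = "insert")
  if (nchar(insert) < 50L) {
    stop("find_insert_reads: insert must be >= 50 nt", call. = FALSE)
  }
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  ids <- if (is.data.frame(reads) && !is.null(reads$read_id)) reads$read_id
         else sprintf("read_%06d", seq_along(seqs))
  aln <- align_batch(seqs, insert, params)

  part_rows <- list()
  insert_only <- character(0)
  non_insert <- character(0)
  discarded <- character(0)
  for (i in seq_along(seqs)) {
    if (is.na(aln$score[i])) {
      non_insert <- c(non_insert, ids[i])
      next
    }
    n <- nchar(seqs[i])
    lclip <- aln$qstart[i]
    rclip <- n - aln$qend[i]
    if (lclip + rclip <= full_clip_tol) {
      insert_only <- c(insert_only, ids[i])
      next
    }
    oriented <- if (aln$strand[i] == "-") revcomp_chr(seqs[i]) else seqs[i]
    ins_len <- aln$qend[i] - aln$qstart[i]
    if (lclip >= rclip) {
      flank <- substr(oriented, 1L, lclip)
    } else {
      flank <- substr(oriented, aln$qend[i] + 1L, n)
    }
    if (ins_len > min_insert && nchar(flank) > min_flank) {
      part_rows[[length(part_rows) + 1L]] <- data.frame(
        read_id = ids[i],
        insert_seq = substr(oriented, lclip + 1L, aln$qend[i]),
        flank_seq = flank,
        insert_len = ins_len, flank_len = nchar(flank),
        strand = aln$strand[i],
        insert_ref_start = aln$ref_start[i],
        insert_ref_end = aln$ref_start[i] + cigar_ref_span(aln$cigar[i]),
        covers_insert_start = aln$ref_start[i] == 0L &&
          cigar_ref_span(aln$cigar[i]) >= 10L,
        stringsAsFactors = FALSE
      )
    } else {
      discarded <- c(discarded, ids[i])
    }
  }
  partitions <- if (length(part_rows)) do.call(rbind, part_rows) else
    data.frame(read_id = character(0), insert_seq = character(0),
               flank_seq = character(0), insert_len = integer(0),
               flank_len = integer(0), strand = character(0),
               insert_ref_start = integer(0), insert_ref_end = integer(0),
               covers_insert_start = logical(0), stringsAsFactors = FALSE)
  structure(
    list(partitions = partitions, insert_only = insert_only,
         non_insert = non_insert, discarded = discarded,
         n_total = length(seqs)),
    class = "read_partitions"
  )
}

#' @export
print.read_partitions <- function(x, ...) {
  cat(sprintf("<read_partitions> %d reads: %d chimeric partitions, %d insert-only, %d non-insert, %d discarded\n",
              x$n_total, nrow(x$partitions), length(x$insert_only),
              length(x$non_insert), length(x$discarded)))
  invisible(x)
}

#' Realign flank portions and tally integration evidence
#'
#' Each flank portion is aligned against every reference (the AAV vector
#' genome and each host chromosome); the best-scoring reference receives
#' the count. Flanks mapping to the vector indicate concatemeric/episomal
#' vector DNA rather than host integration. Equal best scores on two or
#' more references are recorded as ambiguous and excluded from the tally.
#'
#' @param partitions A `read_partitions` (or its `partitions` data.frame).
#' @param references Named character vector of reference sequences.
#' @param params An [align_params()]; default strict preset.
#' @return An `integration_tally`: data.frame `reference`, `count`, `pct`
#'   (of assigned flanks) plus attributes `n_ambiguous`, `n_unaligned`,
#'   `assignments` (per-flank table with best reference and alignment
#'   coordinates).
#' @export
realign_flanks <- function(partitions, references, params = preset_strict()) {
  if (inherits(partitions, "read_partitions")) {
    partitions <- partitions$partitions
  }
  if (length(references) == 0L) {
    stop("realign_flanks: empty reference set", call. = FALSE)
  }
  refnames <- names(references)
  stopifnot(!is.null(refnames), all(nzchar(refnames)))
  n <- nrow(partitions)
  tally <- setNames(integer(length(references)), refnames)
  n_amb <- 0L; n_un <- 0L
  assign_rows <- list()
  if (n > 0L) {
    scores <- matrix(-Inf, nrow = n, ncol = length(references))
    alns <- vector("list", length(references))
    for (k in seq_along(references)) {
      a <- align_batch(partitions$flank_seq, references[[k]], params)
      alns[[k]] <- a
      scores[, k] <- ifelse(is.na(a$score), -Inf, a$score)
    }
    for (i in seq_len(n)) {
      s <- scores[i, ]
      if (!any(is.finite(s))) { n_un <- n_un + 1L; next }
      best <- which(s == max(s))
      if (length(best) > 1L) { n_amb <- n_amb + 1L; next }
      tally[best] <- tally[best] + 1L
      a <- alns[[best]]
      assign_rows[[length(assign_rows) + 1L]] <- data.frame(
        read_id = partitions$read_id[i],
        reference = refnames[best],
        ref_start = a$ref_start[i],
        ref_end = a$ref_start[i] + cigar_ref_span(a$cigar[i]),
        score = a$score[i],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- data.frame(reference = refnames, count = unname(tally),
                    stringsAsFactors = FALSE)
  n_assigned <- sum(out$count)
  out$pct <- if (n_assigned > 0) 100 * out$count / n_assigned else 0
  attr(out, "n_ambiguous") <- n_amb
  attr(out, "n_unaligned") <- n_un
  attr(out, "assignments") <- if (length(assign_rows))
    do.call(rbind, assign_rows) else NULL
  class(out) <- c("integration_tally", class(out))
  out
}

#' On-target donor integration at the cleavage region
#'
#' Reproduces the on-target counting procedure: (1) keep reads whose
#' insert alignment is partial (soft-clipped) and covers the first 10 nt of
#' the insert (the donor 5' anchor; orientation-reversed integrations are
#' caught by strand-aware alignment); (2) realign those reads to the target
#' gene reference; (3) count reads whose alignment overlaps the cleavage
#' region. The frequency denominator is the total number of reads whose
#' target-gene alignment overlaps the cleavage region.
#'
#' @param reads A `read_set` (or character vector).
#' @param insert Donor/insert sequence.
#' @param target_ref Target gene reference sequence.
#' @param cleavage_region Length-2 integer vector, 0-based half-open
#'   interval on `target_ref`.
#' @param params An [align_params()]; default strict preset.
#' @param anchor_len Length of the insert 5' anchor (default 10).
#' @return List: `count` (insert-containing reads at the cleavage region),
#'   `denominator` (reads overlapping the cleavage region), `frequency`,
#'   `anchored_ids`.
#' @export
ontarget_insert_frequency <- function(reads, insert, target_ref,
                                      cleavage_region,
                                      params = preset_strict(),
                                      anchor_len = 10L) {
  target_ref <- chr_seq(target_ref, id = "target")
  stopifnot(length(cleavage_region) == 2L)
  lo <- as.integer(cleavage_region[1]); hi <- as.integer(cleavage_region[2])
  if (lo < 0L || hi > nchar(target_ref) || lo >= hi) {
    stop("ontarget_insert_frequency: cleavage_region outside reference",
         call. = FALSE)
  }
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  ids <- if (is.data.frame(reads) && !is.null(reads$read_id)) reads$read_id
         else sprintf("read_%06d", seq_along(seqs))

  a_ins <- align_batch(seqs, insert, params)
  hit <- !is.na(a_ins$score)
  partial <- hit & (a_ins$qstart > 0L | a_ins$qend < nchar(seqs))
  covers_anchor <- hit & a_ins$ref_start == 0L &
    vapply(seq_along(seqs), function(i) {
      if (!hit[i]) return(FALSE)
      cigar_ref_span(a_ins$cigar[i]) >= anchor_len
    }, logical(1))
  anchored <- partial & covers_anchor

  a_tgt <- align_batch(seqs, target_ref, params)
  tgt_hit <- !is.na(a_tgt$score)
  overlaps <- rep(FALSE, length(seqs))
  for (i in which(tgt_hit)) {
    s0 <- a_tgt$ref_start[i]
    s1 <- s0 + cigar_ref_span(a_tgt$cigar[i])
    overlaps[i] <- s0 < hi && s1 > lo
  }
  count <- sum(anchored & overlaps)
  denom <- sum(overlaps)
  list(count = count, denominator = denom,
       frequency = if (denom > 0) count / denom else 0,
       anchored_ids = ids[anchored & overlaps])
}

#' Write the two split-read partition FASTA files
#'
#' Mirrors the two intermediate FASTA files of the split-read procedure:
#' insert portions (> 22 nt) and flank portions (> 30 nt).
#'
#' @param partitions A `read_partitions`.
#' @param insert_path,flank_path Output FASTA paths.
#' @return Invisibly, the two paths.
#' @export
write_partition_fastas <- function(partitions, insert_path, flank_path) {
  p <- if (inherits(partitions, "read_partitions")) partitions$partitions
       else partitions
  if (nrow(p)) {
    write_fasta(setNames(p$insert_seq, paste0(p$read_id, "_insert")),
                insert_path)
    write_fasta(setNames(p$flank_seq, paste0(p$read_id, "_flank")),
                flank_path)
  } else {
    writeLines(character(0), insert_path)
    writeLines(character(0), flank_path)
  }
  invisible(c(insert_path, flank_path))
}
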