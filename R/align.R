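#' Alignment scoring parameters
#'
#' Affine-gap local alignment scoring: a gap of length `k` costs
#' `gap_open + k * gap_extend`; unaligned query ends are soft-clipped at
#' `clip_penalty` per base (0 in both presets); alignments scoring below
#' `min_score` are reported as no-hit.
#'
#' `preset_strict()` transcribes the near-exact-match regime used for
#' donor-detection alignments (very high mismatch and gap-open costs, so
#' any divergent tail is clipped rather than extended):
#' match 1, mismatch 50, gap_open 60, gap_extend 10, clip 0, min_score 20.
#' `preset_default()` is a permissive preset for amplicon reads carrying
#' editing INDELs: match 2, mismatch 4, gap_open 6, gap_extend 1, clip 0,
#' min_score 20.
#'
#' @param match,mismatch_penalty,gap_open,gap_extend,clip_penalty,min_score
#'   Non-negative integers (`match` is the positive match score).
#' @return An `align_params` list.
#' @export
align_params <- function(match = 2L, mismatch_penalty = 4L, gap_open = 6L,
                         gap_extend = 1L, clip_penalty = 0L, min_score = 20L) {
  p <- lapply(list(match = match, mismatch_penalty = mismatch_penalty,
                   gap_open = gap_open, gap_extend = gap_extend,
                   clip_penalty = clip_penalty, min_score = min_score),
              as.integer)
  if (any(unlist(p) < 0L)) stop("align_params: all values must be >= 0",
                                call. = FALSE)
  structure(p, class = "align_params")
}

#' @rdname align_params
#' @export
preset_strict <- function() {
  align_params(match = 1L, mismatch_penalty = 50L, gap_open = 60L,
               gap_extend = 10L, clip_penalty = 0L, min_score = 20L)
}

#' @rdname align_params
#' @export
preset_default <- function() {
  align_params()
}

#' Local alignment of one query against one reference
#'
#' Smith-Waterman with affine gaps; both strands are tried and the best
#' score wins (plus strand on ties). Unaligned query ends are emitted as
#' soft clips. For minus-strand hits the CIGAR and query interval refer to
#' the reverse-complemented query, as in SAM.
#'
#' @param query,ref Sequences (string or `nuc_seq`).
#' @param params An [align_params()].
#' @param query_id,ref_id Labels carried into the record.
#' @return An `alignment_record` list (`query_id`, `ref_id`, `ref_start`
#'   0-based, `strand`, `cigar`, `score`, `qstart`/`qend` 0-based half-open
#'   on the oriented query) or `NULL` for no-hit.
#' @export
align_local <- function(query, ref, params = preset_default(),
                        query_id = "query", ref_id = "ref") {
  q <- unclass(as_nuc_seq(query, id = query_id))
  r <- unclass(as_nuc_seq(ref, id = ref_id))
  df <- align_batch(q, r, params)
  if (is.na(df$score[1])) return(NULL)
  structure(
    list(query_id = query_id, ref_id = ref_id,
         ref_start = df$ref_start[1], strand = df$strand[1],
         cigar = df$cigar[1], score = df$score[1],
         qstart = df$qstart[1], qend = df$qend[1]),
    class = "alignment_record"
  )
}

#' @export
print.alignment_record <- function(x, ...) {
  cat(sprintf("<alignment> %s vs %s: score %d, %s strand, ref_start %d, %s\n",
              x$query_id, x$ref_id, x$score, x$strand, x$ref_start, x$cigar))
  invisible(x)
}

#' Batch local alignment
#'
#' Vectorized form of [align_local()]: aligns every query against one
#' reference and returns one row per query (`NA` fields for no-hits).
#'
#' @param queries Character vector of query sequences.
#' @param ref Reference sequence.
#' @param params An [align_params()].
#' @param both_strands Try the reverse complement as well (default `TRUE`).
#' @return data.frame with columns `score`, `ref_start`, `strand`, `cigar`,
#'   `qstart`, `qend`.
#' @export
align_batch <- function(queries, ref, params = preset_default(),
                        both_strands = TRUE) {
  stopifnot(inherits(params, "align_params"))
  .sw_align_batch(as.character(queries), as.character(ref),
                  params$match, params$mismatch_penalty, params$gap_open,
                  params$gap_extend, params$clip_penalty, params$min_score,
                  both_strands)
}

# parse "10S80M2D60M10S" -> data.frame(op, len)
parse_cigar <- function(cigar) {
  if (is.na(cigar) || !nzchar(cigar)) stop("malformed CIGAR: empty",
                                           call. = FALSE)
  m <- gregexpr("([0-9]+)([MIDS])", cigar, perl = TRUE)
  if (m[[1]][1] == -1L ||
      sum(attr(m[[1]], "match.length")) != nchar(cigar)) {
    stop("malformed CIGAR: ", cigar, call. = FALSE)
  }
  tok <- regmatches(cigar, m)[[1]]
  data.frame(
    op = substr(tok, nchar(tok), nchar(tok)),
    len = as.integer(substr(tok, 1L, nchar(tok) - 1L)),
    stringsAsFactors = FALSE
  )
}

#' Extract INDEL events from a CIGAR
#'
#' One event per I/D run; `ref_offset` is measured from the alignment's
#' `ref_start` (0-based). Soft clips are not events. Accepts either an
#' `alignment_record` or a bare CIGAR string (with `ref_start` taken as 0).
#'
#' @param rec An `alignment_record`, or a CIGAR string.
#' @return data.frame with columns `type` (`"I"`/`"D"`), `length`,
#'   `ref_offset` (0-based offset of the event from `ref_start`; for a
#'   deletion the first deleted reference base, for an insertion the
#'   reference position the inserted bases precede).
#' @examples
#' cigar_indels("20M5D25M")  # D, 5, 20
#' @export
cigar_indels <- function(rec) {
  cigar <- if (is.character(rec)) rec else rec$cigar
  ops <- parse_cigar(cigar)
  out <- data.frame(type = character(0), length = integer(0),
                    ref_offset = integer(0), stringsAsFactors = FALSE)
  roff <- 0L
  for (k in seq_len(nrow(ops))) {
    op <- ops$op[k]; len <- ops$len[k]
    if (op %in% c("I", "D")) {
      out <- rbind(out, data.frame(type = op, length = len,
                                   ref_offset = roff,
                                   stringsAsFactors = FALSE))
    }
    if (op %in% c("M", "D")) roff <- roff + len
  }
  out
}

# reference span consumed by an alignment (M + D)
cigar_ref_span <- function(cigar) {
  ops <- parse_cigar(cigar)
  sum(ops$len[ops$op %in% c("M", "D")])
}

# query bases consumed (M + I + S); must equal query length
cigar_query_len <- function(cigar) {
  ops <- parse_cigar(cigar)
  sum(ops$len[ops$op %in% c("M", "I", "S")])
}

#' Partition a query by its soft clips
#'
#' Splits the oriented query into (left clip, aligned portion, right clip)
#' according to the CIGAR's terminal S runs.
#'
#' @param rec An `alignment_record`.
#' @param query The query sequence as aligned. For minus-strand records pass
#'   the reverse complement of the original read (the orientation the CIGAR
#'   refers to); [clipped_segments()] reorients automatically when given the
#'   original read and the record's strand.
#' @return Named list `left`, `aligned`, `right` (character).
#' @export
clipped_segments <- function(rec, query) {
  q <- chr_seq(query)
  if (identical(rec$strand, "-")) q <- revcomp_chr(q)
  ops <- parse_cigar(rec$cigar)
  lclip <- if (ops$op[1] == "S") ops$len[1] else 0L
  nlast <- nrow(ops)
  rclip <- if (ops$op[nlast] == "S" && nlast > 1L) ops$len[nlast] else 0L
  n <- nchar(q)
  list(
    left = substr(q, 1L, lclip),
    aligned = substr(q, lclip + 1L, n - rclip),
    right = if (rclip > 0L) substr(q, n - rclip + 1L, n) else ""
  )
}

#' Write alignments as minimal SAM
#'
#' Emits an @HD/@SQ header and the 11 mandatory columns; soft clips are
#' preserved in the CIGAR and minus-strand reads are stored
#' reverse-complemented with FLAG 16, as per the SAM convention.
#'
#' @param alignments data.frame from [align_batch()] plus columns
#'   `read_id` and `seq` (original read orientation).
#' @param ref_id,ref_len Reference name and length for the @SQ line.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, ref_id, ref_len, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", ref_id, as.integer(ref_len))),
             con)
  hit <- !is.na(alignments$score)
  a <- alignments[hit, , drop = FALSE]
  if (nrow(a)) {
    seqs <- ifelse(a$strand == "-", revcomp_chr(a$seq), a$seq)
    lines <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                     a$read_id, ifelse(a$strand == "-", 16L, 0L), ref_id,
                     a$ref_start + 1L, a$cigar, seqs)
    writeLines(lines, con)
  }
  un <- alignments[!hit, , drop = FALSE]
  if (nrow(un)) {
    writeLines(sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*",
                       un$read_id, un$seq), con)
  }
  invisible(path)
}
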