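#' Cleavage window and tissue threshold policy
#'
#' `window_spec(flank)` defines the evaluation window `[cut - flank,
#' cut + flank)` (0-based, half-open) around the blunt cut: an INDEL is
#' attributed to editing only if it overlaps this window, and a read enters
#' the denominator only if its alignment spans the whole window. The
#' default flank of 17 nt follows the evaluation window used for amplicon
#' INDEL quantification.
#'
#' `threshold_policy()` sets the minimum reported frequency for an INDEL
#' species: 0.1% for retina, 0.5% for liver. The comparison is inclusive
#' (a species at exactly the threshold is kept).
#'
#' @param flank Window half-width in nt (>= 1).
#' @return `window_spec`: a list with `flank`.
#' @export
window_spec <- function(flank = 17L) {
  flank <- as.integer(flank)
  if (flank < 1L) stop("window_spec: flank must be >= 1", call. = FALSE)
  structure(list(flank = flank), class = "window_spec")
}

#' @rdname window_spec
#' @param tissue `"retina"` (0.1%) or `"liver"` (0.5%).
#' @param min_species_frequency Override the preset, in percent.
#' @export
threshold_policy <- function(tissue = c("retina", "liver"),
                             min_species_frequency = NULL) {
  tissue <- match.arg(tissue)
  if (is.null(min_species_frequency)) {
    min_species_frequency <- c(retina = 0.1, liver = 0.5)[[tissue]]
  }
  if (min_species_frequency < 0) {
    stop("threshold_policy: min_species_frequency must be >= 0",
         call. = FALSE)
  }
  structure(list(tissue = tissue,
                 min_species_frequency = min_species_frequency),
            class = "threshold_policy")
}

#' Apply a species-frequency threshold
#'
#' Keeps species with `pct >= min_species_frequency` (inclusive).
#' Idempotent: applying a policy twice equals applying it once.
#'
#' @param species data.frame with a `pct` column.
#' @param policy A [threshold_policy()].
#' @return Filtered data.frame.
#' @export
apply_threshold <- function(species, policy) {
  stopifnot(inherits(policy, "threshold_policy"))
  species[species$pct >= policy$min_species_frequency, , drop = FALSE]
}

# does an INDEL event overlap the window [lo, hi) (0-based, half-open)?
# deletions occupy [pos, pos+len); insertions are zero-width at pos and
# overlap when lo <= pos <= hi (an insertion at either boundary touches
# the window)
event_in_window <- function(type, pos, len, lo, hi) {
  if (type == "D") pos < hi && (pos + len) > lo else pos >= lo && pos <= hi
}

# align reads to one reference and keep per-read events; returns data.frame
# with alignment columns plus covers_window and a list column of events
align_and_window <- function(seqs, ref, cut_pos, window, params) {
  aln <- align_batch(seqs, ref, params)
  lo <- cut_pos - window$flank
  hi <- cut_pos + window$flank
  n <- nrow(aln)
  covers <- logical(n)
  modified <- logical(n)
  events <- vector("list", n)
  for (i in seq_len(n)) {
    if (is.na(aln$score[i])) next
    span0 <- aln$ref_start[i]
    span1 <- span0 + cigar_ref_span(aln$cigar[i])
    covers[i] <- span0 <= lo && span1 >= hi
    ev <- cigar_indels(aln$cigar[i])
    if (nrow(ev)) {
      ev$ref_pos <- ev$ref_offset + span0
      inwin <- mapply(event_in_window, ev$type, ev$ref_pos, ev$length,
                      MoreArgs = list(lo = lo, hi = hi))
      ev <- ev[inwin, , drop = FALSE]
    }
    events[[i]] <- ev
    modified[i] <- nrow(ev) > 0L
  }
  aln$covers_window <- covers
  aln$modified <- modified
  aln$events <- events
  aln
}

new_edit_summary <- function(n_assigned, n_excluded, n_ambiguous,
                             n_unmodified, n_indel, n_hiti, spectrum) {
  pct <- function(k) if (n_assigned > 0) 100 * k / n_assigned else 0
  structure(
    list(n_assigned = n_assigned, n_excluded = n_excluded,
         n_ambiguous = n_ambiguous,
         n_unmodified = n_unmodified, n_indel = n_indel, n_hiti = n_hiti,
         pct_unmodified = pct(n_unmodified), pct_indel = pct(n_indel),
         pct_hiti = pct(n_hiti), spectrum = spectrum),
    class = "edit_summary"
  )
}

#' @export
print.edit_summary <- function(x, ...) {
  cat(sprintf(paste0("<edit_summary> %d assigned (%d excluded, %d ambiguous)\n",
                     "  unmodified %.2f%%  indel %.2f%%  hiti %.2f%%\n"),
              x$n_assigned, x$n_excluded, x$n_ambiguous,
              x$pct_unmodified, x$pct_indel, x$pct_hiti))
  if (nrow(x$spectrum)) {
    cat("  INDEL spectrum (signed length, pct):\n")
    print(x$spectrum, row.names = FALSE)
  }
  invisible(x)
}

# signed-length spectrum over a list of in-window event data.frames
indel_spectrum <- function(events, n_assigned) {
  lens <- unlist(lapply(events, function(ev) {
    if (is.null(ev) || !nrow(ev)) return(integer(0))
    ifelse(ev$type == "I", ev$length, -ev$length)
  }))
  if (!length(lens)) {
    return(data.frame(signed_length = integer(0), count = integer(0),
                      pct = numeric(0)))
  }
  tb <- table(lens)
  data.frame(
    signed_length = as.integer(names(tb)),
    count = as.integer(tb),
    pct = if (n_assigned > 0) 100 * as.integer(tb) / n_assigned else 0,
    row.names = NULL
  )
}

#' Windowed INDEL frequency at a cleavage site
#'
#' Aligns reads to the locus reference and classifies each read spanning
#' the evaluation window as modified (any CIGAR I/D event overlapping the
#' window) or unmodified. Reads whose alignment does not cover the whole
#' window are excluded from the denominator. Substitution-only mismatches
#' never count as modified. The INDEL spectrum aggregates signed lengths
#' (insertions positive, deletions negative) of in-window events.
#'
#' @param reads A `read_set` data.frame (or character vector of sequences).
#' @param ref Reference sequence the reads derive from.
#' @param cut_pos 0-based cut position on `ref`. When `ref` is a
#'   `target_locus` this defaults to its `cut_pos` and the reference to its
#'   `ref`.
#' @param window A [window_spec()].
#' @param params An [align_params()].
#' @return An `edit_summary` (with `pct_hiti = 0`; this quantification has
#'   no HITI class).
#' @export
window_indel_frequency <- function(reads, ref, cut_pos = NULL,
                                   window = window_spec(),
                                   params = preset_default()) {
  if (inherits(ref, "target_locus")) {
    if (is.null(cut_pos)) cut_pos <- ref$cut_pos
    ref <- as.vector(unclass(ref$ref))
  }
  stopifnot(!is.null(cut_pos))
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  aw <- align_and_window(seqs, ref, cut_pos, window, params)
  assigned <- aw$covers_window
  if (!any(assigned)) {
    stop("window_indel_frequency: no read covers the evaluation window",
         call. = FALSE)
  }
  n_assigned <- sum(assigned)
  n_mod <- sum(aw$modified[assigned])
  new_edit_summary(
    n_assigned = n_assigned,
    n_excluded = sum(!assigned),
    n_ambiguous = 0L,
    n_unmodified = n_assigned - n_mod,
    n_indel = n_mod,
    n_hiti = 0L,
    spectrum = indel_spectrum(aw$events[assigned], n_assigned)
  )
}

#' Dual-amplicon HITI-allele quantification
#'
#' Reads pooled from co-amplified wild-type and hybrid (donor-integrated)
#' amplicons are assigned to the reference with the higher local alignment
#' score; ties go to an ambiguous bucket and are excluded. Hybrid-assigned
#' reads count as HITI; wild-type-assigned reads spanning the cleavage
#' window are sub-classified as INDEL-modified or unmodified. Percentages
#' are over assigned reads (hybrid reads plus window-covering wild-type
#' reads); wild-type reads that do not span the window are excluded.
#'
#' @param reads A `read_set` (or character vector of sequences).
#' @param wt_ref Wild-type amplicon reference.
#' @param hybrid_ref Hybrid (integrated) amplicon reference sharing the
#'   forward-primer side with `wt_ref`.
#' @param wt_cut_pos 0-based cut position on `wt_ref`.
#' @param window A [window_spec()].
#' @param params An [align_params()].
#' @return An `edit_summary` with `pct_hiti` the estimated integrated-allele
#'   percentage.
#' @export
dual_amplicon_hiti <- function(reads, wt_ref, hybrid_ref, wt_cut_pos,
                               window = window_spec(),
                               params = preset_default()) {
  wt_ref <- chr_seq(wt_ref, id = "wt")
  hybrid_ref <- chr_seq(hybrid_ref, id = "hybrid")
  if (identical(wt_ref, hybrid_ref)) {
    stop("dual_amplicon_hiti: wild-type and hybrid references are identical",
         call. = FALSE)
  }
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  a_wt <- align_batch(seqs, wt_ref, params)
  a_hy <- align_batch(seqs, hybrid_ref, params)
  s_wt <- ifelse(is.na(a_wt$score), -Inf, a_wt$score)
  s_hy <- ifelse(is.na(a_hy$score), -Inf, a_hy$score)

  no_hit <- !is.finite(s_wt) & !is.finite(s_hy)
  ambiguous <- !no_hit & s_wt == s_hy
  to_hy <- !no_hit & !ambiguous & s_hy > s_wt
  to_wt <- !no_hit & !ambiguous & s_wt > s_hy

  n_hiti <- sum(to_hy)
  # sub-classify wild-type-assigned reads in the cleavage window
  n_unmod <- 0L; n_indel <- 0L; n_wt_excl <- 0L
  spectrum <- data.frame(signed_length = integer(0), count = integer(0),
                         pct = numeric(0))
  events_in <- list()
  if (any(to_wt)) {
    aw <- align_and_window(seqs[to_wt], wt_ref, wt_cut_pos, window, params)
    cov <- aw$covers_window
    n_wt_excl <- sum(!cov)
    n_indel <- sum(aw$modified[cov])
    n_unmod <- sum(cov) - n_indel
    events_in <- aw$events[cov]
  }
  n_assigned <- n_hiti + n_unmod + n_indel
  out <- new_edit_summary(
    n_assigned = n_assigned,
    n_excluded = sum(no_hit) + n_wt_excl,
    n_ambiguous = sum(ambiguous),
    n_unmodified = n_unmod, n_indel = n_indel, n_hiti = n_hiti,
    spectrum = indel_spectrum(events_in, n_assigned)
  )
  out
}

#' Junction precision classification
#'
#' Aligns junction-amplicon reads to the precise-junction reference,
#' extracts CIGAR INDEL events in the window around the ligation point, and
#' groups modified reads into species by (type, length). Reads with no
#' in-window event are precise. Species frequencies are percentages over
#' assigned reads; species below the policy threshold are dropped from the
#' report (inclusive >=). A named species is retrievable by length query
#' on the returned table (e.g. the +40 insertion).
#'
#' @param reads A `read_set` (single-end junction reads).
#' @param junction_ref Precise-junction reference sequence.
#' @param junction_pos 0-based position of the ligation point on
#'   `junction_ref`.
#' @param window A [window_spec()].
#' @param policy A [threshold_policy()].
#' @param params An [align_params()].
#' @param denominator `"window"` (default): frequencies over reads whose
#'   alignment spans the evaluation window; `"all"`: over all aligned
#'   reads.
#' @return A `junction_report` list: `n_assigned`, `n_excluded`,
#'   `n_precise`, `pct_precise`, `species` (type, length, signed_length,
#'   count, pct; threshold-filtered), `species_all` (unfiltered), `policy`.
#' @export
classify_junctions <- function(reads, junction_ref, junction_pos,
                               window = window_spec(),
                               policy = threshold_policy("retina"),
                               params = preset_default(),
                               denominator = c("window", "all")) {
  denominator <- match.arg(denominator)
  junction_ref <- chr_seq(junction_ref, id = "junction")
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  aw <- align_and_window(seqs, junction_ref, junction_pos, window, params)
  aligned <- !is.na(aw$score)
  assigned <- if (denominator == "window") aw$covers_window else aligned
  n_assigned <- sum(assigned)
  if (n_assigned == 0L) {
    stop("classify_junctions: no assignable reads", call. = FALSE)
  }
  modified <- aw$modified & assigned
  n_precise <- n_assigned - sum(modified)

  # one species contribution per read and event
  evs <- do.call(rbind, aw$events[modified])
  if (is.null(evs) || !nrow(evs)) {
    species <- data.frame(type = character(0), length = integer(0),
                          signed_length = integer(0), count = integer(0),
                          pct = numeric(0))
  } else {
    key <- paste(evs$type, evs$length)
    tb <- table(key)
    parts <- strsplit(names(tb), " ")
    species <- data.frame(
      type = vapply(parts, `[`, character(1), 1L),
      length = as.integer(vapply(parts, `[`, character(1), 2L)),
      count = as.integer(tb),
      stringsAsFactors = FALSE, row.names = NULL
    )
    species$signed_length <- ifelse(species$type == "I", species$length,
                                    -species$length)
    species$pct <- 100 * species$count / n_assigned
    species <- species[order(-species$count), ,
                       drop = FALSE]
    species <- species[, c("type", "length", "signed_length", "count", "pct")]
  }
  structure(
    list(n_assigned = n_assigned,
         n_excluded = length(seqs) - n_assigned,
         n_precise = n_precise,
         pct_precise = 100 * n_precise / n_assigned,
         species = apply_threshold(species, policy),
         species_all = species,
         policy = policy, denominator = denominator),
    class = "junction_report"
  )
}

#' @export
print.junction_report <- function(x, ...) {
  cat(sprintf("<junction_report> %d assigned, %.2f%% precise (%s policy, >= %.2f%%)\n",
              x$n_assigned, x$pct_precise, x$policy$tissue,
              x$policy$min_species_frequency))
  if (nrow(x$species)) print(x$species, row.names = FALSE)
  invisible(x)
}

#' Export an edit summary or junction report as TSV
#'
#' One row per class and per INDEL species: sample, class, length, count,
#' pct.
#'
#' @param x An `edit_summary` or `junction_report`.
#' @param sample Sample label for the first column.
#' @param path Output path.
#' @return The table, invisibly if written.
#' @export
report_table <- function(x, sample = "sample", path = NULL) {
  if (inherits(x, "edit_summary")) {
    rows <- data.frame(
      sample = sample,
      class = c("unmodified", "indel", "hiti"),
      length = NA_integer_,
      count = c(x$n_unmodified, x$n_indel, x$n_hiti),
      pct = c(x$pct_unmodified, x$pct_indel, x$pct_hiti),
      stringsAsFactors = FALSE
    )
    if (nrow(x$spectrum)) {
      rows <- rbind(rows, data.frame(
        sample = sample, class = "indel_species",
        length = x$spectrum$signed_length,
        count = x$spectrum$count, pct = x$spectrum$pct,
        stringsAsFactors = FALSE))
    }
  } else if (inherits(x, "junction_report")) {
    rows <- data.frame(
      sample = sample, class = "precise", length = NA_integer_,
      count = x$n_precise, pct = x$pct_precise, stringsAsFactors = FALSE)
    if (nrow(x$species)) {
      rows <- rbind(rows, data.frame(
        sample = sample, class = "junction_species",
        length = x$species$signed_length,
        count = x$species$count, pct = x$species$pct,
        stringsAsFactors = FALSE))
    }
  } else {
    stop("report_table: unsupported object", call. = FALSE)
  }
  if (!is.null(path)) {
    write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(rows))
  }
  rows
}
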