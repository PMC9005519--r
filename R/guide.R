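#' Guide RNA specification
#'
#' A 20-nt protospacer with a PAM pattern (IUPAC, default NGG for SpCas9)
#' and a blunt-cut offset measured from the PAM-proximal end of the
#' protospacer (default 3 nt, the canonical SpCas9 cut).
#'
#' @param protospacer 20-nt sequence (string or `nuc_seq`).
#' @param pam_pattern 3-letter IUPAC pattern, default `"NGG"`.
#' @param cut_offset Integer in `[1, 19]`; nt from the PAM-proximal
#'   protospacer end to the blunt cut.
#' @return A `guide_spec` list.
#' @export
guide_spec <- function(protospacer, pam_pattern = "NGG", cut_offset = 3L) {
  p <- as_nuc_seq(protospacer, id = "protospacer")
  if (nchar(p) != 20L) {
    stop("guide_spec: protospacer must be 20 nt, got ", nchar(p), call. = FALSE)
  }
  stopifnot(nchar(pam_pattern) == 3L)
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 1L || cut_offset > 19L) {
    stop("guide_spec: cut_offset must be in [1, 19]", call. = FALSE)
  }
  structure(
    list(protospacer = unclass(p), pam_pattern = toupper(pam_pattern),
         cut_offset = cut_offset),
    class = "guide_spec"
  )
}

#' @export
print.guide_spec <- function(x, ...) {
  cat(sprintf("<guide_spec> %s-%s (cut %d nt 5' of PAM)\n",
              x$protospacer, x$pam_pattern, x$cut_offset))
  invisible(x)
}

# IUPAC letter -> regex character class
iupac_regex <- function(pattern) {
  map <- c(A = "A", C = "C", G = "G", T = "T",
           R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
           K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
           H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  chars <- strsplit(toupper(pattern), "")[[1]]
  unknown <- setdiff(chars, names(map))
  if (length(unknown)) stop("unknown IUPAC letters: ",
                            paste(unknown, collapse = ","), call. = FALSE)
  paste(map[chars], collapse = "")
}

# 0-based start positions of protospacer+PAM on the given strand of `ref`.
# N in the reference never matches a protospacer base (protospacer letters
# are literal A/C/G/T so the regex cannot match N); the PAM's N positions
# also only match A/C/G/T, i.e. conservative placement.
site_starts_plus <- function(ref, guide) {
  pat <- paste0(guide$protospacer, iupac_regex(guide$pam_pattern))
  m <- gregexpr(pat, ref, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

#' Place a guide on a reference and derive the cut coordinate
#'
#' Searches both strands for protospacer followed by PAM. The match must be
#' unique across strands. Coordinates are 0-based; `cut_pos` names the first
#' base 3' of the blunt cut on the reference top strand, so the edited
#' allele is `ref[0, cut_pos) + insert + ref[cut_pos, end)`.
#'
#' @param ref Reference sequence (string or `nuc_seq`).
#' @param guide A [guide_spec()].
#' @return A `target_locus` list with fields `ref`, `guide`, `strand`,
#'   `protospacer_start` (0-based, top-strand coordinates of the site),
#'   `cut_pos`.
#' @examples
#' g <- guide_spec("GACGGTACCTAGCATCATTG")
#' ref <- paste0("TTTTT", "GACGGTACCTAGCATCATTG", "AGG", "CCCCC")
#' place_guide(ref, g)$cut_pos  # 22
#' @export
place_guide <- function(ref, guide) {
  r <- as_nuc_seq(ref, id = "ref")
  stopifnot(inherits(guide, "guide_spec"))
  plus <- site_starts_plus(unclass(r), guide)
  rc <- unclass(revcomp(r))
  minus_rc <- site_starts_plus(rc, guide)
  n <- nchar(r)
  site_len <- 20L + nchar(guide$pam_pattern)
  # map minus-strand hits to top-strand start of the (revcomp'd) site
  minus <- if (length(minus_rc)) n - (minus_rc + site_len) else integer(0)

  total <- length(plus) + length(minus)
  if (total == 0L) {
    stop("place_guide: protospacer+PAM not found on either strand",
         call. = FALSE)
  }
  if (total > 1L) {
    stop("place_guide: ambiguous placement; matches at + strand [",
         paste(plus, collapse = ","), "], - strand [",
         paste(minus, collapse = ","), "]", call. = FALSE)
  }
  if (length(plus)) {
    start <- plus
    strand <- "+"
    # protospacer occupies [start, start+20); cut cut_offset nt 5' of PAM
    cut_pos <- start + 20L - guide$cut_offset
  } else {
    start <- minus
    strand <- "-"
    # top strand layout: revcomp(PAM) at [start, start+pam), then
    # revcomp(protospacer); the cut sits cut_offset nt into the protospacer
    # from its PAM-proximal (top-strand-left) end
    cut_pos <- start + nchar(guide$pam_pattern) + guide$cut_offset
  }
  structure(
    list(ref = r, guide = guide, strand = strand,
         protospacer_start = as.integer(start), cut_pos = as.integer(cut_pos)),
    class = "target_locus"
  )
}

#' @export
print.target_locus <- function(x, ...) {
  cat(sprintf("<target_locus> ref '%s' (%d nt), guide on %s strand at %d, cut_pos %d\n",
              seq_id(x$ref), nchar(x$ref), x$strand,
              x$protospacer_start, x$cut_pos))
  invisible(x)
}

#' Scan a sequence for cleavable guide sites
#'
#' Exact protospacer match immediately followed by a PAM-pattern match, on
#' either strand. This is the Cas9 re-cleavage model used by the donor
#' design: forward integration destroys both half-sites while inverted
#' integration regenerates two intact ones.
#'
#' @param seq Sequence to scan.
#' @param guide A [guide_spec()].
#' @return `count_guide_sites`: integer count over both strands.
#'   `is_recleavable`: `TRUE` iff the count is positive.
#' @export
count_guide_sites <- function(seq, guide) {
  s <- chr_seq(seq)
  length(site_starts_plus(s, guide)) +
    length(site_starts_plus(revcomp_chr(s), guide))
}

#' @rdname count_guide_sites
#' @export
is_recleavable <- function(seq, guide) {
  count_guide_sites(seq, guide) > 0L
}

#' Export a guide placement as a BED-like record
#'
#' Six columns (chrom, start, end, name, score, strand), 0-based half-open,
#' spanning protospacer+PAM in top-strand coordinates.
#'
#' @param locus A `target_locus`.
#' @param chrom Chromosome/sequence name for column 1.
#' @param path Optional file to write (tab-separated, no header).
#' @return A one-row data.frame, invisibly if written to file.
#' @export
locus_to_bed <- function(locus, chrom = seq_id(locus$ref), path = NULL) {
  site_len <- 20L + nchar(locus$guide$pam_pattern)
  df <- data.frame(
    chrom = chrom,
    start = locus$protospacer_start,
    end = locus$protospacer_start + site_len,
    name = paste0("guide_cut_", locus$cut_pos),
    score = 0L,
    strand = locus$strand,
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    return(invisible(df))
  }
  df
}
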