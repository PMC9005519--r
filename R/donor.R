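#' Default donor parts
#'
#' The STOP cassette carries six STOP codons arranged so that every reading
#' frame contains at least two, blocking endogenous translation downstream
#' of any integration junction. The kozak element is the 6-nt consensus
#' preceding the payload ATG; the IRES element is a fixed 50-nt stand-in for
#' a short synthetic internal ribosomal entry site (the biological activity
#' of the element is irrelevant to sequence-level analyses, only its length
#' and presence matter). All are configurable in [build_donor()].
#'
#' @name donor_parts
#' @keywords internal
NULL

DEFAULT_STOP_CASSETTE <- "TAATTAATTAATAATTAATTAA"  # 22 nt, 6 TAA stops, 3 frames
DEFAULT_KOZAK <- "GCCACC"
DEFAULT_IRES <- paste0("GGTTATTGTGCTGTCTCATCATTTTGGCAAAGAATTCCTCGA",
                       "CGGTACCG")                  # fixed 50-nt element
DEFAULT_POLYA <- paste0("AATAAAAGATCTTTATTTTCATTAGATCTGTGTGTTGGTTTTTTGTGTG",
                        "TCTAGA")                    # 56-nt compact pA signal

#' Build a HITI donor cassette
#'
#' Assembles the cassette in functional order:
#' inverted target site | STOP cassette (3 frames) | START element |
#' payload CDS | polyA | inverted target site. Both flanking sites equal
#' `revcomp(protospacer + PAM)` of the guide, so that forward integration
#' destroys the sites while inverted integration regenerates them and is
#' re-cleaved by Cas9.
#'
#' @param guide A [guide_spec()]. The PAM pattern must be concrete here
#'   (a realized PAM, e.g. `"AGG"`, not the IUPAC class), because the donor
#'   carries literal sequence; pass `pam` to override.
#' @param payload CDS beginning with ATG.
#' @param start_type `"kozak"` (6 nt) or `"IRES"` (50 nt).
#' @param polya PolyA sequence.
#' @param pam Realized 3-nt PAM placed in the flanking sites; defaults to
#'   the guide's `pam_pattern` with N replaced by A... it must be concrete.
#' @param stop_cassette STOP cassette; must satisfy
#'   [stops_in_three_frames()] in all frames and contain >= 6 stop codons.
#' @param start_seq Override the START element sequence (length must be 6
#'   for kozak, 50 for IRES).
#' @param max_len AAV payload cap in nt (default 2700).
#' @return A `hiti_donor` list with parts, the assembled `seq`, and a part
#'   coordinate table.
#' @export
build_donor <- function(guide, payload, start_type = c("kozak", "IRES"),
                        polya = DEFAULT_POLYA, pam = NULL,
                        stop_cassette = DEFAULT_STOP_CASSETTE,
                        start_seq = NULL, max_len = 2700L) {
  stopifnot(inherits(guide, "guide_spec"))
  start_type <- match.arg(start_type)
  payload <- chr_seq(payload, id = "payload")
  if (substr(payload, 1, 3) != "ATG") {
    stop("build_donor: payload CDS must begin with ATG", call. = FALSE)
  }
  if (is.null(pam)) {
    pam <- chartr("N", "A", guide$pam_pattern)
  }
  pam <- chr_seq(pam, id = "pam")
  stopifnot(nchar(pam) == nchar(guide$pam_pattern))

  stop_cassette <- chr_seq(stop_cassette, id = "stop")
  if (!all(stops_in_three_frames(stop_cassette))) {
    stop("build_donor: stop_cassette must contain a STOP in all 3 frames",
         call. = FALSE)
  }
  if (count_stop_codons(stop_cassette) < 6L) {
    stop("build_donor: stop_cassette must contain >= 6 STOP codons",
         call. = FALSE)
  }

  if (is.null(start_seq)) {
    start_seq <- if (start_type == "kozak") DEFAULT_KOZAK else DEFAULT_IRES
  }
  start_seq <- chr_seq(start_seq, id = "start")
  want <- if (start_type == "kozak") 6L else 50L
  if (nchar(start_seq) != want) {
    stop("build_donor: ", start_type, " START element must be ", want, " nt",
         call. = FALSE)
  }

  polya <- chr_seq(polya, id = "polya")
  site <- paste0(guide$protospacer, pam)
  inv_site <- revcomp_chr(site)

  parts <- list(
    five_site = inv_site,
    stop_cassette = stop_cassette,
    start_element = start_seq,
    payload = payload,
    polya = polya,
    three_site = inv_site
  )
  seq <- paste(unlist(parts), collapse = "")
  if (nchar(seq) > max_len) {
    stop("build_donor: cassette length ", nchar(seq),
         " exceeds payload cap ", max_len, call. = FALSE)
  }
  lens <- vapply(parts, nchar, integer(1))
  ends <- cumsum(lens)
  part_table <- data.frame(
    part = names(parts),
    start = c(0L, ends[-length(ends)]),
    end = unname(ends),
    stringsAsFactors = FALSE
  )
  structure(
    list(parts = parts, seq = nuc_seq(seq, id = "hiti_donor"),
         part_table = part_table, guide = guide, pam = pam,
         start_type = start_type, max_len = as.integer(max_len)),
    class = "hiti_donor"
  )
}

count_stop_codons <- function(seq) {
  n <- nchar(seq)
  if (n < 3L) return(0L)
  k <- 0L
  for (i in seq_len(n - 2L)) {
    if (substr(seq, i, i + 2L) %in% c("TAA", "TAG", "TGA")) k <- k + 1L
  }
  k
}

#' @export
print.hiti_donor <- function(x, ...) {
  cat(sprintf("<hiti_donor> %d nt, START=%s\n", nchar(x$seq), x$start_type))
  print(x$part_table)
  invisible(x)
}

#' Validate a HITI donor against its guide
#'
#' Checks performed:
#' \itemize{
#'   \item `five_site_inverted`, `three_site_inverted`: each flank equals
#'     `revcomp(protospacer + PAM)`. Direct (non-inverted) flanks fail with
#'     a re-cleavage warning, because forward integration of such a donor
#'     regenerates two intact cleavable sites.
#'   \item `stops_three_frames`: STOP cassette covers all frames.
#'   \item `payload_atg`: payload begins with ATG.
#'   \item `size_cap`: assembled cassette <= `max_len` nt (default 2700).
#' }
#'
#' @param donor A `hiti_donor` (or a list with the same `parts` fields).
#' @param guide A [guide_spec()]; defaults to the donor's own guide.
#' @param max_len Size cap in nt.
#' @return A `donor_validation` data.frame (check, pass, note) with an
#'   `ok` attribute.
#' @export
validate_donor <- function(donor, guide = donor$guide,
                           max_len = donor$max_len %||% 2700L) {
  stopifnot(!is.null(donor$parts))
  p <- donor$parts
  site <- paste0(guide$protospacer, donor$pam %||% chartr("N", "A", guide$pam_pattern))
  inv <- revcomp_chr(site)

  checks <- list()
  note5 <- ""
  ok5 <- identical(p$five_site, inv)
  if (!ok5 && identical(p$five_site, site)) {
    note5 <- "direct-orientation site: forward integration regenerates a cleavable site"
  }
  checks$five_site_inverted <- c(ok5, note5)
  note3 <- ""
  ok3 <- identical(p$three_site, inv)
  if (!ok3 && identical(p$three_site, site)) {
    note3 <- "direct-orientation site: forward integration regenerates a cleavable site"
  }
  checks$three_site_inverted <- c(ok3, note3)
  checks$stops_three_frames <- c(all(stops_in_three_frames(p$stop_cassette)), "")
  checks$payload_atg <- c(substr(p$payload, 1, 3) == "ATG", "")
  total <- sum(vapply(p, nchar, integer(1)))
  checks$size_cap <- c(total <= max_len,
                       sprintf("%d nt vs cap %d", total, max_len))

  df <- data.frame(
    check = names(checks),
    pass = vapply(checks, function(x) as.logical(x[1]), logical(1)),
    note = vapply(checks, function(x) x[2], character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(df, "ok") <- all(df$pass)
  class(df) <- c("donor_validation", class(df))
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 0-based cut position inside one donor flank, in donor top-strand
# coordinates. An inverted flank (revcomp of protospacer+PAM) presents the
# guide on the donor minus strand, so the cut falls pam_len + cut_offset
# into the flank; a direct-orientation flank is cut 20 - cut_offset in, as
# on the genomic plus strand. Flanks matching neither orientation (not
# cleavable) default to the inverted arithmetic so downstream coordinates
# stay defined.
flank_cut_offset <- function(guide, flank_seq, pam) {
  site <- paste0(guide$protospacer, pam)
  if (identical(flank_seq, site)) {
    20L - guide$cut_offset
  } else {
    nchar(guide$pam_pattern) + guide$cut_offset
  }
}

#' Donor core released by Cas9 cleavage of both flanks
#'
#' Cas9 cuts each flanking target site at its own blunt-cut position
#' (orientation-aware); for the canonical inverted flanks the released core
#' carries the PAM-distal remnant of the 5' flank and the PAM-proximal
#' remnant of the 3' flank.
#'
#' @param donor A `hiti_donor`.
#' @return Character scalar, the released core sequence.
#' @export
donor_core <- function(donor) {
  g <- donor$guide
  seq <- as.vector(unclass(donor$seq))
  site_len <- 20L + nchar(g$pam_pattern)
  off5 <- flank_cut_offset(g, donor$parts$five_site, donor$pam)
  off3 <- flank_cut_offset(g, donor$parts$three_site, donor$pam)
  from <- off5 + 1L                      # cut inside 5' flank
  to <- nchar(seq) - site_len + off3     # cut inside 3' flank
  substr(seq, from, to)
}

#' Predict the edited allele after HITI
#'
#' Models Cas9 cutting the genomic locus and both donor flanks at their
#' blunt-cut positions, then ligating the released donor core into the
#' genomic gap. Cuts are modeled blunt with no end resection; junction
#' INDELs are injected only by the simulator. Forward integration leaves no
#' intact target site; inverted integration regenerates two.
#'
#' @param locus A `target_locus` from [place_guide()].
#' @param donor A `hiti_donor`.
#' @param orientation `"forward"` or `"inverted"`.
#' @return An `integration_prediction` list: `orientation`, `edited_allele`
#'   (`nuc_seq`), `five_junction` / `three_junction` (sequences centered on
#'   the ligation points), `recleavable_sites` (count over both strands),
#'   `core_start` / `core_end` (0-based interval of the inserted core in the
#'   edited allele).
#' @export
predict_integration <- function(locus, donor,
                                orientation = c("forward", "inverted")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(locus, "target_locus"), inherits(donor, "hiti_donor"))
  ref <- as.vector(unclass(locus$ref))
  cut <- locus$cut_pos
  core <- donor_core(donor)
  # orientation is functional (relative to the guide): on a minus-strand
  # locus the forward-integrated core appears reverse-complemented on the
  # reference top strand
  flip <- (orientation == "inverted") != (locus$strand == "-")
  if (flip) core <- revcomp_chr(core)
  left <- substr(ref, 1L, cut)
  right <- substr(ref, cut + 1L, nchar(ref))
  allele <- paste0(left, core, right)

  jwin <- 30L  # junction context reported on each side of the ligation point
  j5 <- substr(allele, max(1L, cut - jwin + 1L), cut + jwin)
  cut2 <- cut + nchar(core)
  j3 <- substr(allele, max(1L, cut2 - jwin + 1L), cut2 + jwin)

  structure(
    list(orientation = orientation,
         edited_allele = nuc_seq(allele, id = paste0("hiti_", orientation)),
         five_junction = j5, three_junction = j3,
         recleavable_sites = count_guide_sites(allele, locus$guide),
         core_start = cut, core_end = cut2),
    class = "integration_prediction"
  )
}

#' @export
print.integration_prediction <- function(x, ...) {
  cat(sprintf("<integration_prediction> %s, allele %d nt, %d recleavable site(s)\n",
              x$orientation, nchar(x$edited_allele), x$recleavable_sites))
  invisible(x)
}

#' Export a donor as annotated FASTA plus a part table
#'
#' The FASTA description line lists part boundaries; the sidecar TSV has
#' columns part, start, end (0-based half-open).
#'
#' @param donor A `hiti_donor`.
#' @param fasta_path,tsv_path Output paths; `tsv_path` defaults to the
#'   FASTA path with extension `.parts.tsv`.
#' @return `fasta_path`, invisibly.
#' @export
write_donor_fasta <- function(donor, fasta_path,
                              tsv_path = sub("\\.fa(sta)?$", "", fasta_path)) {
  tsv_path <- paste0(tsv_path, ".parts.tsv")
  ann <- paste(sprintf("%s:%d-%d", donor$part_table$part,
                       donor$part_table$start, donor$part_table$end),
               collapse = ";")
  seqs <- setNames(as.vector(unclass(donor$seq)), paste0("hiti_donor ", ann))
  write_fasta(seqs, fasta_path)
  write.table(donor$part_table, tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(fasta_path)
}
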