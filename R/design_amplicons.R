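#' Design the dual-amplicon assay for a locus/donor pair
#'
#' Builds the primer trio and reference pair for dual-amplicon HITI
#' quantification: a forward primer upstream of the cut shared by both
#' amplicons, a wild-type reverse primer downstream of the cut, and a
#' hybrid reverse primer inside the donor payload, giving similar-size
#' wild-type and hybrid amplicons. Offsets are chosen so that both mates
#' of a 150-nt pair span the evaluation window around the cut.
#'
#' @param locus A `target_locus`.
#' @param donor A `hiti_donor`.
#' @param primer_len Primer length (nt).
#' @param fwd_upstream Distance from the cut to the forward primer start
#'   (nt upstream on the locus reference).
#' @param wt_downstream Distance from the cut to the end of the wild-type
#'   amplicon (nt downstream).
#' @param payload_offset 0-based offset into the payload at which the
#'   hybrid reverse primer site starts.
#' @return An `amplicon_design` list: `fwd`, `rev_primers` (named `wt`,
#'   `hybrid`), `wt_ref`, `hybrid_ref`, `wt_cut_pos` (0-based cut on
#'   `wt_ref`).
#' @export
dual_amplicon_design <- function(locus, donor, primer_len = 20L,
                                 fwd_upstream = 87L, wt_downstream = 113L,
                                 payload_offset = 100L) {
  ref <- as.vector(unclass(locus$ref))
  cut <- locus$cut_pos
  fwd_start <- cut - fwd_upstream          # 0-based
  wt_end <- cut + wt_downstream            # 0-based, exclusive
  if (fwd_start < 0L || wt_end > nchar(ref)) {
    stop("dual_amplicon_design: amplicon exceeds the locus reference; ",
         "shrink fwd_upstream/wt_downstream or extend the reference",
         call. = FALSE)
  }
  fwd <- substr(ref, fwd_start + 1L, fwd_start + primer_len)
  wt_rev_site <- substr(ref, wt_end - primer_len + 1L, wt_end)
  payload <- donor$parts$payload
  if (payload_offset + primer_len > nchar(payload)) {
    stop("dual_amplicon_design: payload_offset beyond payload", call. = FALSE)
  }
  hyb_site <- substr(payload, payload_offset + 1L,
                     payload_offset + primer_len)
  rev_primers <- c(wt = revcomp_chr(wt_rev_site),
                   hybrid = revcomp_chr(hyb_site))

  wt_ref <- substr(ref, fwd_start + 1L, wt_end)
  edited <- as.vector(unclass(predict_integration(locus, donor, "forward")$edited_allele))
  amp <- find_amplicon(edited, fwd, rev_primers[["hybrid"]])
  if (is.null(amp)) {
    stop("dual_amplicon_design: hybrid primer pair yields no product on ",
         "the forward-integrated allele", call. = FALSE)
  }
  hybrid_ref <- substr(edited, amp[1], amp[2])
  structure(
    list(fwd = fwd, rev_primers = rev_primers,
         wt_ref = wt_ref, hybrid_ref = hybrid_ref,
         wt_cut_pos = cut - fwd_start),
    class = "amplicon_design"
  )
}

#' Design a junction amplicon for one HITI junction
#'
#' Primer pair and precise-junction reference for the 5' (genomic-to-donor)
#' or 3' (donor-to-genomic) integration junction of the forward-integrated
#' allele, plus the 0-based ligation-point coordinate on that reference.
#'
#' @param locus A `target_locus`.
#' @param donor A `hiti_donor`.
#' @param side `"five"` or `"three"`.
#' @param primer_len Primer length (nt).
#' @param genomic_offset Distance from the junction to the genomic primer
#'   start.
#' @param core_offset Distance from the junction to the donor-side primer
#'   site end (into the donor core).
#' @return A `junction_design` list: `fwd`, `rev`, `junction_ref`,
#'   `junction_pos`.
#' @export
junction_amplicon_design <- function(locus, donor,
                                     side = c("five", "three"),
                                     primer_len = 24L,
                                     genomic_offset = 107L,
                                     core_offset = 150L) {
  side <- match.arg(side)
  pred <- predict_integration(locus, donor, "forward")
  edited <- as.vector(unclass(pred$edited_allele))
  if (side == "five") {
    fwd_start <- pred$core_start - genomic_offset      # 0-based on edited
    rev_end <- pred$core_start + core_offset           # exclusive
    jpos <- pred$core_start - fwd_start
  } else {
    fwd_start <- pred$core_end - core_offset
    rev_end <- pred$core_end + genomic_offset
    jpos <- pred$core_end - fwd_start
  }
  if (fwd_start < 0L || rev_end > nchar(edited)) {
    stop("junction_amplicon_design: amplicon exceeds the edited allele; ",
         "reduce the offsets", call. = FALSE)
  }
  fwd <- substr(edited, fwd_start + 1L, fwd_start + primer_len)
  rev_site <- substr(edited, rev_end - primer_len + 1L, rev_end)
  structure(
    list(fwd = fwd, rev = revcomp_chr(rev_site),
         junction_ref = substr(edited, fwd_start + 1L, rev_end),
         junction_pos = jpos),
    class = "junction_design"
  )
}
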