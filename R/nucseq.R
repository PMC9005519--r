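#' Validated nucleotide sequence
#'
#' A `nuc_seq` is a length-1 uppercase character string over the alphabet
#' A, C, G, T, N with an `id` attribute. All sequence-level operations in
#' the package accept either a `nuc_seq` or a plain string, which is
#' validated on entry.
#'
#' @param bases Character scalar, the sequence.
#' @param id Character scalar label.
#' @return A `nuc_seq` object (character scalar with `id` attribute).
#' @examples
#' s <- nuc_seq("ACGTACGT", id = "example")
#' revcomp(s)
#' @export
nuc_seq <- function(bases, id = "seq") {
  stopifnot(is.character(bases), length(bases) == 1L, !is.na(bases))
  bases <- toupper(bases)
  if (nchar(bases) == 0L) {
    stop("nuc_seq: sequence must be non-empty", call. = FALSE)
  }
  if (grepl("[^ACGTN]", bases)) {
    bad <- unique(strsplit(gsub("[ACGTN]", "", bases), "")[[1]])
    stop("nuc_seq: invalid characters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(bases, id = as.character(id), class = "nuc_seq")
}

#' @export
print.nuc_seq <- function(x, ...) {
  n <- nchar(x)
  shown <- if (n > 60) paste0(substr(x, 1, 60), "...") else unclass(x)
  cat(sprintf("<nuc_seq '%s', %d nt> %s\n", attr(x, "id"), n, shown))
  invisible(x)
}

# coerce + validate; used at the top of every sequence-consuming function
as_nuc_seq <- function(x, id = "seq") {
  if (inherits(x, "nuc_seq")) return(x)
  nuc_seq(x, id = id)
}

seq_id <- function(x) {
  id <- attr(x, "id")
  if (is.null(id)) "seq" else id
}

# validate and return the bare character string (no class, no attributes)
chr_seq <- function(x, id = "seq") {
  as.vector(unclass(as_nuc_seq(x, id = id)))
}

#' Reverse complement
#'
#' N complements to N. Involution: `revcomp(revcomp(s))` equals `s`.
#'
#' @param seq A `nuc_seq` or character scalar.
#' @return A `nuc_seq` of the same length.
#' @examples
#' revcomp("AAACCC")  # "GGGTTT"
#' @export
revcomp <- function(seq) {
  s <- as_nuc_seq(seq)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(unclass(s)))
  )
  nuc_seq(rc, id = paste0(seq_id(s), "_rc"))
}

# plain-character reverse complement for inner loops (no validation)
revcomp_chr <- function(x) {
  vapply(
    x,
    function(s) {
      chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    },
    character(1), USE.NAMES = FALSE
  )
}

#' STOP codons in all three reading frames
#'
#' Scans a sequence for TAA/TAG/TGA codons starting at indices congruent to
#' 0, 1, 2 (mod 3). A donor STOP cassette must return `TRUE` in every frame
#' so that translation of the endogenous gene is blocked regardless of the
#' INDELs introduced by NHEJ at the integration junction.
#'
#' @param seq A `nuc_seq` or string of length >= 3.
#' @return Logical vector of length 3, one element per frame.
#' @examples
#' stops_in_three_frames("TAAATAAATAAA")  # all TRUE
#' @export
stops_in_three_frames <- function(seq) {
  s <- unclass(as_nuc_seq(seq))
  n <- nchar(s)
  if (n < 3L) stop("stops_in_three_frames: sequence shorter than one codon",
                   call. = FALSE)
  stops <- c("TAA", "TAG", "TGA")
  out <- c(frame0 = FALSE, frame1 = FALSE, frame2 = FALSE)
  for (i in seq_len(n - 2L)) {
    if (substr(s, i, i + 2L) %in% stops) out[((i - 1L) %% 3L) + 1L] <- TRUE
    if (all(out)) break
  }
  out
}

#' Generate a random nucleotide sequence
#'
#' Uniform over A/C/G/T. Used by the simulator for mock genomes, decoy
#' chromosomes and inserted bases.
#'
#' @param n Length in nt.
#' @param id Sequence label.
#' @return A `nuc_seq`.
#' @export
random_nucseq <- function(n, id = "random") {
  nuc_seq(paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                collapse = ""), id = id)
}

#' Read and write FASTA
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] that return / accept named character
#' vectors of sequences (80-column wrapped on output).
#'
#' @param path File path.
#' @param seqs Named character vector (or list of `nuc_seq`).
#' @return `read_fasta`: named character vector. `write_fasta`: `path`,
#'   invisibly.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  if (is.list(seqs)) {
    nm <- vapply(seqs, seq_id, character(1))
    seqs <- setNames(vapply(seqs, unclass, character(1)), nm)
  }
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}
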