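#' Allele frequency vector
#'
#' Labeled allele frequencies (e.g. wild-type, P23H, HITI-edited,
#' INDEL-disrupted) that must be in `[0, 1]` and sum to 1 within 1e-9.
#'
#' @param x Named numeric vector.
#' @return Validated named numeric vector of class `allele_freqs`.
#' @export
allele_freqs <- function(x) {
  stopifnot(is.numeric(x), !is.null(names(x)), all(nzchar(names(x))))
  if (any(x < 0 | x > 1)) {
    stop("allele_freqs: frequencies must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(x) - 1) > 1e-9) {
    stop("allele_freqs: frequencies must sum to 1 (got ", sum(x), ")",
         call. = FALSE)
  }
  structure(x, class = "allele_freqs")
}

#' Hardy-Weinberg genotype frequencies
#'
#' Multi-allelic Hardy-Weinberg: genotype (i,i) has frequency p_i^2 and
#' (i,j), i != j, frequency 2 p_i p_j; the table sums to 1.
#'
#' @param p An [allele_freqs()] (or a named numeric vector summing to 1).
#' @return A `hw_table`: data.frame `allele1`, `allele2`, `freq` (one row
#'   per unordered genotype) with the full symmetric matrix in attribute
#'   `matrix`.
#' @examples
#' hw_genotypes(c(wt = 0.5, mut = 0.5))  # 0.25 / 0.50 / 0.25
#' @export
hw_genotypes <- function(p) {
  p <- allele_freqs(unclass(p))
  labs <- names(p)
  m <- outer(unclass(p), unclass(p))
  rows <- list()
  for (i in seq_along(p)) {
    for (j in i:length(p)) {
      rows[[length(rows) + 1L]] <- data.frame(
        allele1 = labs[i], allele2 = labs[j],
        freq = if (i == j) unclass(p)[i]^2 else 2 * unclass(p)[i] * unclass(p)[j],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "matrix") <- m
  class(out) <- c("hw_table", class(out))
  out
}

#' Heterozygote adjustment of measured allele frequencies
#'
#' Allele frequencies are measured in homozygous wild-type animals; in a
#' heterozygous mutant the wild-type allele pool is half as large, so the
#' measured wild-type frequency is halved and an equal frequency is
#' assigned to the mutant allele (e.g. a measured 86% wild-type becomes
#' 43% wild-type + 43% P23H). The edited-class frequencies keep their
#' mutual proportions; because the wild-type plus mutant mass equals the
#' original wild-type mass, they are unchanged up to renormalization.
#'
#' @param measured An [allele_freqs()] measured in homozygous wild-type
#'   tissue; must contain `wt_label`.
#' @param mutant_label Label for the mutant allele added to the vector.
#' @param wt_label Label of the wild-type allele (default `"wild_type"`).
#' @return An [allele_freqs()] including `mutant_label`, summing to 1.
#' @examples
#' heterozygote_adjust(c(wild_type = 0.86, hiti = 0.10, indel = 0.04),
#'                     mutant_label = "P23H")
#' @export
heterozygote_adjust <- function(measured, mutant_label = "P23H",
                                wt_label = "wild_type") {
  measured <- allele_freqs(unclass(measured))
  if (!wt_label %in% names(measured)) {
    stop("heterozygote_adjust: no '", wt_label, "' allele to halve",
         call. = FALSE)
  }
  if (mutant_label %in% names(measured)) {
    stop("heterozygote_adjust: '", mutant_label, "' already present",
         call. = FALSE)
  }
  wt <- unclass(measured)[[wt_label]]
  out <- unclass(measured)
  out[[wt_label]] <- wt / 2
  out[[mutant_label]] <- wt / 2
  others <- setdiff(names(out), c(wt_label, mutant_label))
  rest <- 1 - wt
  if (length(others) && rest > 0) {
    out[others] <- out[others] * (1 - wt) / rest  # factor 1; keeps proportions
  } else if (length(others)) {
    out[others] <- 0
  }
  out <- out / sum(out)
  allele_freqs(out)
}

#' Percent reduction between two measurements
#'
#' `100 * (from - to) / from`; e.g. DsRed-positive hepatocytes falling from
#' 18.2% to 2.5% is an 86% reduction.
#'
#' @param from,to Numeric values on the same scale, `from != 0`.
#' @return Percent reduction.
#' @export
percent_reduction <- function(from, to) {
  stopifnot(is.numeric(from), is.numeric(to), all(from != 0))
  100 * (from - to) / from
}

#' Read and write allele/genotype frequency TSV
#'
#' `read_allele_freqs`: two-column TSV (allele, freq) to [allele_freqs()].
#' `write_hw_table`: genotype table to TSV (allele1, allele2, freq).
#'
#' @param path File path.
#' @param x A `hw_table`.
#' @return `read_allele_freqs`: an `allele_freqs`; `write_hw_table`:
#'   `path`, invisibly.
#' @export
read_allele_freqs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  allele_freqs(setNames(df[[2]], df[[1]]))
}

#' @rdname read_allele_freqs
#' @export
write_hw_table <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
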