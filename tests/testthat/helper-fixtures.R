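# Shared fixtures: a small locus/donor pair built fresh in code.

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a 20-nt protospacer guaranteed free of accidental self-matches is not
# required; tests that need uniqueness embed the site in random flanks and
# retry via seed choice
fix_guide <- function() guide_spec("GACGGTACCTAGCATCATTG")

# locus: 150 random nt | protospacer | AGG | 150 random nt  (cut_pos = 167)
fix_locus <- function(seed = 7) {
  set.seed(seed)
  g <- fix_guide()
  ref <- paste0(rand_seq(150), g$protospacer, "AGG", rand_seq(150))
  place_guide(ref, g)
}

fix_payload <- function(seed = 7, n = 300) {
  set.seed(seed + 1000)
  paste0("ATG", rand_seq(n - 3))
}

fix_donor <- function(seed = 7, start_type = "kozak") {
  build_donor(fix_guide(), fix_payload(seed), start_type, pam = "AGG")
}

# random sequence of length n whose first base differs from `avoid`, so a
# chimeric junction cannot extend an exact match across the boundary
rand_seq_mismatch <- function(n, avoid) {
  first <- sample(setdiff(c("A", "C", "G", "T"), avoid), 1)
  if (n == 1) first else paste0(first, rand_seq(n - 1))
}

# random guide embedded in random flanks with a concrete AGG PAM; used by
# property tests over many guides
random_guide_locus <- function(flank = 60) {
  repeat {
    proto <- rand_seq(20)
    g <- guide_spec(proto)
    ref <- paste0(rand_seq(flank), proto, "AGG", rand_seq(flank))
    loc <- tryCatch(place_guide(ref, g), error = function(e) NULL)
    if (!is.null(loc)) return(loc)
  }
}
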