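# Shared fixtures built in code.

SYM_A <- "α"; SYM_B <- "β"; SYM_C <- "γ"

# Tiny hand-built registry: 120 bp alleles, two per class.
# Class B carries a private SacI site; classes A and B share a HinfI site
# that C lacks (so SacI separates B, HinfI separates C: a 2-enzyme panel).
tiny_registry <- function() {
  backbone <- paste(rep("ACGGTA", 20), collapse = "")  # 120 bp, no SacI/HinfI
  plant <- function(seq, pos0, motif) {
    paste0(substr(seq, 1, pos0), motif,
           substr(seq, pos0 + nchar(motif) + 1, nchar(seq)))
  }
  a <- plant(backbone, 30, "GAATC")                 # HinfI, cut 31
  b <- plant(plant(backbone, 30, "GAATC"), 70, "GAGCTC")  # + SacI, cut 75
  c_ <- backbone                                     # uncut by both
  snp <- function(seq, pos0, base) plant(seq, pos0, base)
  allele_registry(list(
    allele("A1", "A", a), allele("A2", "A", snp(a, 5, "T")),
    allele("B1", "B", b), allele("B2", "B", snp(b, 5, "T")),
    allele("C1", "C", c_), allele("C2", "C", snp(c_, 5, "T"))
  ))
}

# Independent brute-force digestion oracle: expands the IUPAC recognition
# into all concrete strings (both orientations), scans every window by
# string comparison, and cuts at start + offset.
oracle_digest <- function(seq, recognition, cut_offset) {
  expand <- function(pat) {
    sets <- lapply(strsplit(pat, "")[[1]], function(ch) {
      strsplit(radicans:::IUPAC_MAP[[ch]], "")[[1]]
    })
    apply(do.call(expand.grid, c(sets, stringsAsFactors = FALSE)), 1,
          paste, collapse = "")
  }
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  pats <- unique(c(expand(recognition), vapply(expand(recognition), rc, "")))
  w <- nchar(recognition)
  n <- nchar(seq)
  starts <- integer(0)
  if (n >= w) {
    windows <- substring(seq, 1:(n - w + 1), w:n)
    starts <- which(windows %in% pats) - 1L
  }
  cuts <- unique(sort(starts + cut_offset))
  cuts <- cuts[cuts > 0 & cuts < n]
  sort(diff(c(0, cuts, n)))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# cohort data.frame from compact genotype strings and counts
cohort_from_counts <- function(counts) {
  compact <- rep(names(counts), counts)
  data.frame(formula = compact,
             ploidy = nchar(compact),
             stringsAsFactors = FALSE)
}
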