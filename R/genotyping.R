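## Genomic-formula assembly and taxon assignment.
##
## A sample's genotype is written as a string of genome symbols whose
## length equals its ploidy: the maternal genome (from the chloroplast
## rbcL haplotype) occupies the first slot, the nuclear alleles recovered
## by cloning fill the rest, and "*" marks slots whose dosage could not
## be resolved. Genome classes map A -> alpha, B -> beta, C -> gamma.
## The canonical plain-text rendering separates the maternal slot with a
## pipe ("beta|alpha alpha" is written "β|αα"); a renderer
## with the maternal symbol underlined is available for display.

GENOME_SYMBOL <- c(A = "α", B = "β", C = "γ")
SYMBOL_CLASS <- stats::setNames(names(GENOME_SYMBOL), GENOME_SYMBOL)

TAXON_KALAMOCARPA <- "V. kalamocarpa"
TAXON_NIPPONICA <- "V. nipponica"
TAXON_STENOSIPHON <- "V. × stenosiphon"
TAXON_QUELPAERTENSIS <- "V. × quelpaertensis"
TAXON_TRIPLE <- "V. kalamocarpa × V. nipponica × V. striata"
TAXON_UNRECORDED <- "not recorded in Korea"

#' Minimum number of clones to sequence for a given ploidy
#'
#' Cloned colonies of the GapCp amplicon are sequenced until at least
#' 2.5 times the ploidy level have been examined, so that every allele
#' has a fair chance of being recovered.
#'
#' @param ploidy integer ploidy level(s).
#' @return `ceiling(2.5 * ploidy)` as integer.
#' @export
required_clones <- function(ploidy) {
  stopifnot(all(ploidy >= 1L))
  as.integer(ceiling(2.5 * as.numeric(ploidy)))
}

genomic_formula <- function(maternal, nuclear, unresolved, ploidy,
                            flags = character(0)) {
  stopifnot(1L + length(nuclear) + unresolved == ploidy, unresolved >= 0L)
  structure(list(maternal = maternal, nuclear = nuclear,
                 unresolved = as.integer(unresolved),
                 ploidy = as.integer(ploidy), flags = flags),
            class = "genomic_formula")
}

#' Render a genomic formula
#'
#' @param x a `genomic_formula`.
#' @param style `"pipe"` (canonical, maternal slot before a `|`),
#'   `"compact"` (no separator, first symbol maternal) or `"underline"`
#'   (maternal symbol carries a combining low line, U+0332).
#' @param ... unused.
#' @return character scalar.
#' @export
format.genomic_formula <- function(x, style = c("pipe", "compact", "underline"),
                                   ...) {
  style <- match.arg(style)
  rest <- paste0(paste(x$nuclear, collapse = ""),
                 strrep("*", x$unresolved))
  switch(style,
         pipe = paste0(x$maternal, "|", rest),
         compact = paste0(x$maternal, rest),
         underline = paste0(x$maternal, "̲", rest))
}

#' @export
print.genomic_formula <- function(x, ...) {
  cat(sprintf("<genomic_formula %s (%dx%s)>\n", format(x), x$ploidy,
              if (length(x$flags)) paste0("; ", paste(x$flags, collapse = ", "))
              else ""))
  invisible(x)
}

#' Parse a compact genotype string into a genomic formula
#'
#' Accepts strings as printed in the field's genotype notation, e.g.
#' `"ββα"` or `"αβ*"`, whose first symbol is
#' the maternal genome. The pipe rendering (`"β|βα"`) is
#' also accepted.
#'
#' @param s genotype string over the alphabet alpha/beta/gamma/*.
#' @return a `genomic_formula`.
#' @export
parse_formula <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  s <- gsub("|", "", s, fixed = TRUE)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  if (length(chars) < 2L) stop("genotype string must cover ploidy >= 2")
  bad <- setdiff(chars, c(GENOME_SYMBOL, "*"))
  if (length(bad) > 0L) stop("unknown genotype symbol(s): ",
                             paste(bad, collapse = ", "))
  if (chars[1L] == "*") stop("maternal (first) slot cannot be unresolved")
  nuclear <- chars[-1L]
  genomic_formula(chars[1L], nuclear[nuclear != "*"],
                  sum(nuclear == "*"), length(chars))
}

## Ordering of nuclear symbols after the maternal slot, matching the
## printed genotype strings: remaining copies of the maternal class
## first, then the other classes by descending dosage, ties in Greek
## order (so maternal beta + {beta, alpha} renders beta|beta alpha).
order_nuclear <- function(symbols, maternal) {
  if (length(symbols) == 0L) return(character(0))
  tab <- table(factor(symbols, levels = GENOME_SYMBOL))
  mat <- rep(maternal, tab[[maternal]])
  others <- names(tab)[names(tab) != maternal & tab > 0L]
  others <- others[order(-tab[others], match(others, GENOME_SYMBOL))]
  c(mat, unlist(lapply(others, function(s) rep(s, tab[[s]])), use.names = FALSE))
}

#' Assemble a genomic formula from haplotype, clones and ploidy
#'
#' When the number of distinct cloned alleles equals the ploidy level,
#' the full dosage is known and the precise formula is produced. When
#' fewer distinct alleles were recovered, each observed non-maternal
#' class appears once and the remaining slots are filled with `"*"`.
#' More distinct alleles than the ploidy level signals contamination or
#' chimeric clones and is an error.
#'
#' @param maternal maternal genome, given as an rbcL haplotype
#'   (`"I"`, `"I'"`, `"I''"`, `"II"`, `"III"`) or a genome class letter.
#' @param clone_classes character multiset of the genome classes of the
#'   *distinct* alleles recovered by cloning, e.g. `c("A", "A", "B")`
#'   for two distinct A alleles plus one B allele.
#' @param ploidy integer ploidy level (>= 2).
#' @return a `genomic_formula`; inconsistencies (maternal class not
#'   among the clones) are recorded in `$flags` with a warning.
#' @export
assemble_formula <- function(maternal, clone_classes, ploidy) {
  stopifnot(ploidy >= 2L, length(clone_classes) >= 1L)
  if (maternal %in% c("I", "I'", "I''", "II", "III")) {
    maternal <- haplotype_to_class(maternal)
  }
  maternal <- match.arg(maternal, c("A", "B", "C"))
  stopifnot(all(clone_classes %in% c("A", "B", "C")))
  n_alleles <- length(clone_classes)
  if (n_alleles > ploidy) {
    stop(sprintf("%d distinct alleles exceed ploidy %d: contamination or chimeric clones",
                 n_alleles, ploidy))
  }
  mat_sym <- GENOME_SYMBOL[[maternal]]
  syms <- unname(GENOME_SYMBOL[clone_classes])
  flags <- character(0)
  if (!maternal %in% clone_classes) {
    flags <- "maternal_class_not_recovered"
    warning("maternal genome class ", maternal,
            " not among cloned alleles; formula flagged")
  }
  if (n_alleles == ploidy && !length(flags)) {
    ## dosage known: deduct the maternal first-slot copy
    nuclear <- syms[-match(mat_sym, syms)]
    unresolved <- 0L
  } else {
    distinct <- unique(syms[syms != mat_sym])
    nuclear <- distinct
    unresolved <- ploidy - 1L - length(distinct)
    if (unresolved < 0L) {
      stop("more distinct non-maternal classes than nuclear slots")
    }
  }
  genomic_formula(mat_sym, order_nuclear(nuclear, mat_sym), unresolved,
                  ploidy, flags = flags)
}

#' Assign a taxon to a genomic formula
#'
#' Known printed genotypes map through an exact table; any other valid
#' formula falls back to the class-set rule: {alpha} only ->
#' *V. kalamocarpa*; {beta} only -> *V. nipponica*; {alpha, beta} ->
#' *V. x stenosiphon*; {alpha, gamma} -> *V. x quelpaertensis*;
#' {alpha, beta, gamma} -> the triple hybrid *V. kalamocarpa x
#' V. nipponica x V. striata*; {gamma} or {beta, gamma} combinations are
#' flagged as not recorded in Korea.
#'
#' @param f a `genomic_formula` (or a compact genotype string).
#' @return a `taxon_assignment`: list with `taxon`, `formula`, `basis`
#'   and an optional `note`.
#' @export
classify_taxon <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(inherits(f, "genomic_formula"))
  classes <- sort(unique(SYMBOL_CLASS[c(f$maternal, f$nuclear)]))
  if (length(classes) == 0L) stop("empty genome class set")
  key <- paste(classes, collapse = "")
  compact <- format(f, style = "compact")
  exact <- compact %in% known_genotype_strings()
  note <- NULL
  taxon <- switch(
    key,
    "A" = TAXON_KALAMOCARPA,
    "B" = TAXON_NIPPONICA,
    "AB" = TAXON_STENOSIPHON,
    "AC" = TAXON_QUELPAERTENSIS,
    "ABC" = TAXON_TRIPLE,
    {
      note <- sprintf("genome set {%s} matches no recorded Korean taxon; nearest recorded combinations involve the alpha genome",
                      paste(GENOME_SYMBOL[classes], collapse = ","))
      TAXON_UNRECORDED
    })
  if (key == "AB" && f$ploidy > 3L) {
    note <- "alpha+beta combination recorded only at ploidy 2-3"
  }
  structure(list(taxon = taxon, formula = f,
                 basis = if (exact) "exact_table" else "class_set_rule",
                 note = note),
            class = "taxon_assignment")
}

## genotype strings actually recorded in the Korean cohort
known_genotype_strings <- function() {
  a <- GENOME_SYMBOL[["A"]]; b <- GENOME_SYMBOL[["B"]]; g <- GENOME_SYMBOL[["C"]]
  c(paste0(a, a), paste0(a, a, a),
    paste0(b, b), paste0(b, b, b),
    paste0(a, b),
    paste0(a, a, b), paste0(a, b, b), paste0(a, b, "*"),
    paste0(b, a, a), paste0(b, b, a), paste0(b, a, "*"),
    paste0(a, a, g), paste0(g, a, b),
    paste0(a, a, b, g), paste0(a, b, b, g))
}

#' @export
print.taxon_assignment <- function(x, ...) {
  cat(sprintf("<taxon_assignment: %s = %s (%s)%s>\n",
              format(x$formula), x$taxon, x$basis,
              if (is.null(x$note)) "" else paste0("; ", x$note)))
  invisible(x)
}

round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  ## epsilon guards against values like 8.45 sitting just below .5
  ## after binary representation
  floor(x * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Summarise a genotyped cohort
#'
#' Counts and percentages per genotype group (non-hybrid alpha,
#' non-hybrid beta, and hybrids by ploidy) and per ploidy level; rbcL
#' haplotype frequencies are included when available. Group percentages
#' are rounded half-up to integers, haplotype frequencies to one
#' decimal, matching the reporting precision of the assay.
#'
#' @param cohort data.frame with columns `formula` (compact or pipe
#'   genotype strings, or a list of `genomic_formula`s) and `ploidy`;
#'   optional columns `taxon` and `haplotype`.
#' @return list with data.frames `groups`, `ploidy`, optionally
#'   `taxa` and `haplotypes`, and `n` (cohort size).
#' @export
cohort_summary <- function(cohort) {
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 1L,
            all(c("formula", "ploidy") %in% names(cohort)))
  formulas <- if (is.list(cohort$formula) && !is.character(cohort$formula)) {
    cohort$formula
  } else {
    lapply(cohort$formula, parse_formula)
  }
  n <- nrow(cohort)
  grp <- vapply(seq_len(n), function(i) {
    f <- formulas[[i]]
    classes <- unique(SYMBOL_CLASS[c(f$maternal, f$nuclear)])
    hybrid <- length(classes) > 1L || f$unresolved > 0L
    if (!hybrid && classes == "A") "nonhybrid_alpha"
    else if (!hybrid && classes == "B") "nonhybrid_beta"
    else if (!hybrid) "nonhybrid_gamma"
    else paste0("hybrid_", c("2" = "diploid", "3" = "triploid",
                             "4" = "tetraploid")[as.character(f$ploidy)])
  }, character(1))
  levels_grp <- c("nonhybrid_alpha", "nonhybrid_beta", "nonhybrid_gamma",
                  "hybrid_diploid", "hybrid_triploid", "hybrid_tetraploid")
  tab <- table(factor(grp, levels = levels_grp))
  groups <- data.frame(group = names(tab), n = as.integer(tab),
                       pct = round_half_up(100 * as.integer(tab) / n),
                       row.names = NULL, stringsAsFactors = FALSE)
  ptab <- table(cohort$ploidy)
  ploidy <- data.frame(ploidy = as.integer(names(ptab)), n = as.integer(ptab),
                       pct = round_half_up(100 * as.integer(ptab) / n),
                       row.names = NULL, stringsAsFactors = FALSE)
  out <- list(groups = groups, ploidy = ploidy, n = n)
  if (!is.null(cohort$taxon)) {
    ttab <- sort(table(cohort$taxon), decreasing = TRUE)
    out$taxa <- data.frame(taxon = names(ttab), n = as.integer(ttab),
                           pct = round_half_up(100 * as.integer(ttab) / n),
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  if (!is.null(cohort$haplotype)) {
    htab <- table(cohort$haplotype)
    out$haplotypes <- data.frame(
      haplotype = names(htab), n = as.integer(htab),
      pct = round_half_up(100 * as.integer(htab) / n, 1L),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  out
}
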