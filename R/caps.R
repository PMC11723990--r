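## CAPS (cleaved amplified polymorphic sequence) marker machinery:
## in-silico restriction digestion, diagnostic-enzyme selection over the
## A/B/C genotype classes, gel band-pattern prediction for pure and mixed
## (hybrid) amplicons, and genotype-class calling from observed patterns.
##
## Coordinates are 0-based, half-open. Cut positions are modeled on the
## top strand only; the shipped panel enzymes (SacI, HinfI) have
## palindromic recognition sites, so both strands give the same cut set.
## Only fragment lengths are modeled, not sticky ends; partial digestion,
## heteroduplexes and PCR recombination artifacts are out of scope.

#' Construct a restriction enzyme
#'
#' @param name enzyme name, e.g. `"SacI"`.
#' @param recognition IUPAC recognition site, e.g. `"GAGCTC"` or `"GANTC"`.
#' @param cut_offset 0-based offset within the recognition site; the cut
#'   falls immediately before this position's base on the top strand
#'   (SacI GAGCT^C has `cut_offset = 5`, HinfI G^ANTC has `cut_offset = 1`).
#' @return an object of class `enzyme`.
#' @export
enzyme <- function(name, recognition, cut_offset) {
  recognition <- check_dna(recognition)
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > nchar(recognition)) {
    stop("cut_offset must lie within [0, nchar(recognition)]")
  }
  structure(list(name = name, recognition = recognition,
                 cut_offset = cut_offset),
            class = "enzyme")
}

#' @export
print.enzyme <- function(x, ...) {
  rec <- strsplit(x$recognition, "", fixed = TRUE)[[1]]
  cat(sprintf("<enzyme %s: %s>\n", x$name,
              paste0(c(rec[seq_len(x$cut_offset)], "^",
                       rec[-seq_len(x$cut_offset)]), collapse = "")))
  invisible(x)
}

#' Built-in restriction enzyme table
#'
#' A minimal REBASE-like catalogue of common 4-6 bp cutters, shipped as
#' JSON lines under `inst/extdata/enzymes.jsonl` and user-extensible via
#' `extra`. The two enzymes of the GapCp diagnostic assay, SacI and
#' HinfI, are included.
#'
#' @param names optional character vector restricting (and ordering) the
#'   returned enzymes.
#' @param extra optional list of additional [enzyme()] objects.
#' @return named list of `enzyme` objects in catalogue order.
#' @export
enzyme_db <- function(names = NULL, extra = NULL) {
  path <- system.file("extdata", "enzymes.jsonl", package = "radicans")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  db <- lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln)
    enzyme(rec$name, rec$recognition, rec$cut_offset)
  })
  names(db) <- vapply(db, `[[`, character(1), "name")
  if (!is.null(extra)) {
    stopifnot(all(vapply(extra, inherits, logical(1), "enzyme")))
    for (e in extra) db[[e$name]] <- e
  }
  if (!is.null(names)) {
    missing <- setdiff(names, base::names(db))
    if (length(missing) > 0L) {
      stop("unknown enzyme(s): ", paste(missing, collapse = ", "))
    }
    db <- db[names]
  }
  db
}

#' Find restriction sites on a sequence
#'
#' Scans the top strand for IUPAC matches of the recognition site and of
#' its reverse complement (bottom-strand sites), deduplicates, and
#' returns the 0-based start positions in ascending order. Overlapping
#' matches are reported.
#'
#' @param seq ungapped DNA string.
#' @param enz an [enzyme()].
#' @return integer vector of 0-based site start positions (possibly empty).
#' @export
find_sites <- function(seq, enz) {
  stopifnot(inherits(enz, "enzyme"))
  seq <- check_dna(seq)
  if (grepl("-", seq, fixed = TRUE)) stop("sequence must be ungapped")
  pats <- unique(c(enz$recognition, revcomp(enz$recognition)))
  starts <- integer(0)
  for (p in pats) {
    m <- gregexpr(paste0("(?=", iupac_regex(p), ")"), seq, perl = TRUE)[[1]]
    if (m[1L] != -1L) starts <- c(starts, as.integer(m) - 1L)
  }
  sort(unique(starts))
}

#' Digest a sequence in silico
#'
#' Cut coordinates are `site_start + cut_offset` for every recognition
#' site; fragments are the lengths between consecutive cuts including the
#' sequence ends, so they always sum to `nchar(seq)`.
#'
#' @inheritParams find_sites
#' @return a `digest_pattern`: integer multiset of fragment lengths
#'   (ascending), with the enzyme name attached.
#' @export
digest <- function(seq, enz) {
  seq <- check_dna(seq)
  n <- nchar(seq)
  cuts <- find_sites(seq, enz) + enz$cut_offset
  cuts <- cuts[cuts > 0L & cuts < n]    # end-coincident cuts produce no fragment
  frags <- diff(c(0L, sort(unique(cuts)), n))
  structure(list(fragments = as.integer(sort(frags)), enzyme = enz$name,
                 seq_length = n),
            class = "digest_pattern")
}

#' @export
print.digest_pattern <- function(x, ...) {
  cat(sprintf("<digest %s: %s bp>\n", x$enzyme,
              paste(rev(x$fragments), collapse = " + ")))
  invisible(x)
}

#' Reduce a digest to its gel-visible band pattern
#'
#' Fragments shorter than `min_band_bp` run off (or out of) a 2% agarose
#' gel and are ignored; specific shared fragment lengths can additionally
#' be dropped via `drop_shared` (the assay ignores a 40 bp HinfI fragment
#' shared by all three genotypes and a 52 bp fragment shared by A and B).
#' Equal lengths co-migrate and collapse to a single band.
#'
#' @param d a `digest_pattern` from [digest()], or a numeric vector of
#'   fragment lengths.
#' @param min_band_bp minimum visible band length (default 60, which
#'   auto-ignores the assay's 40 and 52 bp fragments).
#' @param drop_shared optional lengths to ignore regardless of size.
#' @return a `band_pattern`: `bands` (distinct lengths, descending) and
#'   `ignored` (multiset of suppressed fragment lengths).
#' @export
to_band_pattern <- function(d, min_band_bp = 60L, drop_shared = integer(0)) {
  frags <- if (inherits(d, "digest_pattern")) d$fragments else as.integer(d)
  stopifnot(min_band_bp >= 0L)
  drop <- frags < min_band_bp | frags %in% drop_shared
  band_pattern(frags[!drop], ignored = frags[drop])
}

#' Construct a band pattern directly
#'
#' @param bands numeric band lengths (deduplicated, stored descending).
#' @param ignored multiset of suppressed fragment lengths.
#' @return a `band_pattern`.
#' @export
band_pattern <- function(bands, ignored = integer(0)) {
  structure(list(bands = sort(unique(as.integer(bands)), decreasing = TRUE),
                 ignored = as.integer(sort(ignored))),
            class = "band_pattern")
}

#' @export
print.band_pattern <- function(x, ...) {
  cat(sprintf("<bands: %s%s>\n",
              if (length(x$bands)) paste(x$bands, collapse = ", ") else "(none)",
              if (length(x$ignored))
                paste0(" | ignored: ", paste(x$ignored, collapse = ", "))
              else ""))
  invisible(x)
}

## Merge co-migrating bands (gap < tol) and compare two band sets.
## tol = 0 demands identical length sets.
merge_bands <- function(bands, tol) {
  b <- sort(unique(as.numeric(bands)))
  if (length(b) <= 1L || tol <= 0) return(b)
  groups <- cumsum(c(1, diff(b) >= tol))
  as.numeric(tapply(b, groups, mean))
}

bands_equal <- function(a, b, tol = 0) {
  a <- merge_bands(a, tol)
  b <- merge_bands(b, tol)
  if (length(a) != length(b)) return(FALSE)
  if (length(a) == 0L) return(TRUE)
  if (tol <= 0) return(all(a == b))
  all(abs(a - b) < tol)
}

## Band patterns per class for one enzyme, NULL if the class is not
## invariant (alleles of the class disagree on the gel).
class_patterns <- function(registry, enz, min_band_bp, drop_shared,
                           min_diff_bp) {
  out <- list()
  for (cls in registry_classes(registry)) {
    ids <- registry$class_index[[cls]]
    pats <- lapply(registry$alleles[ids], function(a) {
      to_band_pattern(digest(a$sequence, enz), min_band_bp, drop_shared)
    })
    ok <- all(vapply(pats[-1L], function(p) {
      bands_equal(p$bands, pats[[1L]]$bands, tol = min_diff_bp)
    }, logical(1)))
    if (!ok) return(NULL)
    out[[cls]] <- pats[[1L]]
  }
  out
}

#' Select a minimal diagnostic enzyme panel
#'
#' Searches subsets of the enzyme catalogue in order of increasing size
#' (ties broken by catalogue order) for the smallest panel such that
#' (i) within each genotype class every registry allele yields the same
#' band pattern and (ii) every pair of classes differs for at least one
#' panel enzyme, where bands closer than `min_diff_bp` are treated as
#' unresolvable on the gel.
#'
#' @param registry an `allele_registry` with at least one allele per class.
#' @param enzymes list of candidate [enzyme()]s (e.g. from [enzyme_db()]).
#' @param min_band_bp,drop_shared passed to [to_band_pattern()].
#' @param min_diff_bp gel resolution: two bands are distinct only if
#'   their lengths differ by at least this many bp (default 20).
#' @return a `diagnostic_panel`: the selected enzymes plus
#'   `reference_patterns[[class]][[enzyme]]` band patterns.
#' @export
select_diagnostic_enzymes <- function(registry, enzymes,
                                      min_band_bp = 60L,
                                      drop_shared = integer(0),
                                      min_diff_bp = 20L) {
  stopifnot(inherits(registry, "allele_registry"), length(enzymes) > 0L)
  classes <- registry_classes(registry)
  if (length(classes) < 2L) stop("registry must contain at least two classes")

  ## per-enzyme reference patterns; enzymes violating within-class
  ## invariance are unusable in any panel
  usable <- list()
  for (e in enzymes) {
    pats <- class_patterns(registry, e, min_band_bp, drop_shared, min_diff_bp)
    if (!is.null(pats)) usable[[e$name]] <- list(enzyme = e, patterns = pats)
  }
  if (length(usable) == 0L) {
    stop("no diagnostic panel: no enzyme is within-class invariant")
  }

  pairs <- utils::combn(classes, 2L, simplify = FALSE)
  separates <- function(name, pr) {
    p <- usable[[name]]$patterns
    !bands_equal(p[[pr[1L]]]$bands, p[[pr[2L]]]$bands, tol = min_diff_bp)
  }
  nm <- names(usable)
  for (size in seq_along(nm)) {
    for (subset in utils::combn(nm, size, simplify = FALSE)) {
      ok <- all(vapply(pairs, function(pr) {
        any(vapply(subset, separates, logical(1), pr = pr))
      }, logical(1)))
      if (ok) {
        ref <- lapply(classes, function(cls) {
          stats::setNames(
            lapply(subset, function(nmi) usable[[nmi]]$patterns[[cls]]),
            subset)
        })
        names(ref) <- classes
        return(structure(
          list(enzymes = lapply(usable[subset], `[[`, "enzyme"),
               reference_patterns = ref,
               min_band_bp = min_band_bp, drop_shared = drop_shared,
               min_diff_bp = min_diff_bp),
          class = "diagnostic_panel"))
      }
    }
  }
  bad <- Filter(function(pr) {
    !any(vapply(nm, separates, logical(1), pr = pr))
  }, pairs)
  stop("no diagnostic panel: class pair(s) indistinguishable: ",
       paste(vapply(bad, paste, character(1), collapse = "/"), collapse = ", "))
}

#' @export
print.diagnostic_panel <- function(x, ...) {
  cat(sprintf("<diagnostic_panel: %s>\n",
              paste(names(x$enzymes), collapse = " + ")))
  for (cls in names(x$reference_patterns)) {
    for (enz in names(x$reference_patterns[[cls]])) {
      b <- x$reference_patterns[[cls]][[enz]]$bands
      cat(sprintf("  %s / %-6s: %s\n", cls, enz,
                  if (length(b)) paste(b, collapse = ", ") else "(uncut, no band)"))
    }
  }
  invisible(x)
}

#' Predict the gel pattern of a genotype mixture
#'
#' A hybrid's PCR product is a mixture of its allele classes; on the gel
#' the observed bands are the union of each distinct class's reference
#' bands. Dosage is invisible: AA, AAA and A all give the single-class
#' pattern.
#'
#' @param classes character multiset of genome classes, e.g. `c("A","A","B")`.
#' @param panel a `diagnostic_panel`.
#' @param enz an [enzyme()] or enzyme name present in the panel.
#' @return a `band_pattern`.
#' @export
predict_mixture_pattern <- function(classes, panel, enz) {
  stopifnot(inherits(panel, "diagnostic_panel"), length(classes) > 0L)
  name <- if (inherits(enz, "enzyme")) enz$name else enz
  if (!name %in% names(panel$enzymes)) {
    stop("enzyme not in panel: ", name)
  }
  classes <- unique(classes)
  missing <- setdiff(classes, names(panel$reference_patterns))
  if (length(missing) > 0L) {
    stop("class(es) missing from panel: ", paste(missing, collapse = ", "))
  }
  bands <- unlist(lapply(classes, function(cls) {
    panel$reference_patterns[[cls]][[name]]$bands
  }))
  ignored <- unlist(lapply(classes, function(cls) {
    panel$reference_patterns[[cls]][[name]]$ignored
  }))
  band_pattern(bands, ignored = ignored)
}

#' Call genotype classes from observed band patterns
#'
#' Finds the unique smallest set of genome classes whose predicted
#' mixture pattern matches the observed pattern for every panel enzyme.
#' Two patterns match when their band sets are equal after merging bands
#' closer than `tolerance_bp` (0 demands exact lengths).
#'
#' @param observed named list (by enzyme name) of `band_pattern`s or
#'   numeric band-length vectors, covering every panel enzyme.
#' @param panel a `diagnostic_panel`.
#' @param tolerance_bp per-band length tolerance (default 0).
#' @return character vector of called classes (sorted).
#' @export
call_classes <- function(observed, panel, tolerance_bp = 0L) {
  stopifnot(inherits(panel, "diagnostic_panel"))
  enz_names <- names(panel$enzymes)
  missing <- setdiff(enz_names, names(observed))
  if (length(missing) > 0L) {
    stop("observed patterns missing for panel enzyme(s): ",
         paste(missing, collapse = ", "))
  }
  obs_bands <- lapply(observed[enz_names], function(o) {
    if (inherits(o, "band_pattern")) o$bands else as.numeric(o)
  })
  classes <- names(panel$reference_patterns)
  subsets <- unlist(lapply(seq_along(classes), function(k) {
    utils::combn(classes, k, simplify = FALSE)
  }), recursive = FALSE)
  matches <- Filter(function(s) {
    all(vapply(enz_names, function(nm) {
      pred <- predict_mixture_pattern(s, panel, nm)
      bands_equal(pred$bands, obs_bands[[nm]], tol = tolerance_bp)
    }, logical(1)))
  }, subsets)
  if (length(matches) == 0L) {
    stop("uninterpretable pattern: no class set predicts the observed bands")
  }
  sizes <- lengths(matches)
  minimal <- matches[sizes == min(sizes)]
  if (length(minimal) > 1L) {
    stop("ambiguous call: candidate class sets ",
         paste(vapply(minimal, paste, character(1), collapse = ""),
               collapse = ", "))
  }
  sort(minimal[[1L]])
}
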