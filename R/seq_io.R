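## Sequence input/output and the registry of numbered GapCp alleles.
##
## Alleles of the single-copy nuclear GapCp region fall into three genome
## classes, A, B and C, corresponding to the alpha, beta and gamma genomes
## of the Vandenboschia radicans complex. The registry houses the known
## numbered alleles per class (A1, A2, ..., B1, ..., C1, ...); sequences
## recovered from cloned colonies are classified against it, and sequences
## that match no registry allele within a mismatch budget are assigned
## novel ids with a "K" infix (AK1, BK1, ...).

#' Read a (multi-record) FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that uppercases
#' sequences, preserves alignment gaps, and enforces unique record ids.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences (names are record ids,
#'   taken as the first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ", conditionMessage(e))
  )
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for record(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Construct an allele record
#'
#' @param id allele id, e.g. `"A1"` or `"BK1"`.
#' @param genome_class one of `"A"`, `"B"`, `"C"`.
#' @param sequence ungapped DNA string.
#' @param source `"registry"` for catalogued alleles, `"novel"` for
#'   newly observed ones; accession is optional GenBank metadata.
#' @param accession optional accession string (metadata only; never fetched).
#' @return an object of class `allele`.
#' @export
allele <- function(id, genome_class, sequence, source = "registry",
                   accession = NA_character_) {
  genome_class <- match.arg(genome_class, c("A", "B", "C"))
  source <- match.arg(source, c("registry", "novel"))
  sequence <- check_dna(sequence)
  if (nchar(sequence) == 0L) stop("allele sequence must be non-empty")
  structure(
    list(id = id, genome_class = genome_class, sequence = sequence,
         source = source, accession = accession),
    class = "allele"
  )
}

#' @export
print.allele <- function(x, ...) {
  cat(sprintf("<allele %s class %s, %d bp, %s>\n",
              x$id, x$genome_class, nchar(x$sequence), x$source))
  invisible(x)
}

#' Build an allele registry
#'
#' @param alleles list of [allele()] objects.
#' @return an `allele_registry`: the allele list plus a class index.
#' @export
allele_registry <- function(alleles) {
  stopifnot(length(alleles) > 0L,
            all(vapply(alleles, inherits, logical(1), "allele")))
  ids <- vapply(alleles, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate allele id(s) in registry: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(alleles) <- ids
  classes <- vapply(alleles, `[[`, character(1), "genome_class")
  structure(
    list(alleles = alleles,
         class_index = split(ids, factor(classes, levels = c("A", "B", "C")))),
    class = "allele_registry"
  )
}

#' @export
print.allele_registry <- function(x, ...) {
  n <- lengths(x$class_index)
  cat(sprintf("<allele_registry: %d alleles (A: %d, B: %d, C: %d)>\n",
              length(x$alleles), n[["A"]], n[["B"]], n[["C"]]))
  invisible(x)
}

registry_classes <- function(registry) {
  names(registry$class_index)[lengths(registry$class_index) > 0L]
}

registry_sequences <- function(registry) {
  vapply(registry$alleles, `[[`, character(1), "sequence")
}

#' Serialize / deserialize an allele registry as JSON
#'
#' The on-disk layout is a map genome class -> array of
#' `{id, accession, sequence}` records.
#'
#' @param registry an `allele_registry`.
#' @param path file path.
#' @return `read_registry_json` returns an `allele_registry`;
#'   `write_registry_json` returns `path` invisibly.
#' @export
write_registry_json <- function(registry, path) {
  by_class <- lapply(registry$class_index, function(ids) {
    lapply(registry$alleles[ids], function(a) {
      list(id = a$id, accession = a$accession, sequence = a$sequence)
    })
  })
  by_class <- by_class[lengths(by_class) > 0L]
  jsonlite::write_json(by_class, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_registry_json
#' @export
read_registry_json <- function(path) {
  raw <- jsonlite::read_json(path)
  alleles <- list()
  for (cls in names(raw)) {
    for (rec in raw[[cls]]) {
      acc <- if (is.null(rec$accession)) NA_character_ else rec$accession
      alleles[[length(alleles) + 1L]] <-
        allele(rec$id, cls, rec$sequence, accession = acc)
    }
  }
  allele_registry(alleles)
}

#' Classify a cloned sequence against the allele registry
#'
#' An exact sequence match returns the catalogued allele. Otherwise the
#' nearest registry allele is found by Hamming distance (equal lengths) or
#' Levenshtein edit distance (unequal lengths); within `max_mismatch` the
#' query becomes a novel allele of that neighbour's class, named with the
#' next free "K" id of the class (AK1, AK2, ...). Ambiguity codes in the
#' query count as mismatches: catalogued alleles are resolved sequences.
#'
#' @param seq ungapped DNA string.
#' @param registry an `allele_registry`.
#' @param max_mismatch maximum distance to the nearest registry allele
#'   before the query is declared unclassifiable (default 10).
#' @return an [allele()]; novel alleles have `source = "novel"`.
#' @export
classify_allele <- function(seq, registry, max_mismatch = 10L) {
  stopifnot(inherits(registry, "allele_registry"))
  seq <- check_dna(seq)
  if (grepl("-", seq, fixed = TRUE)) stop("query sequence must be ungapped")
  refs <- registry_sequences(registry)
  hit <- which(refs == seq)
  if (length(hit) > 0L) return(registry$alleles[[hit[1L]]])

  d <- vapply(refs, function(ref) seq_distance(seq, ref), numeric(1))
  dmin <- min(d)
  if (dmin > max_mismatch) {
    stop(sprintf("unclassified sequence: nearest registry allele is %d mismatches away (max_mismatch = %d)",
                 as.integer(dmin), as.integer(max_mismatch)))
  }
  nearest <- registry$alleles[d == dmin]
  near_classes <- unique(vapply(nearest, `[[`, character(1), "genome_class"))
  if (length(near_classes) > 1L) {
    stop("ambiguous classification: sequence equidistant from classes ",
         paste(sort(near_classes), collapse = " and "))
  }
  cls <- near_classes
  allele(next_novel_id(registry, cls), cls, seq, source = "novel")
}

## Hamming when lengths match, Levenshtein otherwise.
seq_distance <- function(a, b) {
  if (nchar(a) == nchar(b)) {
    sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
  } else {
    as.numeric(utils::adist(a, b))
  }
}

next_novel_id <- function(registry, genome_class) {
  ids <- names(registry$alleles)
  pat <- paste0("^", genome_class, "K([0-9]+)$")
  used <- as.integer(sub(pat, "\\1", ids[grepl(pat, ids)]))
  n <- 1L
  while (n %in% used) n <- n + 1L
  paste0(genome_class, "K", n)
}

#' Map a chloroplast rbcL haplotype to its maternal genome class
#'
#' rbcL is maternally inherited; haplotypes I, I' and I'' belong to the
#' alpha (A) lineage, II to beta (B), III to gamma (C).
#'
#' @param haplotype one of `"I"`, `"I'"`, `"I''"`, `"II"`, `"III"`.
#' @return the maternal genome class, `"A"`, `"B"` or `"C"`.
#' @export
haplotype_to_class <- function(haplotype) {
  map <- c("I" = "A", "I'" = "A", "I''" = "A", "II" = "B", "III" = "C")
  stopifnot(is.character(haplotype))
  if (!all(haplotype %in% names(map))) {
    stop("unknown rbcL haplotype(s): ",
         paste(setdiff(haplotype, names(map)), collapse = ", "))
  }
  unname(map[haplotype])
}
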