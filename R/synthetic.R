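## Synthetic cohorts with known truth.
##
## The generator emulates the five observable layers of the assay on the
## Korean *V. radicans* complex: (1) a registry of ~569 bp GapCp alleles
## whose classes differ by SacI/HinfI site polymorphisms and whose
## within-class alleles differ only by neutral SNPs placed away from any
## recognition site; (2) cloned-colony sequences per sample at >= 2.5x
## ploidy with optional per-allele dropout; (3) chloroplast rbcL
## haplotypes matched to the maternal genome; (4) flow-cytometry G1 peak
## pairs with multiplicative Gaussian noise around x * 6.5 pg against
## the 9.2 pg standard; (5) per-genotype-group morphology at the
## published group means and SDs. Default genotype frequencies follow
## the study cohort of 47 samples.

## study cohort composition (counts / 47)
DEFAULT_GENOTYPE_COUNTS <- c(
  "αα" = 2, "ααα" = 2,
  "ββ" = 4, "βββ" = 6,
  "ααβ" = 7, "αββ" = 6,
  "βαα" = 6, "ββα" = 5,
  "γαβ" = 3, "ααγ" = 2,
  "ααβγ" = 2, "αββγ" = 1,
  "αβ" = 1
)

## Table of per-group trait means and SDs (mm except PN; IW_IL unitless).
## Groups: G1 = alpha non-hybrids, G2 = beta non-hybrids, G3 = alpha+beta
## hybrids, G4 = triple hybrids; AAG = the single alpha-alpha-gamma
## individual (SDs synthetic at 5% CV since only one plant was measurable).
trait_param_table <- function() {
  p <- list(
    G1 = list(RD = c(0.43, 0.01), SL = c(15.92, 3.47), RL = c(32.29, 1.11),
              LW = c(16.71, 1.25), PL = c(10.04, 0.67), PW = c(6.46, 0.84),
              PN = c(7.12, 0.37), IL = c(1.42, 0.12), IW_IL = c(0.53, 0.01)),
    G2 = list(RD = c(0.41, 0.02), SL = c(16.68, 12.53), RL = c(49.98, 22.26),
              LW = c(17.89, 6.43), PL = c(9.22, 3.57), PW = c(6.49, 2.34),
              PN = c(10.41, 1.97), IL = c(0.98, 0.09), IW_IL = c(0.85, 0.05)),
    G3 = list(RD = c(0.42, 0.05), SL = c(29.04, 16.63), RL = c(75.01, 39.31),
              LW = c(24.45, 7.59), PL = c(14.50, 5.70), PW = c(9.80, 2.98),
              PN = c(10.86, 2.55), IL = c(1.46, 0.18), IW_IL = c(0.53, 0.06)),
    AAG = list(RD = c(0.57, 0.0285), SL = c(31.5, 1.575), RL = c(64.0, 3.2),
               LW = c(33.5, 1.675), PL = c(19.5, 0.975), PW = c(12.25, 0.6125),
               PN = c(10.0, 0.5), IL = c(1.74, 0.087), IW_IL = c(0.43, 0.0215)),
    G4 = list(RD = c(0.65, 0.02), SL = c(54.03, 19.47), RL = c(137.27, 27.97),
              LW = c(48.77, 2.71), PL = c(27.07, 2.14), PW = c(15.80, 2.87),
              PN = c(15.27, 1.91), IL = c(1.79, 0.32), IW_IL = c(0.39, 0.02))
  )
  p
}

#' Simulation configuration for synthetic cohorts
#'
#' @param seed integer RNG seed; the same seed reproduces the cohort
#'   byte for byte.
#' @param n_samples cohort size (default 47, the study cohort).
#' @param amplicon_len GapCp amplicon length in bp (default 569; the
#'   assay's products run 568-570 bp).
#' @param genotype_frequencies named numeric vector of compact genotype
#'   strings (first symbol maternal) summing to 1; defaults to the
#'   study cohort composition.
#' @param clone_depth_factor clones sequenced per ploidy unit
#'   (default 2.5, the assay's sampling rule).
#' @param clone_dropout probability that a distinct allele is missed
#'   entirely by cloning (default 0).
#' @param flow_cv coefficient of variation of the flow-cytometry genome
#'   sizes (default 0.03).
#' @param monoploid_1Cx monoploid genome size in pg (default 6.5).
#' @param standard_2C_pg internal standard 2C in pg (default 9.2).
#' @param trait_params per-group trait (mean, sd) list; defaults to the
#'   published group table.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_samples = 47L, amplicon_len = 569L,
                       genotype_frequencies = NULL,
                       clone_depth_factor = 2.5, clone_dropout = 0,
                       flow_cv = 0.03, monoploid_1Cx = 6.5,
                       standard_2C_pg = 9.2, trait_params = NULL) {
  if (is.null(genotype_frequencies)) {
    genotype_frequencies <- DEFAULT_GENOTYPE_COUNTS / sum(DEFAULT_GENOTYPE_COUNTS)
  }
  stopifnot(amplicon_len >= 200L, clone_depth_factor >= 1,
            clone_dropout >= 0, clone_dropout < 1,
            abs(sum(genotype_frequencies) - 1) < 1e-8)
  if (is.null(trait_params)) trait_params <- trait_param_table()
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 amplicon_len = as.integer(amplicon_len),
                 genotype_frequencies = genotype_frequencies,
                 clone_depth_factor = clone_depth_factor,
                 clone_dropout = clone_dropout, flow_cv = flow_cv,
                 monoploid_1Cx = monoploid_1Cx,
                 standard_2C_pg = standard_2C_pg,
                 trait_params = trait_params),
            class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

replace_at <- function(seq, pos0, insert) {
  ## pos0 is 0-based
  paste0(substr(seq, 1L, pos0), insert,
         substr(seq, pos0 + nchar(insert) + 1L, nchar(seq)))
}

## remove every SacI/HinfI site from a random backbone by resampling a
## base inside each site until none remain
scrub_sites <- function(seq, enzymes) {
  repeat {
    sites <- unlist(lapply(enzymes, function(e) find_sites(seq, e)))
    if (length(sites) == 0L) return(seq)
    s <- sites[1L]
    ## both panel motifs start with G on either strand; killing the
    ## first base destroys the site without touching ambiguous positions
    seq <- replace_at(seq, s, sample(c("C", "T"), 1L))
  }
}

#' Generate a synthetic allele registry
#'
#' Builds one random backbone, scrubs all SacI/HinfI sites, then plants
#' class-diagnostic sites: a HinfI site near the 3' end shared by all
#' classes (terminal 40 bp fragment), a HinfI site at 52 bp shared by
#' classes A and B, an additional HinfI site private to class B, and a
#' SacI site private to class B. On a 2% gel (bands < 60 bp ignored)
#' this gives HinfI bands A: 477, B: 198 + 279, C: 529 and SacI bands
#' A/C: 569 (uncut), B: 205 + 364 — every class shows at least one band
#' no other class produces, so mixtures of any class subset remain
#' identifiable. Within-class alleles differ by neutral SNPs placed away
#' from every recognition site.
#'
#' @param cfg a [sim_config()].
#' @return an `allele_registry` with alleles
#'   A1/A2/A5/A13, B1/B2/B3, C1/C2/C7 (synthetic sequences).
#' @export
make_alleles <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  withr_seed(cfg$seed, {
    enz <- enzyme_db(c("SacI", "HinfI"))
    L <- cfg$amplicon_len
    ## site layout scales with amplicon length; defaults quoted for 569 bp
    pos_shared <- L - 41L      # HinfI start: cut at L-40 -> 40 bp tail
    pos_ab <- 51L              # HinfI start: cut at 52 -> 52 bp head (A, B)
    pos_b_hinf <- 249L         # HinfI start: cut at 250, B only
    pos_b_sac <- 200L          # SacI start: cut at 205, B only
    expected <- list(
      A = list(SacI = integer(0), HinfI = c(pos_ab, pos_shared)),
      B = list(SacI = pos_b_sac,
               HinfI = c(pos_ab, pos_b_hinf, pos_shared)),
      C = list(SacI = integer(0), HinfI = pos_shared)
    )
    build_class_seq <- function(base, cls) {
      s <- base
      s <- replace_at(s, pos_shared, "GAATC")
      if (cls %in% c("A", "B")) s <- replace_at(s, pos_ab, "GACTC")
      if (cls == "B") {
        s <- replace_at(s, pos_b_hinf, "GATTC")
        s <- replace_at(s, pos_b_sac, "GAGCTC")
      }
      s
    }
    sites_ok <- function(s, cls) {
      identical(as.integer(find_sites(s, enz$SacI)),
                as.integer(expected[[cls]]$SacI)) &&
        identical(as.integer(find_sites(s, enz$HinfI)),
                  as.integer(expected[[cls]]$HinfI))
    }
    repeat {
      base <- scrub_sites(random_dna(L), enz)
      class_seq <- lapply(c(A = "A", B = "B", C = "C"),
                          function(cls) build_class_seq(base, cls))
      if (all(mapply(sites_ok, class_seq, names(class_seq)))) break
    }
    ## neutral within-class SNPs away from any planted motif
    forbidden <- unique(unlist(lapply(
      list(pos_shared, pos_ab, pos_b_hinf, pos_b_sac),
      function(p) seq(max(0L, p - 6L), p + 11L))))
    free_pos <- setdiff(seq(10L, L - 11L), forbidden)
    ids <- list(A = c("A1", "A2", "A5", "A13"), B = c("B1", "B2", "B3"),
                C = c("C1", "C2", "C7"))
    alleles <- list()
    for (cls in names(ids)) {
      for (i in seq_along(ids[[cls]])) {
        s <- class_seq[[cls]]
        if (i > 1L) {
          ## i-1 neutral SNPs; re-draw any that would touch a site
          for (k in seq_len(i - 1L)) {
            repeat {
              p <- sample(free_pos, 1L)
              old <- substr(s, p + 1L, p + 1L)
              cand <- replace_at(s, p, sample(setdiff(c("A", "C", "G", "T"), old), 1L))
              if (sites_ok(cand, cls)) { s <- cand; break }
            }
          }
        }
        alleles[[length(alleles) + 1L]] <-
          allele(ids[[cls]][i], cls, s, source = "registry")
      }
    }
    allele_registry(alleles)
  })
}

## run code under a temporary seed, restoring RNG state afterwards
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

## group label of a true genotype string (trait generation)
genotype_group <- function(compact) {
  f <- parse_formula(compact)
  classes <- sort(unique(SYMBOL_CLASS[c(f$maternal, f$nuclear)]))
  key <- paste(classes, collapse = "")
  if (key == "A") "G1"
  else if (key == "B") "G2"
  else if (key == "AC") "AAG"
  else if (key == "ABC") "G4"
  else if (f$ploidy == 2L) "AB2"   # the diploid alpha-beta plant: no involucres
  else "G3"
}

#' Generate a complete synthetic cohort
#'
#' Draws a genotype for every sample from the configured frequencies and
#' emits all observable layers plus the truth: the allele registry,
#' per-sample clone FASTA sequences, rbcL haplotype calls, flow peak
#' pairs, and the morphology table. Clone colonies cover the sample's
#' allele multiset evenly (each surviving allele appears
#' `ceiling(depth x ploidy) / n` times, shuffled), so with zero dropout
#' every allele is always recovered; dropout removes whole alleles
#' before colony picking, producing `*` slots downstream but never a
#' wrong class.
#'
#' @param cfg a [sim_config()].
#' @return list with `registry`, `samples` (list per sample: `clones`
#'   named character vector, `haplotype`, `flow` row), `flow`
#'   data.frame, `traits` data.frame, `truth` data.frame.
#' @export
make_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  registry <- make_alleles(cfg)
  withr_seed(cfg$seed + 1L, {
    freqs <- cfg$genotype_frequencies
    genotypes <- sample(names(freqs), cfg$n_samples, replace = TRUE,
                        prob = freqs)
    sample_ids <- sprintf("S%03d", seq_len(cfg$n_samples))
    samples <- vector("list", cfg$n_samples)
    names(samples) <- sample_ids
    flow <- truth <- traits <- NULL
    flow_rows <- list(); truth_rows <- list(); trait_rows <- list()

    for (i in seq_len(cfg$n_samples)) {
      compact <- genotypes[i]
      f <- parse_formula(compact)
      ploidy <- f$ploidy
      classes <- SYMBOL_CLASS[c(f$maternal, f$nuclear)]   # no "*" in truth

      ## one distinct allele per genome copy, drawn without replacement
      ## within each class
      allele_ids <- unlist(lapply(split(classes, classes), function(cc) {
        sample(registry$class_index[[cc[1L]]], length(cc))
      }), use.names = FALSE)

      ## dropout per distinct allele; at least one survives
      kept <- allele_ids[stats::runif(length(allele_ids)) >= cfg$clone_dropout]
      if (length(kept) == 0L) kept <- sample(allele_ids, 1L)

      n_clones <- as.integer(ceiling(cfg$clone_depth_factor * ploidy))
      reps <- rep_len(kept, n_clones)
      clone_ids <- sprintf("%s_clone%02d", sample_ids[i], seq_len(n_clones))
      clones <- stats::setNames(
        vapply(reps, function(id) registry$alleles[[id]]$sequence, character(1)),
        clone_ids)[sample(n_clones)]
      names(clones) <- clone_ids   # ids stay ordered; sequences shuffled

      hap <- switch(SYMBOL_CLASS[[f$maternal]],
                    A = sample(c("I", "I'"), 1L), B = "II", C = "III")

      gs_true <- ploidy * cfg$monoploid_1Cx
      gs_noisy <- gs_true * (1 + stats::rnorm(1L, 0, cfg$flow_cv))
      std_peak <- stats::rnorm(1L, 200, 5)
      smp_peak <- std_peak * gs_noisy / cfg$standard_2C_pg

      grp <- genotype_group(compact)
      if (grp == "AB2") {
        tr <- as.list(stats::setNames(rep(NA_real_, 9L),
                                      c(names(cfg$trait_params$G1))))
      } else {
        pars <- cfg$trait_params[[grp]]
        tr <- lapply(pars, function(ms) {
          max(stats::rnorm(1L, ms[1L], ms[2L]), 0.1 * ms[1L])
        })
        tr$PN <- max(3L, as.integer(round(tr$PN)))
      }
      iw <- if (is.na(tr$IW_IL[1L])) NA_real_ else tr$IW_IL * tr$IL

      samples[[i]] <- list(clones = clones, haplotype = hap,
                           sample_peak = smp_peak, standard_peak = std_peak)
      flow_rows[[i]] <- data.frame(sample_id = sample_ids[i],
                                   sample_peak = smp_peak,
                                   standard_peak = std_peak,
                                   standard_2C_pg = cfg$standard_2C_pg)
      trait_rows[[i]] <- data.frame(
        sample_id = sample_ids[i],
        group = if (grp %in% paste0("G", 1:4)) grp else NA_character_,
        RD = tr$RD, SL = tr$SL, RL = tr$RL, LW = tr$LW, PL = tr$PL,
        PW = tr$PW, PN = tr$PN, IL = tr$IL, IW = iw)
      truth_rows[[i]] <- data.frame(
        sample_id = sample_ids[i], true_formula = format(f),
        true_compact = compact, true_ploidy = ploidy,
        true_2C_pg = gs_true, true_group = grp,
        haplotype = hap, alleles = paste(sort(allele_ids), collapse = ","),
        alleles_recovered = paste(sort(unique(kept)), collapse = ","))
    }
    flow <- do.call(rbind, flow_rows)
    traits <- do.call(rbind, trait_rows)
    traits$IW_IL <- traits$IW / traits$IL
    truth <- do.call(rbind, truth_rows)
    list(registry = registry, samples = samples, flow = flow,
         traits = traits, truth = truth, config = cfg)
  })
}

#' Generate a balanced synthetic trait table
#'
#' Morphology-only generator used for the univariate and DAPC studies:
#' draws group trait values at the published means and SDs. `n_per_group`
#' defaults to the study's group sizes (G1 = 4, G2 = 10, G3 = 24,
#' G4 = 6). IW_IL is drawn directly from its published row (IW derived
#' as ratio x IL) so the ratio's spread matches the printed one.
#'
#' @param n_per_group named or unnamed integer vector for groups
#'   G1..G4; a scalar is recycled.
#' @param seed RNG seed.
#' @param trait_params per-group (mean, sd) list; defaults published.
#' @return data.frame with `sample_id`, `group`, the nine traits and `IW_IL`.
#' @export
make_trait_table <- function(n_per_group = c(G1 = 4L, G2 = 10L, G3 = 24L, G4 = 6L),
                             seed = 1L, trait_params = NULL) {
  if (is.null(trait_params)) trait_params <- trait_param_table()
  groups <- paste0("G", 1:4)
  if (length(n_per_group) == 1L) n_per_group <- rep(n_per_group, 4L)
  if (is.null(names(n_per_group))) names(n_per_group) <- groups
  withr_seed(seed, {
    rows <- list()
    for (g in groups) {
      pars <- trait_params[[g]]
      for (i in seq_len(n_per_group[[g]])) {
        tr <- lapply(pars, function(ms) {
          max(stats::rnorm(1L, ms[1L], ms[2L]), 0.1 * ms[1L])
        })
        tr$PN <- max(3L, as.integer(round(tr$PN)))
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_%02d", g, i), group = g,
          RD = tr$RD, SL = tr$SL, RL = tr$RL, LW = tr$LW, PL = tr$PL,
          PW = tr$PW, PN = tr$PN, IL = tr$IL, IW = tr$IW_IL * tr$IL)
      }
    }
    out <- do.call(rbind, rows)
    out$IW_IL <- out$IW / out$IL
    out
  })
}

#' Write a synthetic cohort to disk
#'
#' Emits `alleles.fasta`, `clones/<sample>.fasta`, `flow.csv`,
#' `traits.csv` and `truth.tsv` under `dir`.
#'
#' @param cohort result of [make_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "clones"), recursive = TRUE, showWarnings = FALSE)
  write_fasta(registry_sequences(cohort$registry),
              file.path(dir, "alleles.fasta"))
  for (id in names(cohort$samples)) {
    write_fasta(cohort$samples[[id]]$clones,
                file.path(dir, "clones", paste0(id, ".fasta")))
  }
  utils::write.csv(cohort$flow, file.path(dir, "flow.csv"), row.names = FALSE)
  utils::write.csv(cohort$traits, file.path(dir, "traits.csv"), row.names = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(dir)
}
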