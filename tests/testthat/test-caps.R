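sacI <- enzyme_db()$SacI
hinfI <- enzyme_db()$HinfI

test_that("find_sites locates IUPAC matches on both strands, ascending", {
  expect_identical(find_sites("GAGCTC", sacI), 0L)
  expect_identical(find_sites("GATTCGACTC", hinfI), c(0L, 5L))
  expect_identical(find_sites("AAAA", sacI), integer(0))
  # bottom-strand-only site of a non-palindromic pattern is still found
  ecoRV <- enzyme("half", "GGATAC", 3)
  expect_identical(find_sites("GTATCC", ecoRV), 0L)
})

test_that("digest cuts at site start + offset and conserves total length", {
  seq <- paste0(strrep("A", 100), "GAGCTC", strrep("T", 463))  # 569 bp
  d <- digest(seq, sacI)
  expect_identical(sort(d$fragments), sort(c(105L, 464L)))
  expect_identical(sum(d$fragments), 569L)
  # no site: single fragment
  expect_identical(digest("ACGTACGT", sacI)$fragments, 8L)
})

test_that("digest agrees with the brute-force IUPAC-expansion oracle", {
  set.seed(42)
  for (i in 1:50) {
    s <- random_seq(sample(200:2000, 1))
    for (e in list(sacI, hinfI)) {
      expect_identical(as.integer(digest(s, e)$fragments),
                       as.integer(oracle_digest(s, e$recognition, e$cut_offset)))
    }
  }
})

test_that("band patterns drop short and listed fragments and collapse co-migration", {
  bp <- to_band_pattern(c(517, 52), min_band_bp = 60)
  expect_identical(bp$bands, 517L)
  expect_identical(bp$ignored, 52L)

  bp <- to_band_pattern(c(40, 40, 489), min_band_bp = 60)
  expect_identical(bp$bands, 489L)
  expect_identical(bp$ignored, c(40L, 40L))

  bp <- to_band_pattern(c(100, 100, 250), min_band_bp = 0)
  expect_identical(bp$bands, c(250L, 100L))   # co-migration collapses

  bp <- to_band_pattern(c(100, 70, 250), min_band_bp = 0, drop_shared = 70)
  expect_identical(bp$bands, c(250L, 100L))
  expect_identical(bp$ignored, 70L)
})

test_that("panel selection finds the minimal diagnostic subset and reference patterns", {
  reg <- tiny_registry()
  panel <- select_diagnostic_enzymes(reg, enzyme_db(c("SacI", "HinfI")))
  # B has a private SacI site, C lacks the shared HinfI site: both needed
  expect_setequal(names(panel$enzymes), c("SacI", "HinfI"))
  expect_identical(panel$reference_patterns$B$SacI$bands, 75L)
  expect_identical(panel$reference_patterns$A$SacI$bands, 120L)
  expect_identical(panel$reference_patterns$C$HinfI$bands, 120L)
  expect_identical(panel$reference_patterns$A$HinfI$bands, 89L)
})

test_that("panel selection verified against an exhaustive subset-search oracle", {
  reg <- tiny_registry()
  db <- enzyme_db(c("SacI", "HinfI", "EcoRI", "AluI"))
  panel <- select_diagnostic_enzymes(reg, db)
  # oracle: brute-force check that no single enzyme separates all pairs,
  # and that the returned panel does
  sep <- function(enzs) {
    pats <- lapply(c(A = "A", B = "B", C = "C"), function(cls) {
      id <- reg$class_index[[cls]][1]
      lapply(enzs, function(e)
        to_band_pattern(digest(reg$alleles[[id]]$sequence, e), 60)$bands)
    })
    prs <- combn(c("A", "B", "C"), 2, simplify = FALSE)
    all(vapply(prs, function(pr) {
      any(vapply(seq_along(enzs), function(i) {
        a <- pats[[pr[1]]][[i]]; b <- pats[[pr[2]]][[i]]
        length(a) != length(b) || any(abs(sort(a) - sort(b)) >= 20)
      }, logical(1)))
    }, logical(1)))
  }
  for (e in db) expect_false(sep(list(e)))
  expect_true(sep(panel$enzymes))
  expect_length(panel$enzymes, 2L)
})

test_that("identical classes yield a 'no diagnostic panel' error naming the pair", {
  seq <- paste(rep("ACGGTA", 20), collapse = "")
  reg <- allele_registry(list(allele("A1", "A", seq), allele("B1", "B", seq),
                              allele("C1", "C", paste0("GAGCTC", substr(seq, 7, 120)))))
  expect_error(select_diagnostic_enzymes(reg, enzyme_db(c("SacI", "HinfI"))),
               "A/B")
})

test_that("mixture patterns are unions, invisible to dosage", {
  reg <- tiny_registry()
  panel <- select_diagnostic_enzymes(reg, enzyme_db(c("SacI", "HinfI")))
  one <- predict_mixture_pattern("A", panel, "SacI")
  expect_identical(predict_mixture_pattern(c("A", "A", "A"), panel, "SacI")$bands,
                   one$bands)
  ab <- predict_mixture_pattern(c("A", "B"), panel, "SacI")
  expect_setequal(ab$bands, union(one$bands,
                                  predict_mixture_pattern("B", panel, "SacI")$bands))
  expect_gt(length(ab$bands), length(one$bands))
  abc <- predict_mixture_pattern(c("A", "B", "C"), panel, "HinfI")
  expect_setequal(abc$bands, c(89L, 120L))
  expect_error(predict_mixture_pattern("A", panel, "EcoRI"), "not in panel")
})

test_that("call_classes recovers pure patterns and flags unexplained bands", {
  reg <- tiny_registry()
  panel <- select_diagnostic_enzymes(reg, enzyme_db(c("SacI", "HinfI")))
  obs_a <- lapply(panel$enzymes, function(e) predict_mixture_pattern("A", panel, e))
  expect_identical(call_classes(obs_a, panel), "A")
  obs_ab <- lapply(panel$enzymes,
                   function(e) predict_mixture_pattern(c("A", "B"), panel, e))
  expect_identical(call_classes(obs_ab, panel), c("A", "B"))
  # a band absent from every prediction is uninterpretable
  obs_bad <- obs_a
  obs_bad$SacI <- band_pattern(c(obs_a$SacI$bands, 300))
  expect_error(call_classes(obs_bad, panel), "uninterpretable")
  # missing enzyme coverage
  expect_error(call_classes(obs_a["SacI"], panel), "missing")
})

test_that("gel tolerance merges nearby bands when calling", {
  reg <- tiny_registry()
  panel <- select_diagnostic_enzymes(reg, enzyme_db(c("SacI", "HinfI")))
  obs <- lapply(panel$enzymes, function(e) predict_mixture_pattern("B", panel, e))
  obs$SacI <- band_pattern(obs$SacI$bands + 3L)  # small gel drift
  expect_error(call_classes(obs, panel, tolerance_bp = 0), "uninterpretable")
  expect_identical(call_classes(obs, panel, tolerance_bp = 10L), "B")
})

test_that("fragment-length conservation holds on random sequences", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(50:1500, 1)
    s <- random_seq(n)
    expect_identical(sum(digest(s, hinfI)$fragments), n)
    expect_identical(sum(digest(s, sacI)$fragments), n)
  }
})
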