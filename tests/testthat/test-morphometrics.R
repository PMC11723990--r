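test_that("overwhelming group shifts give tiny adjusted p on either route", {
  set.seed(3)
  d <- data.frame(group = rep(c("G1", "G2", "G3"), each = 15),
                  y = rnorm(45) + rep(c(0, 5, 10), each = 15))
  cmp <- compare_groups(d, "y")
  expect_lt(cmp$omnibus_p, 1e-6)
  expect_true(all(cmp$pairwise_p < 0.001))
})

test_that("groups from one distribution keep the type-I rate near alpha", {
  set.seed(17)
  rejections <- vapply(1:400, function(i) {
    d <- data.frame(group = rep(c("a", "b"), each = 25), y = rnorm(50))
    compare_groups(d, "y")$omnibus_p < 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_gt(rate, 0.02)   # binomial 99% band around 0.05 at 400 reps
  expect_lt(rate, 0.09)
})

test_that("the gate routes normal homoscedastic data to ANOVA and skewed data to Kruskal-Wallis", {
  set.seed(9)
  d <- data.frame(group = rep(c("a", "b"), each = 30), y = rnorm(60))
  expect_identical(compare_groups(d, "y")$omnibus, "anova")
  d$y <- rexp(60)^2   # strongly non-normal
  cmp <- compare_groups(d, "y")
  expect_identical(cmp$omnibus, "kruskal_wallis")
  expect_identical(cmp$posthoc, "dunn_holm")
})

test_that("a group with fewer than two observations errors by name", {
  d <- data.frame(group = c("a", "a", "b"), y = 1:3)
  expect_error(compare_groups(d, "y"), "b")
})

test_that("Tukey HSD equals the studentized-range oracle on balanced toy data", {
  set.seed(2)
  k <- 3; n <- 5
  d <- data.frame(group = rep(paste0("g", 1:k), each = n),
                  y = rnorm(k * n) + rep(c(0, 0.5, 2), each = n))
  # force the parametric route by construction (normal, equal variance)
  cmp <- compare_groups(d, "y")
  expect_identical(cmp$posthoc, "tukey_hsd")
  # oracle: all-pairs studentized range p-values from first principles
  means <- tapply(d$y, d$group, mean)
  mse <- sum(unlist(tapply(d$y, d$group, function(v) (v - mean(v))^2))) / (k * n - k)
  for (pr in combn(names(means), 2, simplify = FALSE)) {
    q <- abs(means[pr[1]] - means[pr[2]]) / sqrt(mse / n)
    p_oracle <- ptukey(q, nmeans = k, df = k * n - k, lower.tail = FALSE)
    key <- paste(sort(pr, decreasing = TRUE), collapse = "-")
    got <- cmp$pairwise_p[grepl(pr[1], names(cmp$pairwise_p)) &
                            grepl(pr[2], names(cmp$pairwise_p))]
    expect_equal(unname(got), unname(p_oracle), tolerance = 1e-8)
  }
})

test_that("Dunn z reduces to the Kruskal-Wallis statistic for two groups", {
  set.seed(4)
  x <- c(rnorm(12), rnorm(15, 1))
  x[3] <- x[4]   # introduce a tie to exercise the correction
  g <- rep(c("a", "b"), c(12, 15))
  p <- dunn_test(x, g, adjust = "none")
  z <- qnorm(p / 2, lower.tail = FALSE)
  H <- kruskal.test(x, factor(g))$statistic
  expect_equal(unname(z^2), unname(H), tolerance = 1e-10)
})

test_that("Holm adjustment is monotone and never below the raw p", {
  set.seed(6)
  x <- rnorm(40) + rep(c(0, 0.3, 0.8, 1), each = 10)
  g <- rep(paste0("g", 1:4), each = 10)
  raw <- dunn_test(x, g, adjust = "none")
  holm <- dunn_test(x, g, adjust = "holm")
  expect_true(all(holm >= raw - 1e-12))
  ord <- order(raw)
  expect_true(all(diff(holm[ord]) >= -1e-12))
})

test_that("PCA retention in DAPC reaches the variance threshold with the smallest k", {
  d <- make_trait_table(n_per_group = 12, seed = 42)
  res <- dapc(d, cv = NULL)
  expect_gte(res$pc_variance_explained, 0.90)
  # removing one PC would fall below the threshold
  xs <- scale(as.matrix(d[, radicans:::DAPC_TRAITS]))
  cum <- cumsum(prcomp(xs)$sdev^2) / ncol(xs)
  if (res$n_pcs > 1) expect_lt(cum[res$n_pcs - 1], 0.90)
  # contributions are a simplex per discriminant
  expect_equal(unname(colSums(res$var_contrib)), rep(1, res$n_discriminants))
})

test_that("a 10-SD trait separation yields perfect CV accuracy and dominates LD1", {
  set.seed(8)
  d <- data.frame(group = rep(c("a", "b"), each = 15),
                  t1 = rnorm(30) + rep(c(0, 10), each = 15),
                  t2 = rnorm(30), t3 = rnorm(30))
  res <- dapc(d, traits = c("t1", "t2", "t3"), var_threshold = 0.9,
              cv = list(folds = 5, repeats = 3))
  expect_equal(max(res$cv_accuracy), 1)
  expect_identical(rownames(res$var_contrib)[which.max(res$var_contrib[, 1])],
                   "t1")
})

test_that("duplicated group labels give chance-level discrimination", {
  set.seed(10)
  d <- data.frame(t1 = rnorm(60), t2 = rnorm(60), t3 = rnorm(60))
  d$group <- rep(c("a", "b"), 30)   # same distribution, split at random
  res <- dapc(d, traits = c("t1", "t2", "t3"), cv = list(folds = 5, repeats = 5))
  expect_lt(max(res$cv_accuracy), 0.72)   # chance is 0.5
})

test_that("the involucre ratio flag is strict at 0.7", {
  expect_true(involucre_rule(0.85))
  expect_false(involucre_rule(0.53))
  expect_false(involucre_rule(0.70))
  expect_error(involucre_rule(-1))
})

test_that("trait CSV reader derives the involucre ratio", {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  d <- make_trait_table(n_per_group = 3, seed = 1)
  write.csv(d[, c("sample_id", "group", radicans:::TRAIT_NAMES)], tmp,
            row.names = FALSE)
  got <- read_trait_csv(tmp)
  expect_equal(got$IW_IL, d$IW / d$IL)
  write.csv(d[, 1:5], tmp, row.names = FALSE)
  expect_error(read_trait_csv(tmp), "missing")
})
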