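## Morphometric discrimination of genotype groups.
##
## Ten traits are measured per sample: rhizome diameter (RD, mm), stipe
## length (SL, mm), rachis length (RL, mm), maximum leaf blade width
## (LW, mm), maximum pinna length and width (PL, PW, mm), pinna number
## (PN), and involucre length and width (IL, IW, mm), with the derived
## involucre width-to-length ratio IW_IL. Univariate group comparisons
## use a gated test choice: Shapiro-Wilk normality per group and
## Brown-Forsythe (median-centered Levene) homogeneity decide between
## one-way ANOVA + Tukey HSD and Kruskal-Wallis + Dunn's test with Holm
## correction. Multivariate discrimination uses DAPC: unit-variance
## scaling, PCA retaining the smallest number of components reaching the
## variance threshold, then linear discriminant analysis on the retained
## scores.

TRAIT_NAMES <- c("RD", "SL", "RL", "LW", "PL", "PW", "PN", "IL", "IW")
DAPC_TRAITS <- c("RD", "SL", "RL", "LW", "PL", "PW", "PN", "IW_IL")

#' Read a morphology trait table
#'
#' @param path CSV with columns `sample_id`, `group` and the nine
#'   measured traits (RD, SL, RL, LW, PL, PW, PN, IL, IW).
#' @return data.frame with the derived `IW_IL` ratio appended.
#' @export
read_trait_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("sample_id", "group", TRAIT_NAMES), names(df))
  if (length(missing) > 0L) {
    stop("trait CSV missing column(s): ", paste(missing, collapse = ", "))
  }
  df$IW_IL <- df$IW / df$IL
  df
}

#' Gated univariate comparison of a trait across groups
#'
#' Per-group Shapiro-Wilk tests and a Brown-Forsythe homogeneity test at
#' `alpha` gate the analysis: if all groups are consistent with
#' normality and variances are homogeneous, a one-way ANOVA with Tukey
#' HSD post hoc is used; otherwise Kruskal-Wallis with Dunn's pairwise
#' z-tests and Holm adjustment. Groups with fewer than 3 observations
#' cannot be tested for normality and route to the nonparametric branch.
#'
#' @param data data.frame of trait measurements.
#' @param trait trait column name.
#' @param group grouping column name (default `"group"`).
#' @param alpha significance level of the gate tests (default 0.05).
#' @return a `group_comparison`: omnibus test name and p-value, post-hoc
#'   name, matrix-free pairwise adjusted p-values (named `"G1-G2"` etc.),
#'   and the gate diagnostics.
#' @export
compare_groups <- function(data, trait, group = "group", alpha = 0.05) {
  stopifnot(trait %in% names(data), group %in% names(data))
  x <- data[[trait]]
  g <- factor(data[[group]])
  keep <- stats::complete.cases(x, g)
  x <- x[keep]; g <- droplevels(g[keep])
  counts <- table(g)
  if (length(counts) < 2L) stop("need at least two groups")
  small <- names(counts)[counts < 2L]
  if (length(small) > 0L) {
    stop("group(s) with fewer than 2 observations: ",
         paste(small, collapse = ", "))
  }

  can_shapiro <- all(counts >= 3L)
  shapiro_p <- if (can_shapiro) {
    vapply(levels(g), function(lv) {
      xi <- x[g == lv]
      if (stats::sd(xi) == 0) 0 else stats::shapiro.test(xi)$p.value
    }, numeric(1))
  } else NULL
  levene_p <- car::leveneTest(x, g, center = stats::median)[1L, "Pr(>F)"]
  parametric <- can_shapiro && all(shapiro_p > alpha) && levene_p > alpha

  if (parametric) {
    fit <- stats::aov(x ~ g)
    omnibus_p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
    tk <- stats::TukeyHSD(fit)$g
    pairwise <- stats::setNames(tk[, "p adj"], rownames(tk))
    omnibus <- "anova"; posthoc <- "tukey_hsd"
  } else {
    omnibus_p <- stats::kruskal.test(x, g)$p.value
    pairwise <- dunn_test(x, g, adjust = "holm")
    omnibus <- "kruskal_wallis"; posthoc <- "dunn_holm"
  }
  structure(list(trait = trait, omnibus = omnibus, omnibus_p = omnibus_p,
                 posthoc = posthoc, pairwise_p = pairwise,
                 shapiro_p = shapiro_p, levene_p = levene_p,
                 alpha = alpha, group_n = as.integer(counts)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<%s: %s p = %.3g; %s pairwise:>\n", x$trait, x$omnibus,
              x$omnibus_p, x$posthoc))
  print(round(x$pairwise_p, 4))
  invisible(x)
}

#' Dunn's post-hoc test with tie correction
#'
#' Pairwise z-statistics on mean ranks following a Kruskal-Wallis test,
#' with the tie correction `sum(t^3 - t) / (12 (N - 1))` subtracted from
#' the rank variance, and multiplicity adjustment via [stats::p.adjust()].
#'
#' @param x numeric response.
#' @param g grouping factor.
#' @param adjust adjustment method (default `"holm"`).
#' @return named vector of adjusted pairwise p-values (`"A-B"` names).
#' @export
dunn_test <- function(x, g, adjust = "holm") {
  g <- factor(g)
  r <- rank(x)
  N <- length(x)
  tie_sizes <- table(x)
  tie_corr <- sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  v <- N * (N + 1) / 12 - tie_corr
  mean_ranks <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  prs <- utils::combn(levels(g), 2L, simplify = FALSE)
  p_raw <- vapply(prs, function(pr) {
    z <- (mean_ranks[[pr[1L]]] - mean_ranks[[pr[2L]]]) /
      sqrt(v * (1 / n[[pr[1L]]] + 1 / n[[pr[2L]]]))
    2 * stats::pnorm(-abs(z))
  }, numeric(1))
  names(p_raw) <- vapply(prs, paste, character(1), collapse = "-")
  stats::p.adjust(p_raw, method = adjust)
}

#' Discriminant analysis of principal components
#'
#' Traits are centered and scaled to unit variance, reduced by PCA to
#' the smallest number of components whose cumulative variance reaches
#' `var_threshold`, and the retained scores enter a linear discriminant
#' analysis with uniform group priors. The number of discriminants is
#' chosen by repeated stratified k-fold cross-validated assignment
#' accuracy (ties to the smaller count); original-variable contributions
#' per discriminant are the normalised absolute values of the
#' discriminant loadings back-projected through the PC rotation.
#'
#' @param data data.frame of trait measurements (complete cases used).
#' @param traits trait columns entering the analysis (default: the eight
#'   assay traits, IL and IW replaced by their ratio IW_IL).
#' @param group grouping column (default `"group"`).
#' @param var_threshold cumulative PC variance to retain (default 0.90).
#' @param cv list with `folds` and `repeats` for the discriminant-count
#'   cross-validation (default 5-fold, 30 repeats), or `NULL` to keep
#'   all `min(n_groups - 1, n_pcs)` discriminants without CV.
#' @param seed seed for the CV fold draws (default 1).
#' @return a `dapc_result`: `n_pcs`, `pc_variance_explained`,
#'   `n_discriminants`, `ld_scores`, `var_contrib` (traits x
#'   discriminants, columns sum to 1), `group`, and `cv_accuracy`.
#' @export
dapc <- function(data, traits = DAPC_TRAITS, group = "group",
                 var_threshold = 0.90, cv = list(folds = 5L, repeats = 30L),
                 seed = 1L) {
  stopifnot(all(traits %in% names(data)), group %in% names(data))
  keep <- stats::complete.cases(data[, c(traits, group)])
  x <- as.matrix(data[keep, traits])
  g <- droplevels(factor(data[[group]][keep]))
  if (nlevels(g) < 2L) stop("need at least two groups")

  fit <- dapc_fit(x, g, var_threshold)
  n_ld_max <- ncol(fit$lda$scaling)

  cv_acc <- NULL
  if (!is.null(cv)) {
    cv_acc <- dapc_cv(x, g, var_threshold, folds = cv$folds,
                      repeats = cv$repeats, n_ld_max = n_ld_max, seed = seed)
    n_ld <- as.integer(names(cv_acc)[which.max(cv_acc)])
  } else {
    n_ld <- n_ld_max
  }

  scaling <- fit$lda$scaling[, seq_len(n_ld), drop = FALSE]
  contrib_raw <- abs(fit$rotation %*% scaling)
  var_contrib <- sweep(contrib_raw, 2L, colSums(contrib_raw), "/")
  ld_scores <- fit$scores %*% scaling
  structure(list(n_pcs = fit$n_pcs,
                 pc_variance_explained = fit$cumvar,
                 n_discriminants = n_ld,
                 ld_scores = ld_scores,
                 var_contrib = var_contrib,
                 group = g,
                 cv_accuracy = cv_acc),
            class = "dapc_result")
}

## scale -> PCA -> LDA on retained scores; shared by fit and CV folds
dapc_fit <- function(x, g, var_threshold) {
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  if (any(scl == 0)) stop("constant trait column; cannot scale")
  xs <- scale(x, center = ctr, scale = scl)
  pca <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  cum <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
  n_pcs <- which(cum >= var_threshold)[1L]
  if (is.na(n_pcs)) n_pcs <- length(cum)
  scores <- pca$x[, seq_len(n_pcs), drop = FALSE]
  lda <- tryCatch(
    MASS::lda(scores, grouping = g,
              prior = rep(1 / nlevels(g), nlevels(g))),
    error = function(e) {
      stop("singular within-group covariance; retain fewer PCs (",
           conditionMessage(e), ")")
    })
  list(center = ctr, scale = scl, rotation = pca$rotation[, seq_len(n_pcs), drop = FALSE],
       n_pcs = n_pcs, cumvar = cum[n_pcs], scores = scores, lda = lda)
}

## repeated stratified k-fold CV accuracy per candidate discriminant count
dapc_cv <- function(x, g, var_threshold, folds, repeats, n_ld_max, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  acc <- matrix(0, nrow = repeats * folds, ncol = n_ld_max)
  row <- 0L
  for (rep_i in seq_len(repeats)) {
    fold_of <- integer(length(g))
    for (lv in levels(g)) {
      idx <- sample(which(g == lv))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
    for (f in seq_len(folds)) {
      test <- fold_of == f
      if (all(test) || length(unique(g[!test])) < nlevels(g)) next
      fit <- tryCatch(dapc_fit(x[!test, , drop = FALSE], droplevels(g[!test]),
                               var_threshold),
                      error = function(e) NULL)
      if (is.null(fit)) next
      xt <- scale(x[test, , drop = FALSE], center = fit$center, scale = fit$scale)
      st <- xt %*% fit$rotation
      row <- row + 1L
      for (d in seq_len(min(n_ld_max, ncol(fit$lda$scaling)))) {
        pred <- stats::predict(fit$lda, st, dimen = d)$class
        acc[row, d] <- mean(as.character(pred) == as.character(g[test]))
      }
    }
  }
  means <- colMeans(acc[seq_len(row), , drop = FALSE])
  stats::setNames(means, seq_len(n_ld_max))
}

#' @export
print.dapc_result <- function(x, ...) {
  cat(sprintf("<dapc: %d PCs (%.1f%% variance), %d discriminants>\n",
              x$n_pcs, 100 * x$pc_variance_explained, x$n_discriminants))
  top <- apply(x$var_contrib, 2L, function(v) rownames(x$var_contrib)[which.max(v)])
  for (d in seq_along(top)) {
    cat(sprintf("  LD%d top contributor: %s (%.2f)\n", d, top[d],
                max(x$var_contrib[, d])))
  }
  invisible(x)
}

#' Involucre width-to-length diagnostic flag
#'
#' An involucre ratio above 0.7 (strict) occurs only in *V. nipponica*
#' and flags the sample as consistent with that species.
#'
#' @param iw_il involucre width-to-length ratio(s), > 0.
#' @return logical vector: `TRUE` when the ratio exceeds 0.7.
#' @export
involucre_rule <- function(iw_il) {
  stopifnot(all(iw_il > 0))
  iw_il > 0.7
}
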