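#' Average replicate samples to tree-level trait values
#'
#' Replicate samples taken from the same tree and organ are arithmetic-mean
#' averaged so each tree contributes a single value per organ and trait,
#' avoiding pseudo-replication in all downstream inference.
#'
#' @param samples long-format data frame with columns `species`, `tree_id`,
#'   `organ`, `leaf_habit`, `trait`, `value` (rows with `NA` values are
#'   dropped).
#' @return Data frame of tree means with the same columns, one row per
#'   species x tree x organ x trait.
#' @export
aggregate_tree_means <- function(samples) {
  need <- c("species", "tree_id", "organ", "leaf_habit", "trait", "value")
  if (!all(need %in% names(samples)))
    stop("sample table needs columns: ", paste(need, collapse = ", "))
  samples <- samples[is.finite(samples$value), , drop = FALSE]
  out <- stats::aggregate(
    value ~ species + tree_id + organ + leaf_habit + trait,
    data = samples, FUN = mean)
  out[order(out$species, out$tree_id, out$organ, out$trait), , drop = FALSE]
}

#' Species means from tree means
#'
#' @param tree_means output of [aggregate_tree_means()].
#' @return Data frame with one row per species x organ x trait; the value is
#'   the mean of the tree means.
#' @export
species_means <- function(tree_means) {
  out <- stats::aggregate(value ~ species + organ + leaf_habit + trait,
                          data = tree_means, FUN = mean)
  out[order(out$species, out$organ, out$trait), , drop = FALSE]
}

#' Log10-transform selected traits of a trait table
#'
#' Right-skewed conductivities are log10-transformed before parametric
#' tests. The returned table carries a `transform_applied` column so results
#' can be labeled with the scale they were computed on.
#'
#' @param trait_table long-format table with `trait` and `value` columns.
#' @param traits names of traits to transform (default: the conductivities).
#' @return The table with transformed values and a `transform_applied`
#'   column (`"log10"` or `"none"`).
#' @export
transform_traits <- function(trait_table,
                             traits = c("KShydr", "KSpot", "KL")) {
  sel <- trait_table$trait %in% traits
  if (any(sel & trait_table$value <= 0, na.rm = TRUE))
    stop("log10 transform requested for non-positive values")
  trait_table$transform_applied <-
    ifelse(sel, "log10", "none")
  trait_table$value[sel] <- log10(trait_table$value[sel])
  trait_table
}

# two-level marginal-mean contrast from a one-factor linear model;
# 'a_minus_b' fixes the direction. Identical to the pooled-variance
# two-sample computation, which the test suite checks to 1e-10.
.two_level_contrast <- function(values, group, a, b) {
  keep <- is.finite(values) & group %in% c(a, b)
  values <- values[keep]
  group <- factor(group[keep], levels = c(a, b))
  n <- table(group)
  if (any(n < 2L))
    stop("each level needs at least two observations (got ",
         paste(n, collapse = "/"), " for ", a, "/", b, ")")
  fit <- stats::lm(values ~ group)
  est <- -unname(stats::coef(fit)[2L])           # a - b
  se <- sqrt(stats::vcov(fit)[2L, 2L])
  df <- stats::df.residual(fit)
  t_ratio <- est / se
  p <- 2 * stats::pt(abs(t_ratio), df, lower.tail = FALSE)
  structure(list(contrast = est, SE = se, df = df, t_ratio = t_ratio,
                 p_value = p, levels = c(a, b), n = as.integer(n)),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("Contrast (%s - %s): %.4g  SE %.4g  df %d  t %.3f  p %.4g\n",
              x$levels[1L], x$levels[2L], x$contrast, x$SE, x$df,
              x$t_ratio, x$p_value))
  invisible(x)
}

#' Leaf-habit contrast on species means
#'
#' Marginal-mean contrast deciduous minus evergreen from a one-factor
#' linear model fitted to angiosperm species means. Gymnosperm entries are
#' excluded. With 13 angiosperm species the residual df is 11.
#'
#' @param values species-mean trait values.
#' @param habit leaf habit per value: `"deciduous"`, `"evergreen"`
#'   (`"gymnosperm"` rows are dropped).
#' @return A `contrast_result` with elements `contrast`, `SE`, `df`,
#'   `t_ratio`, `p_value`.
#' @export
habit_contrast <- function(values, habit) {
  .two_level_contrast(values, habit, "deciduous", "evergreen")
}

#' Organ contrast on species means
#'
#' Marginal-mean contrast root minus branch from a one-factor linear model
#' on species means (both organs of a species enter as separate
#' observations). Missing cells simply reduce the residual df.
#'
#' @param values species-mean trait values.
#' @param organ organ per value: `"root"` or `"branch"`.
#' @return A `contrast_result`.
#' @export
organ_contrast <- function(values, organ) {
  .two_level_contrast(values, organ, "root", "branch")
}

#' Tukey all-pairs comparisons with a compact letter display
#'
#' All pairwise group comparisons using the studentized-range distribution
#' with the pooled error variance of a one-way fit (Tukey-Kramer for
#' unequal group sizes), summarized as a compact letter display built with
#' the insert-and-absorb algorithm: two groups share at least one letter
#' exactly when their adjusted p-value is >= `alpha`.
#'
#' @param values numeric observations.
#' @param groups group label per observation (>= 2 groups with >= 2 values
#'   each).
#' @param alpha significance level for the display.
#' @return An object of class `letter_display`: list with `letters` (named
#'   character vector, one letter string per group, ordered by group mean),
#'   `p_matrix` (Tukey-adjusted pairwise p-values) and `means`.
#' @examples
#' set.seed(1)
#' tukey_letters(c(rnorm(5), rnorm(5, 10), rnorm(5, 20)),
#'               rep(c("a1", "b1", "c1"), each = 5))
#' @export
tukey_letters <- function(values, groups, alpha = 0.05) {
  keep <- is.finite(values)
  values <- values[keep]
  groups <- factor(groups[keep])
  k <- nlevels(groups)
  if (k < 2L) stop("at least two groups are required")
  n <- tabulate(groups)
  if (any(n < 2L)) stop("every group needs at least two observations")
  if (any(tapply(values, groups, stats::var) == 0) &&
      stats::var(values) == 0)
    stop("degenerate zero-variance data")

  means <- tapply(values, groups, mean)
  df_err <- length(values) - k
  mse <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2))) / df_err
  if (mse <= 0) stop("pooled error variance is zero; letters are undefined")

  lev <- levels(groups)
  p_mat <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    se_pair <- sqrt(mse / 2 * (1 / n[i] + 1 / n[j]))
    q_obs <- abs(means[i] - means[j]) / se_pair
    p_mat[i, j] <- p_mat[j, i] <-
      stats::ptukey(q_obs, nmeans = k, df = df_err, lower.tail = FALSE)
  }

  distinct <- which(p_mat < alpha, arr.ind = TRUE)
  distinct <- distinct[distinct[, 1L] < distinct[, 2L], , drop = FALSE]
  letters_vec <- .insert_absorb(lev, distinct, order(means))
  structure(list(letters = letters_vec, p_matrix = p_mat,
                 means = means[order(means)], alpha = alpha),
            class = "letter_display")
}

# insert-and-absorb compact letter display. 'distinct' is a 2-column index
# matrix of significantly different pairs; 'mean_order' orders groups for
# letter assignment so 'a' goes to the smallest mean.
.insert_absorb <- function(lev, distinct, mean_order) {
  cols <- list(seq_along(lev))
  if (nrow(distinct)) {
    for (r in seq_len(nrow(distinct))) {
      i <- distinct[r, 1L]; j <- distinct[r, 2L]
      hit <- vapply(cols, function(cl) i %in% cl && j %in% cl, logical(1L))
      if (!any(hit)) next
      new_cols <- list()
      for (cl in cols[hit]) {
        new_cols <- c(new_cols, list(setdiff(cl, i)), list(setdiff(cl, j)))
      }
      cols <- c(cols[!hit], new_cols)
      # absorb columns that are subsets of another column
      keep <- rep(TRUE, length(cols))
      for (a in seq_along(cols)) for (b in seq_along(cols)) {
        if (a != b && keep[a] && keep[b] &&
            all(cols[[a]] %in% cols[[b]]) &&
            !(length(cols[[a]]) == length(cols[[b]]) && a < b)) {
          keep[a] <- FALSE
        }
      }
      cols <- cols[keep]
    }
  }
  # order columns by the first (smallest-mean) group they contain
  pos <- match(seq_along(lev), mean_order)
  col_rank <- vapply(cols, function(cl) min(pos[cl]), numeric(1L))
  cols <- cols[order(col_rank)]
  out <- vapply(seq_along(lev), function(g) {
    paste0(letters[which(vapply(cols, function(cl) g %in% cl, logical(1L)))],
           collapse = "")
  }, character(1L))
  names(out) <- lev
  out[mean_order]
}

#' @export
print.letter_display <- function(x, ...) {
  cat("Tukey compact letter display (alpha =", x$alpha, ")\n")
  df <- data.frame(mean = round(x$means, 4),
                   letters = x$letters[names(x$means)])
  print(df)
  invisible(x)
}

#' Pairwise Pearson correlations among species-level traits
#'
#' Pairwise-complete Pearson correlations between trait columns, with
#' two-sided t-test p-values and significance flags (`"*"` for p < 0.05,
#' `"(*)"` for p < 0.10). Cells with fewer than three complete pairs are
#' left `NA`.
#'
#' @param species_table data frame of species-wise trait means, one row per
#'   species; `traits` selects the numeric columns to correlate.
#' @param traits character vector of column names (default: all numeric
#'   columns).
#' @return An object of class `trait_correlations`: list of matrices `r`,
#'   `p`, `n` and `flag`.
#' @export
pearson_matrix <- function(species_table, traits = NULL) {
  if (is.null(traits))
    traits <- names(species_table)[vapply(species_table, is.numeric,
                                          logical(1L))]
  m <- length(traits)
  if (m < 2L) stop("at least two traits are required")
  r <- p <- matrix(NA_real_, m, m, dimnames = list(traits, traits))
  nmat <- matrix(0L, m, m, dimnames = list(traits, traits))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    x <- species_table[[traits[i]]]
    y <- species_table[[traits[j]]]
    ok <- is.finite(x) & is.finite(y)
    nmat[i, j] <- sum(ok)
    if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
    if (sum(ok) < 3L) next
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    r[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  flag <- matrix("", m, m, dimnames = list(traits, traits))
  flag[!is.na(p) & p < 0.10] <- "(*)"
  flag[!is.na(p) & p < 0.05] <- "*"
  diag(flag) <- ""
  structure(list(r = r, p = p, n = nmat, flag = flag),
            class = "trait_correlations")
}

#' @export
print.trait_correlations <- function(x, digits = 2, ...) {
  cat("Pairwise Pearson correlations (pairwise-complete species means)\n")
  print(round(x$r, digits))
  invisible(x)
}

#' Root-to-branch trait ratios
#'
#' Per-pair root/branch ratios matched by tree or species, and their mean.
#' The mean of the pairwise ratios is the reported statistic; it is not the
#' ratio of the group means. Pairs with a zero branch value are dropped
#' with a warning; pairs with a missing member are dropped silently.
#'
#' @param root,branch numeric vectors of matched root and branch values, in
#'   the same pair order (names, if present, must agree).
#' @return An object of class `rb_ratio`: list with `ratios`, `mean` and
#'   `n`.
#' @export
rb_ratio <- function(root, branch) {
  if (length(root) != length(branch))
    stop("'root' and 'branch' must be matched vectors of equal length")
  if (!is.null(names(root)) && !is.null(names(branch)) &&
      !identical(names(root), names(branch)))
    stop("pair names of 'root' and 'branch' disagree")
  ok <- is.finite(root) & is.finite(branch)
  zero <- ok & branch == 0
  if (any(zero)) {
    warning(sum(zero), " pair(s) with zero branch value dropped")
    ok <- ok & !zero
  }
  ratios <- root[ok] / branch[ok]
  structure(list(ratios = ratios, mean = mean(ratios), n = sum(ok)),
            class = "rb_ratio")
}

#' @export
print.rb_ratio <- function(x, ...) {
  cat(sprintf("Root-to-branch ratio: mean %.3f over %d pairs\n", x$mean, x$n))
  invisible(x)
}

#' Trait-height relationship with species as a random effect
#'
#' Fits a random-intercept model `value ~ height + (1 | species)` by
#' maximum likelihood and tests the height slope with a likelihood-ratio
#' test against the intercept-only model. When the random-effect variance
#' collapses to zero (singular fit) the model falls back to a pooled
#' ordinary regression with a warning.
#'
#' @param values trait values (one per tree).
#' @param heights tree heights, m.
#' @param species species label per tree.
#' @return List with `slope`, `slope_se`, `p_value`, `method`
#'   (`"lmm"` or `"pooled_lm"`) and the fitted model in `fit`.
#' @export
height_model <- function(values, heights, species) {
  ok <- is.finite(values) & is.finite(heights) & !is.na(species)
  d <- data.frame(value = values[ok], height = heights[ok],
                  species = factor(species[ok]))
  if (nlevels(d$species) < 2L)
    stop("at least two species are required")
  fit <- suppressMessages(
    lme4::lmer(value ~ height + (1 | species), data = d, REML = FALSE))
  if (lme4::isSingular(fit, tol = 1e-6)) {
    warning("random-intercept variance is zero; falling back to pooled ",
            "regression")
    pfit <- stats::lm(value ~ height, data = d)
    sm <- summary(pfit)$coefficients
    return(list(slope = sm["height", "Estimate"],
                slope_se = sm["height", "Std. Error"],
                p_value = sm["height", "Pr(>|t|)"],
                method = "pooled_lm", fit = pfit))
  }
  null_fit <- suppressMessages(
    lme4::lmer(value ~ 1 + (1 | species), data = d, REML = FALSE))
  lr <- 2 * (as.numeric(stats::logLik(fit)) -
             as.numeric(stats::logLik(null_fit)))
  p <- stats::pchisq(max(lr, 0), df = 1L, lower.tail = FALSE)
  co <- summary(fit)$coefficients
  list(slope = co["height", "Estimate"], slope_se = co["height", "Std. Error"],
       p_value = p, method = "lmm", fit = fit)
}
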