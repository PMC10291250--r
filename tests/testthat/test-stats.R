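test_that("tree-wise averaging removes pseudo-replication", {
  d <- data.frame(species = "sp", tree_id = "t1", organ = "root",
                  leaf_habit = "deciduous", trait = "Dh", value = c(8, 12))
  expect_equal(aggregate_tree_means(d)$value, 10)
  d1 <- d[1, ]
  expect_equal(aggregate_tree_means(d1)$value, 8)
  # brute-force group-by oracle on a seeded long table
  set.seed(81)
  big <- expand.grid(species = c("A", "B"), tree_id = paste0("t", 1:3),
                     organ = c("root", "branch"), trait = c("Dh", "WD"),
                     rep = 1:2, stringsAsFactors = FALSE)
  big$leaf_habit <- ifelse(big$species == "A", "deciduous", "evergreen")
  big$value <- rnorm(nrow(big), 10)
  got <- aggregate_tree_means(big)
  for (i in sample(nrow(got), 10)) {
    r <- got[i, ]
    manual <- mean(big$value[big$species == r$species &
                             big$tree_id == r$tree_id &
                             big$organ == r$organ & big$trait == r$trait])
    expect_equal(r$value, manual)
  }
  sp <- species_means(got)
  r <- sp[sp$species == "A" & sp$organ == "root" & sp$trait == "Dh", ]
  manual <- mean(got$value[got$species == "A" & got$organ == "root" &
                           got$trait == "Dh"])
  expect_equal(r$value, manual)
})

test_that("habit contrast equals the pooled two-sample computation", {
  dec <- c(10, 12, 14, 11, 13)
  ev <- c(8, 9, 10, 9, 9, 8, 10, 9)
  cr <- habit_contrast(c(dec, ev),
                       rep(c("deciduous", "evergreen"), c(5, 8)))
  expect_equal(cr$contrast, 3.0)
  expect_equal(cr$SE, 0.643, tolerance = 1e-3)
  expect_equal(cr$df, 11)
  expect_equal(cr$t_ratio, 4.665, tolerance = 1e-3)
  oracle <- pooled_t_oracle(dec, ev)
  expect_equal(cr$contrast, oracle$estimate, tolerance = 1e-12)
  expect_equal(cr$SE, oracle$se, tolerance = 1e-12)
  expect_equal(cr$p_value, oracle$p, tolerance = 1e-12)
  # identical groups: zero contrast, p = 1
  same <- c(4, 5, 6)
  cr0 <- habit_contrast(c(same, same),
                        rep(c("deciduous", "evergreen"), each = 3))
  expect_equal(cr0$contrast, 0)
  expect_equal(cr0$p_value, 1)
  expect_error(habit_contrast(1:5, c("deciduous", rep("evergreen", 4))),
               "at least two")
})

test_that("contrast operations match the pooled-t oracle to 1e-10", {
  set.seed(91)
  for (i in 1:40) {
    nx <- sample(2:10, 1); ny <- sample(2:10, 1)
    x <- rnorm(nx, 10, 2); y <- rnorm(ny, 8, 2)
    oracle <- pooled_t_oracle(x, y)
    hc <- habit_contrast(c(x, y), rep(c("deciduous", "evergreen"), c(nx, ny)))
    oc <- organ_contrast(c(x, y), rep(c("root", "branch"), c(nx, ny)))
    for (cr in list(hc, oc)) {
      expect_equal(cr$contrast, oracle$estimate, tolerance = 1e-10)
      expect_equal(cr$SE, oracle$se, tolerance = 1e-10)
      expect_equal(cr$df, oracle$df)
      expect_equal(cr$t_ratio, oracle$t, tolerance = 1e-10)
      expect_equal(cr$p_value, oracle$p, tolerance = 1e-10)
    }
  }
})

test_that("contrasts agree with the marginal-means machinery of emmeans", {
  set.seed(101)
  v <- rnorm(13, 10, 3)
  habit <- rep(c("deciduous", "evergreen"), c(5, 8))
  cr <- habit_contrast(v, habit)
  fit <- lm(v ~ habit)
  em <- emmeans::emmeans(fit, "habit")
  ct <- as.data.frame(emmeans::contrast(em, method = "pairwise"))
  expect_equal(cr$contrast, ct$estimate, tolerance = 1e-10)
  expect_equal(cr$SE, ct$SE, tolerance = 1e-10)
  expect_equal(cr$df, ct$df)
  expect_equal(cr$p_value, ct$p.value, tolerance = 1e-10)
})

test_that("organ contrast df bookkeeping follows the observation count", {
  set.seed(111)
  root <- rnorm(13, 60, 10); branch <- rnorm(13, 40, 8)
  full <- organ_contrast(c(root, branch),
                         rep(c("root", "branch"), each = 13))
  expect_equal(full$df, 24)
  # one missing root cell
  part <- organ_contrast(c(root[-1], branch),
                         rep(c("root", "branch"), c(12, 13)))
  expect_equal(part$df, 23)
  # equal organs give a zero contrast
  zero <- organ_contrast(c(root, root), rep(c("root", "branch"), each = 13))
  expect_equal(zero$contrast, 0)
})

test_that("Tukey p-values match TukeyHSD and letters separate cleanly", {
  set.seed(121)
  v <- c(rnorm(5, 0, 0.1), rnorm(5, 10, 0.1), rnorm(5, 20, 0.1))
  g <- rep(c("g1", "g2", "g3"), each = 5)
  ld <- tukey_letters(v, g)
  expect_equal(unname(ld$letters[c("g1", "g2", "g3")]), c("a", "b", "c"))
  # identical groups (same values, nonzero spread) share one letter
  same <- tukey_letters(rep(c(1, 2, 3), 3),
                        rep(c("a1", "a2", "a3"), each = 3))
  expect_true(all(same$letters == "a"))
  # pairwise p-values against the aov/TukeyHSD oracle, balanced + unbalanced
  for (i in 1:10) {
    k <- sample(3:5, 1)
    n <- sample(3:7, k, replace = TRUE)
    g <- rep(paste0("s", seq_len(k)), n)
    v <- rnorm(length(g), rep(runif(k, 0, 6), n))
    ld <- tukey_letters(v, g)
    hsd <- TukeyHSD(aov(v ~ factor(g)))[[1]]
    for (row in rownames(hsd)) {
      pair <- strsplit(row, "-", fixed = TRUE)[[1]]
      expect_equal(ld$p_matrix[pair[1], pair[2]], hsd[row, "p adj"],
                   tolerance = 1e-8)
    }
    # sharing a letter must coincide with p >= alpha, pair by pair
    share <- function(a, b) {
      la <- strsplit(ld$letters[[a]], "")[[1]]
      lb <- strsplit(ld$letters[[b]], "")[[1]]
      length(intersect(la, lb)) > 0
    }
    lev <- paste0("s", seq_len(k))
    for (a in seq_len(k - 1)) for (b in seq(a + 1, k)) {
      expect_equal(share(lev[a], lev[b]),
                   ld$p_matrix[lev[a], lev[b]] >= 0.05)
    }
  }
})

test_that("letter displays agree with multcomp and ignore input order", {
  set.seed(131)
  v <- rnorm(24, rep(c(0, 0.5, 4, 8), each = 6))
  g <- rep(c("w", "x", "y", "z"), each = 6)
  ld <- tukey_letters(v, g)
  fit <- aov(v ~ g, data = data.frame(v = v, g = factor(g)))
  cld <- multcomp::cld(multcomp::glht(fit, multcomp::mcp(g = "Tukey")))
  share_ours <- function(a, b)
    length(intersect(strsplit(ld$letters[[a]], "")[[1]],
                     strsplit(ld$letters[[b]], "")[[1]])) > 0
  share_ref <- function(a, b)
    length(intersect(strsplit(cld$mcletters$Letters[[a]], "")[[1]],
                     strsplit(cld$mcletters$Letters[[b]], "")[[1]])) > 0
  for (a in c("w", "x", "y")) for (b in setdiff(c("x", "y", "z"), a)) {
    expect_equal(share_ours(a, b), share_ref(a, b))
  }
  # permuting the observations leaves the sharing structure unchanged
  perm <- sample(length(v))
  ld2 <- tukey_letters(v[perm], g[perm])
  for (a in c("w", "x", "y")) for (b in setdiff(c("x", "y", "z"), a)) {
    share2 <- length(intersect(strsplit(ld2$letters[[a]], "")[[1]],
                               strsplit(ld2$letters[[b]], "")[[1]])) > 0
    expect_equal(share2, share_ours(a, b))
  }
})

test_that("Pearson matrix matches the textbook formula and flags gaps", {
  x <- c(1, 2, 3, 4, 5)
  tab <- data.frame(a = x, b = 2 * x, c = c(2, 1, 4, 3, 6))
  pm <- pearson_matrix(tab)
  expect_equal(pm$r["a", "b"], 1)
  r_manual <- sum((x - mean(x)) * (tab$c - mean(tab$c))) /
    sqrt(sum((x - mean(x))^2) * sum((tab$c - mean(tab$c))^2))
  expect_equal(pm$r["a", "c"], r_manual, tolerance = 1e-12)
  t_manual <- r_manual * sqrt(3) / sqrt(1 - r_manual^2)
  expect_equal(pm$p["a", "c"], 2 * pt(abs(t_manual), 3, lower.tail = FALSE),
               tolerance = 1e-12)
  # independent noise at n = 13 stays unflagged in expectation
  set.seed(141)
  flags <- replicate(30, {
    nn <- data.frame(u = rnorm(13), v = rnorm(13))
    pearson_matrix(nn)$p["u", "v"] < 0.05
  })
  expect_lt(mean(flags), 0.3)
  # fewer than three complete pairs leaves the cell unavailable
  gap <- data.frame(a = c(1, 2, NA, NA, NA), b = c(1, NA, 2, NA, NA))
  pmg <- pearson_matrix(gap)
  expect_true(is.na(pmg$r["a", "b"]))
})

test_that("root-to-branch ratios are means of pairwise ratios", {
  expect_equal(rb_ratio(9.5, 2.3)$mean, 9.5 / 2.3)
  expect_equal(rb_ratio(9.5, 2.3)$mean, 4.13, tolerance = 1e-2)
  expect_equal(rb_ratio(c(3, 4, 5), c(3, 4, 5))$mean, 1)
  expect_warning(rb <- rb_ratio(c(2, 4), c(1, 0)), "zero branch")
  expect_equal(rb$n, 1)
  # mean of ratios differs from ratio of means
  root <- c(10, 1); branch <- c(1, 10)
  expect_equal(rb_ratio(root, branch)$mean, (10 + 0.1) / 2)
  expect_false(isTRUE(all.equal(rb_ratio(root, branch)$mean,
                                mean(root) / mean(branch))))
  expect_error(rb_ratio(1:3, 1:2), "equal length")
})

test_that("height model reduces to pooled regression without species variance", {
  set.seed(155)
  h <- runif(40, 5, 20)
  sp <- rep(paste0("s", 1:8), each = 5)
  y <- 2 + 0.5 * h + rnorm(40, 0, 0.3)   # no species effect at all
  expect_warning(hm <- height_model(y, h, sp), "pooled")
  expect_equal(hm$method, "pooled_lm")
  expect_equal(hm$slope, unname(coef(lm(y ~ h))[2]), tolerance = 1e-6)
  # with a real species effect the slope is recovered within its CI
  b <- 0.8
  spe <- rnorm(8, 0, 2)[match(sp, paste0("s", 1:8))]
  y2 <- 1 + b * h + spe + rnorm(40, 0, 0.4)
  hm2 <- height_model(y2, h, sp)
  expect_equal(hm2$method, "lmm")
  expect_lt(abs(hm2$slope - b), 3 * hm2$slope_se)
  expect_lt(hm2$p_value, 0.05)
})
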