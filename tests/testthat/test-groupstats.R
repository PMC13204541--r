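test_that("pair enumeration counts n(n-1)/2 pairs in lexicographic order", {
  p36 <- enumerate_pairs(36)
  expect_equal(nrow(p36), 630L)
  expect_equal(nrow(enumerate_pairs(2)), 1L)
  expect_equal(nrow(enumerate_pairs(5)), 10L)
  expect_true(all(p36[, "i"] < p36[, "j"]))
  expect_true(all(diff(order(p36[, 1] * 100 + p36[, 2])) == 1))
  expect_error(enumerate_pairs(1), "at least 2")
})

test_that("the zero filter excludes pairs with strictly more than half zeros", {
  a <- zero_filter(c(0, 0, 0, 7))
  expect_equal(a$zero_fraction, 0.75)
  expect_false(a$included)
  b <- zero_filter(c(0, 0, 5, 7))  # exactly half: kept
  expect_equal(b$zero_fraction, 0.5)
  expect_true(b$included)
  expect_true(zero_filter(c(1, 2, 3))$included)
  expect_error(zero_filter(numeric(0)), "no observations")
})

test_that("log transform adds the pseudocount before the natural log", {
  expect_equal(log_pseudo(0), 0)
  expect_equal(log_pseudo(exp(1) - 1), 1)
  expect_equal(log_pseudo(c(0, 9)), c(0, log(10)))
  expect_error(log_pseudo(-1), "nonnegative")
})

test_that("pooled t matches the hand-computed example and stats::t.test", {
  tt <- pooled_ttest(c(0, 1, 2), c(3, 4, 5))
  expect_equal(tt$t, -3.674, tolerance = 1e-3)
  expect_equal(tt$df, 4)
  expect_equal(tt$p, 0.0213, tolerance = 1e-2)
  expect_equal(tt$sign, 1L)
  # independent oracle on random samples
  set.seed(31)
  for (i in 1:25) {
    wt <- rnorm(sample(3:9, 1))
    ko <- rnorm(sample(3:9, 1), mean = runif(1, -1, 1))
    mine <- pooled_ttest(wt, ko)
    ref <- t.test(wt, ko, var.equal = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    welch <- pooled_ttest(wt, ko, var_equal = FALSE)
    refw <- t.test(wt, ko)
    expect_equal(welch$t, unname(refw$statistic), tolerance = 1e-12)
    expect_equal(welch$df, unname(refw$parameter), tolerance = 1e-9)
  }
})

test_that("pooled t handles ties and degenerate variance explicitly", {
  same <- pooled_ttest(c(1, 2, 3), c(3, 2, 1))
  expect_equal(same$p, 1)
  expect_equal(same$sign, 0L)
  const_eq <- pooled_ttest(c(2, 2), c(2, 2))
  expect_equal(const_eq$p, 1)
  const_diff <- pooled_ttest(c(2, 2), c(5, 5))
  expect_true(const_diff$degenerate)
  expect_equal(const_diff$sign, 1L)
  expect_lt(const_diff$p, 1e-300)
  # label swap: t negated, p unchanged, sign flipped
  a <- pooled_ttest(c(0, 1, 2), c(3, 4, 5))
  b <- pooled_ttest(c(3, 4, 5), c(0, 1, 2))
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  expect_equal(a$sign, -b$sign)
})

test_that("BH adjustment reproduces the step-up by hand and by reference", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04))$p_adj, rep(0.04, 4))
  expect_equal(bh_adjust(0.05)$p_adj, 0.05)
  expect_equal(bh_adjust(numeric(0))$p_adj, numeric(0))
  set.seed(32)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    mine <- bh_adjust(p)
    expect_equal(mine$p_adj, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(mine$p_adj >= p))           # inflation
    expect_true(all(mine$p_adj <= 1))
    expect_equal(mine$discovery, mine$p_adj <= 0.05)
  }
})

test_that("edgewise comparison produces a symmetric signed matrix with NA where filtered", {
  cfg <- sim_config(n_wt = 4L, n_ko = 5L, n_regions = 12L, zero_prob = 0.4,
                    seed = 41L)
  co <- simulate_cohort(cfg)
  ew <- edgewise_compare(co, "whole")
  sp <- ew$signed_p
  expect_equal(sp, t(sp))
  expect_true(all(is.na(diag(sp))))
  excl <- ew$edges[!ew$edges$included, ]
  expect_true(all(is.na(excl$t)))
  expect_true(all(is.na(excl$p_adj)))
  for (r in seq_len(min(5, nrow(excl)))) {
    expect_true(is.na(sp[excl$region_a[r], excl$region_b[r]]))
  }
  incl <- ew$edges[ew$edges$included, ]
  expect_true(all(abs(incl$signed_p) <= 1))
  expect_true(all(incl$df == 4 + 5 - 2))
  # bins partition |p_adj| < 0.05
  expect_true(all(incl$bin[abs(incl$p_adj) < 0.01] == "dark"))
  expect_true(all(incl$bin[incl$p_adj >= 0.01 & incl$p_adj < 0.05] == "light"))
  expect_true(all(incl$bin[incl$p_adj >= 0.05] == "none"))
})

test_that("the edgewise pipeline is invariant to animal ordering", {
  cfg <- sim_config(n_wt = 4L, n_ko = 4L, n_regions = 10L, seed = 42L)
  co <- simulate_cohort(cfg)
  co2 <- co
  set.seed(1)
  co2$connectomes <- co2$connectomes[sample(length(co2$connectomes))]
  a <- edgewise_compare(co, "whole")
  b <- edgewise_compare(co2, "whole")
  expect_equal(a$edges, b$edges, tolerance = 1e-12)
  expect_equal(a$signed_p, b$signed_p, tolerance = 1e-12)
})

test_that("a strongly planted edge is discovered with positive sign in most seeds", {
  n_seeds <- 20L
  hits <- 0L
  for (seed in seq_len(n_seeds)) {
    cfg <- sim_config(n_wt = 8L, n_ko = 12L, n_regions = 36L,
                      planted_edges = list(list(pair = c(2L, 9L),
                                                effect = 6)),
                      seed = seed)
    co <- simulate_cohort(cfg)
    ew <- edgewise_compare(co, "whole")
    row <- ew$edges[ew$edges$pair == paste(rownames(co$connectomes[[1]]$counts)[3],
                                           rownames(co$connectomes[[1]]$counts)[10],
                                           sep = "~"), ]
    if (isTRUE(row$discovery) && row$sign == 1L) hits <- hits + 1L
  }
  expect_gte(hits, round(0.75 * n_seeds))
})

test_that("hemisphere modes select the documented blocks", {
  tab <- tiny_region_table(3L)
  base <- labelled_counts(tab)
  make_conn <- function(lval, rval, cval, id, grp) {
    m <- base
    m["LS01", "LS02"] <- m["LS02", "LS01"] <- lval
    m["RS01", "RS02"] <- m["RS02", "RS01"] <- rval
    m["LS01", "RS02"] <- m["RS02", "LS01"] <- cval
    connectome(m, animal_id = id, group = grp)
  }
  co <- structure(list(connectomes = list(
    make_conn(10, 20, 5, "w1", "WT"), make_conn(12, 22, 6, "w2", "WT"),
    make_conn(30, 40, 7, "k1", "KO"), make_conn(32, 42, 8, "k2", "KO")),
    diffusivity = NULL, config = NULL), class = "cohort_study")
  ipsi <- edgewise_compare(co, "ipsilateral", table = tab)
  row <- ipsi$edges[ipsi$edges$pair == "S01~S02", ]
  # ipsilateral value is the mean of the L-L and R-R entries
  expect_true(row$included)
  expect_equal(row$zero_fraction, 0)
  contra <- edgewise_compare(co, "contralateral", table = tab)
  crow <- contra$edges[contra$edges$pair == "S01~S02", ]
  expect_true(crow$included)  # counts L1-R2 + L2-R1 per animal
})

test_that("region streamline totals are row sums and respond to planted effects", {
  cfg <- sim_config(n_wt = 3L, n_ko = 3L, n_regions = 8L, seed = 51L)
  co <- simulate_cohort(cfg)
  totals <- rowSums(co$connectomes[[1]]$counts)
  res <- region_streamline_compare(co)
  expect_equal(nrow(res), 8L)
  expect_equal(res$mean_wt[1],
               mean(vapply(co$connectomes[1:3],
                           function(c) rowSums(c$counts)[1], numeric(1))))
  # planting a x2 effect on every edge of one region flags that region
  hits <- 0L
  n_seeds <- 15L
  for (seed in seq_len(n_seeds)) {
    planted <- lapply(setdiff(0:35, 4L),
                      function(j) list(pair = c(4L, j), effect = 2))
    cfgp <- sim_config(n_wt = 8L, n_ko = 12L, n_regions = 36L,
                       planted_edges = planted, seed = seed)
    cop <- simulate_cohort(cfgp)
    rs <- region_streamline_compare(cop)
    if (isTRUE(rs$discovery[5]) && rs$sign[5] == 1L) hits <- hits + 1L
  }
  expect_gte(hits, round(0.9 * n_seeds))
})

test_that("network parameter comparison handles identity, swaps and NA metrics", {
  metrics <- data.frame(
    group = rep(c("WT", "KO"), each = 4),
    density = c(1, 2, 3, 4, 1, 2, 3, 4),
    sigma = c(rnorm(4, 1), rnorm(4, 3)),
    broken = NA_real_)
  res <- compare_network_params(metrics)
  expect_equal(res$p[res$metric == "density"], 1)
  expect_false(res$testable[res$metric == "broken"])
  expect_equal(res$n_dropped[res$metric == "broken"], 8L)
  swapped <- metrics
  swapped$group <- ifelse(metrics$group == "WT", "KO", "WT")
  res2 <- compare_network_params(swapped)
  ok <- res$testable
  expect_equal(res$p[ok], res2$p[ok], tolerance = 1e-12)
  expect_equal(res$sign[ok], -res2$sign[ok])
})

test_that("groups with planted density differences separate on the density metric", {
  # KO cohorts generated with much sparser topology than WT
  dens <- function(cfg) {
    co <- simulate_cohort(cfg)
    vapply(co$connectomes, function(c) {
      net_density(threshold_weights(normalize_weights(c$counts), 0.001))
    }, numeric(1))
  }
  hits <- 0L
  for (seed in 1:5) {
    wt_cfg <- sim_config(n_wt = 8L, n_ko = 1L, n_regions = 20L,
                         zero_prob = 0.1, seed = seed)
    ko_cfg <- sim_config(n_wt = 1L, n_ko = 12L, n_regions = 20L,
                         zero_prob = 0.5, seed = seed + 100L)
    d_wt <- dens(wt_cfg)[1:8]
    d_ko <- dens(ko_cfg)[2:13]
    metrics <- data.frame(group = rep(c("WT", "KO"), c(8, 12)),
                          density = c(d_wt, d_ko))
    res <- compare_network_params(metrics)
    if (res$p[1] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("an all-filtered cohort raises the no-testable-pairs error", {
  tab <- tiny_region_table(3L)
  zero <- labelled_counts(tab)
  co <- structure(list(connectomes = list(
    connectome(zero, "w1", "WT"), connectome(zero, "w2", "WT"),
    connectome(zero, "k1", "KO"), connectome(zero, "k2", "KO")),
    diffusivity = NULL, config = NULL), class = "cohort_study")
  expect_error(edgewise_compare(co, "whole"), "no testable pairs")
})
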