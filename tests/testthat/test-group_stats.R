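test_that("two-way ANOVA matches the brute-force cell-sum oracle", {
  set.seed(9)
  tissue <- rep(c("cardiac", "skeletal"), each = 40)
  age <- rep(rep(c(6, 12, 17, 24), each = 10), 2)
  v <- rnorm(80) + 0.5 * (tissue == "cardiac") + 0.02 * age
  tab <- two_way_anova(v, tissue, age)
  ora <- brute_anova(v, tissue, age)
  expect_equal(tab$sum_sq, ora$sum_sq, tolerance = 1e-8)
  expect_equal(tab$df, ora$df)
  expect_equal(tab$F[1:3], ora$F[1:3], tolerance = 1e-8)
  expect_equal(tab$p[1:3], ora$p[1:3], tolerance = 1e-8)
  expect_equal(sum(tab$df), 79)
})

test_that("balanced and Type-II paths agree on balanced data", {
  set.seed(10)
  tissue <- rep(c("cardiac", "skeletal"), each = 20)
  age <- rep(rep(c(6, 12, 17, 24), each = 5), 2)
  v <- rnorm(40)
  bal <- two_way_anova(v, tissue, age)
  a2 <- car::Anova(stats::lm(v ~ tissue * age,
                             data = data.frame(v, tissue = factor(tissue),
                                               age = factor(age)),
                             contrasts = list(tissue = "contr.sum",
                                              age = "contr.sum")),
                   type = 2)
  expect_equal(bal$sum_sq[1:3],
               a2[c("tissue", "age", "tissue:age"), "Sum Sq"],
               tolerance = 1e-8)
})

test_that("interaction sum of squares matches the closed form on a 2x2", {
  n <- 6
  delta <- 2
  tissue <- rep(c("a", "b"), each = 2 * n)
  age <- rep(rep(c("x", "y"), each = n), 2)
  mu <- ifelse(tissue == "b" & age == "y", delta, 0)
  set.seed(11)
  v <- mu + rnorm(length(mu), sd = 1e-6)
  # near-perfect fit: the F-test warning is expected, only the SS matters
  tab <- suppressWarnings(two_way_anova(v, tissue, age))
  expect_equal(tab$sum_sq[tab$effect == "tissue:age"], n * delta^2 / 4,
               tolerance = 1e-3)
})

test_that("ANOVA rejects degenerate designs", {
  expect_error(two_way_anova(rep(1, 16), rep(c("a", "b"), 8),
                             rep(c("x", "y"), each = 8)), "variance")
  expect_error(two_way_anova(rnorm(8), rep("a", 8),
                             rep(c("x", "y"), 4)), "2 levels")
  tissue <- c("a", "a", "b", "b", "a", "a")
  age <- c("x", "x", "x", "x", "y", "y")
  expect_error(two_way_anova(rnorm(6), tissue, age), "empty design cell")
})

test_that("Sidak adjustment is the exact closed form", {
  expect_equal(sidak_adjust(0, 5), 0)
  expect_equal(sidak_adjust(1, 5), 1)
  expect_lt(abs(sidak_adjust(0.01, 6) - (1 - 0.99^6)), 1e-15)
  expect_lt(abs(sidak_adjust(0.01, 6) - 0.0585198505), 1e-9)
  expect_equal(sidak_adjust(c(0.2, 0.7), 1), c(0.2, 0.7))
  set.seed(2)
  p <- runif(10)
  expect_true(all(sidak_adjust(p, 4) >= p))
  expect_error(sidak_adjust(1.2, 3), "\\[0, 1\\]")
})

test_that("age-wise tissue contrasts behave under null and strong effects", {
  set.seed(12)
  tissue <- rep(c("cardiac", "skeletal"), each = 40)
  age <- rep(rep(c(6, 12, 17, 24), each = 10), 2)
  # identical cell means: nothing significant, sidak_p >= raw_p
  v0 <- rnorm(80, sd = 0.5)
  c0 <- pairwise_cells(v0, tissue, age)
  expect_equal(nrow(c0), 4)
  expect_true(all(c0$sidak_p >= c0$raw_p))
  expect_true(all(!c0$significant))
  # large tissue offset at every age: all four comparisons extreme
  v1 <- v0 + 10 * (tissue == "cardiac")
  c1 <- pairwise_cells(v1, tissue, age)
  expect_true(all(c1$significant))
  expect_true(all(c1$sidak_p < 1e-4))
  expect_true(all(c1$stars == "****"))
})

test_that("panel statistics run per index on animal-level values", {
  cfg <- small_config(seed = 13)
  set <- generate_cohort(cfg)
  regions <- list(lipid = preprocess_region(set, "lipid", sg = sg_params(7)),
                  amide = preprocess_region(set, "amide", sg = sg_params(7)),
                  fingerprint = preprocess_region(set, "fingerprint",
                                                  sg = sg_params(7)))
  panel <- compute_panel(regions)
  st <- panel_stats(panel)
  expect_named(st, c("anova", "comparisons"))
  expect_equal(length(st$anova), 9)
  tab <- st$anova$glucose
  # animal-level rows: 2 tissues x 4 ages x n_bio animals
  expect_equal(sum(tab$df) + 1, 2 * 4 * cfg$n_bio)
})
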