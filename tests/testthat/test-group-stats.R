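test_that("Mann-Whitney U handles identity, antisymmetry and the small-sample oracle", {
  # identical multisets: U = n^2 / 2, Z = 0, p = 1
  r <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 9 / 2)
  expect_equal(r$z_value, 0)
  expect_equal(r$p_value, 1)
  # the {1,2} vs {3,4,5} textbook case: U(x) = 0, exact p = 0.2
  r <- mann_whitney_u(c(1, 2), c(3, 4, 5))
  expect_equal(r$statistic, 0)
  expect_lt(r$z_value, 0)  # x ranks lower
  ex <- mwu_exact_p(c(1, 2), c(3, 4, 5))
  expect_equal(ex$U, 0)
  expect_equal(ex$p, 0.2)
  # swapping the samples flips Z, keeps p
  set.seed(30)
  x <- rnorm(12); y <- rnorm(15, 0.5)
  a <- mann_whitney_u(x, y)
  b <- mann_whitney_u(y, x)
  expect_equal(a$z_value, -b$z_value, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_error(mann_whitney_u(numeric(0), numeric(0)), "non-empty")
})

test_that("Mann-Whitney normal approximation matches the base-R reference", {
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(10 + i)
    y <- rnorm(14, 0.3)
    # introduce ties in half the cases
    if (i %% 2 == 0) {
      x <- round(x, 1)
      y <- round(y, 1)
    }
    ours <- mann_whitney_u(x, y)
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
    )
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("U statistic agrees with pair counting and p is monotone in |Z|", {
  set.seed(32)
  for (rep in 1:10) {
    nx <- sample(2:5, 1)
    ny <- sample(2:5, 1)
    x <- rnorm(nx)
    y <- rnorm(ny)
    # independent oracle: U counts pairs with x > y
    U_pairs <- sum(outer(x, y, ">"))
    r <- mann_whitney_u(x, y)
    expect_equal(r$statistic, U_pairs)
    expect_equal(mwu_exact_p(x, y)$U, U_pairs)
  }
  # exact p decreases as |Z| increases across possible U values
  x0 <- 1:4
  y0 <- 5:10 + 0.5
  combos <- utils::combn(10, 4)
  vals <- rank(c(x0, y0))
  mu <- 4 * 6 / 2
  # for every achievable |U - mu|, exact p must be non-increasing in |Z|
  res <- lapply(0:24, function(u) NULL)
  zs <- c(); ps <- c()
  pool <- c(x0, y0)
  for (j in seq_len(ncol(combos))) {
    xi <- pool[combos[, j]]
    yi <- pool[-combos[, j]]
    zs <- c(zs, abs(mann_whitney_u(xi, yi)$z_value))
    ps <- c(ps, mwu_exact_p(xi, yi)$p)
  }
  ord <- order(zs)
  expect_true(all(diff(ps[ord]) <= 1e-12))
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(33)
  x <- rexp(14)
  y <- rexp(18) * 1.4
  z <- rexp(9)
  f <- function(v) log(v + 1) * 3 - 2
  a <- mann_whitney_u(x, y)
  b <- mann_whitney_u(f(x), f(y))
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  ka <- kruskal_wallis(list(x, y, z))
  kb <- kruskal_wallis(list(f(x), f(y), f(z)))
  expect_equal(ka$statistic, kb$statistic, tolerance = 1e-12)
})

test_that("Kruskal-Wallis matches the base-R reference and the k = 2 identity", {
  set.seed(34)
  for (i in 1:5) {
    g1 <- rnorm(8); g2 <- rnorm(10, 0.4); g3 <- rnorm(7, -0.2)
    if (i %% 2 == 0) { g1 <- round(g1); g2 <- round(g2); g3 <- round(g3) }
    ours <- kruskal_wallis(list(g1, g2, g3))
    ref <- stats::kruskal.test(list(g1, g2, g3))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
  # two groups without ties: H equals the squared MWU Z
  for (i in 1:10) {
    x <- rnorm(6 + i); y <- rnorm(9)
    H <- kruskal_wallis(list(x, y))$statistic
    Z <- mann_whitney_u(x, y)$z_value
    expect_equal(H, Z^2, tolerance = 1e-9)
  }
  # all values identical: declared convention H = 0, p = 1
  r <- kruskal_wallis(list(rep(2, 5), rep(2, 6)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_error(kruskal_wallis(list(rnorm(5))), "two groups")
  expect_error(kruskal_wallis(list(1, 2)), "n >= 3")
})

test_that("Kruskal-Wallis holds its nominal level on a continuous null", {
  set.seed(35)
  ps <- replicate(1000, {
    kruskal_wallis(list(rnorm(30), rnorm(30), rnorm(30)))$p_value
  })
  expect_gt(mean(ps < 0.05), 0.03)
  expect_lt(mean(ps < 0.05), 0.07)
})

test_that("KS screen accepts normal samples and flags skewed ones", {
  set.seed(36)
  # normal draws: the (conservative) screen should rarely reject
  accept <- replicate(60, ks_normality(rnorm(2000))$p_value > 0.05)
  expect_gte(mean(accept), 0.94)
  # strongly skewed samples are detected essentially always
  reject <- replicate(40, ks_normality(exp(rnorm(500)))$p_value < 0.05)
  expect_gte(mean(reject), 0.95)
  expect_error(ks_normality(rep(1, 10)), "constant")
  expect_error(ks_normality(c(1, 2)), "n >= 5")
})

test_that("summaries report mean and SEM with missing-value bookkeeping", {
  tbl <- tibble::tibble(g = c("a", "a", "a", "b", "b"),
                        v = c(1, 2, 3, 10, NA))
  s <- summarize_features(tbl, v, g)
  expect_equal(s$mean[s$g == "a"], 2)
  expect_equal(s$sem[s$g == "a"], 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(s$n[s$g == "b"], 1)
  expect_equal(s$n_missing[s$g == "b"], 1)
  expect_true(is.na(s$sem[s$g == "b"]))  # single value: SEM undefined
  # doubling the data doubles mean and SEM
  s2 <- summarize_features(dplyr::mutate(tbl, v = 2 * v), v, g)
  expect_equal(s2$mean[s2$g == "a"], 2 * s$mean[s$g == "a"])
  expect_equal(s2$sem[s2$g == "a"], 2 * s$sem[s$g == "a"], tolerance = 1e-12)
})

test_that("demographics of the patient table reproduce the published summary", {
  tab <- pdoc_demographics()
  expect_equal(nrow(tab), 18)
  s <- demographic_summary(tab)
  expect_equal(s$mean_age, 47.83)
  expect_equal(s$sd_age, 12.88)
  expect_equal(unname(s$counts["VS"]), 14L)
  expect_equal(unname(s$counts["MCS"]), 4L)
  expect_equal(s$duration_min, 1.7)
  expect_equal(s$duration_max, 25.2)
  expect_error(demographic_summary(tab[0, ]), "empty")
})

test_that("the comparison grid covers the study design and labels its mode", {
  sched <- build_paradigm(run_order = "fixed")
  hbs <- list()
  schedules <- list()
  for (g in c("HC", "MCS", "VS")) {
    set.seed(match(g, c("HC", "MCS", "VS")) + 40)
    ns <- silent_noise(); ns$white <- 0.2
    sim <- simulate_hb(sched, default_profiles()[default_profiles()$group == g, ], ns)
    sim$hb$subject_id <- g
    sim$hb$group <- g
    hbs[[g]] <- preprocess_recording(forward_mbll(sim$hb))
    schedules[[g]] <- sched
  }
  ft <- build_feature_table(hbs, schedules)
  res <- run_comparisons(ft, mode = "per-epoch")
  # 2 features x 2 chromophores x (2 within + 2 two-group + 2 three-group)
  expect_equal(nrow(res), 24)
  expect_equal(sum(res$test == "MWU"), 16)
  expect_equal(sum(res$test == "KW"), 8)
  expect_true(all(res$mode == "per-epoch"))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  # an empty cell (no MCS rows) drops only the three-group contrasts, with warnings
  ft2 <- ft[ft$group != "MCS", ]
  w <- testthat::capture_warnings(res2 <- run_comparisons(ft2))
  expect_true(all(grepl("empty cell", w)))
  expect_equal(sum(res2$test == "KW"), 0)
  expect_equal(sum(res2$test == "MWU"), 16)
})
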