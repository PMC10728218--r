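# Effect sizes, rank tests, contingency statistics and topology comparison.

test_that("Mann-Whitney U matches brute-force pair counting", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u, 0)                      # complete separation, x below y
  expect_equal(mann_whitney_u(c(1, 3), c(2, 4))$u, 1)
  x <- c(1, 2, 3)
  same <- mann_whitney_u(x, x)
  expect_gt(same$p_value, 0.9)
  set.seed(1)
  for (i in 1:100) {
    x <- sample(1:20, sample(3:12, 1), replace = TRUE)
    y <- sample(1:20, sample(3:12, 1), replace = TRUE)
    expect_equal(mann_whitney_u(x, y)$u, oracle_pairs(x, y)$u)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("Cliff's delta matches enumeration, is antisymmetric and bounded", {
  expect_equal(cliffs_delta(c(10, 11), c(1, 2)), 1)
  expect_equal(cliffs_delta(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cliffs_delta(c(1, 2), c(1, 3)), -0.25)
  set.seed(2)
  for (i in 1:100) {
    x <- sample(1:15, sample(2:30, 1), replace = TRUE)
    y <- sample(1:15, sample(2:30, 1), replace = TRUE)
    d <- cliffs_delta(x, y)
    expect_equal(d, oracle_pairs(x, y)$delta)
    expect_equal(d, -cliffs_delta(y, x))
    expect_lte(abs(d), 1)
  }
})

test_that("delta sign is consistent with U above/below its null mean (no ties)", {
  set.seed(3)
  for (i in 1:30) {
    x <- rnorm(8); y <- rnorm(9)           # continuous: no ties
    d <- cliffs_delta(x, y)
    u <- mann_whitney_u(x, y)$u
    null_mean <- length(x) * length(y) / 2
    if (d != 0) expect_equal(d > 0, u > null_mean)
  }
})

test_that("Cohen's d reproduces printed clinical-table effect sizes", {
  expect_equal(round(cohens_d(42.95, 18.09, 22, 39.29, 16.12, 24), 3), 0.214)
  expect_equal(round(cohens_d(27.50, 16.58, 22, 23.00, 12.13, 24), 3), 0.312)
  expect_equal(cohens_d(5, 1, 10, 5, 1, 10), 0)
  expect_error(cohens_d(1, 0, 5, 1, 0, 5), "pooled")
})

test_that("Cramer's V reproduces printed values and its invariances", {
  sex <- matrix(c(12, 14, 10, 10), 2)       # rows SF/NSF, cols male/female
  expect_equal(round(cramers_v(sex), 3), 0.038)
  ied <- matrix(c(5, 11, 17, 13), 2)        # IED present/absent by group
  expect_equal(round(cramers_v(ied), 3), 0.242)
  expect_equal(cramers_v(matrix(c(10, 0, 0, 10), 2)), 1)
  # swap-invariance and independence -> 0
  expect_equal(cramers_v(sex), cramers_v(sex[2:1, ]))
  expect_equal(cramers_v(sex), cramers_v(t(sex)))
  indep <- outer(c(10, 20), c(3, 7)) / 10   # proportional to margins
  expect_equal(cramers_v(indep * 10), 0, tolerance = 1e-12)
})

test_that("chi-square (no continuity correction) and Fisher agree with oracles", {
  sex <- matrix(c(12, 14, 10, 10), 2)
  cs <- chi_square_test(sex)
  expect_equal(round(cs$p_value, 2), 0.80)  # printed two-decimal agreement
  expect_equal(cs$statistic, 0.067, tolerance = 1e-2)
  indep <- outer(c(10, 20), c(3, 7))
  expect_equal(chi_square_test(indep)$statistic, 0, tolerance = 1e-12)
  set.seed(4)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 8), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_test(tab)$p_value, oracle_fisher(tab),
                 tolerance = 1e-8)
  }
  expect_equal(fisher_exact_test(matrix(c(2, 0, 20, 24), 2))$p_value,
               oracle_fisher(matrix(c(2, 0, 20, 24), 2)), tolerance = 1e-8)
  expect_error(fisher_exact_test(matrix(1:6, 2)), "2x2")
  expect_error(cramers_v(matrix(c(0, 0, 0, 0), 2)), "positive")
})

test_that("topology maps average channels within a group", {
  feats <- tibble::tibble(
    subject_id = c("a", "b", "c"),
    label = c("SF", "SF", "NSF"),
    Fp1_kurtosis = c(1, 3, 5), Cz_kurtosis = c(2, 4, 6),
    Fp1_max = c(0, 0, 1), Cz_max = c(1, 1, 2))
  m_sf <- topology_map(feats, "kurtosis", "SF")
  expect_equal(m_sf$channel, c("Fp1", "Cz"))
  expect_equal(m_sf$value, c(2, 3))
  m_nsf <- topology_map(feats, "kurtosis", "NSF")
  expect_equal(m_nsf$value, c(5, 6))        # single subject: its own values
  # two subjects with values v and -v -> zero map
  f2 <- tibble::tibble(subject_id = c("a", "b"), label = c("SF", "SF"),
                       Fp1_max = c(2, -2), Cz_max = c(-1, 1))
  expect_equal(topology_map(f2, "max", "SF")$value, c(0, 0))
  expect_error(topology_map(feats, "nope", "SF"), "nope")
  expect_error(topology_map(feats, "kurtosis", "XX"), "XX")
})

test_that("cosine similarity / Euclidean distance identities", {
  a <- tibble::tibble(channel = paste0("c", 1:21),
                      value = c(1, rep(0, 20)))
  b <- tibble::tibble(channel = paste0("c", 1:21),
                      value = c(0, 1, rep(0, 19)))
  same <- compare_topologies(a, a)
  expect_equal(same$cosine_similarity, 1)
  expect_equal(same$euclidean_distance, 0)
  orth <- compare_topologies(a, b)
  expect_equal(orth$cosine_similarity, 0)
  expect_equal(orth$euclidean_distance, sqrt(2))
  neg <- a; neg$value <- -a$value
  opp <- compare_topologies(a, neg)
  expect_equal(opp$cosine_similarity, -1)
  expect_equal(opp$euclidean_distance, 2 * sqrt(sum(a$value^2)))
  zero <- a; zero$value <- rep(0, 21)
  expect_error(compare_topologies(a, zero), "zero-norm")
})

test_that("feature-wise group stats run over a wide table", {
  set.seed(5)
  feats <- tibble::tibble(
    subject_id = paste0("s", 1:10),
    label = rep(c("SF", "NSF"), each = 5),
    Fp1_kurtosis = c(rnorm(5), rnorm(5, 3)),
    Cz_kurtosis = rnorm(10))
  st <- feature_group_stats(feats)
  expect_equal(nrow(st), 2)
  expect_lt(st$p_value[st$feature == "Fp1_kurtosis"],
            st$p_value[st$feature == "Cz_kurtosis"])
  expect_lt(st$cliffs_delta[1], 0)          # SF below NSF
})
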