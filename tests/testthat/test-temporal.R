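# Sidak correction, the seriation permutation test, the stability screen,
# and LDA-space trajectories.

test_that("sidak_alpha matches the printed and derived values", {
  expect_equal(signif(sidak_alpha(15, 0.05), 4), 0.003414)
  expect_equal(sidak_alpha(1, 0.05), 0.05)
  expect_equal(sidak_alpha(2, 0.05), 1 - sqrt(0.95), tolerance = 1e-12)
  expect_equal(sidak_alpha(2, 0.05), 0.0253206, tolerance = 1e-5)
  # inversion identity and monotonicity
  for (m in c(1, 5, 15, 100))
    expect_equal(1 - (1 - sidak_alpha(m, 0.05))^m, 0.05, tolerance = 1e-12)
  a <- vapply(1:30, sidak_alpha, numeric(1), fwer = 0.05)
  expect_true(all(diff(a) < 0))
  expect_error(sidak_alpha(0, 0.05), "positive integer")
  expect_error(sidak_alpha(5, 1.2), "in \\(0, 1\\)")
})

test_that("seriation statistic agrees with vegan's spearman Mantel", {
  skip_if_not_installed("vegan")
  set.seed(10)
  X <- matrix(rnorm(12 * 6), 12)
  st <- seriation_test(X, n_permutations = 99, seed = 1)
  td <- dist(seq_len(12))
  mt <- vegan::mantel(dist(X), td, method = "spearman", permutations = 0)
  expect_equal(st$statistic, unname(mt$statistic), tolerance = 1e-12)
})

test_that("seriation test is deterministic and detects planted drift", {
  set.seed(11)
  X <- matrix(rnorm(10 * 4), 10)
  s1 <- seriation_test(X, n_permutations = 199, seed = 42)
  s2 <- seriation_test(X, n_permutations = 199, seed = 42)
  expect_identical(s1$p_value, s2$p_value)
  expect_identical(s1$statistic, s2$statistic)
  # strong monotone drift along one feature
  Xd <- cbind(seq_len(12) * 1.0, matrix(rnorm(12 * 3, 0, 0.1), 12))
  sd_ <- seriation_test(Xd, n_permutations = 999, seed = 1)
  expect_lt(sd_$p_value, 0.003414)
  expect_gt(sd_$statistic, 0.8)
  # dates argument reorders rows
  perm <- sample(12)
  s3 <- seriation_test(Xd[perm, ], dates = perm, n_permutations = 999, seed = 1)
  expect_identical(s3$p_value, sd_$p_value)
})

test_that("seriation edge cases: constant vectors, too few images", {
  expect_error(seriation_test(matrix(1, 2, 3)), "at least 3")
  expect_warning(r <- seriation_test(matrix(1, 5, 3)), "identical")
  expect_equal(r$p_value, 1)
})

test_that("seriation statistic is invariant to feature-space rotation", {
  set.seed(12)
  X <- matrix(rnorm(9 * 5), 9)
  Q <- qr.Q(qr(matrix(rnorm(25), 5)))
  s1 <- seriation_test(X, n_permutations = 99, seed = 3)
  s2 <- seriation_test(X %*% Q, n_permutations = 99, seed = 3)
  expect_equal(s1$statistic, s2$statistic, tolerance = 1e-9)
  expect_equal(s1$p_value, s2$p_value)
})

test_that("permutation p-values are valid under the null", {
  # quick calibration; the full 1000-replicate band check lives in the
  # acceptance suite
  set.seed(13)
  ps <- replicate(200, {
    X <- matrix(rnorm(8 * 4), 8)
    seriation_test(X, n_permutations = 99, seed = sample.int(1e6, 1))$p_value
  })
  for (t in c(0.05, 0.1, 0.2))
    expect_lte(mean(ps <= t), t + 2.576 * sqrt(t * (1 - t) / 200))
})

test_that("stability_screen selects by span then count and sets alpha", {
  set.seed(14)
  mk <- function(id, dates) {
    n <- length(dates)
    data.frame(image_id = paste0(id, seq_len(n)), individual_id = id,
               date = dates, matrix(rnorm(n * 4), n,
                                    dimnames = list(NULL, paste0("f", 1:4))),
               check.names = FALSE)
  }
  feats <- rbind(
    mk("long", as.Date("2002-01-01") + c(0, 500, 3000)),
    mk("dense", as.Date("2004-01-01") + c(0, 100, 200, 300, 900)),
    mk("short", as.Date("2005-01-01") + c(0, 30, 60)),
    mk("two", as.Date("2003-01-01") + c(0, 10))  # ineligible (< 3)
  )
  expect_warning(rep_ <- stability_screen(feats, top_n = 15, fwer = 0.05,
                                          n_permutations = 99, seed = 5),
                 "eligible")
  expect_equal(rep_$m, 3L)
  expect_equal(rep_$table$individual_id, c("long", "dense", "short"))
  expect_equal(rep_$alpha_sidak, sidak_alpha(3, 0.05))
  expect_true(all(rep_$table$reject == (rep_$table$p_value < rep_$alpha_sidak)))

  # with 15 eligible individuals alpha is the study's 0.003414
  feats15 <- do.call(rbind, lapply(1:15, function(k)
    mk(sprintf("id%02d", k), as.Date("2002-01-01") + k * c(0, 200, 400, 800))))
  rep15 <- stability_screen(feats15, top_n = 15, n_permutations = 99, seed = 1)
  expect_equal(signif(rep15$alpha_sidak, 4), 0.003414)
})

test_that("lda_trajectory: 2 classes give one axis; output is deterministic", {
  set.seed(15)
  X <- rbind(matrix(rnorm(10 * 3), 10), matrix(rnorm(10 * 3, 4), 10))
  y <- rep(c("a", "b"), each = 10)
  d <- as.Date("2010-01-01") + seq_len(20)
  t1 <- lda_trajectory(X, y, d)
  expect_true(all(t1$axis2 == 0))
  t2 <- lda_trajectory(X, y, d)
  expect_identical(t1, t2)
  # axis1 separates the classes
  expect_gt(abs(mean(t1$axis1[t1$individual_id == "a"]) -
                  mean(t1$axis1[t1$individual_id == "b"])), 2)
})

test_that("stable identities show no monotone ordering along LDA axes", {
  set.seed(16)
  K <- 5; n_per <- 8
  mu <- matrix(rnorm(K * 6, sd = 5), K)
  X <- mu[rep(1:K, each = n_per), ] + matrix(rnorm(K * n_per * 6), K * n_per)
  y <- rep(sprintf("i%d", 1:K), each = n_per)
  d <- as.Date("2005-06-01") + rep(seq(0, 700, length.out = n_per), K)
  tr <- lda_trajectory(X, y, d)
  rho <- vapply(split(tr, tr$individual_id), function(s)
    abs(cor(as.numeric(s$date), s$axis1, method = "spearman")), numeric(1))
  expect_lt(mean(rho), 0.5)
})
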