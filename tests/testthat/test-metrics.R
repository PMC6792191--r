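test_that("AUC hits its anchors and the brute-force pair count", {
  # perfectly separating predictor
  y <- c(rep(1, 4), rep(0, 6))
  r <- c(runif(4, 0.8, 1), runif(6, 0, 0.5))
  expect_identical(auc(r, y)$estimate, 1.0)
  # constant predictor: all ties
  expect_identical(auc(rep(0.3, 10), y)$estimate, 0.5)
  # 4 cases / 6 controls fixture with ties vs explicit 24-pair enumeration
  set.seed(7)
  r2 <- sample(seq(0.1, 0.9, by = 0.1), 10, replace = TRUE)
  expect_equal(auc(r2, y)$estimate, brute_auc(r2, y))
  # larger fixture
  set.seed(8)
  y3 <- rbinom(150, 1, 0.4)
  r3 <- round(runif(150), 2)
  expect_equal(auc(r3, y3)$estimate, brute_auc(r3, y3))
  expect_error(auc(r, rep(1, 10)), "case")
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(9)
  y <- rbinom(80, 1, 0.3)
  r <- runif(80)
  a <- auc(r, y)$estimate
  expect_equal(auc(qlogis(r), y)$estimate, a)
  expect_equal(auc(r^3, y)$estimate, a)
  expect_equal(auc(rank(r), y)$estimate, a)
})

test_that("DeLong variance matches an independent placement-value oracle", {
  set.seed(10)
  y <- rbinom(20, 1, 0.45)
  r <- runif(20)
  got <- auc_ci(r, y)
  expect_equal(got$variance, delong_var_oracle(r, y), tolerance = 1e-10)
  expect_true(got$interval[1] <= got$estimate &&
                got$estimate <= got$interval[2])

  skip_if_not_installed("pROC")
  roc <- pROC::roc(y, r, quiet = TRUE, direction = "<")
  expect_equal(got$variance, as.numeric(pROC::var(roc)), tolerance = 1e-10)
  expect_equal(got$estimate, as.numeric(pROC::auc(roc)))
})

test_that("paired AUC difference handles identity and matches pROC's DeLong", {
  set.seed(11)
  y <- rbinom(60, 1, 0.4)
  r <- runif(60)
  same <- auc_diff_ci(r, r, y)
  expect_identical(same$estimate, 0)
  expect_equal(same$interval, c(0, 0))

  r2 <- plogis(qlogis(r) + rnorm(60, 0, 0.5))
  d <- auc_diff_ci(r, r2, y)
  skip_if_not_installed("pROC")
  rt <- pROC::roc.test(pROC::roc(y, r, quiet = TRUE, direction = "<"),
                       pROC::roc(y, r2, quiet = TRUE, direction = "<"),
                       method = "delong", paired = TRUE)
  # reconstruct pROC's variance of the difference from its z statistic
  est <- as.numeric(rt$estimate[1] - rt$estimate[2])
  expect_equal(d$estimate, est)
  expect_equal(sqrt(d$variance), abs(est / as.numeric(rt$statistic)),
               tolerance = 1e-10)
})

test_that("analytic AUC intervals achieve near-nominal coverage", {
  # model risks from a known logistic truth; true AUC approximated once by
  # a large independent draw, then 300 analytic CIs checked for coverage
  set.seed(12)
  big_x <- rnorm(2e5)
  big_y <- rbinom(2e5, 1, plogis(-1 + big_x))
  true_auc <- auc(big_x, big_y)$estimate
  hits <- 0L
  reps <- 300L
  for (i in seq_len(reps)) {
    x <- rnorm(250)
    y <- rbinom(250, 1, plogis(-1 + x))
    if (length(unique(y)) < 2L) next
    ci <- auc_ci(x, y)$interval
    if (ci[1] <= true_auc && true_auc <= ci[2]) hits <- hits + 1L
  }
  # binomial(300, 0.95) 3-sigma band
  expect_gt(hits / reps, 0.95 - 3 * sqrt(0.95 * 0.05 / reps))
})

test_that("Hosmer-Lemeshow is zero under exact calibration and matches oracle", {
  # groups built so the observed count equals the expected count exactly
  risks <- rep(seq(0.05, 0.95, by = 0.1), each = 20)
  outcomes <- unlist(lapply(seq(0.05, 0.95, by = 0.1), function(p) {
    k <- round(20 * p)
    c(rep(1, k), rep(0, 20 - k))
  }))
  expect_equal(hosmer_lemeshow(risks, outcomes)$estimate, 0)

  # 30-row fixture against the naive decile-loop oracle
  set.seed(13)
  r <- runif(30, 0.05, 0.9)
  y <- rbinom(30, 1, r)
  got <- hosmer_lemeshow(r, y)
  expect_equal(got$estimate, hl_oracle(r, y), tolerance = 1e-12)
  expect_gte(got$estimate, 0)
  expect_equal(got$df, 8L)
  expect_equal(sum(got$groups$n), 30)

  # a larger fixture, and the risk-scale variant agrees with its formula
  set.seed(14)
  r2 <- runif(500, 0.02, 0.95)
  y2 <- rbinom(500, 1, r2)
  expect_equal(hosmer_lemeshow(r2, y2)$estimate, hl_oracle(r2, y2),
               tolerance = 1e-12)
  alt <- hosmer_lemeshow(r2, y2, form = "risk")
  tab <- alt$groups
  expect_equal(alt$estimate,
               sum((tab$observed / tab$n - tab$expected / tab$n)^2 /
                     (tab$expected / tab$n)))
  expect_gte(alt$estimate, 0)
})

test_that("tied risks stay in one group and degenerate cases error", {
  r <- c(rep(0.2, 55), seq(0.3, 0.75, by = 0.01))
  y <- rbinom(length(r), 1, r)
  set.seed(15)
  got <- hosmer_lemeshow(r, rbinom(length(r), 1, r))
  expect_true(all(got$groups$n > 0))
  # the tied mass at 0.2 occupies a single group
  expect_equal(sum(got$groups$n > 50), 1L)
  expect_error(hosmer_lemeshow(rep(0.4, 100), rbinom(100, 1, 0.4)),
               "identical")
  expect_error(hosmer_lemeshow(runif(5), c(0, 1, 0, 1, 0)), "at least")
})

test_that("net benefit matches hand computation and closed forms", {
  # hand fixture: 20 rows, threshold 0.15
  risks <- c(0.30, 0.10, 0.20, 0.05, 0.16, 0.40, 0.14, 0.80, 0.12, 0.15,
             0.22, 0.08, 0.55, 0.13, 0.18, 0.02, 0.35, 0.09, 0.17, 0.11)
  y <-     c(1,    0,    1,    0,    0,    1,    1,    1,    0,    0,
             0,    0,    1,    0,    1,    0,    0,    0,    1,    0)
  # positives: risks >= 0.15 -> rows 1,3,5,6,8,10,11,13,15,17,19
  # TP = y=1 among them = {1,3,6,8,13,15,19} = 7; FP = 4
  nb <- net_benefit(risks, y, 0.15)
  expect_equal(nb$tp, 7)
  expect_equal(nb$fp, 4)
  expect_equal(nb$estimate, 7 / 20 - (4 / 20) * (0.15 / 0.85))
  expect_equal(nb$nb_all, mean(y) - (1 - mean(y)) * 0.15 / 0.85)

  # treat-all limit: all risks above a vanishing threshold
  nb2 <- net_benefit(rep(0.9, 20), y, threshold = 1e-6)
  expect_equal(nb2$nb_delta_all, 0)
  # treat-none: every risk below the threshold
  expect_equal(net_benefit(rep(0.01, 20), y, 0.5)$estimate, 0)
  # at t = prevalence the treat-all benchmark is exactly zero
  expect_equal(net_benefit(risks, y, threshold = mean(y))$nb_all, 0)
})

test_that("net benefit never exceeds the prevalence", {
  set.seed(16)
  for (i in 1:20) {
    y <- rbinom(100, 1, 0.35)
    r <- runif(100)
    t <- runif(1, 0.05, 0.9)
    expect_lte(net_benefit(r, y, t)$estimate, mean(y))
  }
})

test_that("bootstrap percentile intervals are deterministic and sane", {
  set.seed(17)
  y <- rbinom(200, 1, 0.3)
  r <- plogis(qlogis(0.3) + rnorm(200))
  f <- function(risks, outcomes) net_benefit(risks, outcomes, 0.15)$estimate
  b1 <- bootstrap_percentile(f, r, y, B = 300L, seed = 123L)
  b2 <- bootstrap_percentile(f, r, y, B = 300L, seed = 123L)
  expect_identical(b1$interval, b2$interval)
  expect_identical(b1$replicates, b2$replicates)
  expect_true(b1$interval[1] <= b1$estimate & b1$estimate <= b1$interval[2])

  # degenerate metric collapses the interval to a point
  const <- bootstrap_percentile(function(r, y) 0.42, r, y, B = 50L, seed = 1L)
  expect_equal(const$interval, c(0.42, 0.42))

  # interval width shrinks roughly like 1/sqrt(n)
  mkdata <- function(n, seed) {
    set.seed(seed)
    y <- rbinom(n, 1, 0.3)
    list(y = y, r = plogis(qlogis(0.3) + rnorm(n)))
  }
  d200 <- mkdata(200, 18)
  d800 <- mkdata(800, 19)
  w200 <- diff(bootstrap_percentile(f, d200$r, d200$y, B = 400L, seed = 2L)$interval)
  w800 <- diff(bootstrap_percentile(f, d800$r, d800$y, B = 400L, seed = 2L)$interval)
  expect_lt(w800, w200)
  expect_equal(w800 / w200, 0.5, tolerance = 0.5)

  expect_error(bootstrap_percentile(f, r, y, B = 100L), "seed")
})
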