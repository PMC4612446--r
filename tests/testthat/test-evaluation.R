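make_tbl <- function(P = 5, seed = 1, effect = 0.5) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(P), function(p) {
    data.frame(participant = sprintf("p%02d", p), trial = 1:10,
               cs_type = rep(c("CS+", "CS-"), 5),
               reinforced = c(TRUE, rep(FALSE, 9)),
               sa = rnorm(10, ifelse(rep(c(TRUE, FALSE), 5), effect, 0),
                          0.4))
  }))
}

test_that("reinforced CS+ trials are excluded, everything else kept", {
  des <- make_design(40, reinforced = rep(c(TRUE, FALSE, FALSE, FALSE), 10))
  est <- data.frame(trial = 1:40, cs_type = des$trials$cs_type,
                    reinforced = des$trials$reinforced)
  kept <- exclude_reinforced(est, des)
  expect_equal(nrow(kept), 30)
  expect_false(any(kept$reinforced))

  none <- est; none$reinforced <- FALSE
  expect_identical(exclude_reinforced(none), none)

  allplus <- est
  allplus$reinforced <- allplus$cs_type == "CS+"
  expect_warning(out <- exclude_reinforced(allplus), "no CS\\+")
  expect_true(all(out$cs_type == "CS-"))
})

test_that("z-standardisation gives mean 0, SD 1 per participant", {
  tbl <- data.frame(participant = "a", sa = c(1, 3))
  expect_equal(z_standardise(tbl)$sa, c(-1, 1) / sqrt(2))

  big <- make_tbl(6, seed = 8)
  z <- z_standardise(big)
  for (p in unique(z$participant)) {
    expect_equal(mean(z$sa[z$participant == p]), 0, tolerance = 1e-12)
    expect_equal(sd(z$sa[z$participant == p]), 1, tolerance = 1e-12)
  }
  expect_error(z_standardise(data.frame(participant = "a", sa = c(2, 2))),
               "zero variance")
})

test_that("the CS-type regression matches a normal-equations oracle", {
  for (seed in 1:5) {
    cm <- sa_cell_means(make_tbl(5, seed = seed))
    res <- predictive_validity(cm)
    # explicit design-matrix solve: participant dummies plus the SA column
    X <- cbind(model.matrix(~ 0 + factor(participant), cm), cm$sa)
    y <- as.numeric(cm$cs_type == "CS+")
    beta <- solve(t(X) %*% X, t(X) %*% y)
    r <- y - X %*% beta
    rss <- sum(r^2)
    expect_equal(res$rss, rss, tolerance = 1e-9)
    expect_equal(res$nll, res$n * log(rss / res$n), tolerance = 1e-12)
    s2 <- rss / (nrow(X) - ncol(X))
    se <- sqrt(s2 * solve(t(X) %*% X)[ncol(X), ncol(X)])
    expect_equal(res$t, as.numeric(beta[ncol(X)] / se), tolerance = 1e-9)
    expect_equal(res$df, nrow(X) - ncol(X))
  }
})

test_that("the regression t equals the textbook paired t", {
  cm <- sa_cell_means(make_tbl(8, seed = 3))
  res <- predictive_validity(cm)
  wide <- reshape(cm, idvar = "participant", timevar = "cs_type",
                  direction = "wide")
  d <- wide$`sa.CS+` - wide$`sa.CS-`
  t_paired <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res$t, t_paired, tolerance = 1e-9)
  expect_equal(res$df, length(d) - 1)
})

test_that("identical cell means across CS types give zero signal", {
  cm <- data.frame(participant = rep(sprintf("p%d", 1:4), each = 2),
                   cs_type = rep(c("CS+", "CS-"), 4),
                   sa = rep(c(1.2, 0.4, 2.2, 0.9), each = 2))
  res <- predictive_validity(cm)
  expect_equal(res$t, 0)
  expect_equal(res$coef, 0)
})

test_that("rescaling and shifting the estimates changes nothing", {
  cm <- sa_cell_means(make_tbl(6, seed = 11))
  base <- predictive_validity(cm)
  cm2 <- cm; cm2$sa <- cm2$sa * 1000
  cm3 <- cm; cm3$sa <- cm3$sa + 42
  scaled <- predictive_validity(cm2)
  shifted <- predictive_validity(cm3)
  expect_equal(scaled$nll, base$nll, tolerance = 1e-9)
  expect_equal(scaled$t, base$t, tolerance = 1e-9)
  expect_equal(shifted$nll, base$nll, tolerance = 1e-9)
  expect_equal(shifted$t, base$t, tolerance = 1e-9)
})

test_that("participants with a missing cell are dropped with a warning", {
  cm <- sa_cell_means(make_tbl(5, seed = 2))
  cm <- cm[-1, ]
  expect_warning(res <- predictive_validity(cm), "missing")
  expect_equal(res$participants, 4)
  expect_error(suppressWarnings(predictive_validity(cm[1:5, ])),
               "at least 3")
})

test_that("log Bayes factors difference NLLs with the stated conventions", {
  cm <- sa_cell_means(make_tbl(20, seed = 5))  # n = 40 regression rows
  a <- predictive_validity(cm)
  expect_equal(as.numeric(log_bayes_factor(a, a)), 0)

  # halving the RSS at fixed n = 40 gives 40 * log(1/2)
  b <- a; b$rss <- a$rss / 2; b$nll <- b$n * log(b$rss / b$n)
  expect_equal(as.numeric(log_bayes_factor(b, a)), 40 * log(0.5),
               tolerance = 1e-9)
  expect_equal(40 * log(0.5), -27.73, tolerance = 0.01)

  # antisymmetry and decisiveness flag
  expect_equal(as.numeric(log_bayes_factor(a, b)),
               -as.numeric(log_bayes_factor(b, a)))
  expect_true(attr(log_bayes_factor(b, a), "decisive"))

  bad <- a; bad$n <- 10
  expect_error(log_bayes_factor(bad, a), "row counts")
})

test_that("comparison reports mirror the standard table layout", {
  cm <- sa_cell_means(make_tbl(6, seed = 9))
  a <- predictive_validity(cm)
  cmz <- sa_cell_means(z_standardise(make_tbl(6, seed = 9)))
  b <- predictive_validity(cmz)
  rep <- comparison_report(list(default = a, z = b))
  expect_equal(names(rep), c("model", "nll", "t", "df", "lbf", "decisive"))
  expect_equal(rep$lbf[1], 0)
})
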