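# Small crossed-design generator used across these tests: outcome =
# intercept + beta * x + participant intercept + image intercept + noise.
sim_crossed <- function(n_part, n_img, beta = 0, sd_p = 5, sd_i = 5,
                        sd_e = 10, x = NULL, per_row_x = FALSE) {
  d <- expand.grid(participant_id = sprintf("p%02d", seq_len(n_part)),
                   image_id = sprintf("i%02d", seq_len(n_img)),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (per_row_x) d$x <- rnorm(nrow(d))
  else d$x <- (x %||% runif(n_img, 0, 50))[match(d$image_id,
                                                 unique(d$image_id))]
  bp <- rnorm(n_part, 0, sd_p)
  bi <- rnorm(n_img, 0, sd_i)
  d$y <- 10 + beta * d$x + bp[match(d$participant_id,
                                    unique(d$participant_id))] +
    bi[match(d$image_id, unique(d$image_id))] + rnorm(nrow(d), 0, sd_e)
  d
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("a known slope is recovered with crossed random intercepts", {
  set.seed(61)
  d <- sim_crossed(30, 40, beta = 0.4)
  fit <- fit_mixed_model(model_spec("y", fixed = "x"), d)
  est <- fit$coefficients[fit$coefficients$term == "x", ]
  expect_lt(abs(est$estimate - 0.4), 3 * est$se)
  expect_true(est$p < 0.001)
  # both variance components present and positive
  expect_true(all(fit$varcomp$random > 0))
  expect_equal(sort(names(fit$varcomp$random)),
               c("image_id", "participant_id"))
})

test_that("AIC identity and R2 ordering hold on every fit", {
  set.seed(62)
  d <- sim_crossed(15, 15, beta = 0.3)
  for (fx in list(character(), "x")) {
    fit <- fit_mixed_model(model_spec("y", fixed = fx), d)
    expect_equal(fit$aic, 2 * fit$npar - 2 * fit$logLik, tolerance = 1e-12)
    expect_equal(fit$aic, AIC(fit$fit), tolerance = 1e-8)
    r2 <- r2_nakagawa(fit)
    expect_gte(r2$marginal_r2, 0)
    expect_lte(r2$marginal_r2, r2$conditional_r2)
    expect_lte(r2$conditional_r2, 1)
  }
})

test_that("R2 follows the variance-component arithmetic", {
  r2 <- r2_components(1, c(participant = 1, image = 0), 2)
  expect_equal(r2$marginal_r2, 0.25)
  expect_equal(r2$conditional_r2, 0.5)
  expect_error(r2_components(0, c(0, 0), 0), "zero total variance")

  # no random variance -> marginal equals conditional
  set.seed(63)
  d <- sim_crossed(12, 12, beta = 0.5, sd_p = 0, sd_i = 0, sd_e = 5)
  fit <- fit_mixed_model(model_spec("y", fixed = "x"), d)
  r2f <- r2_nakagawa(fit)
  expect_equal(r2f$marginal_r2, r2f$conditional_r2, tolerance = 0.02)
})

test_that("variance components match a closed-form ML oracle", {
  # balanced one-way random-intercept design: the profile likelihood has a
  # closed form in (sigma_e^2, sigma_b^2, mu), maximized independently here
  set.seed(71)
  k <- 30; n <- 6
  g <- rep(sprintf("g%02d", seq_len(k)), each = n)
  y <- rep(rnorm(k, 0, 3), each = n) + rnorm(k * n, 10, 2)
  d <- data.frame(participant_id = g, y = y)
  fit <- fit_mixed_model(model_spec("y", random = "participant_id"), d)
  ybar <- tapply(y, g, mean)
  ssw <- sum((y - ave(y, g))^2)
  N <- k * n
  negll <- function(par) {
    s2e <- exp(par[1]); s2b <- exp(par[2]); mu <- par[3]
    0.5 * ((N - k) * log(s2e) + k * log(s2e + n * s2b) + ssw / s2e +
             n * sum((ybar - mu)^2) / (s2e + n * s2b) + N * log(2 * pi))
  }
  opt <- optim(c(log(4), log(9), 10), negll, method = "BFGS")
  expect_equal(unname(fit$varcomp$residual), exp(opt$par[1]),
               tolerance = 1e-3)
  expect_equal(unname(fit$varcomp$random[["participant_id"]]),
               exp(opt$par[2]), tolerance = 1e-3)
  expect_equal(fit$logLik, -opt$value, tolerance = 1e-8)
})

test_that("degenerate and ill-posed designs are flagged or rejected", {
  d <- data.frame(participant_id = rep(c("a", "b", "c"), each = 4),
                  image_id = rep(paste0("i", 1:4), 3), y = 5)
  fit <- fit_mixed_model(model_spec("y"), d)
  expect_true(fit$degenerate)
  expect_false(fit$converged)
  expect_lt(fit$varcomp$residual, 1e-10)

  # rank-deficient fixed design names the aliased term
  set.seed(64)
  d2 <- sim_crossed(8, 8, beta = 0.2)
  d2$x2 <- 2 * d2$x
  expect_error(fit_mixed_model(model_spec("y", fixed = c("x", "x2")), d2),
               "aliased.*x2")
  # single-level random factor is rejected
  d3 <- d2; d3$participant_id <- "only"
  expect_error(fit_mixed_model(model_spec("y", fixed = "x"), d3),
               ">= 2 levels")
  expect_error(fit_mixed_model(model_spec("y", fixed = "nope"), d2),
               "nope")
})

test_that("likelihood-ratio tests enforce nesting and the chi-square form", {
  set.seed(65)
  d <- sim_crossed(15, 15, beta = 0.5)
  f0 <- fit_mixed_model(model_spec("y"), d)
  f1 <- fit_mixed_model(model_spec("y", fixed = "x"), d)
  res <- lrt(f0, f1)
  expect_equal(res$statistic, 2 * (f1$logLik - f0$logLik), tolerance = 1e-12)
  expect_equal(res$df, 1)
  expect_equal(res$p_value, pchisq(res$statistic, 1, lower.tail = FALSE))

  same <- lrt(f1, f1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  d_sub <- d[1:100, ]
  f_sub <- fit_mixed_model(model_spec("y", fixed = "x"), d_sub)
  expect_error(lrt(f0, f_sub), "different numbers of rows")

  d$z <- rnorm(nrow(d))
  fz <- fit_mixed_model(model_spec("y", fixed = "z"), d)
  expect_error(lrt(f1, fz), "not nested")
})

test_that("the model ladder fits, compares and reports subset sizes", {
  set.seed(66)
  d <- sim_crossed(12, 24, beta = 0.5)
  # single-step ladder: one fit, no comparison
  one <- run_model_ladder(d, list(list(name = "x", outcome = "y",
                                       fixed = "x")))
  expect_equal(nrow(one$summary), 1)
  expect_true(is.na(one$summary$lrt_p))

  # two steps compared on the same rows
  two <- run_model_ladder(d, list(
    list(name = "null", outcome = "y", fixed = character()),
    list(name = "x", outcome = "y", fixed = "x", compare_to = "null")))
  expect_false(is.na(two$summary$lrt_p[2]))
  expect_equal(sum(two$summary$preferred), 1)
  expect_equal(two$summary$step[two$summary$preferred], "x")

  # subset predicate: reported n matches a hand count
  d$edb_sky <- rep(c(0, 5), length.out = nrow(d))
  keep <- function(dd) dd$edb_sky > 0
  sub <- run_model_ladder(d, list(list(name = "pos", outcome = "y",
                                       fixed = "x", subset = keep)))
  expect_equal(sub$summary$n, sum(d$edb_sky > 0))
  expect_equal(sub$steps$pos$n_images, length(unique(d$image_id[keep(d)])))

  # a subset below the floor is skipped with a diagnostic, not an error
  tiny <- run_model_ladder(d, list(list(name = "empty", outcome = "y",
                                        fixed = "x",
                                        subset = function(dd) dd$x > 1e9)))
  expect_true(tiny$summary$skipped)
  expect_match(tiny$steps$empty$diagnostic, "rows")
})

test_that("the default ladders encode the intended step structure", {
  lad <- default_sky_ladder()
  expect_equal(vapply(lad, `[[`, "", "name")[1:3],
               c("environment", "environment+horizon", "horizon"))
  expect_true(all(vapply(lad, function(s) s$outcome, "") == "edb_sky"))
  nat <- default_naturalness_ladder()
  expect_equal(length(nat), 3)
  d <- data.frame(edb_sky = c(0, 1, 2), edb_trees = c(1, 0, 2))
  expect_equal(nat[[1]]$subset(d), c(FALSE, FALSE, TRUE))
})
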