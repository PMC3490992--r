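test_that("Mann-Whitney U counts pairwise wins with ties halved", {
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$U, 0)
  expect_equal(mann_whitney_u(c(3, 4), c(1, 2))$U, 4)
  expect_equal(mann_whitney_u(c(1, 2), c(2, 3))$U, 0.5)
  expect_error(mann_whitney_u(numeric(0), 1), "nonempty")
})

test_that("U statistics satisfy the complementarity and invariance laws", {
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(sample(3:15, 1)); y <- rnorm(sample(3:15, 1))
    ux <- mann_whitney_u(x, y)$U
    uy <- mann_whitney_u(y, x)$U
    expect_equal(ux + uy, length(x) * length(y))
    # strictly monotone transforms leave U untouched
    expect_equal(mann_whitney_u(exp(x), exp(y))$U, ux)
  }
})

test_that("exact and approximate p-values match the stats package", {
  set.seed(13)
  for (i in 1:8) {
    x <- rnorm(sample(4:12, 1)); y <- rnorm(sample(4:12, 1))
    mine <- mann_whitney_u(x, y)
    expect_equal(mine$method, "exact")
    expect_equal(mine$p, wilcox.test(x, y, exact = TRUE)$p.value)
  }
  # ties force the tie-corrected normal approximation
  x <- c(1, 2, 2, 3, 5, 7); y <- c(2, 3, 3, 4, 6)
  mine <- mann_whitney_u(x, y)
  expect_equal(mine$method, "normal")
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
})

test_that("Pearson correlation guards its domain", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("OLS-ML fits agree with the independent lm/logLik oracle", {
  set.seed(8)
  n <- 40
  X <- cbind(a = rnorm(n), b = runif(n))
  y <- 1 + 2 * X[, 1] - 0.5 * X[, 2] + rnorm(n, sd = 0.3)
  fit <- ols_fit(y, X)
  ref <- lm(y ~ X)
  expect_equal(unname(fit$coefficients), unname(coef(ref)))
  expect_equal(fit$loglik, as.numeric(logLik(ref)))
  expect_equal(fit$r_squared, summary(ref)$r.squared)
  expect_equal(unname(fit$p_values[-1]),
               unname(summary(ref)$coefficients[-1, 4]))
  expect_equal(fit$K, 4)

  # an exact linear response has r^2 = 1
  fit0 <- ols_fit(2 * X[, 1] + 3, X[, 1, drop = FALSE])
  expect_equal(fit0$r_squared, 1)

  expect_error(ols_fit(y, cbind(X, X[, 1])), "singular")
})

test_that("the GLS profile likelihood matches a direct numerical fit", {
  set.seed(21)
  n <- 25
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  pos <- X
  y <- 0.5 + X[, 1] - 0.3 * X[, 2] + rnorm(n, sd = 0.4)
  rho <- 0.8
  fit <- gls_fit(y, X, positions = pos, rho = rho)
  # independent route: brute-force maximization of the joint Gaussian density
  D <- as.matrix(dist(pos))
  C <- exp(-(D / rho)^2)
  Xd <- cbind(1, X)
  nll <- function(par) {
    beta <- par[1:3]; s2 <- exp(par[4])^2
    r <- y - Xd %*% beta
    0.5 * (n * log(2 * pi) + determinant(s2 * C)$modulus +
             crossprod(r, solve(s2 * C, r)))
  }
  opt <- optim(c(0, 0, 0, 0), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  expect_equal(fit$loglik, -as.numeric(opt$value), tolerance = 1e-6)
  expect_equal(unname(fit$coefficients), opt$par[1:3], tolerance = 1e-4)
})

test_that("GLS collapses to OLS as the correlation range vanishes", {
  tab <- table1()
  y <- tab$ln_upper
  X <- as.matrix(tab[, c("ln_lower", "rd")])
  ols <- ols_fit(y, X)
  near0 <- gls_fit(y, X, positions = X, rho = 1e-8)
  expect_equal(near0$loglik, ols$loglik, tolerance = 1e-6)
  # and the optimizer never does worse than the independent-errors limit
  est <- gls_fit(y, X, positions = X)
  expect_gte(est$loglik, ols$loglik - 1e-9)
})

test_that("own GLS optimum dominates and agrees with nlme at its estimate", {
  skip_if_not_installed("nlme")
  tab <- table1()
  df <- as.data.frame(tab)
  ref <- nlme::gls(ln_upper ~ ln_lower + rd, data = df,
                   correlation = nlme::corGaus(form = ~ ln_lower + rd),
                   method = "ML")
  rho_ref <- as.numeric(coef(ref$modelStruct$corStruct, unconstrained = FALSE))
  X <- as.matrix(df[, c("ln_lower", "rd")])
  at_ref <- gls_fit(df$ln_upper, X, positions = X, rho = rho_ref)
  expect_equal(at_ref$loglik, as.numeric(logLik(ref)), tolerance = 1e-5)
  free <- gls_fit(df$ln_upper, X, positions = X)
  expect_gte(free$loglik, as.numeric(logLik(ref)) - 1e-6)
})

test_that("AICc arithmetic matches its closed form", {
  expect_equal(round(aicc(19.43, 3, 34), 2), -32.06)
  expect_equal(aicc(10, 3, 34), -20 + 6 + 24 / 30)
  # n -> infinity limit is plain AIC
  expect_equal(aicc(100, 5, 1e5), -200 + 10, tolerance = 1e-3)
  expect_error(aicc(10, 33, 34), "n > K")
})

test_that("Akaike weights normalize exp(-delta/2)", {
  w <- akaike_weights(c(-43.32, -40.58, -37.71, -32.06, -31.92))
  expect_equal(round(w, 3), c(0.757, 0.192, 0.046, 0.003, 0.003))
  expect_equal(sum(w), 1)
  expect_equal(akaike_weights(5), 1)
  expect_equal(akaike_weights(c(2, 2)), c(0.5, 0.5))
  # ranking is invariant to shifting all AICc values
  expect_equal(akaike_weights(c(1, 3, 7) + 100), akaike_weights(c(1, 3, 7)))
})

fake_selection_table <- function(rows) {
  structure(rows, class = c("selection_table", "data.frame"),
            response = "upper", metric = "maximum",
            correlation_space = "candidate_covariates", conf_level = 0.95,
            fits = list())
}

test_that("model averaging follows both conventions", {
  rows <- data.frame(model = c(3, 4, 2),
                     intercept = c(0.98, 0.87, 0.76),
                     opp_opcr = c(0.77, 0.78, 0.81),
                     rt = c(NA, -0.04, -0.17),
                     rd = c(-0.21, -0.18, NA),
                     ln_a = NA_real_,
                     df = c(5, 6, 5), logLik = c(27.73, 27.84, 24.93),
                     AICc = c(-43.32, -40.58, -37.71),
                     delta_AICc = c(0, 2.75, 5.61),
                     weight = c(0.757, 0.192, 0.046),
                     in_conf_set = TRUE, rho = 0.1)
  tab <- fake_selection_table(rows)
  # zero substitution: absent terms count as zero slopes
  za <- model_average(tab, method = "zero")
  w <- c(0.757, 0.192, 0.046) / sum(c(0.757, 0.192, 0.046))
  expect_equal(unname(za["rt"]), sum(w * c(0, -0.04, -0.17)))
  expect_lt(abs(unname(za["rt"]) - (-0.0155)), 2e-4)
  # natural averaging renormalizes over the models holding the term
  na_ <- model_average(tab, method = "natural")
  wn <- w[2:3] / sum(w[2:3])
  expect_equal(unname(na_["rt"]), sum(wn * c(-0.04, -0.17)))

  # single-model scope returns its coefficients unchanged
  one <- fake_selection_table(rows[1, ])
  expect_equal(unname(model_average(one)["opp_opcr"]), 0.77)
  # two equal-weight models with equal slopes average to that slope
  two <- rows[1:2, ]; two$weight <- 0.5; two$opp_opcr <- 0.8
  expect_equal(unname(model_average(fake_selection_table(two))["opp_opcr"]), 0.8)

  none <- rows; none$in_conf_set <- FALSE
  expect_error(model_average(fake_selection_table(none)), "empty")
})

test_that("candidate sets rank as published on the packaged table", {
  tab <- table1()
  up <- build_selection_table(tab, "upper")
  lo <- build_selection_table(tab, "lower")
  expect_equal(up$model[1], 3)               # opposing OPCR + rd wins
  expect_equal(lo$model[1], 3)
  expect_equal(up$model, c(3, 4, 2, 1, 5))
  expect_equal(lo$model, c(3, 2, 4, 1, 5))
  expect_equal(sum(lo$in_conf_set), 3)       # lower confidence set = top 3
  expect_equal(sum(up$weight), 1)
  expect_equal(up$delta_AICc[1], 0)
  # df column convention: 3 for the OLS model, 5/5/6/5 for the GLS models
  expect_equal(up$df[match(1:5, up$model)], c(3, 5, 5, 6, 5))
})
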