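make_pgls_data <- function(n = 30, seed = 101, lambda = 0.5, slope = -0.3) {
  tr <- fixture_tree(n, seed = seed)
  set.seed(seed + 1)
  C <- phylo_covariance(tr)
  V <- lambda_transform(C, lambda)
  x <- rnorm(n)
  y <- slope * x + drop(t(chol(V)) %*% rnorm(n)) * 0.8
  list(tree = tr,
       data = data.frame(species = tr$tip.label, y = y, x = x,
                         g = factor(rep(c("XY", "ZW"), length.out = n))))
}

test_that("PGLS at lambda = 0 equals ordinary least squares", {
  d <- make_pgls_data(40)
  fit <- fit_pgls(y ~ x, d$data, tree = d$tree, lambda = 0)
  ols <- lm(y ~ x, data = d$data)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-10)
  sm <- summary(ols)$coefficients
  expect_equal(unname(fit$se), unname(sm[, 2]), tolerance = 1e-10)
})

test_that("PGLS at lambda = 1 equals the direct weighted matrix solve", {
  d <- make_pgls_data(12, seed = 77)
  fit <- fit_pgls(y ~ x, d$data, tree = d$tree, lambda = 1)
  C <- phylo_covariance(d$tree)[d$data$species, d$data$species]
  X <- cbind(1, d$data$x)
  beta <- brute_gls(d$data$y, X, C)
  expect_equal(unname(coef(fit)), drop(beta), tolerance = 1e-8)
})

test_that("ML lambda beats a 1001-point grid scan", {
  d <- make_pgls_data(50, seed = 5, lambda = 0.4)
  fit <- fit_pgls(y ~ x, d$data, tree = d$tree)
  prof <- function(l) fit_pgls(y ~ x, d$data, tree = d$tree, lambda = l)$logLik
  grid_best <- max(vapply(seq(0, 1, length.out = 1001), prof, numeric(1)))
  expect_gte(fit$logLik, grid_best - 1e-6)
  expect_true(fit$lambda >= 0 && fit$lambda <= 1)
})

test_that("fit matches nlme::gls with corPagel on the same data", {
  d <- make_pgls_data(45, seed = 31, lambda = 0.5)
  fit <- fit_pgls(y ~ x, d$data, tree = d$tree)
  rownames(d$data) <- d$data$species
  g <- nlme::gls(y ~ x, data = d$data,
                 correlation = ape::corPagel(0.5, d$tree, form = ~species),
                 method = "ML")
  lam_nlme <- unname(coef(g$modelStruct$corStruct, unconstrained = FALSE))
  expect_equal(fit$lambda, lam_nlme, tolerance = 0.02)
  expect_equal(unname(coef(fit)), unname(coef(g)), tolerance = 1e-2)
  ours_at <- fit_pgls(y ~ x, d$data, tree = d$tree,
                      lambda = min(max(lam_nlme, 0), 1))
  expect_equal(unname(coef(ours_at)), unname(coef(g)), tolerance = 1e-6)
  expect_equal(ours_at$logLik, as.numeric(logLik(g)), tolerance = 1e-6)
})

test_that("singular designs and degenerate inputs error informatively", {
  d <- make_pgls_data(20)
  d$data$x2 <- d$data$x
  expect_error(fit_pgls(y ~ x + x2, d$data, tree = d$tree), "singular")
  expect_error(fit_pgls(y ~ x, d$data[1:2, ], tree = d$tree), "fewer than 3")
})

test_that("marginal Wald F equals t^2 for single-df terms", {
  d <- make_pgls_data(35, seed = 8)
  fit <- fit_pgls(y ~ x * g, d$data, tree = d$tree)
  am <- anova_marginal(fit)
  i <- match("x:g", am$term)
  expect_equal(am$F[i], unname(fit$tstat["x:gZW"]^2), tolerance = 1e-8)
  expect_equal(am$df_den[i], fit$n - length(coef(fit)))
  expect_true(all(am$F >= 0))
})

test_that("interaction type-I error rate is near nominal", {
  # zero-interaction data: rejection rate of the marginal interaction test
  set.seed(99)
  tr <- fixture_tree(40, seed = 55)
  C <- phylo_covariance(tr)
  V <- lambda_transform(C, 0.3)
  L <- t(chol(V))
  g <- factor(rep(c("XY", "ZW"), each = 20))
  x <- rnorm(40)
  hits <- vapply(seq_len(400), function(r) {
    y <- 0.3 * x + drop(L %*% rnorm(40))
    d <- data.frame(species = tr$tip.label, y = y, x = x, g = g)
    fit <- fit_pgls(y ~ x * g, d, cov = C, lambda = 0.3)
    am <- anova_marginal(fit)
    am$p[match("x:g", am$term)] < 0.05
  }, logical(1))
  rate <- mean(hits)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("group slopes recombine the interaction coefficients exactly", {
  d <- make_pgls_data(36, seed = 12)
  fit <- fit_pgls(y ~ x * g, d$data, tree = d$tree)
  gs <- group_slopes(fit, "x", "g")
  expect_equal(gs$slope[gs$group == "XY"], unname(coef(fit)["x"]),
               tolerance = 1e-12)
  expect_equal(gs$slope[gs$group == "ZW"] - gs$slope[gs$group == "XY"],
               unname(coef(fit)["x:gZW"]), tolerance = 1e-12)
  expect_true(all(gs$upper > gs$lower))
})

test_that("group-slope intervals cover a known group-specific effect", {
  set.seed(7)
  tr <- fixture_tree(80, seed = 70)
  C <- phylo_covariance(tr)
  g <- factor(rep(c("XY", "ZW"), each = 40))
  covered <- vapply(seq_len(100), function(r) {
    x <- rnorm(80)
    y <- ifelse(g == "ZW", -0.3 * x, 0) + rnorm(80)
    d <- data.frame(species = tr$tip.label, y = y, x = x, g = g)
    gs <- group_slopes(fit_pgls(y ~ x * g, d, cov = C, lambda = 0), "x", "g")
    zw <- gs[gs$group == "ZW", ]
    xy <- gs[gs$group == "XY", ]
    (zw$lower <= -0.3 && zw$upper >= -0.3) && (xy$lower <= 0 && xy$upper >= 0)
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})

test_that("quadratic comparison detects curvature and honours the AIC identity", {
  tr <- fixture_tree(40, seed = 33)
  set.seed(34)
  x <- rnorm(40)
  d_lin <- data.frame(species = tr$tip.label, y = 0.5 * x, x = x)
  star <- ape::stree(40, "star"); star$edge.length <- rep(1, 40)
  star$tip.label <- tr$tip.label
  cq_lin <- compare_quadratic("y", "x", d_lin, tree = star)
  expect_lt(abs(coef(cq_lin$quadratic)[3]), 1e-8)
  expect_gt(cq_lin$p, 0.3)
  d_quad <- data.frame(species = tr$tip.label, y = x^2 + rnorm(40, sd = 0.1),
                       x = x)
  cq <- compare_quadratic("y", "x", d_quad, tree = star)
  expect_lt(cq$p, 0.001)
  expect_equal(cq$dAIC, -2 * (cq$quadratic$logLik - cq$linear$logLik) + 2,
               tolerance = 1e-10)
})

test_that("power simulation saturates for large effects and matches theory", {
  set.seed(3)
  x <- rnorm(100)
  pw_big <- power_simulation(x, 2, n_reps = 200, seed = 4, type = "difference")
  expect_gt(pw_big$power, 0.99)
  # analytic noncentral-t oracle for a correlation effect of 0.3 at n = 243
  x2 <- rnorm(243)
  pw <- power_simulation(x2, 0.3, n_reps = 600, seed = 5)
  xs <- (x2 - mean(x2)) / sd(x2)
  ncp <- 0.3 * sqrt(sum((xs - mean(xs))^2)) / sqrt(1 - 0.3^2)
  tc <- qt(0.975, 241)
  theory <- pt(-tc, 241, ncp) + pt(tc, 241, ncp, lower.tail = FALSE)
  expect_lt(abs(pw$power - theory), 3 * max(pw$se, 1e-3))
  expect_error(power_simulation(rep(1, 50), 0.3), "degenerate")
})

test_that("outlier exclusion preserves strong coefficient signs", {
  d <- make_pgls_data(60, seed = 44, lambda = 0.3, slope = -0.8)
  fit <- fit_pgls(y ~ x, d$data, tree = d$tree)
  if (abs(fit$tstat["x"]) > 4) {
    flags <- flag_outliers(standardize(d$data$x), rep("XY", 60))
    d2 <- d$data[!flags, ]
    fit2 <- fit_pgls(y ~ x, d2, tree = prune_to(d$tree, d2$species))
    expect_equal(sign(coef(fit2)["x"]), sign(coef(fit)["x"]))
  } else succeed("reference slope not strong enough to bind")
})
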