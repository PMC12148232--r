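models <- build_model_set()

test_that("the model set has the required structure and nesting", {
  expect_named(models, c("m1.a", "m1.b", "m2.a", "m2.b", "m3.a", "m3.b",
                         "m4.a", "m4.b"), ignore.order = TRUE)
  expect_equal(nrow(models$m1.b$edges), 5)
  expect_equal(nrow(models$m4.b$edges), 7)
  core <- c("GSD AMB", "AMB ASR", "JMB ASR", "MAT ASR")
  for (m in models) {
    e <- paste(m$edges[, 1], m$edges[, 2])
    expect_true(all(core %in% e))
    expect_true(asrpath:::path_is_acyclic(m))
  }
  e1a <- paste(models$m1.a$edges[, 1], models$m1.a$edges[, 2])
  e1b <- paste(models$m1.b$edges[, 1], models$m1.b$edges[, 2])
  expect_true(all(e1a %in% e1b))
  for (id in c("m2.b", "m3.b", "m4.b"))
    expect_true(all(e1b %in% paste(models[[id]]$edges[, 1], models[[id]]$edges[, 2])))
})

test_that("basis sets reproduce both published claim-count conventions", {
  k_hard <- vapply(models, function(m) length(basis_set(m, "hardenberg")),
                   integer(1))
  expect_equal(unname(k_hard[c("m1.b", "m1.a", "m3.b", "m2.b", "m3.a",
                               "m2.a", "m4.b", "m4.a")]),
               c(5L, 6L, 4L, 4L, 5L, 5L, 3L, 4L))
  expect_equal(unname(k_hard), 10L - vapply(models, function(m) nrow(m$edges),
                                            integer(1)), ignore_attr = TRUE)
  df_santos <- vapply(models, function(m) 2L * length(basis_set(m, "santos")),
                      integer(1))
  expect_equal(unname(df_santos[c("m1.b", "m1.a", "m2.b", "m3.b", "m4.b",
                                  "m2.a", "m3.a", "m4.a")]),
               c(4L, 6L, 6L, 6L, 6L, 8L, 8L, 8L))
  # claims never pair adjacent vertices, never condition on themselves
  for (m in models) for (st in c("santos", "hardenberg")) {
    for (cl in basis_set(m, st)) {
      adj <- paste(m$edges[, 1], m$edges[, 2])
      expect_false(paste(cl$predictor, cl$response) %in% adj)
      expect_false(paste(cl$response, cl$predictor) %in% adj)
      expect_false(cl$response %in% cl$conditioning)
      expect_false(cl$predictor %in% cl$conditioning)
    }
  }
})

test_that("parameter counts match both conventions", {
  q_hard <- vapply(models, path_q, integer(1), style = "hardenberg")
  expect_equal(unname(q_hard[c("m1.b", "m1.a", "m3.b", "m2.b", "m3.a",
                               "m2.a", "m4.b", "m4.a")]),
               c(10L, 9L, 11L, 11L, 10L, 10L, 12L, 11L))
  expect_equal(path_q(models$m1.b, "santos"), 9L)
  expect_equal(path_q(models$m1.a, "santos"), 8L)
})

test_that("Fisher's C follows its definition and chi-squared calibration", {
  expect_equal(fisher_c(rep(1, 4)), list(C = 0, df = 8, p = 1,
                                         degenerate = FALSE))
  ps <- c(0.3, 0.02, 0.77)
  fc <- fisher_c(ps)
  expect_equal(fc$C, -2 * sum(log(ps)))
  expect_equal(fc$df, 6)
  z <- fisher_c(c(0.5, 0))
  expect_true(is.infinite(z$C) && z$p == 0 && z$degenerate)
  expect_error(fisher_c(numeric(0)), "at least one")
})

test_that("the small-sample information criterion matches its formula", {
  expect_equal(information_criterion(13.0, 10, 95), 13 + 1900 / 84)
  expect_equal(information_criterion(8.5, 0, 95), 8.5)
  expect_error(information_criterion(5, 10, 11), "exceed")
})

test_that("per-variable transform estimates lambda and aligns contrasts", {
  sim <- simulate_dataset(generator_config("small", n_tips = 60, seed = 9))
  pd <- as_path_data(sim$table)
  tr <- prune_to(sim$tree, pd$species)
  ct <- santos_transform(pd, tr, variables = c("ASR", "AMB", "JMB"))
  expect_equal(nrow(ct), 59)
  expect_named(attr(ct, "lambdas"), c("ASR", "AMB", "JMB"))
  expect_true(all(attr(ct, "lambdas") >= 0 & attr(ct, "lambdas") <= 1))
  bad <- pd; bad$AMB <- 1
  expect_error(santos_transform(bad, tr, variables = "AMB"), "constant")
})

test_that("per-variable lambda recovers the generating signal", {
  lams <- vapply(1:40, function(r) {
    tr <- simulate_tree(100, seed = 500 + r)
    C <- phylo_covariance(tr)
    V <- lambda_transform(C, 0.3)
    set.seed(900 + r)
    d <- data.frame(species = tr$tip.label,
                    v = drop(t(chol(V)) %*% rnorm(100)))
    fit_pgls(v ~ 1, d, cov = C)$lambda
  }, numeric(1))
  expect_gte(median(lams), 0.15)
  expect_lte(median(lams), 0.45)
})

test_that("claim tests reject injected violations and guard bad claims", {
  sim <- simulate_dataset(generator_config("small", n_tips = 120, seed = 17))
  pd <- as_path_data(sim$table)
  tr <- prune_to(sim$tree, pd$species)
  # GSD -> ASR is a strong generated effect; m1.a treats it as independent
  bs <- basis_set(models$m1.a, "santos")
  viol <- Filter(function(cl) setequal(c(cl$response, cl$predictor),
                                       c("GSD", "ASR")), bs)
  expect_length(viol, 1)
  ct <- santos_transform(pd, tr)
  expect_lt(test_claim(viol[[1]], ct, "santos"), 0.01)
  ph <- test_claim(viol[[1]], pd, "hardenberg", tree = tr)
  expect_lt(ph, 0.01)
  bad <- viol[[1]]; bad$conditioning <- c(bad$conditioning, bad$predictor)
  expect_error(test_claim(bad, ct, "santos"), "conditioning")
})

test_that("the d-sep driver favours the generating model", {
  sim <- simulate_dataset(generator_config("small", n_tips = 150, seed = 23))
  pd <- as_path_data(sim$table)
  tr <- prune_to(sim$tree, pd$species)
  rep_s <- dsep(models, pd, tr, style = "santos")
  expect_s3_class(rep_s, "dsep")
  expect_equal(rep_s$dIC[1], 0)
  expect_true(rep_s$model[1] %in% c("m1.b", "m2.b", "m3.b", "m4.b"))
  # m1.b's claims are a strict subset of m1.a's (same conditioning sets),
  # so its Fisher's C cannot exceed m1.a's on the same data
  rep_h <- dsep(models[c("m1.a", "m1.b")], pd, tr, style = "hardenberg")
  Ch <- setNames(rep_h$C, rep_h$model)
  expect_lte(Ch[["m1.b"]], Ch[["m1.a"]] + 1e-9)
})

test_that("path coefficients are seed-reproducible with sane intervals", {
  sim <- simulate_dataset(generator_config("small", n_tips = 80, seed = 29))
  pd <- as_path_data(sim$table)
  tr <- prune_to(sim$tree, pd$species)
  a <- fit_path_coefficients(models$m1.b, pd, tr, "santos",
                             n_boot = 150, seed = 7)
  b <- fit_path_coefficients(models$m1.b, pd, tr, "santos",
                             n_boot = 150, seed = 7)
  expect_identical(a, b)
  expect_equal(nrow(a), 5)
  expect_true(all(a$lower <= a$coef & a$coef <= a$upper))
  h <- fit_path_coefficients(models$m1.b, pd, tr, "hardenberg",
                             n_boot = 150, seed = 7)
  expect_equal(nrow(h), 5)
})

test_that("bootstrap intervals cover a null effect at the nominal rate", {
  single <- structure(list(id = "single", vertices = c("X", "Y"),
                           edges = matrix(c("X", "Y"), 1, 2,
                                          dimnames = list(NULL, c("from", "to")))),
                      class = "path_model")
  covered <- vapply(1:60, function(r) {
    tr <- simulate_tree(60, seed = 3000 + r)
    set.seed(4000 + r)
    d <- data.frame(species = tr$tip.label, X = rnorm(60), Y = rnorm(60))
    cf <- fit_path_coefficients(single, d, tr, "santos", n_boot = 150,
                                seed = r)
    cf$lower <= 0 && 0 <= cf$upper
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})

test_that("nested likelihood-ratio tests behave at both extremes", {
  sim <- simulate_dataset(generator_config("small", n_tips = 100, seed = 37))
  pd <- as_path_data(sim$table)
  tr <- prune_to(sim$tree, pd$species)
  ct <- santos_transform(pd, tr)
  same <- lrt_nested(models$m1.b, models$m1.b, ct)
  expect_equal(same$chisq, 0)
  expect_equal(same$p, 1)
  lr <- lrt_nested(models$m1.a, models$m1.b, ct)
  expect_equal(lr$df, 1)
  expect_lt(lr$p, 0.05)        # the generated direct GSD -> ASR link binds
  expect_error(lrt_nested(models$m1.b, models$m1.a, ct), "not nested")
})

test_that("nested LRT statistics are chi-squared calibrated under the null", {
  # saturated vs generating model on data with no extra effects
  chis <- vapply(1:200, function(r) {
    set.seed(6000 + r)
    n <- 80
    X <- rnorm(n)
    Y <- 0.4 * X + rnorm(n)
    d <- data.frame(X = X, Y = Y, Z = rnorm(n))
    small <- structure(list(id = "s", vertices = c("X", "Y", "Z"),
      edges = matrix(c("X", "Y"), 1, 2, dimnames = list(NULL, c("from", "to")))),
      class = "path_model")
    large <- structure(list(id = "l", vertices = c("X", "Y", "Z"),
      edges = matrix(c("X", "Z", "Y", "Y"), 2, 2,
                     dimnames = list(NULL, c("from", "to")))),
      class = "path_model")
    lrt_nested(small, large, d)$chisq
  }, numeric(1))
  ks <- suppressWarnings(ks.test(chis, "pchisq", df = 1))
  expect_gt(ks$p.value, 0.01)
})
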