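test_that("bias metrics follow their definitions", {
  raw <- data.frame(
    species = c("sp1", "sp2", "sp3"),
    gsd = c("XY", "ZW", "XY"),
    ad_mort_male = c(0.1, 0.2, 0.15),
    ad_mort_female = c(0.1, 0.1, 0.3),
    adult_males = c(30, 50, 10),
    adult_females = c(70, 50, 30)
  )
  tab <- compute_bias_metrics(raw)
  expect_equal(tab$amb[tab$species == "sp1"], 0)
  expect_equal(tab$amb[tab$species == "sp2"], log10(2), tolerance = 1e-12)
  expect_equal(tab$asr[tab$species == "sp1"], 0.30)
  expect_error(compute_bias_metrics(transform(raw, ad_mort_male = -1)),
               "negative")
  expect_warning(compute_bias_metrics(transform(raw, ad_mort_female = 0)),
                 "zero")
})

test_that("bias metrics are antisymmetric under sex-label swap", {
  set.seed(1)
  raw <- data.frame(species = paste0("s", 1:10),
                    ad_mort_male = runif(10, 0.05, 0.5),
                    ad_mort_female = runif(10, 0.05, 0.5),
                    mat_age_male = runif(10, 100, 900),
                    mat_age_female = runif(10, 100, 900))
  swapped <- data.frame(species = raw$species,
                        ad_mort_male = raw$ad_mort_female,
                        ad_mort_female = raw$ad_mort_male,
                        mat_age_male = raw$mat_age_female,
                        mat_age_female = raw$mat_age_male)
  a <- compute_bias_metrics(raw); b <- compute_bias_metrics(swapped)
  expect_equal(a$amb, -b$amb, tolerance = 1e-12)
  expect_equal(a$mat, -b$mat, tolerance = 1e-12)
})

test_that("multiple population records average to a species mean", {
  raw <- data.frame(species = c("sp1", "sp1"),
                    ad_mort_male = c(0.2, 0.4), ad_mort_female = c(0.1, 0.4))
  tab <- compute_bias_metrics(raw)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$amb, mean(c(log10(2), 0)), tolerance = 1e-12)
})

test_that("standardization gives exact z-scores and is idempotent", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  v <- c(rnorm(50), NA, NA)
  z <- standardize(v)
  expect_equal(mean(z, na.rm = TRUE), 0, tolerance = 1e-10)
  expect_equal(sd(z, na.rm = TRUE), 1, tolerance = 1e-10)
  expect_true(all(is.na(z[is.na(v)])))
  expect_equal(standardize(z), z, tolerance = 1e-12)
  expect_error(standardize(rep(2, 5)), "constant")
})

test_that("outlier flags follow the 3-SD within-group rule", {
  set.seed(2)
  vals <- c(rnorm(30, sd = 0.5), 10)
  grp <- rep(c("XY", "ZW"), length.out = 31)
  flags <- flag_outliers(vals, grp)
  expect_true(flags[31])
  expect_equal(sum(flags), 1)
  none <- flag_outliers(runif(20, -1, 1), rep("XY", 20))
  expect_false(any(none))
  expect_warning(flag_outliers(c(1, 2, 3, 10), c("XY", "XY", "XY", "ZW")),
                 "fewer than 3")
})

test_that("model_subset returns complete cases with a matching pruned tree", {
  tr <- fixture_tree(30, seed = 21)
  tab <- data.frame(species = tr$tip.label, asr = runif(30),
                    gsd = sample(c("XY", "ZW"), 30, TRUE),
                    amb = c(rnorm(20), rep(NA, 10)))
  ms <- model_subset(tab, c("asr", "amb"), tr)
  expect_equal(ms$n, 20)
  expect_setequal(ms$tree$tip.label, ms$table$species)
  expect_equal(mean(ms$table$asr_z), 0, tolerance = 1e-10)
  expect_equal(sd(ms$table$amb_z), 1, tolerance = 1e-10)
  full <- model_subset(tab, c("asr", "gsd"), tr)
  expect_equal(full$n, 30)
  expect_error(model_subset(tab, "nope", tr), "unknown")
})

test_that("subset-scope standardization equals recomputation on the subset", {
  tr <- fixture_tree(40, seed = 22)
  tab <- data.frame(species = tr$tip.label,
                    asr = c(runif(28), rep(NA, 12)),
                    amb = rnorm(40))
  ms <- model_subset(tab, c("asr", "amb"), tr)
  expect_equal(ms$table$amb_z, standardize(ms$table$amb), tolerance = 1e-12)
  ms2 <- model_subset(standardize_traits(tab), c("asr", "amb"), tr,
                      restandardize = FALSE)
  expect_false(isTRUE(all.equal(ms2$table$amb_z, standardize(ms2$table$amb))))
})

test_that("trait CSV reader applies column mapping and rejects duplicates", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(Species = c("a", "b", "c"), ASR = c(0.4, 0.5, 0.6)),
            path, row.names = FALSE)
  tab <- read_trait_csv(path, mapping = c(Species = "species", ASR = "asr"))
  expect_named(tab, c("species", "asr"))
  write.csv(data.frame(species = c("a", "a"), asr = c(0.4, 0.5)), path,
            row.names = FALSE)
  expect_error(read_trait_csv(path), "duplicate")
})
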