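make_feat <- function(n, seed = 1) {
  set.seed(seed)
  f <- tibble::tibble(id = paste0("r", seq_len(n)),
                      x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  attr(f, "schema") <- tibble::tibble(name = c("x1", "x2", "x3"),
                                      family = "physchem")
  f
}

test_that("composite value is the linear predictor and is linear in inputs", {
  f <- make_feat(60)
  y <- as.integer(f$x1 + 0.5 * f$x2 > 0)
  m <- fit_composite(f, y, composite_spec("logit_test", c("x1", "x2")))
  f2 <- apply_composite(m, f)
  expect_equal(f2$logit_test,
               m$intercept + as.matrix(f[, c("x1", "x2")]) %*%
                 m$coefficients |> drop())
  # zero input -> intercept
  f0 <- f; f0$x1 <- 0; f0$x2 <- 0
  expect_equal(apply_composite(m, f0)$logit_test,
               rep(unname(m$intercept), 60), ignore_attr = TRUE)
  # doubling one input shifts the output by beta_i * x_i
  fd <- f; fd$x1 <- 2 * f$x1
  expect_equal(apply_composite(m, fd)$logit_test - f2$logit_test,
               m$coefficients[["x1"]] * f$x1)
  # schema gains a composite entry
  expect_true("logit_test" %in% feature_schema(f2)$name)
  expect_error(apply_composite(m, f[, c("id", "x3")]), "missing component")
})

test_that("a label-aligned component earns a positive, ordering coefficient", {
  set.seed(7)
  n <- 80
  f <- tibble::tibble(id = paste0("r", 1:n), sig = rnorm(n))
  y <- as.integer(f$sig + rnorm(n, sd = 0.4) > 0)
  m <- fit_composite(f, y, composite_spec("c1", "sig"))
  expect_gt(m$coefficients[["sig"]], 0)
  v <- apply_composite(m, f)$c1
  expect_gt(mean(v[y == 1]), mean(v[y == 0]))
})

test_that("logistic transform of the composite equals the fitted probability", {
  f <- make_feat(120, seed = 3)
  y <- as.integer(0.8 * f$x1 - 0.6 * f$x3 + rnorm(120, sd = 0.8) > 0)
  m <- fit_composite(f, y, composite_spec("cc", c("x1", "x3")))
  pr <- plogis(apply_composite(m, f)$cc)
  expect_true(all(pr > 0 & pr < 1))
  # agrees with an unpenalized glm refit (penalty 1e-4 is negligible here)
  g <- glm(y ~ x1 + x3, data = f, family = binomial())
  expect_equal(unname(c(m$intercept, m$coefficients)), unname(coef(g)),
               tolerance = 1e-3)
})

test_that("perfect separation falls back to the penalized fit", {
  f <- tibble::tibble(id = paste0("r", 1:40), x = c(rep(-2, 20), rep(2, 20)))
  y <- c(rep(0L, 20), rep(1L, 20))
  m <- fit_composite(f, y, composite_spec("sep", "x"))
  expect_true(all(is.finite(c(m$intercept, m$coefficients))))
  v <- apply_composite(m, f)$sep
  expect_true(all(v[y == 1] > v[y == 0]))
})

test_that("coefficients recover a known linear logit (parameter recovery)", {
  set.seed(11)
  n <- 2000
  f <- tibble::tibble(id = paste0("r", 1:n),
                      a = rnorm(n), b = rnorm(n))
  truth <- c(`(Intercept)` = -0.3, a = 1.2, b = -0.7)
  eta <- truth[1] + truth[2] * f$a + truth[3] * f$b
  y <- rbinom(n, 1, plogis(eta))
  m <- fit_composite(f, y, composite_spec("rec", c("a", "b")))
  g <- glm(y ~ a + b, data = f, family = binomial())
  se <- summary(g)$coefficients[, "Std. Error"]
  est <- c(m$intercept, m$coefficients)
  expect_true(all(abs(est - truth) < 3.5 * se))
})

test_that("persisting and reloading a composite model reproduces values", {
  f <- make_feat(30, seed = 5)
  y <- rep(c(0L, 1L), 15)
  m <- fit_composite(f, y, composite_spec("p", c("x1", "x2", "x3")))
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(m, path)
  m2 <- readRDS(path)
  expect_identical(apply_composite(m, f)$p, apply_composite(m2, f)$p)
})

test_that("the published logistic1 component set is wired to the schema", {
  spec <- logistic1_spec()
  expect_setequal(spec$components,
                  c("mer5", "kmer195", "kmer285", "kmer92", "PseSC16",
                    "Charge"))
  ds <- generate_peptides(default_np_spec(n_pos = 25, n_neg = 25), seed = 5)
  feats <- featurize(ds)
  expect_true(all(spec$components %in% names(feats)))
  m <- fit_composite(feats, ds$label, spec)
  expect_length(m$coefficients, 6)
  f2 <- apply_composite(m, feats)
  expect_true("logistic1" %in% names(f2))
})

test_that("composite specs round-trip through the TSV format", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("logistic1\tmer5\tCharge", "logistic2\tkmer1"), path)
  specs <- read_composite_specs(path)
  expect_length(specs, 2)
  expect_equal(specs[[1]]$components, c("mer5", "Charge"))
  expect_equal(specs[[2]]$name, "logistic2")
})
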