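test_that("chain parameters validate and presets carry the printed defaults", {
  ch <- chain_params()
  expect_equal(ch$burn_in, 10000L)
  expect_equal(ch$n_iter, 70000L)
  expect_equal(ch$thin, 10L)
  expect_identical(chain_preset("paper")$n_iter, 70000L)
  fast <- chain_preset("fast")
  expect_lt(fast$n_iter, 5000L)
  expect_error(chain_params(burn_in = 100, n_iter = 100), "smaller")
  expect_error(chain_params(thin = 0), "thin")
})

test_that("the sampler is deterministic given a seed and counts retained draws", {
  p <- make_panel(20, 100, seed = 1)
  index <- make_index(p$K, "E1")
  y <- draw_response(index, p$K, 1, 0, 0.5, seed = 2)
  y[1:4] <- NA
  ks <- build_kernels(index, "SM", "GP", grm = p$K)
  ch <- chain_preset("fast", seed = 9)
  f1 <- fit_gibbs(y, ks, ch)
  f2 <- fit_gibbs(y, ks, ch)
  expect_identical(f1$sigma_chain, f2$sigma_chain)
  expect_identical(f1$fitted$fitted, f2$fitted$fitted)
  expect_equal(f1$retained, (ch$n_iter - ch$burn_in) / ch$thin)
  f3 <- fit_gibbs(y, ks, chain_preset("fast", seed = 10))
  expect_false(identical(f1$sigma_chain, f3$sigma_chain))
})

test_that("identity-kernel BLUP is classic ridge shrinkage", {
  set.seed(3)
  n <- 40
  ids <- sprintf("G%02d", 1:n)
  K <- diag(n); dimnames(K) <- list(ids, ids)
  index <- make_index(K, "E1")
  y <- rnorm(n, mean = 5)
  ks <- build_kernels(index, "SM", "GP",
                      grm = phenogp:::new_kinship(K, "genomic"))
  lambda <- 2  # sigma2_g / sigma2_e
  bl <- solve_blup(y, ks, list(G_main = 2, residual = 1))
  shrunk <- mean(y) + lambda / (lambda + 1) * (y - mean(y))
  expect_equal(bl$fitted[match(ids, bl$genotype)], shrunk,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("an unrelated masked genotype is predicted at the fixed part", {
  set.seed(4)
  n <- 20
  ids <- sprintf("G%02d", 1:n)
  K <- diag(n)
  K[n, n] <- 1e-12   # last genotype unrelated to everyone, ~zero variance
  dimnames(K) <- list(ids, ids)
  index <- make_index(K, "E1")
  y <- rnorm(n, mean = 3)
  y[n] <- NA
  ks <- build_kernels(index, "SM", "GP",
                      grm = phenogp:::new_kinship(K, "genomic"))
  bl <- solve_blup(y, ks, list(G_main = 1, residual = 1))
  expect_equal(bl$fitted[n], unname(attr(bl, "beta")["(Intercept)"]),
               tolerance = 1e-6)
})

test_that("solve_blup matches the dense GLS oracle", {
  for (s in 1:3) {
    p <- make_panel(30, 150, seed = s)
    index <- make_index(p$K, c("E1", "E2"))
    y <- draw_response(index, p$K, 1, 0.5, 0.25, seed = s + 10,
                       env_effects = list(E1 = 0, E2 = 2))
    set.seed(s)
    y[sample(length(y), 12)] <- NA
    ks <- build_kernels(index, "MDs", "GP", grm = p$K)
    v <- list(G_main = 1, G_gxe = 0.5, residual = 0.25)
    bl <- solve_blup(y, ks, v)
    oracle <- gls_oracle(y, ks, v)
    expect_lt(max(abs(bl$fitted - oracle)), 1e-8)
  }
})

test_that("degenerate genetic priors reduce predictions to the fixed effects", {
  p <- make_panel(25, 120, seed = 5)
  index <- make_index(p$K, c("E1", "E2"))
  y <- draw_response(index, p$K, 1, 0, 0.5, seed = 6,
                     env_effects = list(E1 = 0, E2 = 3))
  mask <- c(3, 10, 30, 44)
  y[mask] <- NA
  ks <- build_kernels(index, "MDs", "GP", grm = p$K)
  fit <- fit_gibbs(y, ks, chain_preset("fast", seed = 1),
                   fixed_variances = list(G_main = 1e-10, G_gxe = 1e-10))
  pred <- fit$fitted$fitted[mask]
  fixed_part <- drop(ks$X[mask, , drop = FALSE] %*% fit$beta)
  expect_equal(pred, fixed_part, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("the posterior centers near a 50/50 variance split when true", {
  # with an identity kernel and one record per genotype only the sum of
  # the two variances is well identified; the split is prior-plus-data
  # and mixes slowly, so average a few independent chains
  set.seed(7)
  n <- 500
  ids <- sprintf("G%03d", 1:n)
  K <- diag(n); dimnames(K) <- list(ids, ids)
  index <- make_index(K, "E1")
  y <- rnorm(n) + rnorm(n)
  ks <- build_kernels(index, "SM", "GP",
                      grm = phenogp:::new_kinship(K, "genomic"))
  ratios <- sapply(1:3, function(r) {
    fit <- fit_gibbs(y, ks, chain_params(1000, 8000, 5, seed = r))
    v <- fit$variances$estimate
    v[1] / sum(v)
  })
  expect_lt(abs(mean(ratios) - 0.5), 0.15)
})

test_that("predict() returns values at fitted and masked targets and validates", {
  p <- make_panel(15, 80, seed = 8)
  index <- make_index(p$K, "E1")
  y <- draw_response(index, p$K, 1, 0, 0.5, seed = 9)
  y[2] <- NA
  ks <- build_kernels(index, "SM", "GP", grm = p$K)
  fit <- fit_gibbs(y, ks, chain_preset("fast", seed = 3))
  pr <- predict(fit, index[c(2, 5), ])
  expect_equal(pr$predicted, fit$fitted$fitted[c(2, 5)])
  empty <- predict(fit, tibble(genotype = character(), env = character()))
  expect_equal(nrow(empty), 0L)
  expect_error(predict(fit, tibble(genotype = "ZZZ", env = "E1")), "outside")
})

test_that("fit_gibbs rejects non-PSD kernels and all-masked responses", {
  ids <- c("A", "B")
  bad <- matrix(c(1, 2, 2, 1), 2, 2, dimnames = list(ids, ids))
  index <- tibble(genotype = ids, env = "E1")
  ksb <- list(
    index = index, X = matrix(1, 2, 1),
    kernels = list(list(label = "G_main", matrix = bad,
                        family = "main_genomic")),
    model = "SM", info = "GP"
  )
  class(ksb) <- "kernel_set"
  expect_error(fit_gibbs(c(1, 2), ksb, chain_preset("fast")), "PSD")

  p <- make_panel(5, 30, seed = 1)
  ks <- build_kernels(make_index(p$K, "E1"), "SM", "GP", grm = p$K)
  expect_error(fit_gibbs(rep(NA_real_, 5), ks, chain_preset("fast")),
               "masked")
})

test_that("tidy and glance expose the posterior summary", {
  p <- make_panel(12, 60, seed = 10)
  ks <- build_kernels(make_index(p$K, "E1"), "SM", "GP", grm = p$K)
  y <- draw_response(make_index(p$K, "E1"), p$K, 1, 0, 1, seed = 11)
  fit <- fit_gibbs(y, ks, chain_preset("fast", seed = 4))
  td <- tidy(fit)
  expect_setequal(td$component, c("G_main", "residual"))
  expect_true(all(td$estimate > 0))
  expect_true(all(td$ess > 1))
  gl <- glance(fit)
  expect_equal(gl$n, 12L)
  expect_equal(gl$n_masked, 0L)
})
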