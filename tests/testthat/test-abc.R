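test_that("prior draws are uniform and reproducible", {
  pr <- prior_spec(C = c(0, 20), lambda_tract = c(50, 2000))
  expect_equal(nrow(sample_priors(pr, 0)), 0)
  d1 <- sample_priors(pr, 5000, seed = 3)
  d2 <- sample_priors(pr, 5000, seed = 3)
  expect_identical(d1, d2)
  expect_lt(abs(mean(d1$C) - 10), 3 * 20 / sqrt(12) / sqrt(5000))
  expect_gt(ks.test(d1$C, "punif", 0, 20)$p.value, 0.01)
  expect_error(prior_spec(C = c(5, 1)), "lower < upper")
  expect_error(prior_spec(c(0, 1)), "named")
})

test_that("the reference table is deterministic and tracks theta", {
  fixed <- list(n_A = 6, n_B = 4, L = 300, t_dup = 0.5)
  pars <- data.frame(C = c(0.5, 2), theta = c(0.005, 0.005))
  t1 <- run_simulations(pars, fixed, seed = 8)
  t2 <- run_simulations(pars, fixed, seed = 8)
  expect_identical(t1$stats, t2$stats)
  expect_equal(nrow(t1$stats), 2)
  expect_false(anyNA(t1$stats))
  # mean S grows with theta
  set.seed(9)
  lo <- run_simulations(data.frame(C = rep(1, 40), theta = 0.002), fixed)
  hi <- run_simulations(data.frame(C = rep(1, 40), theta = 0.02), fixed)
  expect_lt(mean(lo$stats[, "S_A"]), mean(hi$stats[, "S_A"]))
})

test_that("rejection retains the k nearest simulations exactly", {
  set.seed(10)
  stats <- matrix(rnorm(20 * 3), 20, 3,
                  dimnames = list(NULL, c("a", "b", "c")))
  tab <- structure(list(params = data.frame(C = 1:20), stats = stats,
                        n_resampled = 0L), class = "sim_table")
  obs <- c(a = 0.1, b = -0.2, c = 0.3)
  post <- rejection(obs, tab, 5)
  # brute force: standardize, sort Euclidean distances
  sds <- apply(stats, 2, sd)
  d <- sqrt(colSums((t(stats) / sds - obs / sds)^2))
  expect_identical(post$index, order(d)[1:5])
  # observed equal to a table row is retained at distance zero
  obs2 <- stats[7, ]
  post2 <- rejection(obs2, tab, 1)
  expect_identical(post2$index, 7L)
  expect_equal(post2$delta, 0)
  # k = rows retains everything
  expect_equal(nrow(rejection(obs, tab, 20)$retained), 20)
  # zero-variance statistics are dropped with a warning
  stats0 <- cbind(stats, d0 = 1)
  tab0 <- structure(list(params = tab$params, stats = stats0,
                         n_resampled = 0L), class = "sim_table")
  expect_warning(rejection(c(obs, d0 = 1), tab0, 5), "zero-variance")
})

test_that("regression adjustment is exact in the noiseless linear case", {
  # all retained stats equal to observed: adjustment is the identity
  tab <- structure(list(params = data.frame(C = runif(30)),
                        stats = matrix(5, 30, 1,
                                       dimnames = list(NULL, "s")) +
                          rnorm(30) * 0,
                        n_resampled = 0L), class = "sim_table")
  tab$stats[1, ] <- 5 + 1e-9      # avoid all-constant column
  post <- rejection(c(s = 5), tab, 10)
  post <- regression_adjust(post)
  expect_equal(post$adjusted$C, post$retained$C, tolerance = 1e-6)
  # param = 2 * stat exactly: adjusted draws collapse to 2 * observed
  set.seed(12)
  s <- runif(40, 0, 10)
  tab2 <- structure(list(params = data.frame(C = 2 * s),
                         stats = matrix(s, dimnames = list(NULL, "s")),
                         n_resampled = 0L), class = "sim_table")
  post2 <- regression_adjust(rejection(c(s = 4), tab2, 20))
  expect_equal(post2$adjusted$C, rep(8, 20), tolerance = 1e-9)
})

test_that("regression adjustment lowers the error of the C estimate", {
  fixed <- list(n_A = 14, n_B = 9, L = 1000, theta = 0.0085, t_dup = 0.5)
  pr <- prior_spec(C = c(0, 20), lambda_tract = c(50, 2000))
  set.seed(13)
  tab <- run_simulations(sample_priors(pr, 3000), fixed)
  obs_p <- do.call(sim_params, c(list(C = 1, lambda_tract = 500), fixed))
  err <- vapply(1:8, function(r) {
    obs <- summary_vector(paraconv:::sim_once(obs_p))
    post <- rejection(obs[abc_default_stats()], tab, 100)
    post <- suppressWarnings(regression_adjust(post, pr))
    c(adj = mean(post$adjusted$C) - 1, rej = mean(post$retained$C) - 1)
  }, c(adj = 0, rej = 0))
  expect_lte(sqrt(mean(err["adj", ]^2)), sqrt(mean(err["rej", ]^2)))
})

test_that("posterior summaries recover modes and credibility intervals", {
  expect_error(posterior_summary(rnorm(10)), "at least 50")
  # point mass
  ps <- posterior_summary(rep(3.5, 100))
  expect_equal(unname(ps), c(3.5, 3.5, 3.5))
  # normal draws
  set.seed(14)
  x <- rnorm(10000, 5, 1)
  ps2 <- posterior_summary(x, support = c(0, 10))
  expect_equal(ps2[["mode"]], 5, tolerance = 0.15)
  expect_equal(ps2[["ci_lower"]], 3.04, tolerance = 0.15)
  expect_equal(ps2[["ci_upper"]], 6.96, tolerance = 0.15)
  # uniform draws: CI is the central 95% of the support
  u <- runif(20000)
  ps3 <- posterior_summary(u, support = c(0, 1))
  expect_lt(abs(ps3[["ci_lower"]] - 0.025), 0.005)
  expect_lt(abs(ps3[["ci_upper"]] - 0.975), 0.005)
})

test_that("model choice is symmetric for duplicated tables and bounds BF", {
  set.seed(15)
  stats <- matrix(rnorm(50 * 2), 50, 2, dimnames = list(NULL, c("a", "b")))
  t1 <- structure(list(params = data.frame(C = 0), stats = stats,
                       n_resampled = 0L), class = "sim_table")
  mc <- model_choice(c(a = 0, b = 0), t1, t1, k = 20)
  expect_equal(mc$bf, 1)
  # observed far from all model-1 simulations: denominator 0, lower bound
  t2 <- t1
  t2$stats <- stats + 100
  mc2 <- model_choice(c(a = 100, b = 100), t1, t2, k = 10)
  expect_true(mc2$lower_bound)
  expect_equal(mc2$n_M1, 0L)
  expect_error(model_choice(c(a = 0, b = 0), t1, t1, k = 0), "k >= 1")
})

test_that("demographic calibration covers parameters of simulated panels", {
  pr <- prior_spec(theta = c(0.002, 0.03), growth_factor = c(1, 20))
  # observed panel: stats of a draw simulated at known parameters
  set.seed(16)
  truth <- list(theta = 0.012, growth_factor = 6)
  loci <- t(vapply(1:14, function(l) {
    p <- sim_params(n_A = 12, n_B = 0, L = 600, theta = truth$theta, C = 0,
                    t_dup = 100, growth_factor = truth$growth_factor,
                    t_exp = 0.2)
    r <- paraconv:::sim_once(p)
    st <- paraconv:::locus_stats01(r$mat_A, 600)
    c(S = unname(st["S"]), pi_site = unname(st["pi_site"]),
      D = unname(st["D"]))
  }, c(S = 0, pi_site = 0, D = 0)))
  fit <- fit_demography(as.data.frame(loci), pr, n = 12, L = 600,
                        fixed = list(t_exp = 0.2),
                        n_sims = 1500, k = 100, seed = 17)
  expect_true(fit$summary["theta", "ci_lower"] <= truth$theta &&
              truth$theta <= fit$summary["theta", "ci_upper"])
  expect_error(fit_demography(as.data.frame(loci)[1, ], pr), "two reference")
})
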