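rand_design <- function(n, seed = 1) {
  set.seed(seed)
  X <- cbind(intercept = 1,
             diagnosis = rep(c(1, 0), length.out = n),
             age = round(rnorm(n, 10, 2), 1),
             sex = rbinom(n, 1, 0.5))
  rownames(X) <- sprintf("s%03d", seq_len(n))
  X
}

test_that("least-squares fits match the normal equations to 1e-10", {
  X <- rand_design(20, seed = 4)
  Y <- matrix(rnorm(20 * 5, 8), 20, 5,
              dimnames = list(rownames(X), paste0("a", 1:5)))
  fits <- fit_linear_models(Y, X)
  brute_beta <- solve(t(X) %*% X) %*% t(X) %*% Y
  expect_equal(unname(fits$coefficients), unname(t(brute_beta)), tolerance = 1e-10)
  res <- Y - X %*% brute_beta
  expect_equal(unname(fits$sigma2), unname(colSums(res^2) / (20 - 4)),
               tolerance = 1e-10)
  expect_equal(fits$v, solve(t(X) %*% X)["diagnosis", "diagnosis"], tolerance = 1e-12)
})

test_that("an exactly linear response yields zero residual variance", {
  X <- rand_design(15, seed = 2)
  y <- X %*% c(5, 0.7, -0.1, 0.2)
  Y <- cbind(a1 = as.numeric(y))
  rownames(Y) <- rownames(X)
  fits <- fit_linear_models(Y, X)
  expect_equal(unname(fits$coefficients[1, ]), c(5, 0.7, -0.1, 0.2),
               tolerance = 1e-10)
  expect_lt(fits$sigma2[[1L]], 1e-20)
})

test_that("rank-deficient designs fail naming the collinear column", {
  X <- rand_design(20, seed = 4)
  X <- cbind(X, age2 = X[, "age"])
  Y <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(rownames(X), paste0("a", 1:3)))
  expect_error(fit_linear_models(Y, X), "collinear.*age2")
})

test_that("moderation hyperparameters and statistics match the reference EB fit", {
  skip_if_not_installed("limma")
  set.seed(2)
  n <- 40; na_ <- 300
  X <- rand_design(n, seed = 2)
  sds <- sqrt(0.5 / rgamma(na_, shape = 3, rate = 3))
  Y <- matrix(rnorm(n * na_), n, na_) %*% diag(sds) + 8
  dimnames(Y) <- list(rownames(X), sprintf("a%03d", seq_len(na_)))
  fits <- fit_linear_models(Y, X)
  ms <- ebayes_moderate(fits)
  eb <- limma::eBayes(limma::lmFit(t(Y), X))
  expect_equal(ms$d0, eb$df.prior, tolerance = 1e-8)
  expect_equal(ms$s02, eb$s2.prior, tolerance = 1e-8)
  expect_equal(unname(ms$t), unname(eb$t[, "diagnosis"]), tolerance = 1e-10)
  expect_equal(unname(ms$p), unname(eb$p.value[, "diagnosis"]), tolerance = 1e-10)
})

test_that("the d0 limits recover the ordinary t-test and full pooling", {
  X <- rand_design(30, seed = 7)
  Y <- matrix(rnorm(30 * 50, 8), 30, 50,
              dimnames = list(rownames(X), sprintf("a%02d", 1:50)))
  fits <- fit_linear_models(Y, X)
  # d0 = 0: moderated t equals the ordinary per-antigen t
  m0 <- ebayes_moderate(fits, d0 = 0, s02 = 1)
  t_ord <- fits$coefficients[, "diagnosis"] / sqrt(fits$sigma2 * fits$v)
  expect_equal(unname(m0$t), unname(t_ord), tolerance = 1e-12)
  # d0 = Inf: every antigen shares the prior variance
  mi <- ebayes_moderate(fits, d0 = Inf, s02 = 2)
  expect_true(all(mi$s2_post == 2))
})

test_that("identical residual variances trigger the pooled branch with a warning", {
  X <- rand_design(12, seed = 3)
  base <- rnorm(12)
  Y <- vapply(1:20, function(i) base * i, numeric(12))  # scaled copies
  # construct equal variances: use exact duplicates instead
  y0 <- rnorm(12, 8)
  Y <- matrix(rep(y0, 20), 12, 20, dimnames = list(rownames(X), paste0("a", 1:20)))
  fits <- fit_linear_models(Y, X)
  expect_warning(ms <- ebayes_moderate(fits), "d0 = Inf")
  expect_true(is.infinite(ms$d0))
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(12)
  for (i in 1:25) {
    p <- runif(sample(3:200, 1))
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("differential calls partition antigens by direction and significance", {
  stats <- structure(list(
    beta = setNames(c(0.75, -0.3, 0.1, 0.5), paste0("a", 1:4)),
    s2 = rep(1, 4), s2_post = rep(1, 4),
    t = c(3, -2.5, 0.4, 2),
    p = c(0.001, 0.02, 0.7, 0.051),
    adj_p = c(0.004, 0.04, 0.7, 0.068),
    d0 = 4, s02 = 1, df = 20, df_total = 24, v = 0.05),
    class = "moderated_stats")
  tab <- call_differential(stats, alpha = 0.05)
  expect_equal(tab$FC[tab$antigen == "a1"], 2^0.75)     # ~1.68
  expect_equal(tab$call[tab$antigen == "a1"], "up")
  expect_equal(tab$call[tab$antigen == "a2"], "down")
  expect_equal(tab$call[tab$antigen == "a4"], "ns")     # p = 0.051 > alpha
  expect_identical(tab$p, sort(tab$p))
  # partition is exhaustive and exclusive
  expect_true(all(tab$call %in% c("up", "down", "ns")))
  expect_true(all((tab$p <= 0.05 & tab$FC != 1) == (tab$call != "ns")))
})

test_that("covariate adjustment keeps type-I error nominal under confounding", {
  # cases younger than controls, antigens age-dependent, zero true diagnosis
  # effect: the adjusted model must hold the nominal level, the unadjusted
  # diagnosis-only model must inflate
  md <- simulate_matrix(sim_config(n_antigens = 5, n_psa = 0), seed = 30)$metadata
  n <- nrow(md); na_ <- 400; reps <- 60
  rej_adj <- rej_unadj <- numeric(reps)
  set.seed(31)
  for (r in seq_len(reps)) {
    slope <- rnorm(na_, -0.05, 0.02)
    sexoff <- rnorm(na_, 0, 0.05)
    Y <- outer(md$age - 9, slope) + outer(as.numeric(md$sex == "M"), sexoff) +
      matrix(rnorm(n * na_, 0, 0.6), n, na_)
    dimnames(Y) <- list(md$sample_id, sprintf("a%03d", seq_len(na_)))
    Xa <- build_design(Y, md)
    Xu <- build_design(Y, md, covariates = character())
    rej_adj[r] <- mean(ebayes_moderate(fit_linear_models(Y, Xa))$p <= 0.05)
    rej_unadj[r] <- mean(ebayes_moderate(fit_linear_models(Y, Xu))$p <= 0.05)
  }
  expect_lt(abs(mean(rej_adj) - 0.05), 0.02)
  expect_gt(mean(rej_unadj), mean(rej_adj) + 0.02)
})

test_that("no directional bias arises under the null", {
  md <- simulate_matrix(sim_config(n_antigens = 5, n_psa = 0), seed = 33)$metadata
  set.seed(34)
  Y <- matrix(rnorm(nrow(md) * 500, 8, 0.6), nrow(md), 500,
              dimnames = list(md$sample_id, sprintf("a%03d", 1:500)))
  tab <- run_differential(Y, md)
  n_up <- sum(tab$call == "up"); n_down <- sum(tab$call == "down")
  expect_lt(abs(n_up - n_down), 0.5 * max(10, n_up + n_down))
})
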