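make_spots <- function(fg, bg, ids = paste0("A", seq_along(fg)), sample = "s1",
                       flag = 0L, control = "antigen") {
  n <- length(fg)
  d <- data.frame(sample_id = sample, antigen_id = ids, control_flag = control,
                  block = 1L, row = 1L, col = seq_len(n),
                  replicate = stats::ave(seq_len(n), ids, FUN = seq_along),
                  fg_mean = fg, bg_mean = bg, flag = flag,
                  stringsAsFactors = FALSE)
  class(d) <- c("spot_records", "data.frame")
  d
}

test_that("net intensity subtracts background, floors, and flags floored spots", {
  s <- make_spots(fg = c(1025, 10), bg = c(1, 50))
  out <- net_intensity(s)
  expect_equal(out$log2_net[[1L]], 10)                  # log2(1024)
  expect_equal(out$log2_net[[2L]], 0)                   # floored at 1
  expect_identical(out$floored, c(FALSE, TRUE))
  expect_error(net_intensity(make_spots(fg = -1, bg = 0)), "negative raw intensity")
})

test_that("net intensity matches high-precision recomputation on random spots", {
  set.seed(41)
  fg <- runif(500, 0, 5e4); bg <- runif(500, 0, 300)
  out <- net_intensity(make_spots(fg, bg, ids = sprintf("A%03d", 1:500)))
  expect_equal(out$log2_net, log(pmax(fg - bg, 1), base = 2), tolerance = 1e-12)
})

test_that("CV filter computes linear-scale CV% and flags above threshold", {
  s <- net_intensity(make_spots(fg = c(100, 100, 100, 100) + 50,
                                bg = rep(50, 4), ids = rep("A1", 4)))
  cv <- cv_filter(s)
  expect_equal(cv$cv, 0)
  expect_false(cv$flagged)

  # replicates 8,10,12,14: mean 11, sd 2.582, CV 23.47% > 20
  s2 <- net_intensity(make_spots(fg = c(8, 10, 12, 14) + 50, bg = rep(50, 4),
                                 ids = rep("A1", 4)))
  cv2 <- cv_filter(s2)
  expect_equal(cv2$cv, 100 * sd(c(8, 10, 12, 14)) / 11, tolerance = 1e-12)
  expect_true(cv2$flagged)
  expect_equal(cv2$reason, "high_cv")

  # infinite threshold flags nothing
  cv3 <- cv_filter(s2, threshold = Inf)
  expect_false(any(cv3$flagged))
})

test_that("raising the CV threshold never decreases retained groups", {
  st <- small_study()
  spots <- net_intensity(st$spots)
  retained <- vapply(c(5, 10, 20, 40, Inf),
                     function(th) sum(!cv_filter(spots, th)$flagged), 1)
  expect_true(all(diff(retained) >= 0))
})

test_that("replicate aggregation means retained replicates and imputes sparse cells", {
  s <- net_intensity(make_spots(fg = rep(250, 4), bg = rep(50, 4), ids = rep("A1", 4)))
  am <- aggregate_replicates(s, cv_filter(s))
  expect_equal(unname(am$values["s1", "A1"]), log2(200))

  # aggregation equals brute-force group means on a whole study
  st <- small_study()
  spots <- net_intensity(st$spots)
  cv <- cv_filter(spots)
  am2 <- aggregate_replicates(spots, cv)
  good <- spots[spots$flag == 0L & spots$control_flag == "antigen", ]
  bad <- paste(cv$sample_id, cv$antigen_id)[cv$flagged]
  good <- good[!paste(good$sample_id, good$antigen_id) %in% bad, ]
  key <- paste(good$sample_id, good$antigen_id)
  brute <- tapply(good$log2_net, key, mean)
  counts <- tapply(good$log2_net, key, length)
  check <- names(brute)[counts >= 2L]
  idx <- do.call(rbind, strsplit(check, " "))
  expect_equal(unname(am2$values[idx]), as.numeric(brute[check]), tolerance = 1e-12)
  # cells with < 2 retained replicates are marked imputed
  few <- names(counts)[counts < 2L]
  if (length(few)) {
    idx2 <- do.call(rbind, strsplit(few, " "))
    expect_true(all(am2$imputed[idx2]))
  }
})

test_that("antigens missing in most samples are excluded as sparse", {
  # antigen B1 has a single replicate everywhere -> always missing
  mk <- function(sample) {
    rbind(make_spots(rep(300, 4), rep(50, 4), ids = rep("A1", 4), sample = sample),
          make_spots(400, 50, ids = "B1", sample = sample))
  }
  s <- net_intensity(do.call(rbind, lapply(c("s1", "s2", "s3"), mk)))
  am <- aggregate_replicates(s, NULL)
  expect_equal(unname(am$antigen_status["B1"]), "sparse")
  expect_equal(unname(am$antigen_status["A1"]), "retained")
})

ncf_fixture <- function(n = 40, seed = 5) {
  # 3 antigens: one copying the control profile, one reactive with a group
  # effect, one constant; 4 control replicate profiles
  set.seed(seed)
  u <- rnorm(n, 7, 0.6)
  vals <- cbind(copycat = u + rnorm(n, 0, 0.01),
                reactive = 11 + c(rep(1.5, n / 2), rep(0, n / 2)) + rnorm(n, 0, 0.4),
                flat = rep(5, n))
  rownames(vals) <- sprintf("s%02d", seq_len(n))
  nc <- matrix(u + rnorm(4 * n, 0, 0.12), n, 4,
               dimnames = list(rownames(vals), paste0("nc_", 1:4)))
  list(amat = antigen_matrix(vals), nc = nc)
}

test_that("NCF excludes control-tracking and constant antigens, keeps reactive ones", {
  fx <- ncf_fixture()
  res <- negative_control_filter(fx$amat, fx$nc)
  st <- res$amat$antigen_status
  expect_equal(unname(st["copycat"]), "ncf_excluded")
  expect_equal(unname(st["reactive"]), "retained")
  expect_equal(unname(st["flat"]), "constant")
  expect_true(res$stats$threshold <= 1)
})

test_that("NCF is invariant to antigen order and needs enough control replicates", {
  fx <- ncf_fixture()
  res1 <- negative_control_filter(fx$amat, fx$nc)
  perm <- fx$amat
  perm$values <- perm$values[, c(3, 1, 2)]
  perm$antigen_status <- perm$antigen_status[c(3, 1, 2)]
  res2 <- negative_control_filter(perm, fx$nc)
  expect_identical(res1$amat$antigen_status[colnames(fx$amat$values)],
                   res2$amat$antigen_status[colnames(fx$amat$values)])
  expect_error(negative_control_filter(fx$amat, fx$nc[, 1, drop = FALSE]),
               "fewer than 2")
})

test_that("PSA detection flags broad elevation and nothing on homogeneous data", {
  set.seed(11)
  n <- 30; na_ <- 100
  vals <- matrix(rnorm(n * na_, 8, 0.5), n, na_,
                 dimnames = list(sprintf("s%02d", 1:n), sprintf("a%03d", 1:na_)))
  hot <- sample(na_, round(0.95 * na_))
  vals["s05", hot] <- vals["s05", hot] + 4 * 0.5 * 1.4826 + 1   # > +4 MAD
  res <- detect_psa(antigen_matrix(vals))
  expect_identical(res$flagged, "s05")
  expect_identical(unname(res$amat$sample_status["s05"]), "psa_excluded")

  flat <- matrix(3, 10, 20, dimnames = list(sprintf("s%02d", 1:10),
                                            sprintf("a%02d", 1:20)))
  res2 <- detect_psa(antigen_matrix(flat))
  expect_length(res2$flagged, 0L)
})

test_that("cyclic loess removes pairwise trends and preserves antigen means", {
  set.seed(3)
  g <- rnorm(300, 8, 1.2)
  mk <- function(...) {
    m <- rbind(...)
    colnames(m) <- sprintf("a%03d", seq_len(ncol(m)))
    m
  }
  # identical samples are untouched
  m0 <- mk(s1 = g, s2 = g)
  expect_equal(cyclic_loess(m0), m0)

  # constant offset between two samples shrinks by >= 90%
  m1 <- mk(s1 = g + rnorm(300, 0, 0.1), s2 = g + rnorm(300, 0, 0.1) + 1)
  m1n <- cyclic_loess(m1)
  expect_lt(abs(mean(m1n[1, ]) - mean(m1n[2, ])),
            0.1 * abs(mean(m1[1, ]) - mean(m1[2, ])))

  # intensity-dependent distortion: median |M| drops at least 5-fold
  m2 <- mk(s1 = g + rnorm(300, 0, 0.05),
           s2 = g + rnorm(300, 0, 0.05) + 0.15 * (g - 6)^2)
  m2n <- cyclic_loess(m2)
  expect_lt(median(abs(m2n[1, ] - m2n[2, ])),
            median(abs(m2[1, ] - m2[2, ])) / 5)

  # per-antigen grand means preserved exactly, full and subsampled pair sets
  m3 <- matrix(rnorm(60 * 80, 8), 60, 80,
               dimnames = list(sprintf("s%02d", 1:60), sprintf("a%02d", 1:80)))
  expect_equal(colMeans(cyclic_loess(m3, seed = 4)), colMeans(m3), tolerance = 1e-6)
  m4 <- m3[1:30, ]
  expect_equal(colMeans(cyclic_loess(m4)), colMeans(m4), tolerance = 1e-6)
})

test_that("cyclic loess agrees with the reference pairwise implementation", {
  skip_if_not_installed("limma")
  set.seed(8)
  n <- 12; na_ <- 400
  base <- rnorm(na_, 8, 1)
  m <- t(vapply(seq_len(n), function(i) base + rnorm(na_, 0, 0.3) + rnorm(1, 0, 0.4),
                numeric(na_)))
  dimnames(m) <- list(sprintf("s%02d", 1:n), sprintf("a%03d", 1:na_))
  ours <- cyclic_loess(m, span = 0.7, iterations = 3)
  ref <- t(limma::normalizeCyclicLoess(t(m), span = 0.7, iterations = 3,
                                       method = "pairs"))
  # both must remove the same sample-level offsets (agreement well under the
  # offset scale; smoother details differ between lowess and loess)
  expect_lt(max(abs(rowMeans(ours) - rowMeans(ref))), 0.05)
})

test_that("batch correction is the identity for one batch and validates design", {
  sm <- simulate_matrix(sim_config(n_cases = 10, n_controls = 8, n_antigens = 30,
                                   n_batches = 1, n_psa = 0), seed = 6)
  am <- antigen_matrix(sm$values)
  out <- batch_correct(am, sm$metadata)
  expect_equal(out$values, am$values, tolerance = 1e-9)

  md <- sm$metadata
  md$batch <- c("B1", rep("B2", nrow(md) - 1L))
  expect_error(batch_correct(am, md), "fewer than 3 samples")

  md2 <- sm$metadata
  md2$batch <- ifelse(md2$diagnosis == "case", "B1", "B2")
  expect_error(batch_correct(am, md2), "confounded .*diagnosis")
})

test_that("batch correction removes a planted shift without touching biology", {
  cfg <- sim_config(batch_loc = 0, batch_scale = 1, n_psa = 0,
                    n_cases = 40, n_controls = 20, n_antigens = 150)
  sm <- simulate_matrix(cfg, seed = 9)
  clean <- sm$values
  shifted <- clean
  b2 <- sm$metadata$batch == "B2"
  shifted[b2, ] <- shifted[b2, ] + 1.0
  corrected <- retained_values(batch_correct(antigen_matrix(shifted), sm$metadata))

  # the global +1 shift is removed
  resid <- mean(colMeans(corrected[b2, ]) - colMeans(corrected[!b2, ]))
  expect_lt(abs(resid), 0.05)
  # per-antigen batch differences end up below the no-shift sampling baseline
  d_corr <- colMeans(corrected[b2, ]) - colMeans(corrected[!b2, ])
  d_clean <- colMeans(clean[b2, ]) - colMeans(clean[!b2, ])
  expect_lt(mean(abs(d_corr)), mean(abs(d_clean)))

  # diagnosis coefficients barely move relative to the never-shifted data
  X <- build_design(clean, sm$metadata)
  b_clean <- fit_linear_models(clean, X)$coefficients[, "diagnosis"]
  b_corr <- fit_linear_models(corrected, X)$coefficients[, "diagnosis"]
  expect_lt(mean(abs(b_corr - b_clean)), 0.05)
})

test_that("batch scale effects are equalized", {
  cfg <- sim_config(batch_loc = 0, batch_scale = 1, n_psa = 0,
                    n_cases = 40, n_controls = 20, n_antigens = 150,
                    frac_differential = 0)
  sm <- simulate_matrix(cfg, seed = 13)
  vals <- sm$values
  b2 <- sm$metadata$batch == "B2"
  centre <- colMeans(vals)
  vals[b2, ] <- sweep(sweep(vals[b2, ], 2L, centre), 2L, centre,
                      function(resid, m) m + 2 * resid)   # x2 scale in batch 2
  corrected <- retained_values(batch_correct(antigen_matrix(vals), sm$metadata))
  v_b2 <- mean(apply(corrected[b2, ], 2L, var))
  v_b1 <- mean(apply(corrected[!b2, ], 2L, var))
  expect_lt(abs(v_b2 / v_b1 - 1), 0.1)
})

test_that("the preprocessing chain reconciles counts and records provenance", {
  st <- small_study()
  pre <- preprocess_study(st$spots, st$metadata, seed = 3)
  counts <- pre$qc$counts
  expect_equal(counts$retained + counts$ncf_excluded + counts$sparse + counts$constant,
               counts$antigens_tested)
  expect_equal(counts$samples_retained + counts$samples_psa_excluded,
               nrow(st$metadata))
  expect_match(paste(pre$amat$provenance, collapse = ";"), "net_intensity")
  expect_match(paste(pre$amat$provenance, collapse = ";"), "batch_correct")
  # PSA detection precedes NCF in the recorded chain
  prov <- pre$amat$provenance
  expect_lt(grep("detect_psa", prov), grep("negative_control_filter", prov))
})
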