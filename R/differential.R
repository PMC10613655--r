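# Covariate-adjusted moderated differential testing.  Per-antigen least
# squares on a diagnosis + age + sex design, then empirical-Bayes
# shrinkage of the residual variances toward a global prior
# (moment-matching on log s^2 with trigamma inversion), giving the
# moderated t with d0 + d degrees of freedom.

#' Build the differential-testing design matrix
#'
#' Columns: intercept, `diagnosis` (case = 1, control = 0), `age` (years),
#' `sex` (M = 1, F = 0), aligned to the retained samples of `amat`.
#'
#' @param amat an [antigen_matrix()] (only retained samples are used), or
#'   a plain matrix with sample rownames.
#' @param metadata `sample_metadata`.
#' @param covariates which of `age`, `sex` to adjust for (both by default;
#'   an empty vector gives the unadjusted diagnosis-only model).
#' @return numeric design matrix with rownames = sample ids.
#' @export
build_design <- function(amat, metadata, covariates = c("age", "sex")) {
  vals <- if (inherits(amat, "antigen_matrix")) retained_values(amat) else amat
  md <- metadata[match(rownames(vals), metadata$sample_id), , drop = FALSE]
  if (any(is.na(md$sample_id))) stop_sp("metadata missing for retained sample(s)")
  design <- cbind(intercept = 1, diagnosis = as.numeric(md$diagnosis == "case"))
  if ("age" %in% covariates) design <- cbind(design, age = md$age)
  if ("sex" %in% covariates) design <- cbind(design, sex = as.numeric(md$sex == "M"))
  rownames(design) <- md$sample_id
  design
}

#' Per-antigen least-squares fits
#'
#' @param amat [antigen_matrix()] or plain matrix (samples x antigens).
#' @param design design matrix from [build_design()].
#' @param coef name of the coefficient of interest (default `"diagnosis"`).
#' @return `lm_fits` list: `coefficients` (antigens x columns), `sigma2`
#'   (residual variances), `df` (residual degrees of freedom), `v`
#'   (unscaled variance of the coefficient of interest), `coef`, `n`.
#' @export
fit_linear_models <- function(amat, design, coef = "diagnosis") {
  Y <- if (inherits(amat, "antigen_matrix")) retained_values(amat) else amat
  stopifnot(identical(rownames(Y), rownames(design)), coef %in% colnames(design))
  n <- nrow(Y)
  qr_x <- qr(design)
  if (qr_x$rank < ncol(design)) {
    dropped <- colnames(design)[qr_x$pivot[seq.int(qr_x$rank + 1L, ncol(design))]]
    stop_sp("design matrix is rank deficient; collinear column(s): ",
            paste(dropped, collapse = ", "))
  }
  if (n <= ncol(design)) stop_sp("need more samples than design columns")
  fit <- lm.fit(design, Y)
  beta <- t(fit$coefficients)
  res <- Y - design %*% fit$coefficients
  df <- n - qr_x$rank
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(chol(crossprod(design)))
  dimnames(xtx_inv) <- list(colnames(design), colnames(design))
  structure(
    list(coefficients = beta, sigma2 = sigma2, df = df,
         v = xtx_inv[coef, coef], coef = coef, n = n),
    class = "lm_fits"
  )
}

# Solve trigamma(x) = y by Newton iteration on 1/trigamma (monotone).
trigamma_inverse <- function(y) {
  stopifnot(y > 0)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderation of per-antigen variances
#'
#' Estimates prior degrees of freedom `d0` and prior variance `s0^2` by
#' moment-matching the distribution of log residual variances across
#' antigens (the excess of `var(log s^2)` over `trigamma(d/2)` determines
#' `d0` by trigamma inversion), then forms posterior variances
#' `s~^2 = (d0 s0^2 + d s^2) / (d0 + d)`, moderated t statistics
#' `t = beta / sqrt(s~^2 v)` and two-sided p-values on `d0 + d` degrees of
#' freedom.  When the observed spread of log s^2 is no larger than
#' expected under equal true variances, `d0` is infinite and all
#' posteriors equal `s0^2`.
#'
#' @param fits `lm_fits` from [fit_linear_models()].
#' @param d0,s02 optional hyperparameter overrides (for limit checks:
#'   `d0 = 0` recovers the ordinary t-test exactly).
#' @return `moderated_stats` list: per-antigen `beta`, `s2`, `s2_post`,
#'   `t`, `p`, `adj_p`, plus `d0`, `s02`, `df`, `df_total`.
#' @export
ebayes_moderate <- function(fits, d0 = NULL, s02 = NULL) {
  s2 <- fits$sigma2
  d <- fits$df
  if (length(s2) < 10L && is.null(d0)) {
    stop_sp("hyperparameter estimation needs at least 10 antigens")
  }
  if (is.null(d0) || is.null(s02)) {
    z <- log(s2[s2 > 0 & is.finite(s2)])
    if (length(z) < 10L) stop_sp("too few positive residual variances")
    if (var(z) < .Machine$double.eps) {
      warning("all residual variances equal; using d0 = Inf")
      est_d0 <- Inf
    } else {
      excess <- var(z) - trigamma(d / 2)
      est_d0 <- if (excess <= 0) Inf else 2 * trigamma_inverse(excess)
    }
    est_s02 <- if (is.finite(est_d0)) {
      exp(mean(z) - digamma(d / 2) + log(d / 2) + digamma(est_d0 / 2) - log(est_d0 / 2))
    } else {
      exp(mean(z) - digamma(d / 2) + log(d / 2))
    }
    if (is.null(d0)) d0 <- est_d0
    if (is.null(s02)) s02 <- est_s02
  }
  s2_post <- if (is.infinite(d0)) {
    rep(s02, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * s02 + d * s2) / (d0 + d)
  }
  names(s2_post) <- names(s2)
  beta <- fits$coefficients[, fits$coef]
  t_stat <- beta / sqrt(s2_post * fits$v)
  df_total <- d0 + d
  p <- 2 * pt(-abs(t_stat), df = df_total)
  structure(
    list(beta = beta, s2 = s2, s2_post = s2_post, t = t_stat, p = p,
         adj_p = bh_adjust(p), d0 = d0, s02 = s02, df = d,
         df_total = df_total, v = fits$v),
    class = "moderated_stats"
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, order-preserving, with step-up monotonicity
#'   enforced.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop_sp("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric())
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Call differential antigens
#'
#' @param stats `moderated_stats` from [ebayes_moderate()].
#' @param alpha unadjusted p-value cutoff (inclusive, default 0.05).
#' @return `differential_table` data.frame sorted by p: `antigen`, `FC`
#'   (ratio-scale case/control fold change, `2^log2FC`), `log2FC`, `t`,
#'   `p`, `adj_p`, `neg_log10_p`, `call` (`up`/`down`/`ns`).
#' @export
call_differential <- function(stats, alpha = 0.05) {
  tab <- data.frame(
    antigen = names(stats$beta),
    FC = 2^stats$beta,
    log2FC = stats$beta,
    t = stats$t,
    p = stats$p,
    adj_p = stats$adj_p,
    neg_log10_p = -log10(stats$p),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  tab$call <- "ns"
  tab$call[tab$p <= alpha & tab$FC > 1] <- "up"
  tab$call[tab$p <= alpha & tab$FC < 1] <- "down"
  tab <- tab[order(tab$p), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "alpha") <- alpha
  class(tab) <- c("differential_table", "data.frame")
  tab
}

#' Fit, moderate and call in one step
#'
#' @param amat [antigen_matrix()] (retained cells are used).
#' @param metadata `sample_metadata`.
#' @param alpha unadjusted p-value cutoff.
#' @param covariates covariates to adjust for (see [build_design()]).
#' @return a `differential_table` (see [call_differential()]); the
#'   `moderated_stats` are attached as attribute `"stats"`.
#' @export
run_differential <- function(amat, metadata, alpha = 0.05,
                             covariates = c("age", "sex")) {
  design <- build_design(amat, metadata, covariates)
  fits <- fit_linear_models(amat, design)
  stats <- ebayes_moderate(fits)
  tab <- call_differential(stats, alpha = alpha)
  attr(tab, "stats") <- stats
  tab
}
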