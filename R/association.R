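# Correlation of autoantibody levels with clinical covariates (severity
# score among scored cases, age across the cohort).

#' Product-moment correlation with pairwise-complete handling
#'
#' Thin, validated wrapper around `stats::cor.test`: incomplete pairs are
#' dropped, `n` is reported, p is two-sided from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `r`, `p`, `n`.
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop_sp("need at least 3 complete pairs, got ", n)
  if (sd(x) == 0 || sd(y) == 0) {
    stop_sp("correlation undefined: zero variance in ",
            if (sd(x) == 0) "x" else "y")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Correlate every retained antigen with a clinical covariate
#'
#' For `covariate = "ados2"` the analysis is restricted to case samples
#' with a severity score (pairwise-complete, per-antigen `n` reported);
#' for `"age"` all retained samples are used.
#'
#' @param amat an [antigen_matrix()] or plain matrix.
#' @param metadata `sample_metadata`.
#' @param covariate `"age"` or `"ados2"`.
#' @param antigens optional subset of antigen ids (default: all retained).
#' @return data.frame `antigen`, `covariate`, `r`, `p`, `n`, with summary
#'   counts (`n_negative`, `n_significant` at unadjusted p <= 0.05)
#'   attached as attribute `"summary"`.
#' @export
correlate_matrix <- function(amat, metadata, covariate = c("age", "ados2"),
                             antigens = NULL) {
  covariate <- match.arg(covariate)
  vals <- if (inherits(amat, "antigen_matrix")) retained_values(amat) else amat
  if (!is.null(antigens)) {
    missing_a <- setdiff(antigens, colnames(vals))
    if (length(missing_a)) stop_sp("antigen(s) not in matrix: ",
                                   paste(missing_a, collapse = ", "))
    vals <- vals[, antigens, drop = FALSE]
  }
  md <- metadata[match(rownames(vals), metadata$sample_id), , drop = FALSE]
  if (covariate == "ados2") {
    if (!"ados2" %in% names(md)) stop_sp("metadata has no ados2 column")
    keep <- md$diagnosis == "case" & !is.na(md$ados2)
    y <- md$ados2[keep]
  } else {
    keep <- !is.na(md$age)
    y <- md$age[keep]
  }
  if (sum(keep) < 3L) stop_sp("fewer than 3 samples with ", covariate)
  vals <- vals[keep, , drop = FALSE]
  res <- lapply(colnames(vals), function(a) {
    cr <- correlate(vals[, a], y)
    data.frame(antigen = a, covariate = covariate, r = cr$r, p = cr$p,
               n = cr$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "summary") <- list(
    n_antigens = nrow(out),
    n_negative = sum(out$r < 0),
    n_significant = sum(out$p <= 0.05),
    n_negative_significant = sum(out$r < 0 & out$p <= 0.05)
  )
  out
}
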