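# Set overrepresentation of the significant proteins against user-supplied
# annotation sets (GMT), with the tested universe defaulting to the
# filtration-retained panel.

#' Exact test on a 2x2 contingency table
#'
#' Fisher's exact test: hypergeometric probabilities conditional on the
#' margins, two-sided p by summing all tables whose probability does not
#' exceed the observed one.
#'
#' @param table 2x2 matrix (or something coercible) of non-negative
#'   integer counts.
#' @return list with `p` (two-sided), `odds_ratio` (sample odds ratio
#'   `ad/bc`) and `table`.
#' @export
exact_test_2x2 <- function(table) {
  tab <- matrix(as.numeric(table), 2L, 2L)
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab))) {
    stop_sp("table must hold non-negative integers")
  }
  r1 <- sum(tab[1L, ]); r2 <- sum(tab[2L, ])
  c1 <- sum(tab[, 1L]); c2 <- sum(tab[, 2L])
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    stop_sp("empty margin: exact test undefined")
  }
  n <- r1 + r2
  support <- max(0, c1 - r2):min(c1, r1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(tab[1L, 1L], r1, r2, c1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- (tab[1L, 1L] * tab[2L, 2L]) / (tab[1L, 2L] * tab[2L, 1L])
  list(p = p, odds_ratio = or, table = tab)
}

#' Gene-set overrepresentation
#'
#' One-sided hypergeometric enrichment of a query protein set against
#' annotation sets, restricted to a background universe (conventionally
#' the filtration-retained panel proteins).  Benjamini-Hochberg FDR is
#' computed across all tested terms; reported terms need at least
#' `min_overlap` query members and FDR below `fdr_cutoff`.
#'
#' @param query character vector of query proteins (must lie in
#'   `background`).
#' @param sets named list of protein sets (e.g. from [read_gmt()]);
#'   each set is intersected with the background before testing.
#' @param background character vector: the tested universe.
#' @param min_overlap minimum query members per reported term (default 2).
#' @param fdr_cutoff FDR filter on reported terms (default 0.05; use `Inf`
#'   to report every tested term).
#' @return data.frame sorted by FDR then p: `term`, `k` (overlap), `K`
#'   (term size in background), `n` (query size), `N` (background size),
#'   `p`, `fdr`, `members` (comma-joined overlap).
#' @export
overrepresentation <- function(query, sets, background, min_overlap = 2,
                               fdr_cutoff = 0.05) {
  background <- unique(background)
  if (!length(background)) stop_sp("empty background")
  query <- unique(query)
  outside <- setdiff(query, background)
  if (length(outside)) {
    stop_sp("query protein(s) not in background: ",
            paste(utils::head(outside, 10L), collapse = ", "))
  }
  N <- length(background)
  n <- length(query)
  sets_bg <- lapply(sets, intersect, background)
  tested <- names(sets_bg)[vapply(sets_bg, length, 1L) > 0L]
  rows <- lapply(tested, function(tm) {
    members <- intersect(query, sets_bg[[tm]])
    K <- length(sets_bg[[tm]])
    k <- length(members)
    data.frame(term = tm, k = k, K = K, n = n, N = N,
               p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               members = paste(sort(members), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      members = character(), stringsAsFactors = FALSE)
  }
  out$fdr <- if (nrow(out)) bh_adjust(out$p) else numeric()
  out <- out[out$k >= min_overlap & out$fdr < fdr_cutoff, , drop = FALSE]
  out <- out[order(out$fdr, out$p), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("term", "k", "K", "n", "N", "p", "fdr", "members")]
}
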