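# Shared fixtures and independent oracles used across the suite.

# ---- hand-written ATF fixtures ---------------------------------------------

tiny_gal_text <- function() {
  c("ATF\t1.0",
    "2\t5",
    '"Type=GenePix ArrayList V1.0"',
    '"BlockCount=2"',
    "Block\tRow\tColumn\tID\tName",
    "1\t1\t1\tP1\tProtein 1",
    "1\t1\t2\tP2\tProtein 2",
    "1\t2\t1\tP3\tProtein 3",
    "1\t2\t2\tNegCtrl_1\tNegative control",
    "2\t1\t1\tP1\tProtein 1",
    "2\t1\t2\tP2\tProtein 2",
    "2\t2\t1\tP3\tProtein 3",
    "2\t2\t2\tNegCtrl_1\tNegative control")
}

write_tiny_gal <- function(path = tempfile(fileext = ".gal")) {
  writeLines(tiny_gal_text(), path)
  path
}

# 4 antigens x quadruplicate, single block; intensities deterministic
tiny_gpr_lines <- function(fg = NULL, bg = NULL, flags = NULL) {
  ids <- rep(c("A1", "A2", "A3", "NegCtrl_1"), each = 4L)
  n <- length(ids)
  if (is.null(fg)) fg <- 1000 + seq_len(n)
  if (is.null(bg)) bg <- rep(100, n)
  if (is.null(flags)) flags <- rep(0L, n)
  c("ATF\t1.0",
    "1\t7",
    '"Type=GenePix Results 3"',
    "Block\tRow\tColumn\tID\tF532 Mean\tB532 Mean\tFlags",
    sprintf("1\t%d\t%d\t%s\t%s\t%s\t%d",
            (seq_len(n) - 1L) %/% 4L + 1L, (seq_len(n) - 1L) %% 4L + 1L,
            ids, fg, bg, flags))
}

write_tiny_gpr <- function(path = tempfile(fileext = ".gpr"), ...) {
  writeLines(tiny_gpr_lines(...), path)
  path
}

tiny_gpr_layout <- function() {
  ids <- rep(c("A1", "A2", "A3", "NegCtrl_1"), each = 4L)
  layout <- data.frame(
    block = 1L,
    row = (seq_along(ids) - 1L) %/% 4L + 1L,
    col = (seq_along(ids) - 1L) %% 4L + 1L,
    antigen_id = ids,
    control_flag = ifelse(grepl("NegCtrl", ids), "negative_control", "antigen"),
    stringsAsFactors = FALSE
  )
  class(layout) <- c("gal_layout", "data.frame")
  layout
}

# ---- small random amino-acid sequences -------------------------------------

random_aa <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# ---- independent oracles ----------------------------------------------------

# Exhaustive global-alignment score: enumerates every alignment path,
# charging gap_open + gap_ext for the first position of each gap run and
# gap_ext for continuations (run-based affine scoring).  Exponential;
# only usable for short sequences.
enum_align_score <- function(a, b, submat, gap_open = 10, gap_ext = 0.5) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  na <- length(av); nb <- length(bv)
  best <- -Inf
  rec <- function(i, j, score, last) {
    if (i > na && j > nb) {
      if (score > best) best <<- score
      return(invisible())
    }
    if (i <= na && j <= nb) rec(i + 1L, j + 1L, score + submat[av[i], bv[j]], "M")
    if (i <= na) rec(i + 1L, j, score - if (identical(last, "X")) gap_ext else gap_open + gap_ext, "X")
    if (j <= nb) rec(i, j + 1L, score - if (identical(last, "Y")) gap_ext else gap_open + gap_ext, "Y")
  }
  rec(1L, 1L, 0, "start")
  best
}

# Literal step-up definition of Benjamini-Hochberg: adjusted p for the
# k-th smallest p is min over l >= k of p_(l) * m / l, capped at 1.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj_sorted <- vapply(seq_len(m), function(k) {
    min(1, min(sorted[k:m] * m / (k:m)))
  }, 1)
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# Exact 2x2 two-sided p via explicit factorial enumeration over the
# conditional support (independent of dhyper).
brute_fisher_2x2 <- function(tab) {
  tab <- matrix(as.numeric(tab), 2L, 2L)
  r1 <- sum(tab[1L, ]); r2 <- sum(tab[2L, ]); c1 <- sum(tab[, 1L])
  n <- r1 + r2
  lprob <- function(x) {
    lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  }
  support <- max(0, c1 - r2):min(c1, r1)
  probs <- exp(lprob(support))
  p_obs <- exp(lprob(tab[1L, 1L]))
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# High-precision product-moment correlation from raw sums.
brute_cor <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy / sqrt(sxx * syy)
}

# One shared small synthetic study per session (generation is the
# expensive part of many preprocess tests).
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_study(
        sim_config(n_cases = 20, n_controls = 10, n_antigens = 60, n_psa = 2),
        seed = 7)
    }
    cache
  }
})
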