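# Spot-level preprocessing: background subtraction and log2 transform,
# replicate CV filtering, aggregation, negative-control filtration (NCF),
# polyspecific-sample (PSA) detection, cyclic loess normalization and
# empirical-Bayes batch correction.
#
# Fixed stage order (recorded in provenance):
#   net intensity -> CV filter -> aggregate -> PSA detection ->
#   NCF -> cyclic loess -> batch correction
# PSA samples are detected on the aggregated matrix and masked from every
# later computation.

#' Log2 net intensity per spot
#'
#' Subtracts the local background from the foreground intensity and takes
#' log2 of the result, flooring non-positive nets at `floor` so the log is
#' defined.  Floored spots are marked.
#'
#' @param spots `spot_records` (see [read_gpr()]).
#' @param floor linear-scale floor for the net intensity (default 1, i.e.
#'   log2 net 0).
#' @return `spots` with added columns `net_linear`, `log2_net`, `floored`.
#' @export
net_intensity <- function(spots, floor = 1) {
  stopifnot(floor > 0)
  if (any(spots$fg_mean < 0 | spots$bg_mean < 0)) {
    stop_sp("negative raw intensity at spot row(s) ",
            paste(utils::head(which(spots$fg_mean < 0 | spots$bg_mean < 0), 10L),
                  collapse = ", "))
  }
  if (any(!is.finite(spots$fg_mean) | !is.finite(spots$bg_mean))) {
    stop_sp("non-finite raw intensity")
  }
  raw_net <- spots$fg_mean - spots$bg_mean
  spots$net_linear <- pmax(raw_net, floor)
  spots$log2_net <- log2(spots$net_linear)
  spots$floored <- raw_net < floor
  spots
}

#' Replicate CV filter
#'
#' Computes the percent coefficient of variation (100*sd/mean, on the
#' linear net-intensity scale) across the technical replicates of each
#' (sample, antigen) group and flags groups exceeding `threshold`.
#' Scanner-flagged spots (`flag < 0`) are dropped before the computation.
#'
#' @param spots output of [net_intensity()].
#' @param threshold CV% cutoff (default 20).
#' @return data.frame with one row per (sample, antigen) group: `cv`,
#'   `n_replicates`, `flagged`, `reason` (`""`, `"high_cv"` or
#'   `"nonpositive_mean"`).
#' @export
cv_filter <- function(spots, threshold = 20) {
  stopifnot("log2_net" %in% names(spots))
  good <- spots[spots$flag >= 0L & spots$control_flag == "antigen", , drop = FALSE]
  key <- paste(good$sample_id, good$antigen_id, sep = "\r")
  grp <- factor(key, levels = unique(key))
  n_rep <- as.integer(tapply(good$net_linear, grp, length))
  mu <- as.numeric(tapply(good$net_linear, grp, mean))
  sdev <- as.numeric(tapply(good$net_linear, grp, sd))
  cv <- 100 * sdev / mu
  first <- !duplicated(key)
  out <- data.frame(
    sample_id = good$sample_id[first],
    antigen_id = good$antigen_id[first],
    n_replicates = n_rep,
    cv = cv,
    stringsAsFactors = FALSE
  )
  out$reason <- ""
  out$reason[!is.na(mu) & mu <= 0] <- "nonpositive_mean"
  out$reason[out$reason == "" & !is.na(cv) & cv > threshold] <- "high_cv"
  out$flagged <- out$reason != ""
  attr(out, "threshold") <- threshold
  out
}

#' Aggregate technical replicates into a sample x antigen matrix
#'
#' Cell value is the mean log2 net intensity of the retained (unflagged,
#' CV-passing) replicates.  Cells with fewer than two retained replicates
#' are set missing and imputed by the antigen median; antigens missing in
#' more than half the samples are excluded with reason `"sparse"`.
#'
#' @param spots output of [net_intensity()].
#' @param cv_table output of [cv_filter()]; pass `NULL` to skip CV masking.
#' @return an [antigen_matrix()].
#' @export
aggregate_replicates <- function(spots, cv_table = NULL) {
  good <- spots[spots$flag >= 0L & spots$control_flag == "antigen", , drop = FALSE]
  if (!is.null(cv_table)) {
    bad_key <- paste(cv_table$sample_id, cv_table$antigen_id, sep = "\r")[cv_table$flagged]
    key <- paste(good$sample_id, good$antigen_id, sep = "\r")
    good <- good[!key %in% bad_key, , drop = FALSE]
  }
  samples <- unique(spots$sample_id)
  antigens <- unique(spots$antigen_id[spots$control_flag == "antigen"])
  si <- match(good$sample_id, samples)
  ai <- match(good$antigen_id, antigens)
  ncell <- length(samples) * length(antigens)
  idx <- (ai - 1L) * length(samples) + si
  sums <- counts <- matrix(0, length(samples), length(antigens),
                           dimnames = list(samples, antigens))
  agg <- rowsum(good$log2_net, idx)
  sums[as.integer(rownames(agg))] <- agg[, 1L]
  counts[] <- tabulate(idx, nbins = ncell)
  values <- sums / counts
  values[counts < 2L] <- NA_real_

  antigen_status <- setNames(rep("retained", length(antigens)), antigens)
  missing_frac <- colMeans(is.na(values))
  antigen_status[missing_frac > 0.5] <- "sparse"
  imputed <- matrix(FALSE, nrow(values), ncol(values), dimnames = dimnames(values))
  for (a in which(missing_frac > 0 & missing_frac <= 0.5)) {
    na_rows <- is.na(values[, a])
    values[na_rows, a] <- median(values[, a], na.rm = TRUE)
    imputed[na_rows, a] <- TRUE
  }
  antigen_matrix(values, antigen_status = antigen_status,
                 provenance = c(
                   sprintf("net_intensity"),
                   if (!is.null(cv_table))
                     sprintf("cv_filter(threshold=%s)", attr(cv_table, "threshold")),
                   sprintf("aggregate_replicates(imputed=%d)", sum(imputed))),
                 imputed = imputed)
}

#' Per-sample negative-control replicate profiles
#'
#' One column per negative-control spot (coordinate), rows = samples, cell
#' = log2 net intensity of that spot in that sample.  Used both for the
#' data-adaptive NCF threshold (self-correlation of the replicate
#' profiles) and, averaged, as the negative-control reference profile.
#'
#' @param spots output of [net_intensity()].
#' @return numeric matrix samples x negative-control spots.
#' @export
negctrl_profiles <- function(spots) {
  nc <- spots[spots$control_flag == "negative_control" & spots$flag >= 0L, , drop = FALSE]
  if (!nrow(nc)) stop_sp("no negative-control spots present")
  samples <- unique(spots$sample_id)
  coord <- paste0("nc_", nc$block, "_", nc$row, "_", nc$col)
  cols <- unique(coord)
  prof <- matrix(NA_real_, length(samples), length(cols),
                 dimnames = list(samples, cols))
  prof[cbind(match(nc$sample_id, samples), match(coord, cols))] <- nc$log2_net
  prof
}

#' Negative-control filtration (NCF)
#'
#' Excludes antigens whose cross-sample profile tracks the non-reactive
#' negative-control protein, i.e. carries no serological information.  For
#' each retained antigen the correlation (across retained samples) with
#' the mean negative-control profile is computed.  Instead of a fixed
#' cutoff, the threshold is set data-adaptively at the 5th percentile of
#' the pairwise correlations among the negative-control replicate profiles
#' themselves: an antigen is excluded when it correlates with the control
#' at least as strongly as the control's own replicates correlate with
#' each other AND its median intensity sits below the 75th percentile of
#' the negative-control intensity distribution.  Constant antigens are
#' excluded with reason `"constant"`.
#'
#' @param amat an [antigen_matrix()] (aggregated, PSA samples masked).
#' @param nc_profiles matrix from [negctrl_profiles()].
#' @return list with the updated `amat` and `stats` (`threshold`,
#'   `correlations`, `nc_intensity_q75`, counts).
#' @export
negative_control_filter <- function(amat, nc_profiles) {
  keep_s <- amat$sample_status == "retained"
  if (sum(keep_s) < 8L) stop_sp("NCF needs at least 8 retained samples")
  nc <- nc_profiles[rownames(amat$values)[keep_s], , drop = FALSE]
  nc <- nc[, colSums(!is.na(nc)) >= 3L, drop = FALSE]
  if (ncol(nc) < 2L) {
    stop_sp("NCF threshold undefined: fewer than 2 usable negative-control replicate profiles")
  }
  self_cor <- cor(nc, use = "pairwise.complete.obs")[upper.tri(diag(ncol(nc)))]
  self_cor <- self_cor[!is.na(self_cor)]
  if (!length(self_cor)) stop_sp("NCF threshold undefined: no overlapping negative-control replicate pairs")
  threshold <- as.numeric(quantile(self_cor, 0.05))
  nc_mean <- rowMeans(nc, na.rm = TRUE)
  nc_q75 <- as.numeric(quantile(as.vector(nc), 0.75, na.rm = TRUE))

  vals <- amat$values[keep_s, , drop = FALSE]
  imputed <- if (is.null(amat$imputed)) {
    matrix(FALSE, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  } else {
    amat$imputed[keep_s, , drop = FALSE]
  }
  status <- amat$antigen_status
  cors <- setNames(rep(NA_real_, ncol(vals)), colnames(vals))
  for (a in which(status == "retained")) {
    x <- vals[, a]
    if (sd(x) == 0) {
      status[a] <- "constant"
      next
    }
    # imputed cells carry no measurement; correlate over observed cells
    obs <- !imputed[, a]
    if (sum(obs) < 8L) obs <- rep(TRUE, length(x))
    r <- if (sd(x[obs]) == 0) 1 else cor(x[obs], nc_mean[obs])
    cors[a] <- r
    if (r >= threshold && median(x) < nc_q75) status[a] <- "ncf_excluded"
  }
  amat$antigen_status <- status
  amat <- add_provenance(amat, sprintf("negative_control_filter(threshold=%.4f)", threshold))
  list(amat = amat,
       stats = list(threshold = threshold,
                    self_correlations = self_cor,
                    correlations = cors,
                    nc_intensity_q75 = nc_q75,
                    n_excluded = sum(status == "ncf_excluded"),
                    n_constant = sum(status == "constant"),
                    n_retained = sum(status == "retained")))
}

#' Detect polyspecific-antibody (PSA) samples
#'
#' A PSA serum shows broad low-affinity reactivity: its signal exceeds the
#' per-antigen robust upper bound (median + 3 MAD across samples) on a
#' large fraction of antigens.  A sample is flagged when its breadth
#' exceeds both the cohort's own robust bound (median + 3 MAD of the
#' breadth distribution) and the absolute minimum `breadth_min`.
#' Antigens with zero MAD contribute no exceedances, so a perfectly
#' homogeneous matrix flags nothing.
#'
#' @param amat an [antigen_matrix()] (aggregated).
#' @param breadth_min minimum breadth for a flag (default 0.25).
#' @return list with the updated `amat` (flagged samples masked
#'   `"psa_excluded"`), `breadth` (per-sample score) and `flagged`.
#' @export
detect_psa <- function(amat, breadth_min = 0.25) {
  vals <- retained_values(amat, samples = FALSE)
  med <- apply(vals, 2L, median)
  madv <- apply(vals, 2L, mad)
  usable <- madv > 0
  if (!any(usable)) {
    return(list(amat = add_provenance(amat, "detect_psa(flagged=0)"),
                breadth = setNames(rep(0, nrow(vals)), rownames(vals)),
                flagged = character()))
  }
  upper <- med[usable] + 3 * madv[usable]
  exceeds <- sweep(vals[, usable, drop = FALSE], 2L, upper, `>`)
  breadth <- rowMeans(exceeds)
  cutoff <- max(median(breadth) + 3 * mad(breadth), breadth_min)
  flagged <- names(breadth)[breadth > cutoff]
  amat$sample_status[flagged] <- "psa_excluded"
  amat <- add_provenance(amat, sprintf("detect_psa(flagged=%d)", length(flagged)))
  list(amat = amat, breadth = breadth, flagged = flagged)
}

#' Cyclic loess normalization
#'
#' Normalizes every pair of samples to each other: for a pair (i, j),
#' M = xi - xj is smoothed against A = (xi + xj)/2 with a locally weighted
#' regression and half the fitted trend is subtracted from xi and added to
#' xj, removing intensity-dependent distortions while preserving each
#' antigen's grand mean exactly.  With more than `max_full` retained
#' samples a seeded random subset of pairs (3 per sample per iteration) is
#' cycled instead of all pairs.
#'
#' @param amat an [antigen_matrix()] (or plain matrix).
#' @param span loess span (fraction of points in the local window).
#' @param iterations number of cycles over the pair set.
#' @param max_full largest sample count for which all pairs are cycled.
#' @param seed seed for the pair subsample (only used when n > `max_full`).
#' @return object of the same type with normalized retained cells.
#' @export
cyclic_loess <- function(amat, span = 0.7, iterations = 3, max_full = 50,
                         seed = 1) {
  is_amat <- inherits(amat, "antigen_matrix")
  vals <- if (is_amat) retained_values(amat) else amat
  n <- nrow(vals)
  if (n < 2L) stop_sp("cyclic loess needs at least 2 samples")
  x <- t(vals)  # antigens x samples: columns are samples
  pair_sets <- with_seed(seed, {
    lapply(seq_len(iterations), function(it) {
      if (n <= max_full) {
        combn(n, 2L)
      } else {
        k <- 3L * n
        i <- sample.int(n, k, replace = TRUE)
        j <- sample.int(n, k, replace = TRUE)
        keep <- i != j
        rbind(pmin(i, j)[keep], pmax(i, j)[keep])
      }
    })
  })
  for (it in seq_len(iterations)) {
    pairs <- pair_sets[[it]]
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1L, p]; j <- pairs[2L, p]
      M <- x[, i] - x[, j]
      A <- (x[, i] + x[, j]) / 2
      if (var(A) == 0) {
        f <- rep(mean(M), length(M))
      } else {
        lo <- lowess(A, M, f = span)
        f <- approx(lo$x, lo$y, xout = A, rule = 2, ties = "ordered")$y
      }
      x[, i] <- x[, i] - f / 2
      x[, j] <- x[, j] + f / 2
    }
  }
  out <- t(x)
  if (!is_amat) return(out)
  amat$values[rownames(out), colnames(out)] <- out
  add_provenance(amat, sprintf("cyclic_loess(span=%s,iterations=%d)", span, iterations))
}

#' Empirical-Bayes batch correction
#'
#' Adjusts for known processing batches with the ComBat empirical-Bayes
#' model (additive location and multiplicative scale effects per antigen,
#' shrunk toward batch-level priors), preserving the biological covariates
#' supplied in `covariates`.  With a single batch the input is returned
#' unchanged.
#'
#' @param amat an [antigen_matrix()].
#' @param metadata `sample_metadata` covering the retained samples.
#' @param covariates character vector of metadata columns to protect
#'   (default diagnosis, age, sex).
#' @return the corrected `antigen_matrix`.
#' @export
batch_correct <- function(amat, metadata,
                          covariates = c("diagnosis", "age", "sex")) {
  vals <- retained_values(amat)
  md <- metadata[match(rownames(vals), metadata$sample_id), , drop = FALSE]
  if (any(is.na(md$sample_id))) stop_sp("metadata missing for retained sample(s)")
  batch <- factor(md$batch)
  if (nlevels(batch) == 1L) {
    return(add_provenance(amat, "batch_correct(single_batch=identity)"))
  }
  sizes <- table(batch)
  if (any(sizes < 3L)) {
    stop_sp("batch(es) with fewer than 3 samples: ",
            paste(names(sizes)[sizes < 3L], collapse = ", "))
  }
  mod <- model.matrix(stats::reformulate(covariates), data = md)
  contrasts <- model.matrix(~batch)[, -1L, drop = FALSE]
  if (qr(cbind(mod, contrasts))$rank < ncol(mod) + ncol(contrasts)) {
    batch_dummies <- model.matrix(~ batch - 1)
    aliased <- covariates[vapply(covariates, function(cv) {
      x <- if (is.numeric(md[[cv]])) md[[cv]] else as.numeric(factor(md[[cv]]))
      qr(cbind(batch_dummies, x))$rank <= nlevels(batch)
    }, TRUE)]
    stop_sp("batch is confounded with covariate(s): ",
            paste(if (length(aliased)) aliased else "the preserved design", collapse = ", "),
            " (perfect aliasing; batch effects not estimable)")
  }
  corrected <- suppressMessages(
    sva::ComBat(dat = t(vals), batch = batch, mod = mod, par.prior = TRUE)
  )
  amat$values[rownames(vals), colnames(vals)] <- t(corrected)
  add_provenance(amat, sprintf("batch_correct(batches=%d)", nlevels(batch)))
}

#' Run the full preprocessing chain
#'
#' net intensity -> CV filter -> replicate aggregation -> PSA detection ->
#' NCF -> cyclic loess -> batch correction, with a QC report reconciling
#' every exclusion.
#'
#' @param spots `spot_records` for all samples.
#' @param metadata `sample_metadata`.
#' @param floor,cv_threshold,psa_breadth_min,loess_span,loess_iterations,seed
#'   stage parameters (see the individual stage functions).
#' @return list `amat` (final [antigen_matrix()]) and `qc` (QC report list).
#' @export
preprocess_study <- function(spots, metadata, floor = 1, cv_threshold = 20,
                             psa_breadth_min = 0.25, loess_span = 0.7,
                             loess_iterations = 3, seed = 1) {
  spots <- net_intensity(spots, floor = floor)
  cv <- cv_filter(spots, threshold = cv_threshold)
  amat <- aggregate_replicates(spots, cv)
  psa <- detect_psa(amat, breadth_min = psa_breadth_min)
  amat <- psa$amat
  ncf <- negative_control_filter(amat, negctrl_profiles(spots))
  amat <- ncf$amat
  amat <- cyclic_loess(amat, span = loess_span, iterations = loess_iterations,
                       seed = seed)
  amat <- batch_correct(amat, metadata)
  status <- amat$antigen_status
  qc <- list(
    n_samples = nrow(amat$values),
    n_antigens = ncol(amat$values),
    cv_threshold = cv_threshold,
    cv_flagged_groups = sum(cv$flagged),
    cv_mean = mean(cv$cv, na.rm = TRUE),
    psa_breadth = psa$breadth,
    psa_flagged = psa$flagged,
    ncf_threshold = ncf$stats$threshold,
    ncf_correlations = ncf$stats$correlations,
    counts = list(
      antigens_tested = length(status),
      retained = sum(status == "retained"),
      ncf_excluded = sum(status == "ncf_excluded"),
      sparse = sum(status == "sparse"),
      constant = sum(status == "constant"),
      samples_retained = sum(amat$sample_status == "retained"),
      samples_psa_excluded = sum(amat$sample_status == "psa_excluded")
    )
  )
  stopifnot(with(qc$counts, retained + ncf_excluded + sparse + constant) == qc$counts$antigens_tested)
  list(amat = amat, qc = qc)
}
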