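# Truth-known synthetic serum-array studies.  The generator emulates the
# structure of a two-batch autoantibody screen: quadruplicate spots per
# antigen, log-normal foreground/background intensities, a non-reactive
# negative-control protein, a minority of truly reactive antigens, planted
# case/control effects, age/sex covariate imbalance between groups, and a
# few polyspecific (PSA) sera with broad low-affinity reactivity.

#' Simulation configuration
#'
#' Defaults mirror the cohort structure of a 121-sample two-batch screen:
#' 93 cases vs 28 controls with the cases younger (8.3 +/- 2.3 vs
#' 11.3 +/- 2.1 years) and more often male (73/93 vs 14/28), 400 antigens
#' of which 25% are truly reactive, planted case/control effects spanning
#' roughly the 0.7-1.7 fold-change band on the ratio scale, and 9 PSA
#' samples.
#'
#' @param n_cases,n_controls group sizes.
#' @param n_antigens number of probed antigens (negative-control and buffer
#'   spots are added on top).
#' @param frac_reactive fraction of antigens that are truly reactive
#'   (carry serological signal above the negative-control baseline).
#' @param frac_differential fraction of antigens with a planted
#'   case/control effect; must not exceed `frac_reactive`.
#' @param effect_range range of |log2 effect| for differential antigens.
#' @param prop_up probability a planted effect is positive (higher in cases).
#' @param n_batches,batch_loc,batch_scale number of processing batches and
#'   the additive log2 location shift / multiplicative scale factor of each
#'   non-reference batch (per-antigen jitter is added around these).
#' @param n_psa number of planted polyspecific samples.
#' @param psa_breadth_frac,psa_elevation fraction of antigens a PSA sample
#'   reacts against, and the mean log2 elevation on those antigens.
#' @param age_slope_mean,age_slope_sd distribution of per-antigen age
#'   slopes (log2 RFU per year) on reactive antigens; the default mild
#'   negative slope emulates declining autoantibody signal with age.
#' @param sex_offset_sd sd of per-antigen male-vs-female offsets on
#'   reactive antigens.
#' @param mu_nc baseline negative-control log2 net intensity.
#' @param sigma_shared sd of the shared per-sample baseline factor that
#'   makes non-reactive antigens track the negative-control profile.
#' @param sigma_nonreactive,sigma_reactive per-cell biological noise sd
#'   (log2) for non-reactive / reactive antigens.
#' @param reactive_offset_range range of antigen-specific mean elevations
#'   (log2) of reactive antigens above the baseline.
#' @param sdlog_spot sd (natural log) of per-spot multiplicative noise;
#'   0.12 gives replicate CVs near 12% (typical protein-array precision), under the 20% filter.
#' @param frac_noisy,frac_flagged fraction of spots with inflated noise
#'   (to exercise the CV filter) and of scanner-flagged spots.
#' @param bg_meanlog,bg_sdlog log-normal parameters of local background.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_cases = 93, n_controls = 28,
                       n_antigens = 400,
                       frac_reactive = 0.25,
                       frac_differential = 0.05,
                       effect_range = c(0.2, 1.2),
                       prop_up = 0.15,
                       n_batches = 2,
                       batch_loc = 0.4,
                       batch_scale = 1.15,
                       n_psa = 9,
                       psa_breadth_frac = 0.9,
                       psa_elevation = 3,
                       age_slope_mean = -0.02,
                       age_slope_sd = 0.015,
                       sex_offset_sd = 0.05,
                       mu_nc = 7,
                       sigma_shared = 0.4,
                       sigma_nonreactive = 0.05,
                       sigma_reactive = 0.6,
                       reactive_offset_range = c(1.5, 4),
                       sdlog_spot = 0.12,
                       frac_noisy = 0.01,
                       frac_flagged = 0.005,
                       bg_meanlog = log(150),
                       bg_sdlog = 0.2) {
  cfg <- as.list(environment())
  if (cfg$frac_differential > cfg$frac_reactive) {
    stop_sp("infeasible config: frac_differential (", cfg$frac_differential,
            ") exceeds frac_reactive (", cfg$frac_reactive, ")")
  }
  stopifnot(cfg$n_cases > 0, cfg$n_controls > 0, cfg$n_antigens > 1,
            cfg$n_psa <= cfg$n_cases + cfg$n_controls,
            cfg$n_batches >= 1)
  class(cfg) <- "sim_config"
  cfg
}

sim_metadata <- function(cfg) {
  n <- cfg$n_cases + cfg$n_controls
  ids <- sprintf("S%03d", seq_len(n))
  diagnosis <- c(rep("case", cfg$n_cases), rep("control", cfg$n_controls))
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  age <- numeric(n)
  age[diagnosis == "case"] <- round(clip(rnorm(cfg$n_cases, 8.26, 2.29), 6, 15), 1)
  age[diagnosis == "control"] <- round(clip(rnorm(cfg$n_controls, 11.29, 2.05), 6, 15), 1)
  # fixed sex imbalance: most cases male, controls balanced
  n_male_cases <- round(cfg$n_cases * 73 / 93)
  n_male_ctrl <- round(cfg$n_controls * 14 / 28)
  sex <- character(n)
  sex[diagnosis == "case"] <- sample(c(rep("M", n_male_cases),
                                       rep("F", cfg$n_cases - n_male_cases)))
  sex[diagnosis == "control"] <- sample(c(rep("M", n_male_ctrl),
                                          rep("F", cfg$n_controls - n_male_ctrl)))
  # batches stratified within diagnosis so batch is never aliased with group
  batch <- character(n)
  for (dx in c("case", "control")) {
    idx <- which(diagnosis == dx)
    batch[idx] <- paste0("B", rep_len(seq_len(cfg$n_batches), length(idx)))
  }
  # severity scored for roughly half the cases (50-of-93 pattern)
  ados2 <- rep(NA_real_, n)
  scored <- sample(which(diagnosis == "case"), round(cfg$n_cases * 50 / 93))
  ados2[scored] <- round(clip(rnorm(length(scored), 6.39, 1.47), 1, 10), 1)
  scq <- rep(NA_real_, n)
  scq[diagnosis == "control"] <- round(clip(rnorm(cfg$n_controls, 5.71, 3.35), 0, 20), 1)
  md <- data.frame(sample_id = ids, diagnosis = diagnosis, age = age, sex = sex,
                   batch = batch, ados2 = ados2, scq = scq,
                   stringsAsFactors = FALSE)
  validate_metadata(md)
}

sim_truth <- function(cfg, metadata, seed) {
  n_a <- cfg$n_antigens
  antigens <- sprintf("Ag%04d", seq_len(n_a))
  n_reactive <- round(cfg$frac_reactive * n_a)
  n_diff <- round(cfg$frac_differential * n_a)
  reactive <- sort(sample(antigens, n_reactive))
  differential <- sort(sample(reactive, n_diff))
  effect <- numeric(0)
  if (n_diff > 0) {
    magnitude <- runif(n_diff, cfg$effect_range[[1L]], cfg$effect_range[[2L]])
    sign <- ifelse(runif(n_diff) < cfg$prop_up, 1, -1)
    effect <- setNames(magnitude * sign, differential)
  }
  age_slope <- setNames(rep(0, n_a), antigens)
  sex_offset <- setNames(rep(0, n_a), antigens)
  age_slope[reactive] <- rnorm(n_reactive, cfg$age_slope_mean, cfg$age_slope_sd)
  sex_offset[reactive] <- rnorm(n_reactive, 0, cfg$sex_offset_sd)
  batches <- paste0("B", seq_len(cfg$n_batches))
  batch_shifts <- lapply(seq_along(batches), function(b) {
    if (b == 1L) list(location = 0, scale = 1)
    else list(location = cfg$batch_loc, scale = cfg$batch_scale)
  })
  names(batch_shifts) <- batches
  psa <- sort(sample(metadata$sample_id, cfg$n_psa))
  structure(
    list(reactive_antigens = reactive,
         differential_antigens = effect,
         batch_shifts = batch_shifts,
         psa_samples = psa,
         covariate_effects = list(age_slope = age_slope, sex_offset = sex_offset),
         seed = seed),
    class = "simulation_truth"
  )
}

# Sample x antigen matrix of true log2 net intensities (biological layer:
# reactivity, planted effects, covariates, PSA, batch; no spot noise).
sim_values <- function(cfg, metadata, truth) {
  n <- nrow(metadata)
  n_a <- cfg$n_antigens
  antigens <- names(truth$covariate_effects$age_slope)
  reactive <- antigens %in% truth$reactive_antigens
  u <- rnorm(n, 0, cfg$sigma_shared)                      # shared baseline factor
  base <- setNames(rep(NA_real_, n_a), antigens)
  # non-reactive spots all carry the same baseline (background + secondary
  # antibody) signal, so their antigen-to-antigen offsets are small
  # relative to the control's sample-to-sample spread
  base[!reactive] <- cfg$mu_nc + rnorm(sum(!reactive), 0, 0.1)
  base[reactive] <- cfg$mu_nc + runif(sum(reactive),
                                      cfg$reactive_offset_range[[1L]],
                                      cfg$reactive_offset_range[[2L]])
  case <- as.numeric(metadata$diagnosis == "case")
  male <- as.numeric(metadata$sex == "M")
  age_c <- metadata$age - 9      # centred near the cohort mean
  effect <- setNames(rep(0, n_a), antigens)
  effect[names(truth$differential_antigens)] <- truth$differential_antigens

  values <- matrix(rep(base, each = n), nrow = n, ncol = n_a,
                   dimnames = list(metadata$sample_id, antigens))
  # shared factor: full loading on non-reactive antigens, weak on reactive
  loading <- ifelse(reactive, 0.2, 1)
  values <- values + outer(u, loading)
  values <- values + outer(case, effect)
  values <- values + outer(age_c, truth$covariate_effects$age_slope)
  values <- values + outer(male, truth$covariate_effects$sex_offset)
  noise_sd <- ifelse(reactive, cfg$sigma_reactive, cfg$sigma_nonreactive)
  values <- values + matrix(rnorm(n * n_a), n, n_a) %*% diag(noise_sd)

  # polyspecific sera: broad elevation across a random swath of antigens
  for (s in truth$psa_samples) {
    hit <- runif(n_a) < cfg$psa_breadth_frac
    values[s, hit] <- values[s, hit] + rnorm(sum(hit), cfg$psa_elevation, 0.5)
  }

  # batch effects: per-antigen location/scale around the batch-level shift,
  # applied to every spotted protein on the slide, negative control included
  negctrl <- cfg$mu_nc + u + rnorm(n, 0, 0.05)
  for (b in names(truth$batch_shifts)) {
    sh <- truth$batch_shifts[[b]]
    rows <- metadata$batch == b
    if (!any(rows) || (sh$location == 0 && sh$scale == 1)) next
    gamma <- rnorm(n_a + 1L, sh$location, 0.1)
    delta <- exp(rnorm(n_a + 1L, log(sh$scale), 0.05))
    centred <- sweep(values[rows, , drop = FALSE], 2L, base)
    values[rows, ] <- sweep(sweep(centred, 2L, delta[-1L], `*`), 2L,
                            base + gamma[-1L], `+`)
    negctrl[rows] <- cfg$mu_nc + gamma[[1L]] +
      delta[[1L]] * (negctrl[rows] - cfg$mu_nc)
  }
  list(values = values, negctrl = negctrl, shared_factor = u)
}

#' Simulate an aggregated expression matrix (no spot layer)
#'
#' Matrix-level counterpart of [generate_study()]: returns the true log2
#' net-intensity matrix directly, skipping spot replication and file IO.
#' Useful for Monte-Carlo studies of the statistical stages.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the run is deterministic given `config` + `seed`.
#' @return list with `values` (samples x antigens matrix), `metadata`,
#'   `truth` and `negctrl` (per-sample true negative-control profile).
#' @export
simulate_matrix <- function(config = sim_config(), seed = 1) {
  with_seed(seed, {
    metadata <- sim_metadata(config)
    truth <- sim_truth(config, metadata, seed)
    sim <- sim_values(config, metadata, truth)
    list(values = sim$values, metadata = metadata, truth = truth,
         negctrl = sim$negctrl)
  })
}

#' Generate a complete synthetic study
#'
#' Produces a GAL layout, per-sample spot records (quadruplicate spots per
#' antigen plus quadruplicate negative-control and buffer spots), sample
#' metadata, and the simulation truth.  If `dir` is given, writes
#' `layout.gal`, one `<sample>.gpr` per sample, `metadata.tsv` and
#' `truth.json` there.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; outputs are byte-identical for a fixed
#'   `config` + `seed`.
#' @param dir optional output directory (created if needed).
#' @return list with `gal`, `spots` (stacked `spot_records` for all
#'   samples), `metadata`, `truth`, and `paths` when `dir` was given.
#' @export
generate_study <- function(config = sim_config(), seed = 1, dir = NULL) {
  study <- with_seed(seed, {
    metadata <- sim_metadata(config)
    truth <- sim_truth(config, metadata, seed)
    sim <- sim_values(config, metadata, truth)
    n <- nrow(metadata)
    n_a <- config$n_antigens
    antigens <- colnames(sim$values)

    # layout: quadruplicates laid out consecutively, 40 spots per row
    ids <- c(antigens, "NegCtrl_1", "Buffer_1")
    spot_ids <- rep(ids, each = 4L)
    n_spots <- length(spot_ids)
    n_cols <- 40L
    gal <- data.frame(
      block = 1L,
      row = as.integer((seq_len(n_spots) - 1L) %/% n_cols + 1L),
      col = as.integer((seq_len(n_spots) - 1L) %% n_cols + 1L),
      antigen_id = spot_ids,
      control_flag = rep(c("antigen", "negative_control", "buffer"),
                         times = c(4L * n_a, 4L, 4L)),
      stringsAsFactors = FALSE
    )
    class(gal) <- c("gal_layout", "data.frame")

    # spot-level intensities: true value per (sample, spot id), then
    # per-spot multiplicative noise and additive local background
    truth_log2 <- cbind(sim$values,
                        NegCtrl_1 = sim$negctrl,
                        Buffer_1 = rep(1, n))  # buffer: essentially background
    spot_true <- truth_log2[, spot_ids, drop = FALSE]      # n x n_spots
    sdlog <- matrix(config$sdlog_spot, n, n_spots)
    sdlog[runif(n * n_spots) < config$frac_noisy] <- 0.5
    net <- 2^spot_true * exp(matrix(rnorm(n * n_spots), n, n_spots) * sdlog)
    bg <- matrix(rlnorm(n * n_spots, config$bg_meanlog, config$bg_sdlog), n, n_spots)
    flags <- matrix(0L, n, n_spots)
    flags[runif(n * n_spots) < config$frac_flagged] <- -100L

    spots <- data.frame(
      sample_id = rep(metadata$sample_id, each = n_spots),
      antigen_id = rep(spot_ids, times = n),
      control_flag = rep(gal$control_flag, times = n),
      block = rep(gal$block, times = n),
      row = rep(gal$row, times = n),
      col = rep(gal$col, times = n),
      replicate = rep(rep(1:4, times = length(ids)), times = n),
      fg_mean = as.vector(t(net + bg)),
      bg_mean = as.vector(t(bg)),
      flag = as.vector(t(flags)),
      stringsAsFactors = FALSE
    )
    class(spots) <- c("spot_records", "data.frame")
    list(gal = gal, spots = spots, metadata = metadata, truth = truth)
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(gal = file.path(dir, "layout.gal"),
                  metadata = file.path(dir, "metadata.tsv"),
                  truth = file.path(dir, "truth.json"))
    write_gal(study$gal, paths$gal)
    write_metadata(study$metadata, paths$metadata)
    write_truth(study$truth, paths$truth)
    paths$gpr <- vapply(study$metadata$sample_id, function(s) {
      p <- file.path(dir, paste0(s, ".gpr"))
      write_gpr(study$spots[study$spots$sample_id == s, , drop = FALSE], p)
      p
    }, "")
    study$paths <- paths
  }
  study
}

#' Serialize / read simulation truth as JSON
#' @param truth a `simulation_truth`.
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  # named atomic vectors serialize as bare arrays; lists keep their names
  x$differential_antigens <- as.list(x$differential_antigens)
  x$covariate_effects <- lapply(x$covariate_effects, as.list)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$differential_antigens <- if (length(x$differential_antigens)) {
    unlist(x$differential_antigens)
  } else {
    setNames(numeric(), character())
  }
  x$covariate_effects <- lapply(x$covariate_effects, unlist)
  structure(x, class = "simulation_truth")
}

#' Generate amino-acid sequence pairs at target percent identities
#'
#' Copy-and-mutate construction: for each target, a random sequence is
#' paired with a copy in which a fixed fraction of positions is substituted
#' by a different residue, so the global-alignment identity lands within a
#' few points of the target.
#'
#' @param identity_targets numeric vector of target identities in \[0, 100\].
#' @param seed integer seed.
#' @param length sequence length (equal for both members of a pair).
#' @return named character vector with entries `pairNN_a` / `pairNN_b`.
#' @export
generate_sequence_pairs <- function(identity_targets, seed = 1, length = 300) {
  stopifnot(all(identity_targets >= 0 & identity_targets <= 100))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  with_seed(seed, {
    out <- character(0)
    for (i in seq_along(identity_targets)) {
      t <- identity_targets[[i]]
      a <- sample(aa, length, replace = TRUE)
      b <- a
      n_mut <- length - round(t / 100 * length)
      pos <- sample(length, n_mut)
      b[pos] <- vapply(a[pos], function(res) sample(setdiff(aa, res), 1L), "")
      out[sprintf("pair%02d_a", i)] <- paste(a, collapse = "")
      out[sprintf("pair%02d_b", i)] <- paste(b, collapse = "")
    }
    out
  })
}

#' Synthetic stand-in panel for the printed cross-reactivity identities
#'
#' SYNTHETIC sequences (not the real human proteins): three isoform-like
#' pairs built by copy-and-mutate at the identity structure reported for
#' MAPK1/MAPK3 (83%), PAK2/PAK4 (~64%) and YWHAE/YWHAG (~64%), plus six
#' mutually unrelated random sequences standing in for the correlated
#' significant set (ACAT2, TPI1, GOT1, LDHB, SSNA1, GGPS1), whose pairwise
#' identities fall in the random-background band below 25%.  Use for
#' exercising the alignment/adjudication stages; conclusions about the real
#' proteins require their real sequences.
#'
#' @param seed integer seed (fixed default so the panel is reproducible).
#' @return named character vector of 12 amino-acid sequences.
#' @export
synthetic_identity_panel <- function(seed = 1905) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  pairs <- list(MAPK = c("MAPK1", "MAPK3", 83, 360),
                PAK = c("PAK2", "PAK4", 64, 525),
                YWHA = c("YWHAE", "YWHAG", 64, 255))
  singles <- c(ACAT2 = 397L, TPI1 = 286L, GOT1 = 413L,
               LDHB = 334L, SSNA1 = 119L, GGPS1 = 300L)
  with_seed(seed, {
    out <- character(0)
    for (p in pairs) {
      len <- as.integer(p[[4L]])
      a <- sample(aa, len, replace = TRUE)
      b <- a
      n_mut <- len - round(as.numeric(p[[3L]]) / 100 * len)
      pos <- sample(len, n_mut)
      b[pos] <- vapply(a[pos], function(res) sample(setdiff(aa, res), 1L), "")
      out[p[[1L]]] <- paste(a, collapse = "")
      out[p[[2L]]] <- paste(b, collapse = "")
    }
    for (nm in names(singles)) {
      out[nm] <- paste(sample(aa, singles[[nm]], replace = TRUE), collapse = "")
    }
    out
  })
}
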