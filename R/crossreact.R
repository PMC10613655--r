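# Cross-reactivity adjudication for significant autoantibodies: highly
# correlated antibody pairs are screened by global sequence identity
# (antibodies against near-identical antigens may be one cross-reacting
# antibody rather than two), and panel isoforms of each candidate are
# screened the same way.

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

encode_aa <- function(seq, alphabet, label) {
  res <- strsplit(toupper(seq), "")[[1L]]
  if (!length(res)) stop_sp("empty sequence: ", label)
  codes <- match(res, alphabet)
  if (any(is.na(codes))) {
    stop_sp("non-amino-acid symbol(s) in ", label, ": ",
            paste(unique(res[is.na(codes)]), collapse = ", "))
  }
  codes - 1L
}

#' Optimal global alignment and percent identity
#'
#' Needleman-Wunsch dynamic programming with affine gap penalties (a gap
#' of length L costs `gap_open + L * gap_extend`) and deterministic
#' tie-breaking on traceback.  Percent identity is 100 * identical
#' positions / alignment length, gap columns included in the length.
#'
#' @param seq_a,seq_b amino-acid sequences (character scalars).
#' @param gap_open,gap_extend affine gap parameters (EMBOSS-needle-like
#'   defaults 10 / 0.5).
#' @param submat substitution matrix with residue row/colnames
#'   (default BLOSUM62).
#' @return `alignment_result` list: `score`, `identity` (percent),
#'   `matches`, `align_length`, `aligned_a`, `aligned_b`, `gap_open`,
#'   `gap_extend`.
#' @export
global_align_identity <- function(seq_a, seq_b, gap_open = 10, gap_extend = 0.5,
                                  submat = blosum62()) {
  alphabet <- rownames(submat)
  a <- encode_aa(seq_a, alphabet, "seq_a")
  b <- encode_aa(seq_b, alphabet, "seq_b")
  res <- .nw_affine(a, b, submat, gap_open, gap_extend)
  decode <- function(codes) {
    chars <- rep("-", length(codes))
    ok <- codes >= 0L
    chars[ok] <- alphabet[codes[ok] + 1L]
    paste(chars, collapse = "")
  }
  structure(
    list(score = res$score,
         identity = 100 * res$matches / res$align_length,
         matches = res$matches,
         align_length = res$align_length,
         aligned_a = decode(res$aligned_a_codes),
         aligned_b = decode(res$aligned_b_codes),
         gap_open = gap_open, gap_extend = gap_extend),
    class = "alignment_result"
  )
}

#' Pairwise percent-identity matrix
#'
#' @param seqs named character vector of amino-acid sequences.
#' @param ... passed to [global_align_identity()].
#' @return symmetric numeric matrix of percent identities with 100 on the
#'   diagonal.
#' @export
identity_matrix <- function(seqs, ...) {
  ids <- names(seqs)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  m <- matrix(100, length(ids), length(ids), dimnames = list(ids, ids))
  if (length(ids) > 1L) {
    for (i in seq_len(length(ids) - 1L)) {
      for (j in seq.int(i + 1L, length(ids))) {
        m[i, j] <- m[j, i] <- global_align_identity(seqs[[i]], seqs[[j]], ...)$identity
      }
    }
  }
  m
}

#' Screen significant antigens for highly correlated pairs
#'
#' All unordered pairs of the given antigens whose squared product-moment
#' correlation across retained samples exceeds `r2_threshold`.
#'
#' @param amat [antigen_matrix()] or plain matrix.
#' @param antigens antigen ids to screen (>= 2); default all retained.
#' @param r2_threshold squared-correlation cutoff (default 0.7).
#' @return data.frame `antigen_a`, `antigen_b`, `r`, `r2` (possibly empty).
#' @export
correlation_screen <- function(amat, antigens = NULL, r2_threshold = 0.7) {
  vals <- if (inherits(amat, "antigen_matrix")) retained_values(amat) else amat
  if (!is.null(antigens)) {
    missing_a <- setdiff(antigens, colnames(vals))
    if (length(missing_a)) stop_sp("antigen(s) not in matrix: ",
                                   paste(missing_a, collapse = ", "))
    vals <- vals[, antigens, drop = FALSE]
  }
  if (ncol(vals) < 2L) stop_sp("correlation screen needs at least 2 antigens")
  cm <- cor(vals)
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  out <- data.frame(
    antigen_a = colnames(cm)[idx[, 1L]],
    antigen_b = colnames(cm)[idx[, 2L]],
    r = cm[idx],
    r2 = cm[idx]^2,
    stringsAsFactors = FALSE
  )
  out <- out[out$r2 > r2_threshold, , drop = FALSE]
  out <- out[order(-out$r2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Isoform homology screen
#'
#' For each candidate protein, finds all other panel proteins whose global
#' percent identity exceeds `identity_threshold` and (when a matrix is
#' supplied and both antigens are present) the correlation of the two
#' antibody profiles.
#'
#' @param panel_seqs named character vector: the array panel's sequences.
#' @param candidates protein ids to screen (must be in the panel;
#'   unresolvable ids are reported, not fatal).
#' @param amat optional [antigen_matrix()] / matrix for profile correlations.
#' @param identity_threshold percent-identity cutoff (default 50).
#' @param ... passed to [global_align_identity()].
#' @return list with `hits` (data.frame `candidate`, `panel_protein`,
#'   `identity`, `r`, `r2`) and `unresolved` (missing candidate ids).
#' @export
isoform_screen <- function(panel_seqs, candidates, amat = NULL,
                           identity_threshold = 50, ...) {
  unresolved <- setdiff(candidates, names(panel_seqs))
  candidates <- intersect(candidates, names(panel_seqs))
  vals <- if (is.null(amat)) NULL
          else if (inherits(amat, "antigen_matrix")) retained_values(amat)
          else amat
  rows <- list()
  for (cand in candidates) {
    others <- setdiff(names(panel_seqs), cand)
    for (other in others) {
      ident <- global_align_identity(panel_seqs[[cand]], panel_seqs[[other]], ...)$identity
      if (ident > identity_threshold) {
        r <- NA_real_
        if (!is.null(vals) && all(c(cand, other) %in% colnames(vals))) {
          r <- cor(vals[, cand], vals[, other])
        }
        rows[[length(rows) + 1L]] <- data.frame(
          candidate = cand, panel_protein = other,
          identity = ident, r = r, r2 = r^2, stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(candidate = character(), panel_protein = character(),
               identity = numeric(), r = numeric(), r2 = numeric(),
               stringsAsFactors = FALSE)
  }
  rownames(hits) <- NULL
  list(hits = hits, unresolved = unresolved)
}

#' Adjudicate cross-reactivity for a screened pair
#'
#' Pure rule: a pair is `possible_crossreactivity` iff its sequence
#' identity exceeds `identity_threshold` AND its profile r-squared exceeds
#' `r2_threshold` (high homology alone, or high correlation alone, reads
#' as `likely_biological`).
#'
#' @param identity percent identity in \[0, 100\] (vectorized).
#' @param r2 squared correlation in \[0, 1\] (vectorized).
#' @param identity_threshold,r2_threshold rule cutoffs (defaults 50 / 0.7).
#' @return data.frame `identity`, `r2`, `verdict`, `rationale`.
#' @export
adjudicate <- function(identity, r2, identity_threshold = 50, r2_threshold = 0.7) {
  stopifnot(length(identity) == length(r2),
            all(identity >= 0 & identity <= 100), all(r2 >= 0 & r2 <= 1))
  cross <- identity > identity_threshold & r2 > r2_threshold
  rationale <- ifelse(
    cross,
    sprintf("identity %.1f%% > %s%% and r2 %.3f > %s: one antibody may bind both antigens",
            identity, identity_threshold, r2, r2_threshold),
    ifelse(identity <= identity_threshold,
           sprintf("identity %.1f%% <= %s%%: antigens too dissimilar for shared epitopes",
                   identity, identity_threshold),
           sprintf("r2 %.3f <= %s: homologous antigens but uncorrelated signals",
                   r2, r2_threshold)))
  data.frame(identity = identity, r2 = r2,
             verdict = ifelse(cross, "possible_crossreactivity", "likely_biological"),
             rationale = rationale, stringsAsFactors = FALSE)
}

#' Full cross-reactivity report
#'
#' Correlation screen over the significant antigens, identity matrix over
#' every protein appearing in a screened pair, isoform screen of each
#' significant antigen against the panel, and a verdict per screened or
#' isoform pair.
#'
#' @param amat [antigen_matrix()] (processed).
#' @param significant character vector of significant antigen ids.
#' @param panel_seqs named character vector of panel protein sequences.
#' @param r2_threshold,identity_threshold rule cutoffs.
#' @param ... passed to [global_align_identity()].
#' @return `crossreact_report` list: `correlated_pairs`,
#'   `identity_matrix`, `isoform_hits`, `verdicts`, `unresolved`.
#' @export
cross_react_report <- function(amat, significant, panel_seqs,
                               r2_threshold = 0.7, identity_threshold = 50, ...) {
  pairs <- if (length(significant) >= 2L) {
    correlation_screen(amat, intersect(significant,
                                       colnames(if (inherits(amat, "antigen_matrix")) amat$values else amat)),
                       r2_threshold = r2_threshold)
  } else {
    data.frame(antigen_a = character(), antigen_b = character(),
               r = numeric(), r2 = numeric(), stringsAsFactors = FALSE)
  }
  prots <- unique(c(pairs$antigen_a, pairs$antigen_b))
  prots_avail <- intersect(prots, names(panel_seqs))
  idm <- if (length(prots_avail) >= 2L) identity_matrix(panel_seqs[prots_avail], ...) else NULL
  pairs$identity <- rep(NA_real_, nrow(pairs))
  if (!is.null(idm)) {
    ok <- pairs$antigen_a %in% prots_avail & pairs$antigen_b %in% prots_avail
    pairs$identity[ok] <- idm[cbind(pairs$antigen_a[ok], pairs$antigen_b[ok])]
  }
  iso <- isoform_screen(panel_seqs, intersect(significant, names(panel_seqs)),
                        amat = amat, identity_threshold = identity_threshold, ...)
  verdict_input <- rbind(
    if (nrow(pairs)) data.frame(pair = paste(pairs$antigen_a, pairs$antigen_b, sep = ":"),
                                identity = pairs$identity, r2 = pairs$r2,
                                source = "correlation_screen", stringsAsFactors = FALSE),
    if (nrow(iso$hits)) data.frame(pair = paste(iso$hits$candidate, iso$hits$panel_protein, sep = ":"),
                                   identity = iso$hits$identity, r2 = iso$hits$r2,
                                   source = "isoform_screen", stringsAsFactors = FALSE)
  )
  verdicts <- if (!is.null(verdict_input) && nrow(verdict_input)) {
    known <- !is.na(verdict_input$identity) & !is.na(verdict_input$r2)
    out <- verdict_input
    out$verdict <- NA_character_
    out$rationale <- NA_character_
    if (any(known)) {
      adj <- adjudicate(verdict_input$identity[known], verdict_input$r2[known],
                        identity_threshold = identity_threshold,
                        r2_threshold = r2_threshold)
      out$verdict[known] <- adj$verdict
      out$rationale[known] <- adj$rationale
    }
    out
  } else {
    data.frame(pair = character(), identity = numeric(), r2 = numeric(),
               source = character(), verdict = character(),
               rationale = character(), stringsAsFactors = FALSE)
  }
  structure(
    list(correlated_pairs = pairs, identity_matrix = idm,
         isoform_hits = iso$hits, verdicts = verdicts,
         unresolved = union(iso$unresolved, setdiff(prots, names(panel_seqs))),
         r2_threshold = r2_threshold, identity_threshold = identity_threshold),
    class = "crossreact_report"
  )
}

#' Write a cross-reactivity report as JSON
#' @param report a `crossreact_report`.
#' @param path output path.
#' @export
write_xreact <- function(report, path) {
  out <- unclass(report)
  if (!is.null(out$identity_matrix)) {
    out$identity_matrix <- list(proteins = rownames(out$identity_matrix),
                                values = unname(apply(out$identity_matrix, 1L, as.numeric,
                                                      simplify = FALSE)))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}
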