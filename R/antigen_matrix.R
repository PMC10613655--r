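# The pipeline's working container: a samples x antigens grid of log2 net
# intensity (RFU) plus per-antigen and per-sample exclusion masks and an
# append-only provenance trail.

#' Construct an antigen matrix
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   antigens in columns (colnames = antigen ids), log2 net intensity.
#' @param antigen_status named character vector over antigens:
#'   `"retained"` or an exclusion reason (`"cv_excluded"`, `"ncf_excluded"`,
#'   `"sparse"`, `"constant"`).
#' @param sample_status named character vector over samples: `"retained"`
#'   or `"psa_excluded"`.
#' @param provenance character vector of applied transforms (append-only).
#' @param imputed optional logical matrix (same shape as `values`) marking
#'   cells whose value was imputed rather than measured.
#' @return an `antigen_matrix` object.
#' @export
antigen_matrix <- function(values,
                           antigen_status = setNames(rep("retained", ncol(values)), colnames(values)),
                           sample_status = setNames(rep("retained", nrow(values)), rownames(values)),
                           provenance = character(),
                           imputed = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  if (anyDuplicated(rownames(values))) stop_sp("duplicate sample ids")
  if (anyDuplicated(colnames(values))) stop_sp("duplicate antigen ids")
  stopifnot(identical(sort(names(antigen_status)), sort(colnames(values))),
            identical(sort(names(sample_status)), sort(rownames(values))))
  if (!is.null(imputed)) stopifnot(identical(dim(imputed), dim(values)))
  structure(
    list(values = values,
         antigen_status = antigen_status[colnames(values)],
         sample_status = sample_status[rownames(values)],
         provenance = provenance,
         imputed = imputed),
    class = "antigen_matrix"
  )
}

#' @export
print.antigen_matrix <- function(x, ...) {
  cat(sprintf("<antigen_matrix> %d samples x %d antigens\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  retained: %d samples, %d antigens\n",
              sum(x$sample_status == "retained"),
              sum(x$antigen_status == "retained")))
  excl <- table(x$antigen_status[x$antigen_status != "retained"])
  if (length(excl)) {
    cat("  antigen exclusions:",
        paste(sprintf("%s=%d", names(excl), excl), collapse = ", "), "\n")
  }
  if (any(x$sample_status != "retained")) {
    cat("  excluded samples:",
        paste(names(x$sample_status)[x$sample_status != "retained"], collapse = ", "), "\n")
  }
  cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Extract the retained submatrix
#'
#' @param amat an `antigen_matrix`.
#' @param samples,antigens logical; restrict to retained samples / antigens.
#' @return numeric matrix of retained cells.
#' @export
retained_values <- function(amat, samples = TRUE, antigens = TRUE) {
  rows <- if (samples) amat$sample_status == "retained" else rep(TRUE, nrow(amat$values))
  cols <- if (antigens) amat$antigen_status == "retained" else rep(TRUE, ncol(amat$values))
  amat$values[rows, cols, drop = FALSE]
}

add_provenance <- function(amat, step) {
  amat$provenance <- c(amat$provenance, step)
  amat
}

#' Write / read an antigen matrix as annotated TSV
#'
#' The masks and provenance are stored as `#` header comments so that a
#' written matrix round-trips losslessly.
#'
#' @param amat an `antigen_matrix`.
#' @param path output path.
#' @return `write_matrix`: the path, invisibly. `read_matrix`: the
#'   reconstructed `antigen_matrix`.
#' @export
write_matrix <- function(amat, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "# seroprofiler antigen matrix v1",
    paste0("# provenance: ", paste(amat$provenance, collapse = "\t")),
    paste0("# antigen_status: ",
           paste(sprintf("%s=%s", names(amat$antigen_status), amat$antigen_status), collapse = "\t")),
    paste0("# sample_status: ",
           paste(sprintf("%s=%s", names(amat$sample_status), amat$sample_status), collapse = "\t")),
    paste0("# imputed_cells: ", if (is.null(amat$imputed)) "" else {
      idx <- which(amat$imputed, arr.ind = TRUE)
      paste(sprintf("%s=%s", rownames(amat$values)[idx[, 1L]],
                    colnames(amat$values)[idx[, 2L]]), collapse = "\t")
    })
  ), con)
  tab <- data.frame(sample_id = rownames(amat$values), amat$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  writeLines(paste(names(tab), collapse = "\t"), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  parse_kv <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, ":"))]
    if (!length(ln)) stop_sp("matrix file lacks '# ", key, ":' header")
    payload <- sub(paste0("^# ", key, ": ?"), "", ln[[1L]])
    if (!nzchar(payload)) return(character())
    strsplit(payload, "\t", fixed = TRUE)[[1L]]
  }
  prov <- parse_kv("provenance")
  split_eq <- function(x) {
    m <- regmatches(x, regexpr("=", x), invert = TRUE)
    setNames(vapply(m, `[[`, "", 2L), vapply(m, `[[`, "", 1L))
  }
  antigen_status <- split_eq(parse_kv("antigen_status"))
  sample_status <- split_eq(parse_kv("sample_status"))
  tab <- read.delim(text = body, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(values) <- tab$sample_id
  imp_ln <- hdr[startsWith(hdr, "# imputed_cells:")]
  imputed <- NULL
  if (length(imp_ln)) {
    imputed <- matrix(FALSE, nrow(values), ncol(values), dimnames = dimnames(values))
    cells <- parse_kv("imputed_cells")
    if (length(cells)) {
      kv <- split_eq(cells)
      imputed[cbind(names(kv), unname(kv))] <- TRUE
    }
  }
  antigen_matrix(values, antigen_status, sample_status, prov, imputed = imputed)
}
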