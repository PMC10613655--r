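# Readers and writers for the plain-text formats the pipeline touches:
# ATF-dialect spot tables (GAL array lists and GPR scan results), sample
# metadata TSV, FASTA protein panels, GMT annotation sets, and the
# package's own antigen-matrix TSV.

# ---- ATF core ---------------------------------------------------------------

# ATF files open with "ATF <version>" and a line giving the number of
# optional header records and data columns, then the header records
# (conventionally quoted "Key=Value" strings), then one tab-separated
# column-name line, then data.
read_atf <- function(path) {
  if (!file.exists(path)) stop_sp("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || !grepl("^ATF\\b", lines[[1L]])) {
    stop_sp("malformed ATF header: expected first line to start with 'ATF', got: ",
            if (length(lines)) substr(lines[[1L]], 1L, 60L) else "<empty file>")
  }
  counts <- strsplit(lines[[2L]], "\t", fixed = TRUE)[[1L]]
  n_header <- suppressWarnings(as.integer(counts[[1L]]))
  if (is.na(n_header) || n_header < 0L) {
    stop_sp("malformed ATF header: line 2 must give the optional-record count, got: ",
            lines[[2L]])
  }
  header <- if (n_header > 0L) gsub('^"|"$', "", lines[2L + seq_len(n_header)]) else character()
  body_start <- 3L + n_header
  if (body_start > length(lines)) stop_sp("malformed ATF file: no column header line")
  col_line <- gsub('"', "", lines[[body_start]], fixed = TRUE)
  col_names <- strsplit(col_line, "\t", fixed = TRUE)[[1L]]
  data_lines <- lines[seq.int(body_start + 1L, length.out = max(0L, length(lines) - body_start))]
  data_lines <- data_lines[nzchar(data_lines)]
  tab <- if (length(data_lines)) {
    read.delim(text = data_lines, header = FALSE, quote = '"',
               stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    as.data.frame(setNames(rep(list(character()), length(col_names)), col_names))
  }
  if (ncol(tab) != length(col_names)) {
    stop_sp("malformed ATF file: ", length(col_names), " column names but ",
            ncol(tab), " data columns")
  }
  names(tab) <- col_names
  list(header = header, table = tab)
}

write_atf <- function(header, table, path, type_record) {
  records <- c(type_record, header)
  # full-precision float formatting so intensities round-trip bit-exactly
  for (cl in names(table)) {
    if (is.double(table[[cl]])) table[[cl]] <- sprintf("%.17g", table[[cl]])
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("ATF\t1.0",
               paste(length(records), ncol(table), sep = "\t"),
               sprintf('"%s"', records),
               paste(names(table), collapse = "\t")), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- GAL --------------------------------------------------------------------

#' Read a GenePix Array List (GAL) file
#'
#' A GAL file records the position (block, row, column) and identity of
#' every probed spot on the array.  Spot identities matching
#' `negctrl_pattern` are classified as negative-control spots (the
#' non-reactive protein used for negative-control filtration) and those
#' matching `buffer_pattern` as buffer-only spots; everything else is a
#' probed antigen.
#'
#' @param path path to a GAL file (ATF text).
#' @param negctrl_pattern,buffer_pattern regular expressions applied to the
#'   spot ID to classify control spots.
#' @return a `gal_layout`: a data.frame with columns `block`, `row`, `col`
#'   (1-based integers), `antigen_id` and `control_flag`
#'   (`"antigen"`, `"negative_control"` or `"buffer"`).
#' @export
read_gal <- function(path, negctrl_pattern = "NegCtrl", buffer_pattern = "Buffer") {
  atf <- read_atf(path)
  tab <- atf$table
  need <- c("Block", "Row", "Column", "ID")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop_sp("GAL file lacks required column(s) ", paste(missing_cols, collapse = ", "),
            "; available: ", paste(names(tab), collapse = ", "))
  }
  layout <- data.frame(
    block = as.integer(tab$Block),
    row = as.integer(tab$Row),
    col = as.integer(tab$Column),
    antigen_id = as.character(tab$ID),
    stringsAsFactors = FALSE
  )
  layout$control_flag <- ifelse(
    grepl(negctrl_pattern, layout$antigen_id), "negative_control",
    ifelse(grepl(buffer_pattern, layout$antigen_id), "buffer", "antigen")
  )
  validate_gal(layout)
  class(layout) <- c("gal_layout", "data.frame")
  layout
}

validate_gal <- function(layout) {
  key <- paste(layout$block, layout$row, layout$col)
  if (anyDuplicated(key)) {
    stop_sp("duplicate spot coordinates in layout: ",
            paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  if (any(!nzchar(layout$antigen_id) | is.na(layout$antigen_id))) {
    stop_sp("empty antigen ID at layout row(s) ",
            paste(which(!nzchar(layout$antigen_id) | is.na(layout$antigen_id)), collapse = ", "))
  }
  if (!any(layout$control_flag == "negative_control")) {
    warning("layout contains no negative-control spots; negative-control filtration will not be possible")
  }
  invisible(layout)
}

#' Write a GAL layout
#'
#' @param layout a `gal_layout` as returned by [read_gal()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gal <- function(layout, path) {
  tab <- data.frame(Block = layout$block, Row = layout$row, Column = layout$col,
                    ID = layout$antigen_id, Name = layout$antigen_id)
  write_atf(header = sprintf("BlockCount=%d", max(layout$block)),
            table = tab, path = path, type_record = "Type=GenePix ArrayList V1.0")
}

# ---- GPR --------------------------------------------------------------------

#' Read a GenePix Results (GPR) spot table for one sample
#'
#' Joins the scanned spot intensities to a GAL layout by (block, row,
#' column) coordinates and returns one record per layout spot.  Flagged
#' spots are retained with their flag value preserved; downstream
#' aggregation excludes spots with negative flags.
#'
#' @param path path to a GPR file (ATF text).
#' @param layout a `gal_layout`.
#' @param fg_col,bg_col names of the mean foreground / local background
#'   intensity columns (GenePix defaults for the Cy3 channel).
#' @param sample_id sample identifier; defaults to the file name without
#'   extension.
#' @return a `spot_records` data.frame with columns `sample_id`,
#'   `antigen_id`, `control_flag`, `block`, `row`, `col`, `replicate`
#'   (1-based index among same-antigen spots), `fg_mean`, `bg_mean`, `flag`.
#' @export
read_gpr <- function(path, layout, fg_col = "F532 Mean", bg_col = "B532 Mean",
                     sample_id = tools::file_path_sans_ext(basename(path))) {
  atf <- read_atf(path)
  tab <- atf$table
  need <- c("Block", "Row", "Column", "Flags", fg_col, bg_col)
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop_sp("GPR file lacks required column(s) ", paste(missing_cols, collapse = ", "),
            "; available: ", paste(names(tab), collapse = ", "))
  }
  gpr_key <- paste(tab$Block, tab$Row, tab$Column)
  lay_key <- paste(layout$block, layout$row, layout$col)
  orphans <- setdiff(gpr_key, lay_key)
  if (length(orphans)) {
    stop_sp("GPR spot(s) at coordinates not present in the GAL layout: ",
            paste(utils::head(orphans, 10L), collapse = "; "),
            if (length(orphans) > 10L) " ..." else "")
  }
  absent <- setdiff(lay_key, gpr_key)
  if (length(absent)) {
    stop_sp("layout spot(s) missing from the GPR file: ",
            paste(utils::head(absent, 10L), collapse = "; "),
            if (length(absent) > 10L) " ..." else "")
  }
  idx <- match(lay_key, gpr_key)
  fg <- as.numeric(tab[[fg_col]][idx])
  bg <- as.numeric(tab[[bg_col]][idx])
  if (any(!is.finite(fg)) || any(!is.finite(bg))) {
    stop_sp("non-finite intensities in ", basename(path))
  }
  rec <- data.frame(
    sample_id = sample_id,
    antigen_id = layout$antigen_id,
    control_flag = layout$control_flag,
    block = layout$block, row = layout$row, col = layout$col,
    replicate = stats::ave(seq_along(lay_key), layout$antigen_id, FUN = seq_along),
    fg_mean = fg, bg_mean = bg,
    flag = as.integer(tab$Flags[idx]),
    stringsAsFactors = FALSE
  )
  class(rec) <- c("spot_records", "data.frame")
  rec
}

#' Write spot records for one sample as a GPR file
#'
#' @param spots `spot_records` for a single sample.
#' @param path output path.
#' @param fg_col,bg_col intensity column names to emit.
#' @return the path, invisibly.
#' @export
write_gpr <- function(spots, path, fg_col = "F532 Mean", bg_col = "B532 Mean") {
  stopifnot(length(unique(spots$sample_id)) == 1L)
  tab <- data.frame(Block = spots$block, Row = spots$row, Column = spots$col,
                    ID = spots$antigen_id, check.names = FALSE)
  tab[[fg_col]] <- spots$fg_mean
  tab[[bg_col]] <- spots$bg_mean
  tab$Flags <- spots$flag
  write_atf(header = c("Creator=seroprofiler", sprintf("SampleID=%s", spots$sample_id[[1L]])),
            table = tab, path = path, type_record = "Type=GenePix Results 3")
}

# ---- sample metadata --------------------------------------------------------

#' Read and validate a sample metadata table
#'
#' Expects a TSV with columns `sample_id`, `diagnosis` (`case`/`control`),
#' `age` (years), `sex` (`F`/`M`), `batch`, and optionally `ados2`
#' (severity score, cases only) and `scq`.  Unknown columns are kept as
#' passthrough.
#'
#' @param path path to the TSV.
#' @return a validated `sample_metadata` data.frame.
#' @export
read_metadata <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_metadata(tab)
}

#' @rdname read_metadata
#' @param tab a data.frame to validate in place of a file.
#' @export
validate_metadata <- function(tab) {
  need <- c("sample_id", "diagnosis", "age", "sex", "batch")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop_sp("metadata lacks required column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad_row <- function(what, rows) {
    stop_sp("metadata validation failed: ", what, " at row(s) ",
            paste(rows, collapse = ", "))
  }
  tab$sample_id <- as.character(tab$sample_id)
  if (anyDuplicated(tab$sample_id)) {
    bad_row("duplicated sample_id", which(duplicated(tab$sample_id)))
  }
  if (!all(tab$diagnosis %in% c("case", "control"))) {
    bad_row("diagnosis not 'case'/'control'", which(!tab$diagnosis %in% c("case", "control")))
  }
  age <- suppressWarnings(as.numeric(tab$age))
  if (any(is.na(age) | age <= 0)) bad_row("non-numeric or non-positive age", which(is.na(age) | age <= 0))
  tab$age <- age
  if (!all(tab$sex %in% c("F", "M"))) {
    bad_row("unknown sex level (expected F/M)", which(!tab$sex %in% c("F", "M")))
  }
  tab$batch <- as.character(tab$batch)
  if ("ados2" %in% names(tab)) {
    tab$ados2 <- suppressWarnings(as.numeric(tab$ados2))
    bad <- which(!is.na(tab$ados2) & tab$diagnosis == "control")
    if (length(bad)) bad_row("ados2 present for control sample", bad)
  }
  if ("scq" %in% names(tab)) tab$scq <- suppressWarnings(as.numeric(tab$scq))
  class(tab) <- c("sample_metadata", "data.frame")
  tab
}

#' Write a sample metadata table
#' @param metadata a `sample_metadata` data.frame.
#' @param path output path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- FASTA / GMT ------------------------------------------------------------

#' Read a protein FASTA into a named character vector
#'
#' @param path path to an (uncompressed) amino-acid FASTA file.
#' @return named character vector mapping sequence ID (first word of the
#'   description line) to sequence.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  if (anyDuplicated(ids)) {
    stop_sp("duplicate FASTA ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(nchar(seqs) == 0L)) {
    stop_sp("empty sequence for id(s): ", paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  setNames(seqs, ids)
}

#' Write named sequences as FASTA
#' @param seqs named character vector of amino-acid sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Each line is `term <TAB> description <TAB> member1 <TAB> member2 ...`.
#'
#' @param path path to the GMT file.
#' @return named list mapping term to a character vector of members.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short)) stop_sp("GMT line(s) with fewer than 3 fields: ", paste(short, collapse = ", "))
  terms <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(terms)) {
    stop_sp("duplicate GMT terms: ", paste(unique(terms[duplicated(terms)]), collapse = ", "))
  }
  setNames(lapply(fields, function(f) unique(f[-c(1L, 2L)])), terms)
}

#' Write gene sets as GMT
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(tm) {
    paste(c(tm, tm, sets[[tm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
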