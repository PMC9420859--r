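#' Validate and normalize an amino-acid sequence
#'
#' Upper-cases the sequence and resolves residues outside the canonical
#' 20-letter alphabet `ACDEFGHIKLMNPQRSTVWY` according to `policy`:
#'
#' * `"strict"` (default): any nonstandard character (ambiguity codes
#'   B/J/Z/X, the rare residues U/O, gaps, stops) is an error. Silent
#'   coercion would corrupt composition features, so this is the default.
#' * `"drop_residue"`: nonstandard characters are deleted.
#' * `"map_to_nearest"`: ambiguity/rare codes are mapped to their closest
#'   canonical residue (B→D, Z→E, J→L, U→C, O→K); X and anything else
#'   (gaps, stops) are dropped.
#'
#' Sequences must be at least 2 residues long after resolution: the
#' transition and pseudo-PSSM descriptors divide by L−1.
#'
#' @param sequence character scalar.
#' @param policy one of `"strict"`, `"drop_residue"`, `"map_to_nearest"`.
#' @param id record identifier used in error messages.
#' @return the validated upper-case sequence (character scalar).
#' @export
#' @examples
#' validate_sequence("acde")                       # "ACDE"
#' validate_sequence("ACXE", policy = "drop_residue")  # "ACE"
validate_sequence <- function(sequence, policy = c("strict", "drop_residue", "map_to_nearest"),
                              id = "<sequence>") {
  policy <- match.arg(policy)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(sequence)
  chars <- strsplit(s, "")[[1]]
  bad <- !(chars %in% AA20)
  if (any(bad)) {
    if (policy == "strict") {
      stop(sprintf("record '%s': nonstandard residue(s) %s at position(s) %s (policy = strict)",
                   id, paste(unique(chars[bad]), collapse = ","),
                   paste(head(which(bad), 5L), collapse = ",")), call. = FALSE)
    }
    if (policy == "map_to_nearest") {
      map <- c(B = "D", Z = "E", J = "L", U = "C", O = "K")
      hit <- chars %in% names(map)
      chars[hit] <- map[chars[hit]]
      bad <- !(chars %in% AA20)
    }
    chars <- chars[!bad]
  }
  out <- paste(chars, collapse = "")
  if (nchar(out) < 2L)
    stop(sprintf("record '%s': sequence has fewer than 2 valid residues after applying policy '%s'",
                 id, policy), call. = FALSE)
  out
}

#' Read a protein FASTA file
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file into a
#' `protein_set`: a data frame with columns `id`, `sequence` and optionally
#' `label`. Sequences are upper-cased and validated with
#' [validate_sequence()] under the given nonstandard-residue policy;
#' record order is preserved.
#'
#' @param path FASTA file path.
#' @param policy nonstandard-residue policy, see [validate_sequence()].
#' @return data frame of class `protein_set` with columns `id`, `sequence`.
#' @export
read_fasta <- function(path, policy = c("strict", "drop_residue", "map_to_nearest")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not a readable FASTA file: ", path,
                                           " (", conditionMessage(e), ")", call. = FALSE))
  if (length(set) == 0L) stop("FASTA file contains no records: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stop("duplicate FASTA record IDs: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- as.character(set)
  seqs <- vapply(seq_along(seqs), function(i) validate_sequence(seqs[i], policy, ids[i]), "")
  protein_set(ids, seqs)
}

#' Construct a protein_set from vectors
#'
#' @param id character vector of unique record IDs.
#' @param sequence character vector of validated sequences.
#' @param label optional integer vector in \{0, 1\} (1 = moonlighting).
#' @return data frame of class `protein_set`.
#' @export
protein_set <- function(id, sequence, label = NULL) {
  stopifnot(length(id) == length(sequence))
  df <- data.frame(id = as.character(id), sequence = as.character(sequence),
                   stringsAsFactors = FALSE)
  if (!is.null(label)) {
    stopifnot(length(label) == nrow(df), all(label %in% c(0L, 1L)))
    df$label <- as.integer(label)
  }
  class(df) <- c("protein_set", "data.frame")
  df
}

#' Write a protein_set to FASTA
#'
#' @param records a `protein_set`.
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  set <- Biostrings::BStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a PSI-BLAST ASCII PSSM profile
#'
#' Parses the `-out_ascii_pssm` dialect written by PSI-BLAST: header lines,
#' then one row per residue position carrying a position index, the query
#' residue, and at least 20 integer score columns. Only the first 20 score
#' columns (the log-odds substitution block) are used; the weighted
#' observed-percentage block of 40-column files is ignored. Columns are
#' re-ordered to alphabetical residue order `ACDE...Y` regardless of the
#' order in the file, so permuted inputs yield identical matrices.
#'
#' @param path PSSM file path.
#' @param record_id identifier to attach; defaults to the file base name.
#' @return a `pssm_profile`: list with `record_id`, `scores` (L x 20 matrix,
#'   alphabetical columns) and `column_order`.
#' @export
read_pssm <- function(path, record_id = NULL) {
  if (!file.exists(path)) stop("PSSM file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])

  # header: the first line whose tokens are >= 20 single residue letters
  is_header <- vapply(toks, function(tk)
    length(tk) >= 20L && all(nchar(tk) == 1L) && all(tk %in% AA20), NA)
  h <- which(is_header)
  if (length(h) == 0L) stop("not a PSI-BLAST ASCII PSSM (no residue column header): ",
                            path, call. = FALSE)
  cols <- toks[[h[1]]][1:20]
  if (anyDuplicated(cols) || !setequal(cols, AA20))
    stop("PSSM header does not name the 20 residues exactly once: ", path, call. = FALSE)

  # data rows: "<pos> <residue> <20..40 numbers> ..."
  rows <- list()
  for (tk in toks[seq(h[1] + 1L, length(toks))]) {
    if (length(tk) < 22L) next
    if (!grepl("^[0-9]+$", tk[1]) || !(tk[2] %in% c(AA20, "B", "J", "O", "U", "X", "Z"))) next
    vals <- suppressWarnings(as.numeric(tk[3:22]))
    if (anyNA(vals)) stop("malformed PSSM data row near position ", tk[1], ": ", path, call. = FALSE)
    rows[[length(rows) + 1L]] <- vals
  }
  if (length(rows) == 0L) stop("PSSM file has a header but no data rows: ", path, call. = FALSE)
  scores <- do.call(rbind, rows)
  colnames(scores) <- cols
  scores <- scores[, AA20, drop = FALSE]
  pssm_profile(record_id %||% sub("\\.[^.]*$", "", basename(path)), scores)
}

#' Construct a pssm_profile
#'
#' @param record_id record identifier the profile belongs to.
#' @param scores L x 20 numeric matrix in alphabetical residue column order.
#' @return list of class `pssm_profile`.
#' @export
pssm_profile <- function(record_id, scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 20L) stop("a PSSM profile must have exactly 20 score columns", call. = FALSE)
  if (nrow(scores) < 1L) stop("a PSSM profile must have at least one row", call. = FALSE)
  colnames(scores) <- AA20
  structure(list(record_id = as.character(record_id), scores = scores,
                 column_order = AA20),
            class = "pssm_profile")
}

#' Write a pssm_profile as PSI-BLAST-style ASCII
#'
#' Emits the minimal `-out_ascii_pssm`-compatible layout [read_pssm()]
#' consumes: a residue column header followed by one
#' `<pos> <residue> <20 scores>` row per position. `residues` supplies the
#' per-position query residue column (defaults to the highest-scoring
#' residue of each row).
#'
#' @param profile a `pssm_profile`.
#' @param path output file.
#' @param residues optional character vector of query residues, length L.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(profile, path, residues = NULL) {
  sc <- profile$scores
  if (is.null(residues)) residues <- AA20[max.col(sc, ties.method = "first")]
  stopifnot(length(residues) == nrow(sc))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("", "Last position-specific scoring matrix computed",
               paste(" ", paste(sprintf("%3s", AA20), collapse = " "))), con)
  for (i in seq_len(nrow(sc)))
    writeLines(paste(sprintf("%4d %s", i, residues[i]),
                     paste(sprintf("%3d", round(sc[i, ])), collapse = " ")), con)
  invisible(path)
}

#' Check a profile against its sequence
#'
#' @param profile a `pssm_profile`.
#' @param record one-row `protein_set` (or list with `id`, `sequence`).
#' @return `TRUE` invisibly; errors on row/length mismatch.
#' @export
check_pssm <- function(profile, record) {
  L <- nchar(record$sequence)
  if (nrow(profile$scores) != L)
    stop(sprintf("PSSM/sequence mismatch for '%s': %d profile rows vs sequence length %d",
                 record$id, nrow(profile$scores), L), call. = FALSE)
  invisible(TRUE)
}

#' Read a two-column label TSV
#'
#' One line per protein: `<id>\t<label>` with label in \{0, 1\}
#' (1 = moonlighting protein).
#'
#' @param path TSV file path (no header).
#' @return named integer vector, names = IDs.
#' @export
read_labels <- function(path) {
  df <- read.delim(path, header = FALSE, colClasses = "character",
                   col.names = c("id", "label"), strip.white = TRUE)
  if (anyDuplicated(df$id))
    stop("duplicate IDs in label file: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "), call. = FALSE)
  lab <- suppressWarnings(as.integer(df$label))
  if (anyNA(lab) || !all(lab %in% c(0L, 1L)))
    stop("labels must be 0 or 1; offending IDs: ",
         paste(df$id[is.na(lab) | !(lab %in% c(0L, 1L))], collapse = ", "), call. = FALSE)
  setNames(lab, df$id)
}

#' Attach labels to a protein_set
#'
#' Joins a label vector onto the records by ID. IDs present in only one of
#' the two inputs are reported: label IDs with no matching record raise an
#' error (they indicate a mismatched file pair); records left unlabeled are
#' reported in a warning and get `NA`.
#'
#' @param records a `protein_set`.
#' @param labels named vector from [read_labels()].
#' @return the `protein_set` with a `label` column.
#' @export
join_labels <- function(records, labels) {
  orphan <- setdiff(names(labels), records$id)
  if (length(orphan))
    stop("label file references ID(s) absent from the sequences: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  unlab <- setdiff(records$id, names(labels))
  if (length(unlab))
    warning("record(s) without a label (set to NA): ", paste(unlab, collapse = ", "),
            call. = FALSE)
  records$label <- as.integer(labels[records$id])
  records
}

#' Write / read a feature matrix as TSV
#'
#' The matrix is written with an `id` column and a header of feature names,
#' at full precision (17 significant digits), so that
#' `read_matrix(write_matrix(x))` reproduces `x` exactly.
#'
#' @param values numeric matrix, rownames = record IDs.
#' @param path output TSV path.
#' @return `path` invisibly (write); the matrix with rownames (read).
#' @export
write_matrix <- function(values, path) {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  chr <- matrix(formatC(values, digits = 17, format = "g"),
                nrow = nrow(values), dimnames = dimnames(values))
  df <- data.frame(id = rownames(values), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE, colClasses = NA,
                   stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop("feature matrix TSV lacks an 'id' column: ", path, call. = FALSE)
  if (anyDuplicated(df$id)) stop("duplicate IDs in feature matrix: ", path, call. = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$id
  m
}
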