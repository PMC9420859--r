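#' Physicochemical residue groupings for the CTD descriptors
#'
#' Loads the eight three-group partitions of the 20 amino acids
#' (hydrophobicity, normalized van der Waals volume, polarity,
#' polarizability, charge, secondary structure, solvent accessibility,
#' surface tension) that drive the composition/transition/distribution
#' blocks of the 188-D encoder. The packaged default table is documented in
#' `inst/extdata/ctd_groupings.tsv`; users may point `path` at a
#' replacement in the same layout (columns `attribute`, `group_index`,
#' `group_name`, `residues`).
#'
#' Every attribute row is checked at load time: the three residue sets must
#' be disjoint and cover the alphabet exactly — otherwise group frequencies
#' could not sum to 1.
#'
#' @param path optional TSV path; default = packaged table.
#' @return named list of groupings; each is a list with `name` and
#'   `groups` (named list of three residue character vectors, in order).
#' @export
load_groupings <- function(path = NULL) {
  path <- path %||% system.file("extdata", "ctd_groupings.tsv", package = "moonsvm",
                                mustWork = TRUE)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("attribute", "group_index", "group_name", "residues")
  if (!all(need %in% names(df)))
    stop("grouping table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  attrs <- unique(df$attribute)
  out <- lapply(attrs, function(a) {
    sub <- df[df$attribute == a, ]
    sub <- sub[order(sub$group_index), ]
    if (nrow(sub) != 3L) stop("attribute '", a, "' must have exactly 3 groups", call. = FALSE)
    groups <- lapply(sub$residues, function(r) strsplit(toupper(r), "")[[1]])
    names(groups) <- sub$group_name
    all_res <- unlist(groups)
    if (anyDuplicated(all_res) || !setequal(all_res, AA20) || length(all_res) != 20L)
      stop("attribute '", a, "': groups are not a partition of the 20-letter alphabet ",
           "(duplicated: ", paste(unique(all_res[duplicated(all_res)]), collapse = ","),
           "; missing: ", paste(setdiff(AA20, all_res), collapse = ","), ")", call. = FALSE)
    list(name = a, groups = groups)
  })
  setNames(out, attrs)
}

#' Pseudo-amino-acid composition property scales
#'
#' Loads the nine residue property scales (hydrophilic, hydrophobic, mass,
#' pK1, pK2, pI, rigidity, flexibility, irreplaceability) used by the
#' Pse-AAC sequence-correlation factors. Values are stored raw and
#' standardized to zero mean / unit variance over the 20 residues
#' (population variance), which makes the correlation factors invariant to
#' affine rescaling of any published index. The packaged defaults and their
#' sources are documented in `inst/extdata/pseaac_scales.tsv`; a
#' replacement TSV (column `residue` plus one column per scale) can be
#' supplied via `path`.
#'
#' @param path optional TSV path; default = packaged table.
#' @return list with `raw` and `standardized` 20 x k matrices (rows in
#'   alphabetical residue order).
#' @export
load_scales <- function(path = NULL) {
  path <- path %||% system.file("extdata", "pseaac_scales.tsv", package = "moonsvm",
                                mustWork = TRUE)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"residue" %in% names(df)) stop("scale table needs a 'residue' column", call. = FALSE)
  if (!setequal(df$residue, AA20) || nrow(df) != 20L)
    stop("scale table must have exactly one row per canonical residue", call. = FALSE)
  raw <- as.matrix(df[, setdiff(names(df), "residue"), drop = FALSE])
  rownames(raw) <- df$residue
  raw <- raw[AA20, , drop = FALSE]
  std <- apply(raw, 2L, function(v) {
    m <- mean(v); s <- sqrt(mean((v - m)^2))
    if (s == 0) stop("constant property scale cannot be standardized", call. = FALSE)
    (v - m) / s
  })
  rownames(std) <- AA20
  list(raw = raw, standardized = std)
}
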