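# ---- sequence helpers -------------------------------------------------

# accept a plain sequence string or a one-row protein_set
as_sequence <- function(x) {
  if (inherits(x, "protein_set") || (is.list(x) && !is.null(x$sequence))) {
    if (NROW(x) != 1L) stop("expected a single record; use encode_features() for sets",
                            call. = FALSE)
    return(as.character(x$sequence))
  }
  stopifnot(is.character(x), length(x) == 1L)
  x
}

seq_indices <- function(sequence) {
  idx <- match(strsplit(sequence, "")[[1]], AA20)
  if (anyNA(idx))
    stop("sequence contains nonstandard residues; run validate_sequence() first",
         call. = FALSE)
  idx
}

# ---- amino-acid composition -------------------------------------------

#' Amino-acid composition (AAC)
#'
#' The 20 residue frequencies F_i = N_i / L in alphabetical order
#' `ACDE...Y`; they sum to 1 for every non-empty sequence.
#'
#' @param record sequence string or one-row `protein_set`.
#' @return named numeric vector of length 20.
#' @export
#' @examples
#' aac("AAC")  # A = 2/3, C = 1/3
aac <- function(record) {
  s <- as_sequence(record)
  if (nchar(s) == 0L) stop("empty sequence", call. = FALSE)
  idx <- seq_indices(s)
  setNames(tabulate(idx, nbins = 20L) / length(idx), paste0("AAC.", AA20))
}

# ---- pseudo-amino-acid composition ------------------------------------

#' Pse-AAC encoder configuration
#'
#' Pseudo-amino-acid composition augments the 20 composition frequencies
#' with sequence-order correlation factors built from standardized residue
#' property scales, weighted by `omega`. Two layouts are supported:
#'
#' * `mode = "per_scale"` (default): one correlation series per property
#'   scale, `tiers` lag ranks each, concatenated scale by scale. With the
#'   packaged nine scales and `tiers = 5` this yields the default
#'   20 + 45 = 65-component vector.
#' * `mode = "pooled"`: the classic single series whose tier-k factor
#'   averages the squared property difference over all scales; `lambda`
#'   pseudo components in total.
#'
#' @param omega sequence-order weight, non-negative (default 0.05).
#' @param mode `"per_scale"` or `"pooled"`.
#' @param tiers lag ranks per scale in `per_scale` mode (default 5).
#' @param lambda total pseudo components in `pooled` mode (default =
#'   `tiers`).
#' @param scales 20 x k matrix of standardized property values (rows in
#'   alphabetical residue order), or `NULL` for the packaged nine scales.
#' @return list of class `pseaac_config`.
#' @export
pseaac_config <- function(omega = 0.05, mode = c("per_scale", "pooled"),
                          tiers = 5L, lambda = NULL, scales = NULL) {
  mode <- match.arg(mode)
  stopifnot(omega >= 0, tiers >= 1L)
  if (is.null(scales)) scales <- load_scales()$standardized
  scales <- as.matrix(scales)
  stopifnot(nrow(scales) == 20L)
  if (is.null(rownames(scales))) rownames(scales) <- AA20
  if (is.null(colnames(scales))) colnames(scales) <- paste0("s", seq_len(ncol(scales)))
  lambda <- if (mode == "per_scale") ncol(scales) * as.integer(tiers)
            else as.integer(lambda %||% tiers)
  structure(list(omega = omega, mode = mode, tiers = as.integer(tiers),
                 lambda = lambda, scales = scales),
            class = "pseaac_config")
}

#' Pseudo-amino-acid composition (Pse-AAC)
#'
#' Encodes a sequence as `x = [x_1 .. x_20, x_21 .. x_{20+lambda}]` where
#' the first 20 components are proportional to the residue frequencies f_i
#' and the remaining lambda components to the weighted correlation factors
#' theta: `x_i = f_i / (sum f + omega * sum theta)` for i <= 20 and
#' `x_{20+k} = omega * theta_k / (sum f + omega * sum theta)`. The tier-k
#' factor is the mean squared difference of standardized property values
#' between residues k positions apart,
#' `theta_k = mean_i [H(R_i) - H(R_{i+k})]^2` (averaged over all scales in
#' `pooled` mode; one series per scale in `per_scale` mode). All
#' components are non-negative and sum to 1.
#'
#' @param record sequence string or one-row `protein_set`.
#' @param config a [pseaac_config()].
#' @return named numeric vector of length `20 + config$lambda`.
#' @export
pseaac <- function(record, config = pseaac_config()) {
  s <- as_sequence(record)
  idx <- seq_indices(s)
  L <- length(idx)
  max_lag <- if (config$mode == "per_scale") config$tiers else config$lambda
  if (max_lag >= L)
    stop(sprintf("sequence length %d too short for lag rank %d; lower tiers/lambda below L",
                 L, max_lag), call. = FALSE)
  f <- tabulate(idx, nbins = 20L) / L
  H <- config$scales
  if (config$mode == "per_scale") {
    theta <- numeric(0)
    nm <- character(0)
    for (u in seq_len(ncol(H))) {
      h <- H[idx, u]
      for (k in seq_len(config$tiers)) {
        theta <- c(theta, mean((h[seq_len(L - k)] - h[seq_len(L - k) + k])^2))
        nm <- c(nm, sprintf("theta.%s.k%d", colnames(H)[u], k))
      }
    }
  } else {
    hs <- H[idx, , drop = FALSE]
    theta <- vapply(seq_len(config$lambda), function(k)
      mean(rowMeans((hs[seq_len(L - k), , drop = FALSE] -
                     hs[seq_len(L - k) + k, , drop = FALSE])^2)), 0)
    nm <- sprintf("theta.k%d", seq_len(config$lambda))
  }
  denom <- sum(f) + config$omega * sum(theta)
  setNames(c(f, config$omega * theta) / denom, c(paste0("AAC.", AA20), nm))
}

# ---- composition / transition / distribution --------------------------

group_indices <- function(sequence, grouping) {
  idx <- seq_indices(sequence)
  gmap <- integer(20L)
  for (g in 1:3) gmap[match(grouping$groups[[g]], AA20)] <- g
  gmap[idx]
}

#' CTD composition descriptor
#'
#' Frequency of each of the three physicochemical groups of `grouping`
#' in the sequence, in group order; the three values sum to 1.
#'
#' @param record sequence string or one-row `protein_set`.
#' @param grouping one element of [load_groupings()].
#' @return named numeric vector of length 3.
#' @export
#' @examples
#' g <- load_groupings()
#' ctd_composition("RKEDQN", g$hydrophobicity)  # all polar
ctd_composition <- function(record, grouping) {
  gi <- group_indices(as_sequence(record), grouping)
  setNames(tabulate(gi, nbins = 3L) / length(gi),
           paste(grouping$name, "comp", names(grouping$groups), sep = "."))
}

#' CTD transition descriptor
#'
#' For each unordered group pair — (g1,g2), (g2,g3), (g3,g1) — the number
#' of adjacent residue pairs where the group changes between the two
#' members, divided by L - 1.
#'
#' @inheritParams ctd_composition
#' @return named numeric vector of length 3, each in \[0, 1\].
#' @export
ctd_transition <- function(record, grouping) {
  gi <- group_indices(as_sequence(record), grouping)
  L <- length(gi)
  if (L < 2L) stop("transition descriptor requires sequence length >= 2", call. = FALSE)
  a <- gi[-L]; b <- gi[-1L]
  pairs <- list(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  vals <- vapply(pairs, function(p)
    sum((a == p[1] & b == p[2]) | (a == p[2] & b == p[1])) / (L - 1L), 0)
  gn <- names(grouping$groups)
  setNames(vals, paste(grouping$name, "trans",
                       c(paste0(gn[1], gn[2]), paste0(gn[2], gn[3]), paste0(gn[3], gn[1])),
                       sep = "."))
}

#' CTD distribution descriptor
#'
#' For each group, the 1-based sequence positions of the first,
#' 25%, 50%, 75% and last occurrences (occurrence index
#' `ceiling(fraction * n_g)`), each divided by L. A group that never
#' occurs contributes five zeros.
#'
#' @inheritParams ctd_composition
#' @return named numeric vector of length 15 (3 groups x 5 quantiles).
#' @export
ctd_distribution <- function(record, grouping) {
  gi <- group_indices(as_sequence(record), grouping)
  L <- length(gi)
  qs <- c("first", "q25", "q50", "q75", "last")
  out <- numeric(0)
  for (g in 1:3) {
    pos <- which(gi == g)
    n <- length(pos)
    block <- if (n == 0L) rep(0, 5L)
             else pos[c(1L, ceiling(0.25 * n), ceiling(0.50 * n), ceiling(0.75 * n), n)] / L
    out <- c(out, block)
  }
  setNames(out, paste(grouping$name, "dist",
                      rep(names(grouping$groups), each = 5L), rep(qs, 3L), sep = "."))
}

#' SVMProt-188D encoder
#'
#' The 188-component descriptor: amino-acid composition (20) followed, for
#' each of the eight physicochemical attributes in table order, by the
#' 3 composition + 3 transition + 15 distribution values (8 x 21 = 168).
#'
#' @param record sequence string or one-row `protein_set`.
#' @param groupings list from [load_groupings()].
#' @return named numeric vector of length 188.
#' @export
svmprot188 <- function(record, groupings = load_groupings()) {
  s <- as_sequence(record)
  out <- aac(s)
  for (g in groupings)
    out <- c(out, ctd_composition(s, g), ctd_transition(s, g), ctd_distribution(s, g))
  out
}

# ---- pseudo-PSSM -------------------------------------------------------

#' Row-standardize a PSSM profile
#'
#' Each row of raw substitution scores is centered by its mean and divided
#' by the root-mean-square deviation of the row. A row with zero deviation
#' (all 20 scores identical) carries no preference information and maps to
#' the all-zero row rather than dividing by zero.
#'
#' @param profile a `pssm_profile`.
#' @return the profile with standardized `scores`.
#' @export
normalize_pssm <- function(profile) {
  E0 <- profile$scores
  ctr <- E0 - rowMeans(E0)
  rms <- sqrt(rowMeans(ctr^2))
  zero <- rms < 1e-12
  rms[zero] <- 1
  E <- ctr / rms
  E[zero, ] <- 0
  profile$scores <- E
  profile
}

#' Pseudo-PSSM features
#'
#' The 40-component evolutionary descriptor of a (row-standardized) PSSM:
#' components 1–20 are the column means `Ebar_j = mean_i E_{i,j}` and
#' components 21–40 the lag-xi squared-difference correlations
#' `G_j = mean_i (E_{i,j} - E_{i+xi,j})^2`, both in alphabetical residue
#' order.
#'
#' @param profile a `pssm_profile` (raw scores are standardized first
#'   unless `normalize = FALSE`).
#' @param xi correlation lag, a positive integer < L (default 1 — the value
#'   consistent with a 40-D output).
#' @param normalize standardize rows with [normalize_pssm()] first.
#' @return named numeric vector of length 40.
#' @export
psepssm <- function(profile, xi = 1L, normalize = TRUE) {
  stopifnot(inherits(profile, "pssm_profile"), xi >= 1L)
  if (normalize) profile <- normalize_pssm(profile)
  E <- profile$scores
  L <- nrow(E)
  if (L <= xi) stop(sprintf("profile length %d must exceed lag xi = %d", L, xi), call. = FALSE)
  ebar <- colMeans(E)
  i <- seq_len(L - xi)
  g <- colMeans((E[i, , drop = FALSE] - E[i + xi, , drop = FALSE])^2)
  setNames(c(ebar, g), c(paste0("Ebar.", AA20), paste0("G", xi, ".", AA20)))
}

# ---- batch encoding ----------------------------------------------------

#' Encode a protein_set into a feature matrix
#'
#' Applies one of the three encoders to every record and stacks the
#' results into an n x d matrix (rownames = record IDs, deterministic
#' column order).
#'
#' @param records a `protein_set`.
#' @param encoder `"svmprot188"`, `"pseaac"` or `"psepssm"`.
#' @param config [pseaac_config()] for the Pse-AAC encoder.
#' @param groupings groupings for the 188-D encoder (default packaged).
#' @param pssm named list of `pssm_profile`s (required for `"psepssm"`);
#'   names must cover every record ID and each profile must match its
#'   sequence length.
#' @param xi Pse-PSSM lag.
#' @return numeric matrix, one row per record.
#' @export
encode_features <- function(records, encoder = c("svmprot188", "pseaac", "psepssm"),
                            config = pseaac_config(), groupings = NULL,
                            pssm = NULL, xi = 1L) {
  encoder <- match.arg(encoder)
  stopifnot(inherits(records, "protein_set"))
  rows <- switch(encoder,
    svmprot188 = {
      groupings <- groupings %||% load_groupings()
      lapply(records$sequence, svmprot188, groupings = groupings)
    },
    pseaac = lapply(records$sequence, pseaac, config = config),
    psepssm = {
      if (is.null(pssm)) stop("encoder 'psepssm' requires a named list of PSSM profiles",
                              call. = FALSE)
      missing <- setdiff(records$id, names(pssm))
      if (length(missing))
        stop("missing PSSM profile(s) for: ", paste(missing, collapse = ", "), call. = FALSE)
      lapply(seq_len(nrow(records)), function(i) {
        check_pssm(pssm[[records$id[i]]], records[i, ])
        psepssm(pssm[[records$id[i]]], xi = xi)
      })
    })
  m <- do.call(rbind, rows)
  rownames(m) <- records$id
  m
}
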