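#' Generate a labeled synthetic two-class protein dataset
#'
#' Draws seeded random sequences whose two classes differ in
#' physicochemical group composition, emulating the structure of the
#' moonlighting benchmark (default class sizes 268 positives / 162
#' negatives). Each residue is drawn independently: with probability
#' `1/2 + bias/2` (class 1) or `1/2 - bias/2` (class 0) from the
#' hydrophobic group `CVLIMFW` (uniformly within the group), otherwise
#' uniformly from the remaining 13 residues. The signal therefore lives
#' exactly in a grouping the 188-D encoder measures. `bias = 0` makes the
#' classes exchangeable (no signal); `bias = 1` makes class 1 purely
#' hydrophobic. Lengths are uniform over `length_range`. The dataset is a
#' deterministic function of `seed`.
#'
#' @param n_pos,n_neg class sizes (defaults 268 and 162, the benchmark
#'   composition).
#' @param length_range integer (min, max) sequence lengths; min must be
#'   >= 2 and exceed any encoder lag in use.
#' @param bias class separation in \[0, 1\] (default 0.5).
#' @param seed integer seed.
#' @return a labeled `protein_set` (`label` 1 = positive class).
#' @export
generate_sequences <- function(n_pos = 268L, n_neg = 162L,
                               length_range = c(50L, 300L), bias = 0.5,
                               seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, bias >= 0, bias <= 1,
            length(length_range) == 2L, length_range[1] >= 2L,
            length_range[1] <= length_range[2])
  hydroph <- strsplit("CVLIMFW", "")[[1]]
  others <- setdiff(AA20, hydroph)
  draw <- function(n, p_h, lens) {
    vapply(seq_len(n), function(i) {
      L <- lens[i]
      grp <- runif(L) < p_h
      res <- character(L)
      res[grp] <- sample(hydroph, sum(grp), replace = TRUE)
      res[!grp] <- sample(others, sum(!grp), replace = TRUE)
      paste(res, collapse = "")
    }, "")
  }
  with_seed(seed, {
    lens_pos <- sample(seq(length_range[1], length_range[2]), n_pos, replace = TRUE)
    lens_neg <- sample(seq(length_range[1], length_range[2]), n_neg, replace = TRUE)
    seqs_pos <- draw(n_pos, 0.5 + bias / 2, lens_pos)
    seqs_neg <- draw(n_neg, 0.5 - bias / 2, lens_neg)
    protein_set(id = c(sprintf("pos%04d", seq_len(n_pos)),
                       sprintf("neg%04d", seq_len(n_neg))),
                sequence = c(seqs_pos, seqs_neg),
                label = c(rep(1L, n_pos), rep(0L, n_neg)))
  })
}

#' Generate a synthetic PSSM profile consistent with a sequence
#'
#' Stands in for an evolutionary profile so the pseudo-PSSM encoder is
#' testable offline: row i scores +4 for the residue observed at position
#' i and -1 for the other 19 types (the self-substitution-dominated shape
#' of a real log-odds profile), plus integer-rounded Gaussian noise of
#' standard deviation `noise`. Deterministic in `seed`.
#'
#' @param record one-row `protein_set` (or list with `id`, `sequence`).
#' @param noise noise scale, >= 0 (0 = clean profile).
#' @param seed integer seed.
#' @return a `pssm_profile` matching the record's length.
#' @export
generate_pssm <- function(record, noise = 1, seed = 1L) {
  stopifnot(noise >= 0)
  s <- as_sequence(record)
  idx <- seq_indices(s)
  L <- length(idx)
  scores <- matrix(-1, L, 20L)
  scores[cbind(seq_len(L), idx)] <- 4
  if (noise > 0)
    scores <- scores + with_seed(seed, matrix(round(rnorm(L * 20L, 0, noise)), L, 20L))
  id <- if (is.character(record)) "synthetic" else as.character(record$id)
  pssm_profile(id, scores)
}

#' Generate PSSM profiles for a whole protein_set
#'
#' One seed-derived substream per record, so any single profile can be
#' regenerated independently.
#'
#' @param records a `protein_set`.
#' @param noise noise scale passed to [generate_pssm()].
#' @param seed master seed.
#' @return named list of `pssm_profile`s keyed by record ID.
#' @export
generate_pssm_set <- function(records, noise = 1, seed = 1L) {
  stopifnot(inherits(records, "protein_set"))
  sub_seeds <- with_seed(seed, sample.int(2^31 - 2L, nrow(records)))
  out <- lapply(seq_len(nrow(records)), function(i)
    generate_pssm(records[i, ], noise = noise, seed = sub_seeds[i]))
  setNames(out, records$id)
}
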