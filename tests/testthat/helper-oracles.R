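# Independent brute-force re-implementations of every formula, written as
# plain loops straight from the definitions. They share no code with the
# package internals and serve as oracles for the equivalence tests.

AAS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_seq <- function(L) paste(sample(AAS, L, replace = TRUE), collapse = "")

oracle_aac <- function(s) {
  ch <- strsplit(s, "")[[1]]
  v <- numeric(20)
  for (i in 1:20) for (c in ch) if (c == AAS[i]) v[i] <- v[i] + 1
  v / length(ch)
}

oracle_theta_series <- function(h, tiers) {
  # h: per-position property values; one squared-difference series
  L <- length(h)
  vapply(seq_len(tiers), function(k) {
    tot <- 0
    for (i in 1:(L - k)) tot <- tot + (h[i] - h[i + k])^2
    tot / (L - k)
  }, 0)
}

oracle_pseaac <- function(s, scales, omega, tiers, mode = "per_scale") {
  ch <- strsplit(s, "")[[1]]
  f <- oracle_aac(s)
  if (mode == "per_scale") {
    theta <- numeric(0)
    for (u in seq_len(ncol(scales)))
      theta <- c(theta, oracle_theta_series(scales[match(ch, AAS), u], tiers))
  } else {
    L <- length(ch)
    theta <- vapply(seq_len(tiers), function(k) {
      tot <- 0
      for (i in 1:(L - k)) {
        d2 <- 0
        for (u in seq_len(ncol(scales)))
          d2 <- d2 + (scales[match(ch[i], AAS), u] - scales[match(ch[i + k], AAS), u])^2
        tot <- tot + d2 / ncol(scales)
      }
      tot / (L - k)
    }, 0)
  }
  c(f, omega * theta) / (sum(f) + omega * sum(theta))
}

oracle_group_of <- function(res, grouping) {
  for (g in 1:3) if (res %in% grouping$groups[[g]]) return(g)
  stop("ungrouped residue ", res)
}

oracle_ctd_comp <- function(s, grouping) {
  ch <- strsplit(s, "")[[1]]
  v <- numeric(3)
  for (c in ch) v[oracle_group_of(c, grouping)] <- v[oracle_group_of(c, grouping)] + 1
  v / length(ch)
}

oracle_ctd_trans <- function(s, grouping) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  gi <- vapply(ch, oracle_group_of, 0L, grouping = grouping)
  pairs <- list(c(1, 2), c(2, 3), c(3, 1))
  v <- numeric(3)
  for (p in 1:3) {
    for (i in 1:(L - 1)) {
      ab <- sort(c(gi[i], gi[i + 1]))
      if (all(ab == sort(pairs[[p]]))) v[p] <- v[p] + 1
    }
  }
  v / (L - 1)
}

oracle_ctd_dist <- function(s, grouping) {
  ch <- strsplit(s, "")[[1]]
  gi <- vapply(ch, oracle_group_of, 0L, grouping = grouping)
  out <- numeric(0)
  for (g in 1:3) {
    pos <- which(gi == g)
    n <- length(pos)
    if (n == 0) { out <- c(out, rep(0, 5)); next }
    block <- numeric(5)
    fr <- c(NA, 0.25, 0.5, 0.75, NA)
    block[1] <- pos[1]
    block[5] <- pos[n]
    for (q in 2:4) block[q] <- pos[ceiling(fr[q] * n)]
    out <- c(out, block / length(ch))
  }
  out
}

oracle_svmprot188 <- function(s, groupings) {
  v <- oracle_aac(s)
  for (g in groupings)
    v <- c(v, oracle_ctd_comp(s, g), oracle_ctd_trans(s, g), oracle_ctd_dist(s, g))
  v
}

oracle_normalize_pssm <- function(E0) {
  E <- E0
  for (i in seq_len(nrow(E0))) {
    m <- mean(E0[i, ])
    rms <- sqrt(mean((E0[i, ] - m)^2))
    E[i, ] <- if (rms == 0) 0 else (E0[i, ] - m) / rms
  }
  E
}

oracle_psepssm <- function(E0, xi) {
  E <- oracle_normalize_pssm(E0)
  L <- nrow(E)
  ebar <- g <- numeric(20)
  for (j in 1:20) {
    ebar[j] <- sum(E[, j]) / L
    tot <- 0
    for (i in 1:(L - xi)) tot <- tot + (E[i, j] - E[i + xi, j])^2
    g[j] <- tot / (L - xi)
  }
  c(ebar, g)
}

# top generalized eigenvector of SW^-1 SB, by brute force
oracle_lda_direction <- function(X, y) {
  mu0 <- colMeans(X[y == 0, , drop = FALSE])
  mu1 <- colMeans(X[y == 1, , drop = FALSE])
  SW <- matrix(0, ncol(X), ncol(X))
  for (i in seq_len(nrow(X))) {
    mu <- if (y[i] == 1) mu1 else mu0
    SW <- SW + tcrossprod(X[i, ] - mu)
  }
  SB <- tcrossprod(mu0 - mu1)
  ev <- eigen(solve(SW) %*% SB)
  Re(ev$vectors[, which.max(Re(ev$values))])
}

oracle_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

cosine <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
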