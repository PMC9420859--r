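groupings <- load_groupings()
scales <- load_scales()

test_that("packaged tables satisfy their invariants", {
  expect_length(groupings, 8L)
  for (g in groupings) {
    res <- unlist(g$groups)
    expect_setequal(res, AAS)
    expect_equal(anyDuplicated(res), 0L)
  }
  expect_equal(colMeans(scales$standardized), rep(0, 9), ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_equal(colMeans(scales$standardized^2), rep(1, 9), ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_error(load_groupings(system.file("extdata", "pseaac_scales.tsv",
                                          package = "moonsvm")))
})

test_that("amino-acid composition matches hand counts and sums to 1", {
  expect_equal(unname(aac("AAAA")), c(1, rep(0, 19)))
  expect_equal(unname(aac("ACDE")), c(rep(0.25, 4), rep(0, 16)))
  expect_equal(unname(aac("AAC"))[1:2], c(2/3, 1/3))
  set.seed(31)
  for (s in replicate(20, random_seq(sample(2:80, 1))))
    expect_equal(sum(aac(s)), 1, tolerance = 1e-12)
})

test_that("pseaac degenerates correctly and follows the x_i formula", {
  # homopolymer: every pairwise property difference is 0, so all theta = 0
  v <- pseaac("AAAA", pseaac_config(tiers = 3L))
  expect_equal(unname(v[1]), 1)
  expect_equal(unname(v[-1]), rep(0, length(v) - 1))
  # lambda = 0 reduces to plain composition
  s <- random_seq(25)
  expect_equal(unname(pseaac(s, pseaac_config(mode = "pooled", lambda = 0))),
               unname(aac(s)))
  # ACACAC with a single scale: theta_1 = (h_A - h_C)^2, theta_2 = 0
  h <- scales$standardized[, "hydrophobic", drop = FALSE]
  v <- pseaac("ACACAC", pseaac_config(omega = 0.05, tiers = 2L, scales = h))
  t1 <- (h["A", 1] - h["C", 1])^2
  denom <- 1 + 0.05 * t1
  expect_equal(unname(v[c("AAC.A", "AAC.C")]), c(0.5, 0.5) / denom)
  expect_equal(unname(v[21:22]), c(0.05 * t1 / denom, 0))
})

test_that("pseaac default configuration is 65-D, non-negative, unit sum", {
  set.seed(32)
  for (s in replicate(10, random_seq(sample(10:60, 1)))) {
    v <- pseaac(s)
    expect_length(v, 65L)
    expect_true(all(v >= 0))
    expect_equal(sum(v), 1, tolerance = 1e-12)
  }
})

test_that("pseaac rejects sequences shorter than the lag structure", {
  expect_error(pseaac("ACDE", pseaac_config(tiers = 5L)), "lower tiers")
  expect_error(pseaac("AC", pseaac_config(mode = "pooled", lambda = 3L)), "lower")
})

test_that("shuffling changes only the pseudo components of pseaac", {
  set.seed(33)
  s <- random_seq(40)
  shuffled <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  v1 <- pseaac(s); v2 <- pseaac(shuffled)
  expect_equal(v1[1:20] * sum(v2[1:20]) / sum(v1[1:20]), v2[1:20], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(v1[21:65], v2[21:65])))
})

test_that("CTD composition matches the physicochemical group tables", {
  expect_equal(unname(ctd_composition("RKEDQN", groupings$hydrophobicity)), c(1, 0, 0))
  expect_equal(unname(ctd_composition("GC", groupings$hydrophobicity)), c(0, 0.5, 0.5))
  expect_equal(unname(ctd_composition("RG", groupings$charge)), c(0.5, 0.5, 0))
  set.seed(34)
  for (s in replicate(10, random_seq(sample(2:50, 1))))
    for (g in groupings) expect_equal(sum(ctd_composition(s, g)), 1, tolerance = 1e-12)
})

test_that("CTD transition counts unordered adjacent group changes over L-1", {
  for (g in groupings) expect_equal(unname(ctd_transition("RR", g)), c(0, 0, 0))
  expect_equal(unname(ctd_transition("RG", groupings$hydrophobicity)), c(1, 0, 0))
  expect_equal(unname(ctd_transition("RGC", groupings$hydrophobicity)), c(0.5, 0.5, 0))
})

test_that("CTD distribution uses ceiling occurrence indices over L", {
  d <- ctd_distribution("RRRR", groupings$hydrophobicity)
  expect_equal(unname(d), c(0.25, 0.25, 0.5, 0.75, 1, rep(0, 10)))
  d <- ctd_distribution("GR", groupings$hydrophobicity)
  expect_equal(unname(d), c(rep(1, 5), rep(0.5, 5), rep(0, 5)))
})

test_that("svmprot188 is the documented 20 + 8x21 concatenation", {
  set.seed(35)
  s <- random_seq(30)
  v <- svmprot188(s)
  expect_length(v, 188L)
  expect_equal(v[1:20], aac(s))
  # homopolymer: one 1 per composition block, zero transitions
  v <- svmprot188("AAAA")
  for (a in seq_len(8)) {
    comp <- v[20 + (a - 1) * 21 + 1:3]
    expect_equal(sort(unname(comp)), c(0, 0, 1))
    expect_equal(unname(v[20 + (a - 1) * 21 + 4:6]), c(0, 0, 0))
  }
})

test_that("sequence reversal preserves composition blocks of svmprot188", {
  set.seed(36)
  s <- random_seq(45)
  rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  v1 <- svmprot188(s); v2 <- svmprot188(rev_s)
  expect_equal(v1[1:20], v2[1:20])
  for (a in seq_len(8))
    expect_equal(v1[20 + (a - 1) * 21 + 1:3], v2[20 + (a - 1) * 21 + 1:3])
})

test_that("PSSM normalization centers rows and zeroes constant rows", {
  prof <- pssm_profile("x", rbind(rep(3, 20), sample(-5:14), rep(c(1, -1), 10)))
  norm <- normalize_pssm(prof)
  expect_equal(unname(norm$scores[1, ]), rep(0, 20))
  expect_equal(rowMeans(norm$scores), rep(0, 3), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unname(norm$scores[3, ]), rep(c(1, -1), 10))  # already mean 0, RMS 1
})

test_that("psepssm follows the mean / lag-correlation formulas", {
  r1 <- rnorm(20); r2 <- rnorm(20)
  prof <- pssm_profile("x", rbind(r1, r2))
  v <- psepssm(prof, xi = 1L, normalize = FALSE)
  expect_length(v, 40L)
  expect_equal(unname(v[1:20]), (r1 + r2) / 2)
  expect_equal(unname(v[21:40]), (r1 - r2)^2)
  # reversing row order leaves the G block unchanged at L = 2
  v_rev <- psepssm(pssm_profile("x", rbind(r2, r1)), xi = 1L, normalize = FALSE)
  expect_equal(v[21:40], v_rev[21:40])
  # constant columns after normalization give 40 zeros
  expect_equal(unname(psepssm(pssm_profile("x", matrix(7, 5, 20)))), rep(0, 40))
  expect_error(psepssm(pssm_profile("x", matrix(rnorm(20), 1, 20)), xi = 1L), "exceed")
})

test_that("every encoder is deterministic", {
  set.seed(37)
  s <- random_seq(50)
  expect_identical(svmprot188(s), svmprot188(s))
  expect_identical(pseaac(s), pseaac(s))
  prof <- generate_pssm(protein_set("p", s)[1, ], noise = 2, seed = 9)
  expect_identical(psepssm(prof), psepssm(prof))
})

test_that("encode_features stacks records and enforces PSSM availability", {
  recs <- generate_sequences(4, 3, c(20, 30), bias = 0.3, seed = 41)
  M <- encode_features(recs, "svmprot188")
  expect_equal(dim(M), c(7L, 188L))
  expect_equal(rownames(M), recs$id)
  expect_error(encode_features(recs, "psepssm"), "requires")
  profs <- generate_pssm_set(recs, noise = 1, seed = 42)
  expect_equal(dim(encode_features(recs, "psepssm", pssm = profs)), c(7L, 40L))
  expect_error(encode_features(recs, "psepssm", pssm = profs[-1]), recs$id[1])
})
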