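test_that("reference profiles are plain scale lookups with X as missing", {
  s <- toy_scale()
  p <- profile_reference("AV", s)
  expect_equal(p$values, c(0.1, 2.0))
  p2 <- profile_reference("AXA", s)
  expect_equal(p2$values, c(0.1, NA, 0.1))
  expect_length(profile_reference("", s)$values, 0)
})

test_that("family column stats use the population sd and track n", {
  ca <- crop_to_reference(aa_alignment(c("r", "f1", "f2"),
                                       c("AAA", "AA-", "AVX"), "r"))
  s <- toy_scale(values = c(1, rep(0, 17), 0, 3))  # A=1, V=3
  s$values[["V"]] <- 3
  st <- family_column_stats(ca, s)
  # column 1: {A,A} -> mean 1, sd 0, n 2
  expect_equal(st$mean[1], 1); expect_equal(st$sd[1], 0); expect_equal(st$n[1], 2L)
  # column 2: {A,V} = {1,3} -> mean 2, population sd 1
  expect_equal(st$mean[2], 2); expect_equal(st$sd[2], 1); expect_equal(st$n[2], 2L)
  # column 3: {-, X} -> nothing contributes
  expect_equal(st$n[3], 0L)
  expect_true(is.na(st$mean[3]) && is.na(st$sd[3]))
})

test_that("c-scores follow the deviation-over-sd formula with sigma flooring", {
  prof <- structure(list(characteristic_id = "t", values = c(5, 3, 4)),
                    class = "index_profile")
  st <- structure(list(characteristic_id = "t", mean = c(3, 3, 3),
                       sd = c(1, 0.5, 0), n = c(5L, 5L, 5L)),
                  class = "fam_stats")
  row <- c_scores(prof, st, sigma_floor_frac = 0.01)
  expect_equal(row$scores[1], 2.0)       # (5-3)/1
  expect_equal(row$scores[2], 0.0)       # zero numerator
  # sigma = 0: floor = 0.01 * median(positive sd {1, 0.5}) = 0.0075
  expect_equal(row$scores[3], (4 - 3) / 0.0075)
  expect_identical(row$sigma_floored, c(FALSE, FALSE, TRUE))
  # single positive sd 0.5 -> floor 0.005, so a conserved-column deviation of 1 scores 200
  st2 <- structure(list(characteristic_id = "t", mean = c(3, 3),
                        sd = c(0.5, 0), n = c(5L, 5L)), class = "fam_stats")
  prof2 <- structure(list(characteristic_id = "t", values = c(3, 4)),
                     class = "index_profile")
  row2 <- c_scores(prof2, st2)
  expect_equal(row2$scores[2], 200.0)
  expect_true(row2$sigma_floored[2])
  st_bad <- structure(list(characteristic_id = "t", mean = 1, sd = NA_real_,
                           n = 1L), class = "fam_stats")
  expect_error(c_scores(structure(list(characteristic_id = "t", values = 1),
                                  class = "index_profile"), st_bad),
               "no family variance")
})

test_that("missing inputs propagate missing c-scores", {
  ca <- crop_to_reference(aa_alignment(c("r", "f1", "f2"),
                                       c("XA", "AA", "VA"), "r"))
  s <- toy_scale()
  row <- c_scores(profile_reference(reference_sequence(ca), s),
                  family_column_stats(ca, s))
  expect_true(is.na(row$scores[1]))   # reference X
  expect_false(is.na(row$scores[2]))
})

test_that("identical reference and family residues give c-score 0 everywhere", {
  aln <- aa_alignment(c("r", "f1", "f2", "f3"),
                      rep("MKVDWE", 4), "r")
  ca <- crop_to_reference(aln)
  for (seed in 1:3) {
    s <- random_scale(sprintf("RS%06d", seed), seed)
    row <- c_scores(profile_reference(reference_sequence(ca), s),
                    family_column_stats(ca, s))
    expect_equal(row$scores, rep(0, 6))
  }
})

test_that("c-scores are invariant under positive affine index transforms", {
  aln <- random_alignment(8, 15, seed = 3)
  ca <- crop_to_reference(aln)
  ref <- reference_sequence(ca)
  for (seed in 1:10) {
    set.seed(seed)
    v <- rnorm(20); a <- runif(1, 0.1, 10); b <- rnorm(1, sd = 3)
    s1 <- toy_scale("AFF000101", v)
    s2 <- toy_scale("AFF000101", a * v + b)
    r1 <- c_scores(profile_reference(ref, s1), family_column_stats(ca, s1))
    r2 <- c_scores(profile_reference(ref, s2), family_column_stats(ca, s2))
    expect_equal(r1$scores, r2$scores, tolerance = 1e-9)
  }
})

test_that("the class representative is the first principal axis in residue space", {
  # k identical copies: exactly rank one
  s <- standardize_scale(random_scale("ID0000101", 11))
  copies <- lapply(1:4, function(i) { s$accession <- sprintf("ID%07d", i); s })
  pc <- pc1_scale(copies)
  expect_identical(pc$variance_explained, 1)
  expect_equal(abs(sum(pc$loadings * s$values / sqrt(sum(s$values^2)))), 1,
               tolerance = 1e-9)
  expect_equal(sum(pc$loadings^2), 1, tolerance = 1e-12)
  # two orthogonal equal-norm scales: symmetric split
  set.seed(12)
  v1 <- rnorm(20); v1 <- v1 - mean(v1)
  v2 <- rnorm(20); v2 <- v2 - mean(v2)
  v2 <- v2 - v1 * sum(v1 * v2) / sum(v1 * v1)
  v1 <- v1 / sqrt(sum(v1^2)); v2 <- v2 / sqrt(sum(v2^2))
  pc2 <- pc1_scale(list(toy_scale("OR0000101", v1), toy_scale("OR0000102", v2)))
  expect_equal(pc2$variance_explained, 0.5, tolerance = 1e-9)
  expect_error(pc1_scale(list(s)), ">= 2")
})

test_that("pc1 matches a brute-force eigendecomposition and ignores scale order", {
  scales <- lapply(1:5, function(i) standardize_scale(random_scale(sprintf("BF%07d", i), 20 + i)))
  pc <- pc1_scale(scales)
  # explicit-loop second-moment matrix and eigendecomposition
  X <- t(vapply(scales, function(s) unname(s$values), numeric(20)))
  C <- matrix(0, 20, 20)
  for (a in 1:20) for (b in 1:20) {
    acc <- 0
    for (i in 1:5) acc <- acc + X[i, a] * X[i, b]
    C[a, b] <- acc / 5
  }
  e <- eigen(C, symmetric = TRUE)
  expect_equal(pc$variance_explained, e$values[1] / sum(e$values), tolerance = 1e-9)
  expect_equal(abs(unname(pc$loadings)), abs(e$vectors[, 1]), tolerance = 1e-9)
  # orientation: positively correlated with the mean input scale
  expect_gte(sum(pc$loadings * colMeans(X)), 0)
  pc_perm <- pc1_scale(scales[c(3, 1, 5, 2, 4)])
  expect_equal(pc_perm$loadings, pc$loadings, tolerance = 1e-9)
  expect_equal(pc_perm$variance_explained, pc$variance_explained, tolerance = 1e-12)
})

test_that("pc1 drops scales with missing values with a warning", {
  s1 <- standardize_scale(random_scale("PM0000101", 1))
  s2 <- standardize_scale(random_scale("PM0000102", 2))
  s3 <- random_scale("PM0000103", 3)
  s3$values[["W"]] <- NA
  expect_warning(pc <- pc1_scale(list(s1, s2, s3)), "PM0000103")
  expect_equal(pc$n_indices_used, 2)
})

test_that("conservation rows are min-max normalized with conserved-constant fallback", {
  st <- structure(list(characteristic_id = "t", mean = c(0, 0, 0),
                       sd = c(0, 1, 2), n = c(3L, 3L, 3L)), class = "fam_stats")
  cr <- conservation_row(st)
  expect_equal(cr$display, c(0, 0.5, 1))
  st2 <- st; st2$sd <- c(0.7, 0.7, 0.7)
  expect_equal(conservation_row(st2)$display, c(0, 0, 0))
  st3 <- st; st3$sd <- c(0, NA, 2)
  d <- conservation_row(st3)$display
  expect_true(is.na(d[2]))
  expect_equal(d[c(1, 3)], c(0, 1))
})

test_that("score histograms cap at +/-3 and count clamped tails in edge bins", {
  h <- score_histogram(c(-5, 0, 5))
  expect_equal(sum(h$counts), 3)
  expect_equal(h$counts[1], 1); expect_equal(h$counts[40], 1)
  expect_equal(h$counts[21], 1)  # 0 lands in [0, 0.15)
  expect_equal(h$n_clamped_low, 1L); expect_equal(h$n_clamped_high, 1L)
  expect_length(h$bin_edges, 41)
  expect_equal(h$bin_edges[c(1, 41)], c(-3, 3))
  h0 <- score_histogram(numeric(0))
  expect_equal(sum(h0$counts), 0)
})

test_that("histogram binning matches an explicit loop oracle on normal draws", {
  set.seed(99)
  x <- rnorm(1000)
  h <- score_histogram(x)
  edges <- seq(-3, 3, length.out = 41)
  oracle <- integer(40)
  for (v in x) {
    vc <- min(max(v, -3), 3)
    placed <- FALSE
    for (b in 1:39) {
      if (vc >= edges[b] && vc < edges[b + 1]) { oracle[b] <- oracle[b] + 1L; placed <- TRUE; break }
    }
    if (!placed && vc >= edges[40] && vc <= edges[41]) oracle[40] <- oracle[40] + 1L
  }
  expect_identical(h$counts, oracle)
  expect_equal(sum(h$counts), 1000)
})

test_that("score filters select the closed interval over finite scores", {
  sc <- c(-1, -3, 0.2)
  expect_identical(filter_scores(sc, -2, -0.5), c(TRUE, FALSE, FALSE))
  expect_identical(filter_scores(c(sc, NA), -1e9, 1e9), c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(filter_scores(sc, -1, -1), c(TRUE, FALSE, FALSE))
  expect_error(filter_scores(sc, 1, -1), "out of order")
})

test_that("stack layout partitions by sign, clamps magnitudes, keeps raw scores", {
  m <- structure(list(characteristics = c("A", "B", "C"),
                      classes = c("other", "other", "other"),
                      scores = matrix(c(1, -2, 0, 7, NA, -0.5), nrow = 3),
                      L = 2L, ref_id = "r"),
                 class = "c_score_matrix")
  sl <- stack_layout(m)
  expect_identical(sl[[1]]$positive$characteristic, "A")
  expect_equal(sl[[1]]$positive$magnitude, 1)
  expect_identical(sl[[1]]$negative$characteristic, "B")
  expect_equal(sl[[1]]$negative$magnitude, 2)
  # +7 clamps to 3 for display, raw preserved
  expect_equal(sl[[2]]$positive$magnitude, 3)
  expect_equal(sl[[2]]$positive$raw, 7)
  expect_identical(sl[[2]]$negative$characteristic, "C")
  m0 <- m; m0$scores[] <- 0
  sl0 <- stack_layout(m0)
  expect_equal(nrow(sl0[[1]]$positive) + nrow(sl0[[1]]$negative), 0)
})

test_that("the score-matrix driver wires pc1 and indices modes consistently", {
  aln <- random_alignment(10, 20, seed = 5)
  ca <- crop_to_reference(aln)
  scales <- synth_scales(3, seed = 5)
  m <- build_score_matrix(ca, scales, mode = "pc1")
  expect_equal(dim(m$scores), c(6L, nchar(reference_sequence(ca))))
  expect_identical(m$classes, char_classes())
  accs <- vapply(scales, `[[`, character(1), "accession")[1:2]
  m2 <- build_score_matrix(ca, scales, mode = "indices", indices = accs)
  expect_identical(m2$characteristics, accs)
  expect_error(build_score_matrix(ca, scales, mode = "indices",
                                  indices = "NOPE000101"), "not found")
})
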