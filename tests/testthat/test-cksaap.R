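# CKSAAP encoding and feature selection.

test_that("a 21-residue window with gaps 0-4 yields 2205 features", {
  pep <- paste(rep("A", 21), collapse = "")
  v <- encode_cksaap(pep)
  expect_equal(ncol(v), 2205)
  expect_equal(ncol(v), length(cksaap_alphabet())^2 * 5)
})

test_that("encoding length is |alphabet|^2 x |k_set| for arbitrary alphabets", {
  withr::with_seed(5, {
    for (i in 1:10) {
      a <- sample(3:6, 1)
      alpha <- sample(LETTERS, a)
      ks <- sort(sample(0:3, sample(1:3, 1)))
      pep <- paste(sample(alpha, 12, replace = TRUE), collapse = "")
      v <- encode_cksaap(pep, k_set = ks, alphabet = alpha)
      expect_equal(ncol(v), a^2 * length(ks))
    }
  })
})

test_that("hand-enumerated small windows encode exactly", {
  # "XKA", gap 0: adjacent pairs XK and KA, each 1/2
  v <- encode_cksaap("XKA", k_set = 0)
  expect_equal(unname(v[1, "X.0.K"]), 0.5)
  expect_equal(unname(v[1, "K.0.A"]), 0.5)
  expect_equal(sum(v), 1)

  # poly-A window with a central K: (A,A,k) count is slots minus pairs
  # touching the K, i.e. (20-k) - 2 at every gap k of a 21-mer
  pep <- paste0(strrep("A", 10), "K", strrep("A", 10))
  v <- encode_cksaap(pep)
  for (k in 0:4) {
    slots <- 21 - k - 1
    expect_equal(unname(v[1, paste0("A.", k, ".A")]), (slots - 2) / slots)
    expect_equal(unname(v[1, paste0("A.", k, ".K")]), 1 / slots)
    expect_equal(unname(v[1, paste0("K.", k, ".A")]), 1 / slots)
  }
})

test_that("every k-block of every encoded window sums to one", {
  withr::with_seed(9, {
    peps <- vapply(1:50, function(i) {
      paste(sample(cksaap_alphabet(), 21, replace = TRUE), collapse = "")
    }, character(1))
    v <- encode_cksaap(peps)
    for (k in 0:4) {
      block <- v[, (k * 441 + 1):((k + 1) * 441)]
      expect_true(all(abs(rowSums(block) - 1) < 1e-12))
    }
  })
})

test_that("encoding rejects bad input", {
  expect_error(encode_cksaap(c("AKA", "AKAA")), "same length")
  expect_error(encode_cksaap("A1A", k_set = 0), "outside the alphabet")
  expect_error(encode_cksaap("AK", k_set = 0:4), "too short")
  expect_error(encode_cksaap(character(0)), "No peptides")
})

test_that("build_feature_matrix aligns rows with windows and keeps duplicates", {
  w <- tibble::tibble(
    protein_id = c("p", "p", "p"),
    position = c(1L, 5L, 5L),
    peptide = c("XKAAA", "AAKAA", "AAKAA"),
    label = c("positive", "unlabeled", "unlabeled")
  )
  fm <- build_feature_matrix(w, k_set = 0:1)
  expect_equal(nrow(fm$values), 3)
  expect_equal(ncol(fm$values), 441 * 2)
  expect_equal(fm$values[2, ], fm$values[3, ])
  expect_equal(fm$windows$label, w$label)
  expect_error(build_feature_matrix(w[0, ]), "No windows")
})

test_that("chi-square ranking matches the explicit contingency oracle", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      n1 <- sample(5:15, 1)
      n0 <- sample(5:15, 1)
      vals <- matrix(rbinom((n1 + n0) * 30, 1, 0.4) * runif((n1 + n0) * 30),
                     n1 + n0, 30)
      w <- tibble::tibble(protein_id = "p", position = seq_len(n1 + n0),
                          peptide = "AKA",
                          label = rep(c("positive", "unlabeled"), c(n1, n0)))
      fm <- build_feature_matrix(w, k_set = 0)
      fm$values <- vals
      fm$descriptors <- tibble::tibble(column = 1:30,
                                       name = paste0("f", 1:30))
      ranked <- chi_square_rank(fm)
      pos <- w$label == "positive"
      for (j in sample(30, 10)) {
        a <- sum(vals[pos, j] > 0); b <- n1 - a
        c_ <- sum(vals[!pos, j] > 0); d <- n0 - c_
        expect_equal(ranked$statistic[ranked$column == j],
                     chisq2x2(a, b, c_, d), tolerance = 1e-12)
        # cross-check against stats::chisq.test when margins allow
        if (all(c(a + b, c_ + d, a + c_, b + d) > 0) && (a + c_) < n1 + n0) {
          tab <- matrix(c(a, b, c_, d), 2)
          expect_equal(
            ranked$statistic[ranked$column == j],
            unname(suppressWarnings(
              stats::chisq.test(tab, correct = FALSE)$statistic)),
            tolerance = 1e-10
          )
        }
      }
      expect_true(all(diff(ranked$statistic) <= 1e-12))
    }
  })
})

test_that("chi-square edge cases: perfect split, independence, constants", {
  n <- 20
  w <- tibble::tibble(protein_id = "p", position = 1:n, peptide = "AKA",
                      label = rep(c("positive", "unlabeled"), each = 10))
  fm <- build_feature_matrix(w, k_set = 0)
  vals <- matrix(0, n, 3)
  vals[1:10, 1] <- 1                  # present in all positives only
  vals[c(1:5, 11:15), 2] <- 1         # same rate both classes
  # column 3 constant zero
  fm$values <- vals
  fm$descriptors <- tibble::tibble(column = 1:3, name = paste0("f", 1:3))
  ranked <- chi_square_rank(fm)
  expect_equal(ranked$statistic[ranked$column == 1], 20) # the 2x2 maximum n
  expect_equal(ranked$statistic[ranked$column == 2], 0)
  expect_equal(ranked$statistic[ranked$column == 3], 0)
  # zero ties broken by ascending column index
  expect_equal(ranked$column, c(1L, 2L, 3L))

  fm$windows$label <- rep("unlabeled", n)
  expect_error(chi_square_rank(fm), "both positive and unlabeled")
})

test_that("label permutation drives mean chi-square towards zero", {
  sim <- simulate_proteome(simulation_config(n_proteins = 30, site_rate = 0.4,
                                             annotation_rate = 1, seed = 13))
  w <- extract_windows(sim$proteins, sim$annotations)
  fm <- build_feature_matrix(w)
  observed <- mean(chi_square_rank(fm)$statistic[1:50])
  permuted <- withr::with_seed(99, {
    mean(vapply(1:3, function(i) {
      fm$windows$label <- sample(fm$windows$label)
      mean(chi_square_rank(fm)$statistic[1:50])
    }, numeric(1)))
  })
  expect_lt(permuted, observed)
})

test_that("select_top_features takes exactly the n best-ranked columns", {
  ranked <- tibble::tibble(rank = 1:10, column = c(4:1, 10:5),
                           name = letters[1:10], statistic = 10:1)
  sel <- select_top_features(ranked, 3)
  expect_equal(sel$column, c(4L, 3L, 2L))
  expect_error(select_top_features(ranked, 11), "between 1 and")
})

test_that("backward elimination steps down by 50 and clamps onto the target", {
  sim <- small_sim(seed = 17, n_proteins = 8)
  w <- extract_windows(sim$proteins, sim$annotations)
  fm <- build_feature_matrix(w, k_set = 0)  # 441 features for speed
  ranked <- chi_square_rank(fm)
  sizes_seen <- integer(0)
  # evaluator that prefers a mid-sized set, recording the sizes it saw
  res <- backward_feature_elimination(fm, ranked, step = 50, target = 150,
                                      evaluator = function(x, labels) {
                                        sizes_seen <<- c(sizes_seen, ncol(x))
                                        -abs(ncol(x) - 241)
                                      })
  expect_equal(sizes_seen, c(441, 391, 341, 291, 241, 191, 150))
  expect_equal(nrow(res$selected), 241)
  expect_equal(res$provenance$n_features, sizes_seen)
  expect_error(
    backward_feature_elimination(fm, ranked, step = 50, target = 150,
                                 evaluator = function(x, labels) stop("boom")),
    "iteration 1"
  )
})
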