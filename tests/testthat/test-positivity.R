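# A small locus with controlled counts: one novel query junction (Q)
# overlapped by an annotated (A) and a larger novel (C) junction, plus an
# isolated novel junction (I). Tumor totals make C the most abundant
# overall, A the most abundant annotated.
positivity_fixture <- function(countsQ, countsA, countsC, countsI,
                               tumor = 2, normal = 1) {
  keys <- c(Q = "1:1000-2000:+", A = "1:900-1500:+", C = "1:950-2500:+",
            I = "1:9000-9500:+")
  samples <- c(sprintf("T%d", seq_len(tumor)), sprintf("N%d", seq_len(normal)))
  k <- rbind(countsQ, countsA, countsC, countsI)
  dimnames(k) <- list(unname(keys), samples)
  man <- simple_manifest(sprintf("T%d", seq_len(tumor)),
                         sprintf("N%d", seq_len(normal)))
  cat_ <- catalog_from_matrix(unname(keys), k, man,
                              annotated = c(FALSE, TRUE, FALSE, FALSE))
  cat_
}

test_that("the dominant junction prefers annotated, falls back to most abundant", {
  cat_ <- positivity_fixture(countsQ = c(10, 10, 2),
                             countsA = c(500, 400, 100),   # total 900
                             countsC = c(1200, 800, 50),   # total 2000
                             countsI = c(50, 60, 5))
  dom <- dominantJunctions(cat_)
  # annotated A wins for Q despite C being more abundant
  expect_equal(dom["1:1000-2000:+", "dominant_key"], "1:900-1500:+")
  # C's own dominant: overlapping are Q (novel) and A (annotated) -> A
  expect_equal(dom["1:950-2500:+", "dominant_key"], "1:900-1500:+")
  # isolated junction has none
  expect_true(is.na(dom["1:9000-9500:+", "dominant_key"]))
})

test_that("an isolated junction is evaluated against its own count only", {
  cat_ <- positivity_fixture(countsQ = c(0, 0, 0), countsA = c(0, 0, 0),
                             countsC = c(0, 0, 0), countsI = c(25, 19, 2))
  calls <- positivityCalls(cat_)
  expect_equal(unname(calls@depth["1:9000-9500:+", ]), c(25, 19, 2))
  expect_equal(unname(calls@frequency["1:9000-9500:+", ]), c(1, 1, 1))
  # tumor: 25 >= 10/20/0.01 -> positive; 19 fails depth >= 20
  expect_equal(unname(isPositive(calls)["1:9000-9500:+", ]),
               c(TRUE, FALSE, FALSE))
})

test_that("tumor and normal threshold boundaries behave as specified", {
  # tumor boundary: count 10, dominant 10 -> depth 20, freq 0.5 -> positive
  cat_ <- positivity_fixture(countsQ = c(10, 15, 2),
                             countsA = c(10, 2000, 8),
                             countsC = c(0, 0, 0), countsI = c(0, 0, 0))
  calls <- positivityCalls(cat_)
  q <- isPositive(calls)["1:1000-2000:+", ]
  expect_true(q[["T1"]])
  # frequency 15/2015 < 0.01 -> negative despite high counts
  expect_false(q[["T2"]])
  expect_equal(calls@frequency["1:1000-2000:+", "T2"], 15 / 2015)
  # normal boundary: count 2, dominant 8 -> depth 10, freq 0.2 -> positive
  expect_true(q[["N1"]])
})

test_that("each positivity criterion fails when decremented by one unit", {
  mk <- function(q, a) {
    cat_ <- positivity_fixture(countsQ = c(q, 0, q), countsA = c(a, 0, a),
                               countsC = c(0, 0, 0), countsI = c(0, 0, 0))
    isPositive(positivityCalls(cat_))["1:1000-2000:+", c("T1", "N1")]
  }
  expect_equal(unname(mk(10, 10)), c(TRUE, TRUE))      # all tumor boundaries met
  expect_false(mk(9, 11)[["T1"]])                      # count 9 < 10
  expect_false(mk(10, 9)[["T1"]])                      # depth 19 < 20
  expect_true(mk(10, 990)[["T1"]])                     # freq exactly 0.01
  expect_false(mk(10, 991)[["T1"]])                    # freq below 0.01
  expect_equal(unname(mk(2, 8))[2], TRUE)              # normal boundaries met
  expect_false(mk(1, 9)[["N1"]])                       # count 1 < 2
  expect_false(mk(2, 7)[["N1"]])                       # depth 9 < 10
  expect_true(mk(2, 198)[["N1"]])                      # freq exactly 0.01
  expect_false(mk(2, 199)[["N1"]])                     # freq below 0.01
})

test_that("dominance is computed on tumor totals and reused for normals", {
  # in the normal sample, C dwarfs A; the dominant must still be A
  cat_ <- positivity_fixture(countsQ = c(10, 10, 5),
                             countsA = c(500, 400, 1),
                             countsC = c(100, 100, 9000),
                             countsI = c(0, 0, 0))
  calls <- positivityCalls(cat_)
  expect_equal(unname(calls@dominant_count["1:1000-2000:+", "N1"]), 1)
})

test_that("ties break deterministically by total then key", {
  keys <- c("1:100-200:+", "1:150-250:+", "1:120-260:+")
  k <- matrix(c(20, 50, 50,
                20, 50, 50), 3, 2, dimnames = list(keys, c("T1", "N1")))
  man <- simple_manifest("T1", "N1")
  cat_ <- catalog_from_matrix(keys, k, man, annotated = c(FALSE, FALSE, FALSE))
  dom <- dominantJunctions(cat_)
  # both overlapping candidates of the first junction total 50; the
  # lexicographically smaller key wins
  expect_equal(dom["1:100-200:+", "dominant_key"], "1:120-260:+")
})

test_that("vectorized calls equal the brute-force oracle on random catalogs", {
  for (seed in 1:5) {
    set.seed(seed)
    n_j <- 80; n_t <- 12; n_n <- 8
    chrom <- sample(c("1", "2"), n_j, replace = TRUE)
    st <- sample(1:4000, n_j)
    en <- st + sample(50:800, n_j, replace = TRUE)
    strand <- sample(c("+", "-", "*"), n_j, replace = TRUE, prob = c(.45, .45, .1))
    keys <- junctionKey(chrom, st, en, strand)
    dup <- duplicated(keys)
    keys <- keys[!dup]
    n_j <- length(keys)
    k <- matrix(rnbinom(n_j * (n_t + n_n), mu = 40, size = 2), n_j,
                dimnames = list(keys, c(sprintf("T%02d", 1:n_t),
                                        sprintf("N%02d", 1:n_n))))
    annotated <- runif(n_j) < 0.5
    man <- simple_manifest(sprintf("T%02d", 1:n_t), sprintf("N%02d", 1:n_n))
    cat_ <- catalog_from_matrix(keys, k, man, annotated)
    calls <- positivityCalls(cat_)
    oracle <- brute_force_positivity(rownames(cat_), counts(cat_),
                                     isAnnotated(cat_),
                                     cat_$cohort)
    expect_identical(unname(isPositive(calls)), unname(oracle$positive))
    expect_identical(unname(calls@dominant$dominant_key),
                     unname(oracle$dominant_key))
  }
})

test_that("PSR divides positives by the full fixed group denominator", {
  # 3 tumor groups of unequal size; junction positive in chosen samples
  ids <- sprintf("T%03d", 1:20)
  man <- simple_manifest(ids, "N1", groups = c(rep("G1", 10), rep("G2", 6),
                                               rep("G3", 4)))
  keys <- "1:100-200:+"
  k <- matrix(0, 1, 21, dimnames = list(keys, c(ids, "N1")))
  k[1, c(1:4, 11, 17:20)] <- 50  # isolated junction: count==depth, freq 1
  cat_ <- catalog_from_matrix(keys, k, man, annotated = FALSE)
  psr <- positiveSampleRate(positivityCalls(cat_), cat_@colData)
  expect_equal(psr[1, "G1"], 4 / 10)
  expect_equal(psr[1, "G2"], 1 / 6)
  expect_equal(psr[1, "G3"], 4 / 4)
  expect_equal(psr[1, "normal"], 0)
  expect_equal(attr(psr, "denominators")[["G1"]], 10L)
  # the printed-rate convention: 52 of 123 positives
  expect_equal(round(100 * 52 / 123, 1), 42.3)
})

test_that("PSR errors on empty groups and is monotone in sample positivity", {
  ids <- c("T1", "T2", "N1")
  man <- simple_manifest(c("T1", "T2"), "N1")
  keys <- "1:100-200:+"
  k <- matrix(c(5, 50, 0), 1, 3, dimnames = list(keys, ids))
  cat_ <- catalog_from_matrix(keys, k, man, annotated = FALSE)
  calls <- positivityCalls(cat_)
  psr0 <- positiveSampleRate(calls, cat_@colData)
  # raising the negative sample above all thresholds cannot lower PSR
  k2 <- k; k2[1, 1] <- 100
  cat2 <- catalog_from_matrix(keys, k2, man, annotated = FALSE)
  psr1 <- positiveSampleRate(positivityCalls(cat2), cat2@colData)
  expect_true(all(psr1 >= psr0))

  expect_error(positiveSampleRate(calls, man[man$cohort == "tumor", ]),
               "one row per sample")
})
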