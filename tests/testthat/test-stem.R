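test_that("profile enumeration counts and selection are as designed", {
  expect_equal(nrow(candidate_profiles(1L)), 27L)
  expect_equal(nrow(candidate_profiles(2L)), 125L)
  p <- enumerate_profiles(c = 2L, k = 20L)
  expect_equal(nrow(p), 20L)
  expect_equal(unlist(p[p$profile_id == 0, c("v1", "v2", "v3", "v4")],
                      use.names = FALSE), rep(0, 4))   # flat included
  expect_equal(anyDuplicated(p[c("v1", "v2", "v3", "v4")]), 0L)
  expect_true(all(p$v1 == 0))
  steps <- as.matrix(p[c("v2", "v3", "v4")]) -
    as.matrix(p[c("v1", "v2", "v3")])
  expect_true(all(abs(steps) <= 2))
  expect_error(enumerate_profiles(c = 1L, k = 30L), "k")
})

test_that("assignment maximizes correlation with deterministic ties", {
  prof <- enumerate_profiles()
  # a vector built from an enumerated shape is recovered with correlation 1
  shape <- unlist(prof[prof$profile_id == 1L, c("v1", "v2", "v3", "v4")])
  tp <- tibble::tibble(mirna_id = c("exact", "mono", "flat"),
                       CK = c(100 * 2^shape[1], 1, 5),
                       T1 = c(100 * 2^shape[2], 2, 5),
                       T2 = c(100 * 2^shape[3], 4, 5),
                       T3 = c(100 * 2^shape[4], 8, 5))
  a <- stem_assign(tp, prof, pseudocount = 0)
  expect_equal(a$correlation[1], 1)
  hit <- unlist(prof[prof$profile_id == a$profile_id[1],
                     c("v1", "v2", "v3", "v4")])
  expect_equal(abs(cor(hit, shape)), 1)   # collinear shape (ties by id)
  # monotone up vector lands on a monotone-up profile
  mono <- prof[prof$profile_id == a$profile_id[2], ]
  expect_true(all(diff(unlist(mono[c("v1", "v2", "v3", "v4")])) > 0))
  # zero-variance vector goes to the flat profile by convention
  expect_equal(a$profile_id[3], 0L)
  expect_true(is.na(a$correlation[3]))
})

test_that("permutation significance flags a planted profile", {
  set.seed(3)
  prof <- enumerate_profiles()
  n <- 100
  tp <- tibble::tibble(mirna_id = sprintf("g%03d", 1:n),
                       CK = rep(100, n),
                       T1 = 100 * 2^(-2 + rnorm(n, 0, 0.1)),
                       T2 = 100 * 2^(-1 + rnorm(n, 0, 0.1)),
                       T3 = 100 * 2^(0 + rnorm(n, 0, 0.1)))
  a <- stem_assign(tp, prof)
  sig <- profile_significance(a, prof, n_permutations = 500L, seed = 9L)
  most <- as.integer(names(which.max(table(a$profile_id))))
  planted <- sig[sig$profile_id == most, ]
  expect_lt(planted$p_value, 0.01)
  expect_true(planted$significant)
  # every DEM is assigned somewhere; profile counts sum to n
  expect_equal(sum(sig$n_assigned), n)
  expect_error(profile_significance(a, prof, n_permutations = 0L), ">= 1")
})

test_that("fixed seed gives bit-identical permutation p-values", {
  set.seed(4)
  prof <- enumerate_profiles()
  tp <- tibble::tibble(mirna_id = sprintf("g%02d", 1:30),
                       CK = runif(30, 50, 150), T1 = runif(30, 50, 150),
                       T2 = runif(30, 50, 150), T3 = runif(30, 50, 150))
  a <- stem_assign(tp, prof)
  s1 <- profile_significance(a, prof, n_permutations = 200L, seed = 5L)
  s2 <- profile_significance(a, prof, n_permutations = 200L, seed = 5L)
  expect_identical(s1, s2)
  # gene order does not change the observed assignment counts
  a2 <- stem_assign(tp[rev(seq_len(30)), ], prof)
  expect_equal(sort(table(a$profile_id)), sort(table(a2$profile_id)))
})

test_that("randomly shaped genes rarely produce significant profiles", {
  prof <- enumerate_profiles()
  hits <- 0L
  for (rep in 1:5) {
    set.seed(500 + rep)
    n <- 60
    tp <- tibble::tibble(mirna_id = sprintf("g%02d", 1:n),
                         CK = runif(n, 50, 150), T1 = runif(n, 50, 150),
                         T2 = runif(n, 50, 150), T3 = runif(n, 50, 150))
    a <- stem_assign(tp, prof)
    sig <- profile_significance(a, prof, n_permutations = 300L,
                                seed = rep)
    hits <- hits + as.integer(any(sig$significant))
  }
  expect_lte(hits, 1L)
})
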