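prof <- function(s) attribute_profile(s)

test_that("active attributes honour the compound-frequency threshold", {
  profiles <- lapply(c("C", "C", "Cl"), prof)
  expect_identical(active_attributes(profiles, 2L), "C")
  expect_identical(active_attributes(profiles, 1L), c("C", "Cl"))
  expect_length(active_attributes(lapply(c("C", "C"), prof), 3L), 0L)
  expect_error(active_attributes(list(), 1L), "empty")
})

test_that("threshold counts compounds containing an attribute, not occurrences", {
  # "CCCC" has 4 C occurrences but is a single compound
  profiles <- lapply(c("CCCC", "N"), prof)
  expect_false("C" %in% active_attributes(profiles, 2L))
})

test_that("dcw is the weighted attribute count sum", {
  p <- attribute_profile(c("C", "C"), tokenized = TRUE)
  expect_equal(dcw(p, c(C = 0.5, CC = 1.0)), 2.0)
  expect_equal(dcw(p, c(C = 0, CC = 0)), 0.0)
  # unseen attributes contribute zero
  expect_equal(dcw(p, c(N = 5)), 0.0)
})

test_that("dcw equals a brute-force term-by-term oracle on random inputs", {
  syn <- cw_synth(n = 40, seed = 9)
  set.seed(2)
  for (s in sample(syn$data$smiles, 15)) {
    toks <- tokenize_smiles(normalize_smiles(s))
    p <- attribute_profile(s)
    attrs <- names(profile_counts(p))
    w <- stats::setNames(rnorm(length(attrs)), attrs)
    # oracle: walk the token sequence summing weights term by term
    val <- sum(w[toks], na.rm = TRUE)
    if (length(toks) >= 2)
      val <- val + sum(w[pair_attribute(toks[-length(toks)], toks[-1])],
                       na.rm = TRUE)
    expect_equal(dcw(p, w), val, tolerance = 1e-12)
  }
})

test_that("blocked attributes never change the descriptor", {
  p <- attribute_profile("CCN")
  w <- c(C = 1, N = 2, CC = 3, NC = 4)
  full <- dcw(p, w)
  expect_equal(dcw(p, w, blocked = "N"), full - 2)
  expect_equal(dcw(p, w, blocked = names(w)), 0)
})

test_that("dcw is homogeneous and additive over attribute partitions", {
  p <- attribute_profile("CCN(CC)C(=S)N")
  attrs <- names(profile_counts(p))
  set.seed(5)
  w <- stats::setNames(rnorm(length(attrs)), attrs)
  expect_equal(dcw(p, 3 * w), 3 * dcw(p, w), tolerance = 1e-12)
  # partition: Sk-only plus SSk-only contributions add up
  w_sk <- w[names(w) %in% names(p$sk_counts)]
  w_ssk <- w[names(w) %in% names(p$ssk_counts)]
  expect_equal(dcw(p, w), dcw(p, w_sk) + dcw(p, w_ssk), tolerance = 1e-12)
})

test_that("calibration line matches least squares exactly", {
  expect_equal(fit_calibration_line(c(1, 2, 3), c(2, 4, 6)),
               c(c0 = 0, c1 = 2))
  expect_equal(fit_calibration_line(c(1, 2, 3), c(5, 5, 5)),
               c(c0 = 5, c1 = 0))
  expect_error(fit_calibration_line(c(2, 2, 2), c(1, 2, 3)), "degenerate")
  set.seed(8)
  x <- rnorm(50); y <- 1.5 - 2 * x + rnorm(50)
  got <- fit_calibration_line(x, y)
  ref <- stats::coef(stats::lm(y ~ x))
  expect_equal(unname(got), unname(ref), tolerance = 1e-10)
})

test_that("noiseless synthetic data is reproduced exactly by the true weights", {
  syn <- cw_synth(n = 40, noise = 0, seed = 13)
  tr <- synth_truth()
  d <- vapply(syn$data$smiles, function(s)
    dcw(attribute_profile(s), tr$weights), numeric(1))
  line <- fit_calibration_line(d, syn$data$endpoint)
  expect_equal(unname(line), c(tr$c0, 1), tolerance = 1e-8)
  pred <- line["c0"] + line["c1"] * d
  expect_equal(unname(pred), syn$data$endpoint, tolerance = 1e-8)
})

test_that("scaling all weights leaves predictions unchanged after refit", {
  syn <- cw_synth(n = 40, noise = 0.2, seed = 17)
  tr <- synth_truth()
  d <- vapply(syn$data$smiles, function(s)
    dcw(attribute_profile(s), tr$weights), numeric(1))
  alpha <- 3.7
  d2 <- vapply(syn$data$smiles, function(s)
    dcw(attribute_profile(s), alpha * tr$weights), numeric(1))
  expect_equal(d2, alpha * d, tolerance = 1e-10)
  l1 <- fit_calibration_line(d, syn$data$endpoint)
  l2 <- fit_calibration_line(d2, syn$data$endpoint)
  expect_equal(l2[["c1"]], l1[["c1"]] / alpha, tolerance = 1e-10)
  expect_equal(l1[["c0"]] + l1[["c1"]] * d,
               l2[["c0"]] + l2[["c1"]] * d2, tolerance = 1e-10)
})
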