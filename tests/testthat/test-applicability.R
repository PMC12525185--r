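test_that("attribute defects follow the three-set disagreement formula", {
  # equal probabilities cancel exactly
  expect_equal(attribute_defect(10, 10, 10, 50, 50, 50), 0)
  expect_equal(attribute_defect(5, 10, 15, 10, 20, 30), 0)
  # absence from one set is maximal unreliability
  expect_equal(attribute_defect(2, 1, 0, 63, 63, 65), 1.0)
  expect_equal(attribute_defect(0, 3, 4, 63, 63, 65), 1.0)
  expect_error(attribute_defect(0, 0, 0, 10, 10, 10), "unknown attribute")
  # hand-arithmetic oracle on a published-style frequency row
  nA <- 41; nP <- 43; nC <- 39; sA <- 63; sP <- 63; sC <- 65
  pA <- nA / sA; pP <- nP / sP; pC <- nC / sC
  oracle <- abs(pA - pP) / (nA + nP) + abs(pA - pC) / (nA + nC) +
    abs(pP - pC) / (nP + nC)
  expect_equal(attribute_defect(nA, nP, nC, sA, sP, sC), oracle,
               tolerance = 1e-14)
})

test_that("defects are symmetric under permutations of the three sets", {
  vals <- expand.grid(list(c(1, 3), c(2, 5), c(4, 7)))
  base <- attribute_defect(3, 5, 7, 20, 30, 40)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  n <- c(3, 5, 7); s <- c(20, 30, 40)
  for (p in perms)
    expect_equal(attribute_defect(n[p[1]], n[p[2]], n[p[3]],
                                  s[p[1]], s[p[2]], s[p[3]]),
                 base, tolerance = 1e-14)
})

test_that("the domain rule is strict at exactly twice the mean defect", {
  expect_true(in_domain(0, 1))
  expect_false(in_domain(2, 1))
  expect_true(in_domain(1.9, 1))
  expect_error(in_domain(1, 0), "positive")
})

syn <- tiny_dataset(n = 80, seed = 23)
sp <- cw_split(syn$data$id, seed = 23)
fit <- cw_fit(syn$data, sp, cw_control("TF1", epochs = 3, seed = 1))

test_that("compound defects equal a brute-force re-summation", {
  def <- fit$domain$defects
  dk <- stats::setNames(def$dk, def$attribute)
  set.seed(6)
  for (i in sample(nrow(syn$data), 10)) {
    p <- attribute_profile(syn$data$smiles[i])
    cnt <- cwqsar:::profile_counts(p)
    cnt <- cnt[!(names(cnt) %in% fit$blocked)]
    oracle <- sum(cnt * ifelse(is.na(dk[names(cnt)]), 1, dk[names(cnt)]))
    expect_equal(compound_defect(p, fit$domain, fit$blocked), oracle,
                 tolerance = 1e-12)
    expect_equal(fit$domain$dj[[syn$data$id[i]]], oracle, tolerance = 1e-12)
  }
})

test_that("compound defects are additive over concatenated molecules", {
  p1 <- attribute_profile("CCN")
  p2 <- attribute_profile("Oc1ccccc1")
  combined <- attribute_profile(c(
    tokenize_smiles(normalize_smiles("CCN")),
    tokenize_smiles(normalize_smiles("Oc1ccccc1"))), tokenized = TRUE)
  d1 <- compound_defect(p1, fit$domain, fit$blocked)
  d2 <- compound_defect(p2, fit$domain, fit$blocked)
  dc <- compound_defect(combined, fit$domain, fit$blocked)
  # the junction pair "cN"-style attribute adds a non-negative extra term
  expect_gte(dc + 1e-12, d1 + d2)
})

test_that("adding attributes never lowers the compound defect", {
  base <- attribute_profile("CC")
  bigger <- attribute_profile("CCC")
  expect_gte(compound_defect(bigger, fit$domain, fit$blocked),
             compound_defect(base, fit$domain, fit$blocked) - 1e-12)
})

test_that("planted alien compounds are flagged as outliers", {
  # five compounds made only of attributes absent from A/P/C training sets
  alien <- data.frame(id = paste0("alien", 1:5),
                      smiles = rep("[Xx][Xx][Xx][Xx][Xx][Xx][Xx][Xx]", 5),
                      stringsAsFactors = FALSE)
  pred <- predict(fit, alien, domain = TRUE)
  expect_true(all(!pred$in_domain))
  # typical training compounds are mostly in domain
  self_pred <- predict(fit, domain = TRUE)
  expect_gt(mean(self_pred$in_domain), 0.5)
})

test_that("outliers are grouped by split membership and counted", {
  out <- cw_outliers(fit)
  expect_equal(sum(out$counts), out$total)
  expect_named(out$by_set, c("A", "P", "C", "V"))
  dj <- fit$domain$dj
  expect_equal(out$total, sum(dj >= 2 * fit$domain$dbar))
})

test_that("identically distributed sets give few outliers at modest size", {
  syn2 <- tiny_dataset(n = 120, seed = 31)
  sp2 <- cw_split(syn2$data$id, seed = 31)
  f2 <- cw_fit(syn2$data, sp2, cw_control("TF0", epochs = 2, seed = 1))
  expect_lt(cw_outliers(f2)$total / 120, 0.35)
})
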