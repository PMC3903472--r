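test_that("methylation frequency is percent of evaluable samples, 1 decimal", {
  calls <- data.frame(sample = paste0("S", 1:16), gene = "P16",
                      state = rep(c("M", "U"), c(9, 7)))
  expect_equal(methylation_frequency(calls, "P16")$percent, 56.2)
  allm <- transform(calls, state = "M")
  expect_equal(methylation_frequency(allm, "P16")$percent, 100)
  allu <- transform(calls, state = "U")
  expect_equal(methylation_frequency(allu, "P16")$percent, 0)
  # NA states drop gene-wise
  calls$state[1:4] <- NA
  f <- methylation_frequency(calls, "P16")
  expect_equal(f$n_evaluable, 12L)
  expect_warning(methylation_frequency(calls, "P16", subset = "nope"),
                 "no evaluable")
})

test_that("stratified association reproduces the Pearson chi-square", {
  clin <- data.frame(sample = paste0("S", 1:27),
                     sex = rep(c("M", "F"), c(16, 11)),
                     msi = "MSS", location = "L",
                     differentiation = "Well", age = 60)
  # males 9 M / 7 U, females 1 M / 10 U
  calls <- data.frame(sample = paste0("S", 1:27), gene = "RET",
                      state = c(rep("M", 9), rep("U", 7),
                                "M", rep("U", 10)))
  row <- stratified_association(calls, clin, "RET", "sex")
  expect_equal(row$method, "chisq")
  expect_equal(row$p, 0.0127, tolerance = 0.01)
  expect_equal(row$pct_M, 56.2)
  expect_equal(row$pct_F, 9.1)
})

test_that("degenerate tables report NA with a reason; tiny cells go to Fisher", {
  clin <- data.frame(sample = paste0("S", 1:10),
                     sex = rep(c("M", "F"), 5), msi = "MSS",
                     location = "L", differentiation = "Well", age = 50)
  allm <- data.frame(sample = paste0("S", 1:10), gene = "SYNE1",
                     state = "M")
  row <- stratified_association(allm, clin, "SYNE1", "sex")
  expect_true(is.na(row$p))
  expect_match(row$note, "no variation")
  sparse <- data.frame(sample = paste0("S", 1:10), gene = "ICAM5",
                       state = c("M", rep("U", 9)))
  row2 <- stratified_association(sparse, clin, "ICAM5", "sex")
  expect_equal(row2$method, "fisher")
})

test_that("age dichotomises at 60 and MSI means MSI-H only", {
  clin <- data.frame(sample = paste0("S", 1:6),
                     age = c(59, 60, 61, 30, 70, 65),
                     msi = c("MSS", "MSI-L", "MSI-H", "MSI-H", "MSS",
                             "MSS"),
                     sex = "M", location = "L", differentiation = "Well")
  f_age <- oncoclade:::.stratum_factor(clin, "age")
  expect_equal(as.character(f_age),
               c("<60", ">=60", ">=60", "<60", ">=60", ">=60"))
  f_msi <- oncoclade:::.stratum_factor(clin, "msi")
  expect_equal(sum(f_msi == "MSI-H"), 2)
})

test_that("chi-square p approaches a conditional permutation oracle", {
  # the permutation null conditions on both margins and is discrete, so
  # at MSP-panel sample sizes the asymptotic p can sit several hundredths
  # away; it converges as n grows
  mk <- function(n, states, sexes) {
    clin <- data.frame(sample = paste0("S", seq_len(n)), sex = sexes,
                       msi = "MSS", location = "L",
                       differentiation = "Well", age = 50)
    calls <- data.frame(sample = clin$sample, gene = "G", state = states)
    list(p = stratified_association(calls, clin, "G", "sex")$p,
         tab = table(states, sexes))
  }
  small <- mk(24, c(rep("M", 8), rep("U", 4), rep("M", 3), rep("U", 9)),
              rep(c("M", "F"), each = 12))
  set.seed(1)
  perm_small <- chisq.test(small$tab, correct = FALSE,
                           simulate.p.value = TRUE, B = 20000)$p.value
  expect_lt(abs(small$p - perm_small), 0.1)
  big <- mk(100, rep(c("M", "U", "M", "U"), c(30, 20, 15, 35)),
            rep(c("M", "F"), each = 50))
  set.seed(1)
  perm_big <- chisq.test(big$tab, correct = FALSE,
                         simulate.p.value = TRUE, B = 20000)$p.value
  se <- sqrt(perm_big * (1 - perm_big) / 20000)
  expect_lt(abs(big$p - perm_big), 3 * se + 0.01)
})

test_that("the planted methylation-MSI association is detectable at n = 200", {
  hits <- 0L
  for (r in 1:10) {
    coh <- generate_cohort(cohort_config(n_samples = 200, seed = 300 + r))
    sa <- stratified_association(coh$methylation_calls, coh$samples,
                                 "P16", "msi")
    if (!is.na(sa$p) && sa$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("methylation_table covers every gene-covariate pair", {
  coh <- generate_cohort(cohort_config(n_samples = 30, seed = 12))
  tab <- methylation_table(coh$methylation_calls, coh$samples)
  expect_equal(nrow(tab), 15 * 5)
  expect_true(all(tab$method %in% c("chisq", "fisher", "none")))
})
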