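test_that("confusion arithmetic reproduces the small-scale validation", {
  ## 5 pathogenic variants, 2 failing to complement; 2 proxy-benign + WT
  ## complementing; non-complementation called pathogenic
  complemented <- c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)
  pathogenic <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  cs <- confusionStats(!complemented, pathogenic)
  expect_equal(cs$precision, 1.0)
  expect_equal(cs$recall, 0.4)
})

test_that("perfect separation gives AUBPRC and R90BP of 1", {
  scores <- c(p1 = 0.1, p2 = 0.2, n1 = 0.8, n2 = 0.9)
  rs <- list(positives = c("p1", "p2"), negatives = c("n1", "n2"))
  rep <- balancedPrcCurve(scores, rs, minScored = 2L)
  expect_equal(aubprc(rep), 1.0)
  expect_equal(r90bp(rep), 1.0)
})

test_that("zero false positives give balanced precision 1 at any recall", {
  ## recall 0.40 with FPR 0 at some threshold -> balanced precision 1
  scores <- setNames(c(seq(0.1, 0.5, length.out = 5),
                       seq(0.6, 1.4, length.out = 5)),
                     c(paste0("p", 1:5), paste0("n", 1:5)))
  rs <- list(positives = paste0("p", 1:5), negatives = paste0("n", 1:5))
  cv <- curvePoints(balancedPrcCurve(scores, rs))
  pt <- cv[abs(cv$recall - 0.4) < 1e-9, ]
  expect_true(any(pt$fpr == 0 & pt$balanced_precision == 1))
})

test_that("balanced precision equals ordinary precision for equal-size sets", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(3:6, 1)
    sp <- round(runif(n), 2)
    sn <- round(runif(n), 2)
    scores <- setNames(c(sp, sn), c(paste0("p", 1:n), paste0("n", 1:n)))
    rs <- list(positives = paste0("p", 1:n), negatives = paste0("n", 1:n))
    cv <- curvePoints(balancedPrcCurve(scores, rs, minScored = 3L))
    for (k in seq_len(nrow(cv))) {
      tp <- sum(sp <= cv$threshold[k])
      fp <- sum(sn <= cv$threshold[k])
      expect_equal(cv$balanced_precision[k], tp / (tp + fp))
    }
  }
})

test_that("AUBPRC is invariant under strictly monotone score transforms", {
  set.seed(5)
  scores <- setNames(c(rnorm(40, 0, 0.4), rnorm(40, 1, 0.4)),
                     c(paste0("p", 1:40), paste0("n", 1:40)))
  rs <- list(positives = paste0("p", 1:40), negatives = paste0("n", 1:40))
  a1 <- aubprc(balancedPrcCurve(scores, rs))
  a2 <- aubprc(balancedPrcCurve(sign(scores) * abs(scores)^3 + 2, rs))
  expect_equal(a1, a2)
})

test_that("the Epanechnikov KDE matches stats::density and integrates to 1", {
  set.seed(9)
  x <- rnorm(50)
  bw <- bw.SJ(x)
  grid <- seq(min(x) - 3 * bw, max(x) + 3 * bw, length.out = 512)
  mine <- mavemap:::epanechnikovDensity(grid, x, bw)
  ref <- density(x, bw = bw, kernel = "epanechnikov", n = 512,
                 from = min(grid), to = max(grid))
  ## density() bins the data onto an FFT grid, so agreement is approximate
  expect_lt(max(abs(mine - ref$y)), 5e-3)

  ## quadrature: each fitted density integrates to 1
  g2 <- seq(min(x) - bw * sqrt(5), max(x) + bw * sqrt(5),
            length.out = 4096)
  f <- mavemap:::epanechnikovDensity(g2, x, bw)
  integral <- sum((f[-1] + f[-length(f)]) / 2 * diff(g2))
  expect_lt(abs(integral - 1), 1e-3)
})

make_llr_refsets <- function(n = 40L, seed = 3L) {
  set.seed(seed)
  pos_scores <- rnorm(n, 0.05, 0.15)
  neg_scores <- rnorm(n, 1, 0.12)
  scores <- setNames(c(pos_scores, neg_scores, runif(30)),
                     c(paste0("p", 1:n), paste0("n", 1:n),
                       paste0("q", 1:30)))
  list(scores = scores,
       rs = list(positives = paste0("p", 1:n),
                 negatives = paste0("n", 1:n)))
}

test_that("LLRp is zero at equal densities and antisymmetric under swap", {
  fx <- make_llr_refsets()
  llr <- kdeLlr(fx$scores, fx$rs)
  swapped <- kdeLlr(fx$scores, list(positives = fx$rs$negatives,
                                    negatives = fx$rs$positives))
  expect_equal(llr$llr, -swapped$llr)
  ## pathogenic-mode scores get positive LLRp, benign-mode negative
  expect_true(all(llr$llr[match(fx$rs$positives, llr$hgvs_p)] > 0))
  expect_true(all(llr$llr[match(fx$rs$negatives, llr$hgvs_p)] < 0))

  ## identical reference sets make every ratio exactly zero
  same <- kdeLlr(fx$scores, list(positives = fx$rs$positives,
                                 negatives = fx$rs$positives))
  expect_true(all(same$llr == 0))

  const <- setNames(rep(0.5, 25), paste0("c", 1:25))
  expect_error(kdeLlr(c(fx$scores, const),
                      list(positives = names(const),
                           negatives = fx$rs$negatives)),
               "bandwidth")
})

test_that("bootstrap intervals are deterministic and cover the estimate", {
  fx <- make_llr_refsets()
  ci1 <- llrConfidenceIntervals(fx$scores, fx$rs, nBoot = 200L, seed = 4L)
  ci2 <- llrConfidenceIntervals(fx$scores, fx$rs, nBoot = 200L, seed = 4L)
  expect_identical(ci1, ci2)
  covered <- mean(ci1$llr >= ci1$ci_lo & ci1$llr <= ci1$ci_hi)
  expect_gte(covered, 0.95)
  expect_error(llrConfidenceIntervals(fx$scores, fx$rs, nBoot = 50L),
               ">= 200")
})

test_that("evidence strengths follow the odds-of-pathogenicity ladder", {
  expect_identical(evidenceStrength(0), "indeterminate")
  sup <- log(350) / 8
  expect_identical(evidenceStrength(log(350^(1 / 4)),
                                    ciLo = 0.1, ciHi = 3),
                   "pathogenic_moderate")
  expect_identical(evidenceStrength(-sup - 1e-6, ciLo = -2, ciHi = -0.01),
                   "benign_supporting")
  expect_identical(evidenceStrength(log(350) + 0.1, ciLo = 1, ciHi = 9),
                   "pathogenic_very_strong")
  ## CI crossing zero gates the call down to indeterminate
  expect_identical(evidenceStrength(2, ciLo = -0.5, ciHi = 4),
                   "indeterminate")
  ## ungated call stands
  expect_identical(evidenceStrength(3), "pathogenic_strong")
  expect_error(evidenceStrength(1, opVst = 0.5), "opVst")
})

test_that("label noise does not increase expected discrimination", {
  ## truth-effect scores over a seed grid; AUBPRC means must be
  ## non-increasing in label noise
  cfg <- simulationConfig(L = 60L, seed = 1L)
  truth <- simulateTruth(enumerateVariantSpace(randomOrf(60L, seed = 1L)),
                         cfg)
  scores <- setNames(truth$true_effect, truth$hgvs_p)
  mean_auc <- vapply(c(0, 0.25, 0.5), function(noise) {
    mean(vapply(1:5, function(s) {
      rs <- simulateReferenceSets(truth, nPos = 40L, nNeg = 40L,
                                  labelNoise = noise, seed = s)
      aubprc(balancedPrcCurve(scores, rs))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_auc) <= 1e-9))
})

test_that("calibrateMap assembles curve, LLRp, intervals and evidence", {
  fx <- make_llr_refsets(n = 30L)
  rep <- calibrateMap(fx$scores, fx$rs, nBoot = 200L, seed = 2L)
  llr <- llrTable(rep)
  expect_true(all(c("llr", "ci_lo", "ci_hi", "evidence") %in%
                  colnames(llr)))
  expect_true(all(llr$ci_lo <= llr$llr + 1e-9 &
                  llr$llr <= llr$ci_hi + 1e-9))
  expect_gt(aubprc(rep), 0.95)
  expect_true(all(llr$evidence %in%
    c("indeterminate",
      paste0("pathogenic_", c("supporting", "moderate", "strong",
                              "very_strong")),
      paste0("benign_", c("supporting", "moderate", "strong",
                          "very_strong")))))
})
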