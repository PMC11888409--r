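test_that("an empty score set yields an all-missing map of the right shape", {
  ss <- scoreSetFixture(integer(0), character(0), character(0), numeric(0))
  em <- buildEffectMap(ss, "MAG", threshold = 0.5)
  expect_identical(dim(scoreMatrix(em)), c(3L, 21L))
  cls <- classMatrix(em)
  expect_identical(sum(cls == "wt"), 3L)
  expect_identical(sum(cls == "missing"), 3L * 21L - 3L)
})

test_that("cells are classified by threshold, hyper rule and wt identity", {
  ss <- scoreSetFixture(position = c(1, 2, 2),
                        from_aa = c("M", "A", "A"),
                        to_aa = c("V", "D", "W"),
                        score = c(0.4, 1.5, 0.8),
                        se = c(0.05, 0.1, 0.1))
  em <- buildEffectMap(ss, "MAG", threshold = 0.5)
  cls <- classMatrix(em)
  expect_identical(cls[1, "V"], "damaging")   # 0.4 < 0.5
  expect_identical(cls[2, "D"], "hyper")      # 1.5 > 1 + 2 * 0.1
  expect_identical(cls[2, "W"], "tolerated")
  expect_identical(cls[1, "M"], "wt")
  ## completeness accounting
  counts <- table(factor(cls, c("damaging", "tolerated", "hyper",
                                "missing", "wt")))
  expect_identical(sum(counts), 3L * 21L)
  expect_identical(unname(counts[["wt"]]), 3L)

  ## numbering mismatch is an error
  bad <- scoreSetFixture(1, "Q", "V", 0.5)
  expect_error(buildEffectMap(bad, "MAG"), "numbering mismatch")
  out <- scoreSetFixture(9, "M", "V", 0.5)
  expect_error(buildEffectMap(out, "MAG"), "outside")
})

test_that("the bimodal threshold is found near the density valley", {
  set.seed(101)
  x <- c(rnorm(1000, 0, 0.05), rnorm(1000, 1, 0.05))
  thr <- findBimodalThreshold(x)
  expect_lt(abs(thr - 0.5), 0.1)
  modes <- attr(thr, "modes")
  expect_lt(abs(modes[1]), 0.05)
  expect_lt(abs(modes[2] - 1), 0.05)

  ## translation equivariance (up to the 1024-point evaluation grid)
  thr2 <- findBimodalThreshold(x + 3)
  expect_lt(abs(as.numeric(thr2) - (as.numeric(thr) + 3)), 0.01)

  ## unimodal data falls back with a warning
  y <- rnorm(2000, 1, 0.05)
  expect_warning(thr3 <- findBimodalThreshold(y, fallback = -0.4),
                 "unimodal")
  expect_identical(thr3, -0.4)

  expect_error(findBimodalThreshold(rnorm(50)), ">= 100")
})

test_that("deleteriousness vectors find the damaging target residue", {
  ## proline substitutions score 0, everything else 1
  pos <- rep(1:10, each = 19)
  from <- rep(c("M", "A", "G", "L", "K", "S", "T", "V", "I", "F"),
              each = 19)
  to <- unlist(lapply(seq_len(10), function(p) {
    setdiff(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
              "P", "Q", "R", "S", "T", "V", "W", "Y"),
            from[(p - 1) * 19 + 1])
  }))
  score <- ifelse(to == "P", 0, 1)
  ss <- scoreSetFixture(pos, from, to, score)
  em <- buildEffectMap(ss, paste(unique(from), collapse = ""))
  dv <- deleteriousnessVectors(em)
  expect_identical(names(which.min(dv$to)), "P")

  ## identity and antisymmetry of the reference correlation, on a map with
  ## graded per-target severity
  aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
            "P", "Q", "R", "S", "T", "V", "W", "Y")
  graded <- match(to, aa20) / 20
  emg <- buildEffectMap(scoreSetFixture(pos, from, to, graded),
                        paste(unique(from), collapse = ""))
  dvg <- deleteriousnessVectors(emg, referenceTo = dvg_ref <-
                                  deleteriousnessVectors(emg)$to)
  expect_equal(dvg$to_cor$rho, 1)
  expect_equal(deleteriousnessVectors(emg,
                                      referenceTo = -dvg_ref)$to_cor$rho,
               -1)

  ## constant vector reports undefined, not NaN
  cst <- setNames(rep(1, 20), names(dv$to))
  em2 <- buildEffectMap(scoreSetFixture(pos, from, to, rep(1, length(to))),
                        paste(unique(from), collapse = ""))
  res <- deleteriousnessVectors(em2, referenceTo = cst)
  expect_identical(res$to_cor$note, "undefined")
  expect_true(is.na(res$to_cor$rho))
})

test_that("the Mann-Whitney U statistic and exact p follow enumeration", {
  mw <- mannWhitneyU(c(0, 0, 0), c(1, 1, 1))
  expect_identical(mw$U, 0)
  expect_equal(mw$p, 0.1)
  expect_identical(mw$method, "exact enumeration")

  ## identical groups: U = n^2/2, p = 1
  mw2 <- mannWhitneyU(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mw2$U, 4.5)
  expect_equal(mw2$p, 1)
})

test_that("exact Mann-Whitney p agrees with an independent permutation oracle", {
  oracle <- function(x, y) {
    pool <- c(x, y); m <- length(x)
    u_of <- function(a, b) {
      u <- 0
      for (ai in a) for (bi in b)
        u <- u + (ai > bi) + 0.5 * (ai == bi)
      u
    }
    obs <- u_of(x, y)
    sel <- combn(length(pool), m)
    us <- numeric(ncol(sel))
    for (k in seq_len(ncol(sel)))
      us[k] <- u_of(pool[sel[, k]], pool[-sel[, k]])
    min(1, 2 * min(mean(us <= obs + 1e-9), mean(us >= obs - 1e-9)))
  }
  set.seed(17)
  for (i in 1:8) {
    x <- sample(0:3, sample(3:6, 1), replace = TRUE)
    y <- sample(0:3, sample(3:6, 1), replace = TRUE)
    mw <- mannWhitneyU(x, y)
    expect_equal(mw$p, oracle(x, y), tolerance = 1e-12,
                 label = paste("case", i))
  }
})

test_that("property-group comparisons run with BH adjustment", {
  run <- defaultRunFixture()
  em <- buildEffectMap(run$scores,
                       vapply(split(run$variants$from_aa,
                                    run$variants$position),
                              `[`, character(1), 1L),
                       threshold = 0.5)
  gc <- comparePropertyGroups(em)
  expect_true(all(c("contrast", "delta_median", "U", "p", "p_adj") %in%
                  colnames(gc)))
  expect_true(all(gc$p_adj >= gc$p - 1e-12))
  ## BH is monotone in the sorted p-values
  o <- order(gc$p)
  expect_true(all(diff(gc$p_adj[o]) >= -1e-12))
  ## BH agrees with the hand computation on a canonical triple
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), method = "BH"),
               c(0.03, 0.03, 0.03))
})

test_that("counter-selection recovers the hand-computed log-odds ratio", {
  ## 10 damaging (1 observed), 20 tolerated (10 observed)
  n <- 30
  pos <- seq_len(n)
  from <- rep("A", n)
  to <- rep("V", n)
  score <- c(rep(0.1, 10), rep(0.9, 20))
  ss <- scoreSetFixture(pos, from, to, score)
  em <- buildEffectMap(ss, paste(rep("A", n), collapse = ""),
                       threshold = 0.5)
  observed <- hgvsP(c(1, 11:20), "A", "V")
  res <- counterSelectionTest(em, observed)
  expect_equal(res$log_or, log(1 / 9), tolerance = 1e-12)
  expect_equal(res$log_or, -2.197, tolerance = 1e-3)
  expect_true(res$p <= 1 && res$p >= 0)

  ## proportional table gives log-OR 0
  observed2 <- hgvsP(c(1:5, 11:20), "A", "V")
  expect_equal(counterSelectionTest(em, observed2)$log_or, 0)

  expect_error(counterSelectionTest(em, "p.Gly999Trp"), "empty margin")
})

test_that("stability discordance flags score/ddG mismatches", {
  n <- 20L
  score <- c(rep(0.9, 10), rep(0.05, 10))
  ss <- scoreSetFixture(seq_len(n), "A", "V", score)
  em <- buildEffectMap(ss, paste(rep("A", n), collapse = ""),
                       threshold = 0.5)
  ## ddG concordant with the damaging block except position 15
  ddg <- data.frame(position = seq_len(n), to_aa = "V",
                    ddg = c(rep(0, 10), rep(-2, 10)))
  ddg$ddg[15] <- 0
  res <- ddgDiscordance(em, ddg)
  expect_identical(res$positions$position[res$positions$stable_but_inactive],
                   15L)
  expect_identical(nrow(res$windows), n - 10L + 1L)

  ## rank-identical tracks give Spearman 1
  ddg2 <- data.frame(position = seq_len(n), to_aa = "V", ddg = score)
  expect_equal(ddgDiscordance(em, ddg2)$spearman$rho, 1)

  ddg3 <- data.frame(position = 100:110, to_aa = "V", ddg = 0)
  expect_error(ddgDiscordance(em, ddg3), "no position overlap")
})

test_that("phenotype values collapse by study size and correlate", {
  ## the two-study weighted-average conventions
  expect_equal(collapseStudies(c(61, 88), c(1, 1)), 74.5)
  expect_equal(collapseStudies(c(0, 4), c(1, 3)), 3.0)

  summaries <- setNames(seq(0, 1, length.out = 10), paste0("v", 1:10))
  ph <- data.frame(variant = rep(paste0("v", 1:10), 2),
                   phenotype = "half_life",
                   value = rep(seq(0, 1, length.out = 10), 2),
                   study_n = rep(c(1, 3), each = 10))
  res <- phenotypeCorrelations(summaries, ph)
  expect_equal(res$rho, 1)
  expect_identical(res$n, 10L)

  ph_bad <- data.frame(variant = "zzz", phenotype = "none",
                       value = 1, study_n = 1)
  expect_message(res2 <- phenotypeCorrelations(summaries, ph_bad),
                 "skipping")
  expect_identical(nrow(res2), 0L)
})
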