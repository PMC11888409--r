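test_that("frequencies follow count/depth arithmetic", {
  tc <- oracleCountsFixture(nVar = 4L, depth = 1.3e6)
  ## overwrite one count to the canonical 13-reads example
  SummarizedExperiment::assay(tc, "counts")[1, "pre.1"] <- 13
  SummarizedExperiment::assay(tc, "counts")[2, "pre.1"] <- 0
  fr <- computeFrequencies(tc)
  r1 <- fr[fr$hgvs_p == rownames(tc)[1] & fr$condition == "pre" &
             fr$replicate == 1, ]
  expect_equal(r1$cpm, 10)
  r2 <- fr[fr$hgvs_p == rownames(tc)[2] & fr$condition == "pre" &
             fr$replicate == 1, ]
  expect_equal(r2$freq, 0)
  expect_equal(r2$cpm, 0)

  SummarizedExperiment::assay(tc, "depth")[1, 1] <- 0
  expect_error(computeFrequencies(tc), "depth")
})

filter_fixture <- function(pre_count, wt_freqs, depth = 1e6,
                           replicate = 1L) {
  n <- length(pre_count)
  pre <- data.frame(hgvs_p = paste0("v", seq_len(n)), vclass = "missense",
                    tile = 1L, condition = "pre", replicate = replicate,
                    raw_count = pre_count, depth = depth,
                    freq = pre_count / depth, cpm = 1e6 * pre_count / depth)
  wt <- data.frame(hgvs_p = paste0("v", seq_along(wt_freqs)),
                   vclass = "missense", tile = 1L, condition = "wt_pre",
                   replicate = replicate, raw_count = wt_freqs * depth,
                   depth = depth, freq = wt_freqs, cpm = 1e6 * wt_freqs)
  rbind(pre, wt)
}

test_that("pre-selection filters apply the stated thresholds", {
  ## 9 reads -> low_count; 10 cpm exactly -> not_well_measured unset
  fr <- filter_fixture(pre_count = c(9, 10, 10000),
                       wt_freqs = rep(0, 3), depth = 1e6)
  fl <- applyFilters(fr)
  expect_true(fl$low_count[fl$hgvs_p == "v1"])
  expect_false(fl$low_count[fl$hgvs_p == "v2"])
  expect_false(fl$not_well_measured[fl$hgvs_p == "v2"])  # inclusive at 10 cpm
  ## zero-error control: wt frequencies all 0 leave positive variants unflagged
  expect_false(any(fl$below_wt_p90[fl$freq > 0]))
  expect_error(applyFilters(fr[fr$condition == "pre", ]), "WT-control")
})

test_that("the WT 90th-percentile filter works within tiles", {
  wt_f <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 100) * 1e-6
  fr <- filter_fixture(pre_count = c(rep(50, 9), 60),
                       wt_freqs = wt_f, depth = 1e6)
  fl <- applyFilters(fr)
  p90 <- quantile(wt_f, 0.9, names = FALSE)
  expect_identical(fl$below_wt_p90, fl$freq <= p90)
})

test_that("a variant is excluded only when flagged in all replicates", {
  fr <- rbind(filter_fixture(c(9, 5000), rep(0, 2), replicate = 1L),
              filter_fixture(c(5000, 5000), rep(0, 2), replicate = 2L))
  fl <- applyFilters(fr)
  expect_false(fl$excluded[fl$hgvs_p == "v1"][1])  # flagged in rep 1 only
  fr2 <- rbind(filter_fixture(c(9, 5000), rep(0, 2), replicate = 1L),
               filter_fixture(c(8, 5000), rep(0, 2), replicate = 2L))
  fl2 <- applyFilters(fr2)
  expect_true(all(fl2$excluded[fl2$hgvs_p == "v1"]))
})

enrich_fixture <- function(pre, post, wt_pre, wt_post, depth = 1e6) {
  ## single variant, single replicate, frequencies given in cpm
  rows <- function(cond, cpm) {
    data.frame(hgvs_p = "v1", position = 1L, from_aa = "A", to_aa = "V",
               vclass = "missense", tile = 1L, condition = cond,
               replicate = 1L, raw_count = cpm * depth / 1e6,
               depth = depth, freq = cpm / 1e6, cpm = cpm)
  }
  rbind(rows("pre", pre), rows("post", post),
        rows("wt_pre", wt_pre), rows("wt_post", wt_post))
}

test_that("WT subtraction and the enrichment ratio follow the worked example", {
  ## 50/10 cpm pre, 90/10 cpm post -> phi = 80/40 = 2
  enr <- correctAndEnrich(enrich_fixture(50, 90, 10, 10))
  expect_equal(enr$phi, 2)
  expect_equal(enr$log_phi, 1)

  ## library pre equal to WT pre -> unscorable
  enr2 <- correctAndEnrich(enrich_fixture(10, 90, 10, 10))
  expect_identical(enr2$flags, "nonpositive_corrected_pre")
  expect_true(is.na(enr2$phi))

  ## depleted post floors at one pseudo-read
  enr3 <- correctAndEnrich(enrich_fixture(50, 10, 10, 10))
  expect_equal(enr3$phi, (1 / 1e6) / (40 / 1e6))

  fr <- enrich_fixture(50, 90, 10, 10)
  expect_error(correctAndEnrich(fr[fr$condition != "wt_post", ]),
               "missing condition")
})

test_that("error regularisation has the right limits", {
  cfg <- simulationConfig(L = 30L, depth = 2e5, tiles = 3L, seed = 11L)
  truth <- simulateTruth(enumerateVariantSpace(randomOrf(30L, seed = 11L)),
                         cfg)
  counts <- simulateCountTables(truth, cfg)
  fr <- computeFrequencies(counts)
  enr <- correctAndEnrich(fr, applyFilters(fr))

  r0 <- regularizeErrors(enr, m = 0)
  ok <- r0$n_rep >= 2 & is.finite(r0$log_phi) & r0$flags == ""
  expect_equal(r0$se_reg[ok], r0$sd_emp[ok])

  rbig <- regularizeErrors(enr, m = 1e8)
  expect_equal(rbig$se_reg[ok], rbig$sd_model[ok], tolerance = 1e-3)

  ## shrinkage floor: zero empirical sd still yields a positive error
  r2 <- regularizeErrors(enr, m = 2)
  i <- which(ok)[1]
  fake <- enr
  n <- r2$n_rep[i]
  expect_gt(sqrt((2 * r2$sd_model[i]^2 + (n - 1) * 0) / (2 + n - 1)), 0)

  expect_error(regularizeErrors(enr[1:10, ]), "replicate pairs")
})

test_that("replicate combination is an inverse-variance weighted mean", {
  enr <- data.frame(hgvs_p = c("v1", "v1"), replicate = 1:2,
                    pre_cpm = c(100, 100), flags = "",
                    log_phi = c(1.0, 0.5), se_reg = c(0.1, 0.2),
                    df = c(3, 3), n_rep = 2L, sd_emp = 0.3, sd_model = 0.1)
  comb <- combineReplicates(enr)
  expect_equal(comb$log_phi, (100 * 1.0 + 25 * 0.5) / 125)  # 0.9
  expect_equal(comb$se, sqrt(1 / 125))

  ## equal errors -> arithmetic mean
  enr$se_reg <- c(0.2, 0.2)
  expect_equal(combineReplicates(enr)$log_phi, 0.75)

  ## single replicate passes through with its own error and flag
  one <- enr[1, ]
  comb1 <- combineReplicates(one)
  expect_equal(comb1$log_phi, 1.0)
  expect_equal(comb1$se, 0.2)
  expect_identical(comb1$flags, "single_replicate")
})

test_that("rescaling anchors nonsense at 0 and synonymous at 1", {
  make_combined <- function(non, syn, mis) {
    data.frame(
      hgvs_p = c(hgvsP(seq_along(non), "A", "*"),
                 hgvsP(seq_along(syn) + 50, "A", "A"),
                 hgvsP(seq_along(mis) + 100, "A", "V")),
      log_phi = c(non, syn, mis), se = 0.1, df = 3, n_rep = 2L, flags = "")
  }
  variants <- function(cmb) {
    data.frame(hgvs_p = cmb$hgvs_p,
               position = seq_len(nrow(cmb)), from_aa = "A",
               to_aa = c(rep("*", 12), rep("A", 12),
                         rep("V", nrow(cmb) - 24)),
               vclass = c(rep("nonsense", 12), rep("synonymous", 12),
                          rep("missense", nrow(cmb) - 24)))
  }
  non <- seq(-4.5, -4.0, length.out = 12)
  syn <- seq(-0.2, 0.2, length.out = 12)
  cmb <- make_combined(non, syn, 0.8 * c(-4:4) / 4)
  ss <- rescaleScores(cmb, variants(cmb))
  tab <- scoreTable(ss)
  expect_lt(abs(median(tab$score[tab$vclass == "nonsense"])), 1e-12)
  expect_lt(abs(median(tab$score[tab$vclass == "synonymous"]) - 1), 1e-12)

  ## linear midpoint example: anchors 0.2 and 1.4 map 0.8 to 0.5
  non2 <- rep(0.2, 12); syn2 <- rep(1.4, 12)
  cmb2 <- make_combined(non2, syn2, 0.8)
  tab2 <- scoreTable(rescaleScores(cmb2, variants(cmb2)))
  expect_equal(tab2$score[tab2$vclass == "missense"], 0.5)

  ## inverted selection is an error
  cmb3 <- make_combined(syn2, non2, 0.8)
  expect_error(rescaleScores(cmb3, variants(cmb3)), "inverted")
  expect_error(rescaleScores(cmb[1:15, ], variants(cmb)[1:15, ]), ">= 10")
})

## Independent spreadsheet-style recomputation of the whole scoring chain
## on a deterministic fixture.
spreadsheetScores <- function(tc, m = 2) {
  cnt <- SummarizedExperiment::assay(tc, "counts")
  dep <- SummarizedExperiment::assay(tc, "depth")
  rd <- as.data.frame(SummarizedExperiment::rowData(tc))
  f <- cnt / dep
  res <- list()
  for (v in rownames(cnt)) {
    rec <- list()
    for (r in 1:2) {
      pre <- f[v, paste0("pre.", r)] - f[v, paste0("wt_pre.", r)]
      post <- f[v, paste0("post.", r)] - f[v, paste0("wt_post.", r)]
      if (pre <= 0) next
      if (post <= 0) post <- 1 / dep[v, paste0("post.", r)]
      rec[[r]] <- c(lp = log2(post / pre), cpm = pre * 1e6)
    }
    res[[v]] <- rec
  }
  lp <- lapply(res, function(rec) vapply(rec, `[[`, numeric(1), "lp"))
  cpm <- lapply(res, function(rec) vapply(rec, `[[`, numeric(1), "cpm"))
  sd_emp <- vapply(lp, sd, numeric(1))
  mean_cpm <- vapply(cpm, mean, numeric(1))
  use <- sd_emp > 0 & !is.na(sd_emp)
  b <- cov(log(mean_cpm[use]), log(sd_emp[use])) / var(log(mean_cpm[use]))
  a <- mean(log(sd_emp[use])) - b * mean(log(mean_cpm[use]))
  score <- numeric(0)
  for (v in names(lp)) {
    n <- length(lp[[v]])
    se2 <- (m * exp(a + b * log(cpm[[v]]))^2 +
              (n - 1) * ifelse(is.na(sd_emp[v]), 0, sd_emp[v])^2) /
      (m + n - 1)
    w <- 1 / se2
    score[v] <- sum(w * lp[[v]]) / sum(w)
  }
  vclass <- rd$vclass[match(names(score), rd$hgvs_p)]
  mn <- median(score[vclass == "nonsense"])
  ms <- median(score[vclass == "synonymous"])
  (score - mn) / (ms - mn)
}

test_that("scores match an independent spreadsheet-style recomputation", {
  tc <- oracleCountsFixture(nVar = 40L)
  ss <- scoreTileseq(tc, minAnchors = 5L)
  tab <- scoreTable(ss)
  oracle <- spreadsheetScores(tc)
  got <- setNames(tab$score, tab$hgvs_p)[names(oracle)]
  expect_equal(unname(got), unname(oracle), tolerance = 1e-9)
})

test_that("scores are invariant to a global depth rescaling", {
  tc <- oracleCountsFixture(nVar = 40L)
  tab1 <- scoreTable(scoreTileseq(tc, minAnchors = 5L))
  cnt <- SummarizedExperiment::assay(tc, "counts") * 10
  dep <- SummarizedExperiment::assay(tc, "depth") * 10
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cnt, depth = dep),
    rowData = SummarizedExperiment::rowData(tc),
    colData = SummarizedExperiment::colData(tc))
  tab2 <- scoreTable(scoreTileseq(new("TileseqCounts", se),
                                  minAnchors = 5L))
  expect_equal(tab1$score, tab2$score, tolerance = 1e-12)
})

test_that("default-scale synthetic data is scored with high coverage", {
  run <- defaultRunFixture()
  tab <- scoreTable(run$scores)
  expect_gt(mean(!is.na(tab$score[tab$vclass == "missense"])), 0.9)
  m <- merge(tab, run$truth[, c("hgvs_p", "true_effect")], by = "hgvs_p")
  ok <- !is.na(m$score)
  expect_gt(cor(m$score[ok], m$true_effect[ok]), 0.9)
})
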