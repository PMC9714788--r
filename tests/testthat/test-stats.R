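# ROI differential statistics: rank tests, BH, fold changes, volcano,
# class composition, enrichment, compartment comparisons.

# Exhaustive-permutation oracle for the two-sided Mann-Whitney p.
perm_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  idx <- utils::combn(n, length(a))
  u_of <- function(sel) {
    x <- pooled[sel]; y <- pooled[-sel]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(seq_along(a))
  us <- apply(idx, 2, u_of)
  mu <- length(a) * length(b) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

test_that("mann_whitney matches the worked example and symmetry", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)               # 2 / C(6,3) labelings = 2/20
  # identical multisets: U = n1*n2/2, p = 1
  mw2 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mw2$U, 4.5)
  expect_equal(mw2$p, 1)
  expect_error(mann_whitney(numeric(0), 1), "nonempty")
})

test_that("exact mann_whitney equals exhaustive enumeration (n <= 8)", {
  set.seed(17)
  for (i in 1:40) {
    na <- sample(2:4, 1); nb <- sample(2:4, 1)
    repeat {
      a <- round(rnorm(na), 3); b <- round(rnorm(nb), 3)
      if (!anyDuplicated(c(a, b))) break
    }
    expect_equal(mann_whitney(a, b)$p, perm_mw_p(a, b), tolerance = 1e-12)
  }
})

test_that("kruskal_dunn reproduces the hand-computed H and Dunn oracle", {
  kd <- kruskal_dunn(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
  # 12/(N(N+1)) * sum(R_i^2/n_i) - 3(N+1) with rank sums 6, 15, 24
  expect_equal(kd$H, 7.2)
  expect_equal(kd$p, pchisq(7.2, df = 2, lower.tail = FALSE))
  # identical groups: H = 0, all pairwise p = 1
  same <- kruskal_dunn(list(a = c(1, 2), b = c(1, 2), c = c(1, 2)))
  expect_equal(same$H, 0, tolerance = 1e-12)
  expect_true(all(same$dunn$p == 1))
  expect_error(kruskal_dunn(list(1:3, 4:6)), ">= 3 groups")

  # textbook-formula oracle on random data with ties
  set.seed(23)
  g <- list(x = round(rnorm(7), 1), y = round(rnorm(5), 1),
            z = round(rnorm(6), 1))
  kd2 <- kruskal_dunn(g)
  x <- unlist(g); r <- rank(x); N <- length(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, rep(names(g), lengths(g)), mean)
  n <- lengths(g)
  for (j in seq_len(nrow(kd2$dunn))) {
    g1 <- kd2$dunn$group1[j]; g2 <- kd2$dunn$group2[j]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[g1]] + 1 / n[[g2]]))
    z <- (rbar[[g1]] - rbar[[g2]]) / se
    expect_equal(kd2$dunn$z[j], z, tolerance = 1e-10)
    expect_equal(kd2$dunn$p[j], 2 * pnorm(-abs(z)), tolerance = 1e-10)
  }
  expect_equal(kd2$dunn$p_adj, p.adjust(kd2$dunn$p, "BH"))
})

test_that("bh_adjust equals the manual step-up and is well behaved", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.002)),
               c(0.02, 0.04, 0.04, 0.008))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # manual step-up oracle on many random vectors; adjusted >= raw always
  set.seed(29)
  for (i in 1:200) {
    p <- runif(sample(1:20, 1))
    manual <- {
      m <- length(p); o <- order(p, decreasing = TRUE)
      ro <- order(o)
      pmin(1, cummin(p[o] * m / (m:1)))[ro]
    }
    got <- bh_adjust(p)
    expect_equal(got, manual, tolerance = 1e-12)
    expect_true(all(got >= p - 1e-12))
    expect_true(all(diff(got[order(p)]) >= -1e-12))
  }
})

test_that("log2_fold_change follows the per-section-mean definition", {
  expect_equal(log2_fold_change(c(2, 2, 2), c(2, 2, 2)), 0)
  expect_equal(log2_fold_change(c(1, 2, 3), 2 * c(1, 2, 3)), 1)
  expect_warning(fc <- log2_fold_change(c(0, 0), c(1, 1)), "reference")
  expect_true(is.na(fc))
  expect_error(log2_fold_change(numeric(0), 1), "at least one")
})

test_that("volcano classification applies both cutoffs", {
  st <- data.frame(log2fc = c(0.5, 1.2, -1.5, 2, NA),
                   p = c(0.001, 0.01, 0.2, 0.04, 0.01))
  out <- volcano_classify(st)
  expect_equal(out$direction, c("ns", "up", "ns", "up", "ns"))
  counts <- attr(out, "counts")
  expect_equal(unname(counts[c("up", "down")]), c(2L, 0L))
})

test_that("class composition percentages sum to 100 per direction", {
  annos <- data.frame(peak_mz = c(100, 200, 300, 400),
                      id = letters[1:4], name = letters[1:4],
                      adduct = "M-H", theo_mz = c(100, 200, 300, 400),
                      ppm = 0, class = c("A", "A", "A", "B"),
                      endogenous = TRUE, pathways = "", source = "metabolite")
  st <- data.frame(peak_mz = c(100, 200, 300, 400),
                   direction = c("up", "up", "up", "down"))
  cc <- class_composition(annos, st)
  up <- cc[cc$direction == "up", ]
  expect_equal(sum(up$percent), 100, tolerance = 1e-9)
  expect_equal(up$percent[up$class == "A"], 100)
  # two classes 3:1 -> 75/25
  st2 <- data.frame(peak_mz = c(100, 200, 300, 400),
                    direction = c("up", "up", "up", "up"))
  annos2 <- annos; annos2$class <- c("A", "A", "A", "B")
  cc2 <- class_composition(annos2, st2)
  expect_setequal(cc2$percent, c(75, 25))
  # empty direction set gives an empty table
  st3 <- data.frame(peak_mz = 100, direction = "ns")
  expect_equal(nrow(class_composition(annos, st3)), 0L)
})

test_that("ora_enrichment matches the ratio formula and pmf oracle", {
  bg <- sprintf("m%02d", 1:100)
  hits <- bg[1:20]
  sets <- list(pw1 = bg[c(1:5, 40:44)])      # 5 of 10 members are hits
  res <- ora_enrichment(hits, sets, bg)
  expect_equal(res$ratio, 2.5)               # 5 / (10 * 20/100)
  # brute-force hypergeometric upper tail
  pmf <- function(k) choose(10, k) * choose(90, 20 - k) / choose(100, 20)
  expect_equal(res$p, sum(vapply(5:10, pmf, numeric(1))), tolerance = 1e-12)
  # hits = background: every ratio 1, p 1
  res2 <- ora_enrichment(bg, sets, bg)
  expect_equal(res2$ratio, 1)
  expect_equal(res2$p, 1)
  expect_error(ora_enrichment("zz", sets, bg), "subset")
  expect_error(ora_enrichment(hits, sets, character(0)), "empty")
})

test_that("compartment comparisons find the planted osteoid enrichment", {
  truth <- small_truth()
  # a PPi-like peak: home = osteoid
  j <- which(truth$peaks$home == "osteoid")[1]
  cc <- compartment_compare(truth$cubes, truth$masks, truth$groups, j,
                            labels = c("mineralized_bone", "osteoid"))
  expect_true(all(c("section", "group", "label", "median", "min", "max")
                  %in% names(cc$summaries)))
  for (g in names(cc$compartment_tests)) {
    ct <- cc$compartment_tests[[g]]
    expect_identical(ct$test, "mann_whitney")
    expect_lt(ct$p, 0.01)
  }
  # three labels routes through kruskal_dunn
  cc3 <- compartment_compare(truth$cubes, truth$masks, truth$groups, j)
  expect_identical(cc3$compartment_tests[[1]]$test, "kruskal_dunn")
  expect_lt(cc3$compartment_tests[[1]]$p, 0.01)
  # identical compartments: p = 1
  cube0 <- truth$cubes[[1]]
  cube0$intensity[] <- 1
  cc0 <- compartment_compare(list(cube0), list(truth$masks[[1]]), "WT", 1,
                             labels = c("mineralized_bone", "osteoid"))
  expect_equal(cc0$compartment_tests[["WT"]]$p, 1)
})

test_that("roi_stat_table measures planted effects on the ground truth", {
  truth <- small_truth()
  st <- roi_stat_table(truth$cubes, truth$masks, truth$groups)
  eff <- truth$peaks$effect_log2
  planted <- which(eff != 0)
  expect_true(all(abs(st$log2fc[planted] - eff[planted]) < 0.3))
  expect_true(all(st$p[planted] < 1e-6))
  null_cortical <- which(eff == 0 & truth$peaks$home != "background")
  expect_true(all(abs(st$log2fc[null_cortical]) < 1))
})
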