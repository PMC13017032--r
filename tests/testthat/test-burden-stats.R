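mk_calls <- function(vafs, genes = NULL) {
  d <- data.frame(chrom = "c", pos = seq_along(vafs), ref = "A", alt = "G",
                  alt_count = round(vafs * 1000), depth = 1000L,
                  vaf = vafs, classification = "somatic",
                  stringsAsFactors = FALSE)
  if (!is.null(genes)) d$gene_symbol <- genes
  d
}

mk_meta <- function(n, group = "sALS") {
  data.frame(sample_id = sprintf("S%02d", seq_len(n)), group = group,
             sex = "F", age = 60, origin = "site1", total_coverage = 2000,
             stringsAsFactors = FALSE)
}

test_that("burden table bins somatic calls left-open right-closed", {
  meta <- mk_meta(2)
  calls <- list(S01 = mk_calls(c(0.02, 0.02, 0.10, 0.20, 0.34)),
                S02 = NULL)
  b <- build_burden(calls, meta, af_bin_edges = c(0.015, 0.05, 0.15, 0.35))
  expect_equal(unname(unlist(b[1, c("bin_0.015_0.05", "bin_0.05_0.15",
                                    "bin_0.15_0.35")])), c(2, 1, 2))
  expect_equal(b$total[1], 5)
  # sample without calls keeps an all-zero row
  expect_equal(b$total[2], 0)
  expect_equal(sum(b[2, grep("^bin_", names(b))]), 0)
})

test_that("per-gene counts conserve the total under full annotation", {
  meta <- mk_meta(1)
  calls <- list(S01 = mk_calls(c(0.05, 0.1, 0.2, 0.3),
                               genes = c("FUS", "FUS", "TBK1", "NEK1")))
  b <- build_burden(calls, meta, genes = c("FUS", "TBK1", "NEK1"))
  expect_equal(sum(b[1, grep("^gene_", names(b))]), b$total[1])
  expect_equal(b$gene_FUS[1], 2)
})

test_that("intercept-only NB GLM recovers the sample mean exactly", {
  fit <- nb_glm(y ~ 1, data.frame(y = c(4, 6, 5, 5)))
  expect_equal(unname(exp(coef(fit))), 5, tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("nb_glm agrees with an independent NB fitter", {
  set.seed(51)
  n <- 200
  d <- data.frame(x = rnorm(n), g = factor(sample(c("a", "b"), n, TRUE)))
  mu <- exp(1 + 0.7 * (d$g == "b") + 0.3 * d$x)
  d$y <- rnbinom(n, mu = mu, size = 5)
  fit <- nb_glm(y ~ g + x, d)
  ref <- MASS::glm.nb(y ~ g + x, d)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(fit$theta, ref$theta, tolerance = 0.02)
  expect_equal(unname(fit$se), unname(summary(ref)$coefficients[, 2]),
               tolerance = 1e-2)
})

test_that("nb_glm approaches the Poisson GLM as theta grows", {
  set.seed(52)
  d <- data.frame(x = rnorm(50))
  d$y <- rpois(50, exp(1 + 0.5 * d$x))
  fit <- nb_glm(y ~ x, d, theta = 1e6)
  ref <- glm(y ~ x, poisson(), d)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
})

test_that("alternating fit ascends the log-likelihood", {
  set.seed(53)
  d <- data.frame(x = rnorm(80), g = rep(c("a", "b"), 40))
  d$y <- rnbinom(80, mu = exp(1.5 + 0.5 * (d$g == "b")), size = 3)
  lls <- vapply(1:6, function(k)
    nb_glm(y ~ g + x, d, max_iter = k)$loglik, numeric(1))
  expect_true(all(diff(lls) > -1e-8))
})

test_that("rank-deficient designs fail loudly, naming the column", {
  d <- data.frame(y = rpois(10, 5), x = 1:10)
  d$x2 <- 2 * d$x
  expect_error(nb_glm(y ~ x + x2, d), "rank deficient.*x2")
})

test_that("offsets shift the linear predictor", {
  d <- data.frame(y = c(2, 4, 8, 16), off = log(c(1, 2, 4, 8)))
  fit <- nb_glm(y ~ 1 + offset(off), d, theta = 1e6)
  expect_equal(unname(exp(coef(fit))), 2, tolerance = 1e-6)
})

test_that("Welch summary matches the closed-form statistic", {
  meta <- rbind(mk_meta(3, "sALS"), mk_meta(3, "control"))
  meta$sample_id <- sprintf("S%02d", 1:6)
  b <- data.frame(sample_id = meta$sample_id, total = c(1, 2, 3, 4, 5, 6),
                  group = meta$group)
  res <- summary_t_test(b, "sALS", "control")
  # hand-computed Welch: means 2 and 5, each variance 1 on n = 3
  se <- sqrt(1 / 3 + 1 / 3)
  t_exp <- (2 - 5) / se
  df_exp <- (1 / 3 + 1 / 3)^2 / ((1 / 3)^2 / 2 + (1 / 3)^2 / 2)
  expect_equal(res$t, t_exp, tolerance = 1e-10)
  expect_equal(res$df, df_exp, tolerance = 1e-10)
  expect_equal(res$p_value, 2 * pt(t_exp, df_exp), tolerance = 1e-10)
  expect_equal(unname(res$mu), c(2, 5))
  expect_equal(unname(res$sigma), c(1, 1))

  # identical groups: t = 0, p = 1
  b2 <- b; b2$total <- rep(c(1, 2, 3), 2)
  res2 <- summary_t_test(b2, "sALS", "control")
  expect_equal(res2$t, 0)
  expect_equal(res2$p_value, 1)

  expect_error(summary_t_test(b[-(1:2), ], "sALS", "control"),
               ">= 2 samples")
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_identical(fdr_adjust(numeric(0)), numeric(0))
  for (seed in 1:20) {
    set.seed(seed)
    p <- runif(sample(1:30, 1))
    expect_equal(fdr_adjust(p), bh_brute(p), tolerance = 1e-12)
  }
})

test_that("gene burden ratios use the pseudo-count and find planted effects", {
  meta <- rbind(mk_meta(6, "sALS"), mk_meta(6, "control"))
  meta$sample_id <- sprintf("S%02d", 1:12)
  b <- data.frame(sample_id = meta$sample_id, group = meta$group,
                  gene_FUS = c(rep(4, 6), rep(4, 6)),
                  gene_TBK1 = c(rep(0, 6), rep(0, 6)))
  r <- gene_burden_ratio(b, "sALS", "control")
  expect_equal(r$ratio[r$gene == "FUS"], 1)
  expect_equal(r$ratio[r$gene == "TBK1"], 1)  # 0/0 guarded by pseudo-count

  set.seed(61)
  b2 <- data.frame(sample_id = meta$sample_id, group = meta$group,
                   gene_FUS = rpois(12, rep(c(30, 10), each = 6)),
                   gene_NEK1 = rpois(12, 10))
  r2 <- gene_burden_ratio(b2, "sALS", "control")
  expect_equal(r2$ratio[r2$gene == "FUS"], 3, tolerance = 0.4)
  expect_equal(r2$ratio[r2$gene == "NEK1"], 1, tolerance = 0.4)
  expect_lt(r2$p_value[r2$gene == "FUS"], 0.05)
})
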