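test_that("error model pools alt fractions and respects the mask", {
  # noiseless pileup: e clamped at the floor, rho 0
  p <- make_pileup(rep("A", 200), A = 1000)
  m <- estimate_error_model(p)
  expect_equal(m$e, 1e-6)
  expect_equal(m$rho, 0)

  # simulated errors at e = 0.001 are recovered within 10%
  set.seed(21)
  n <- 10000; depth <- 2000; e <- 0.001
  alt <- rbinom(n, depth, e)
  p2 <- make_pileup(rep("A", n), A = depth - alt, G = alt)
  m2 <- estimate_error_model(p2)
  expect_lt(abs(m2$e - e) / e, 0.10)

  # masked planted site leaves the estimate untouched
  p3 <- p2
  p3$G[1] <- 100; p3$A[1] <- depth - 100
  m3 <- estimate_error_model(p3, exclude = seq_len(n) == 1)
  m2b <- estimate_error_model(p2[-1, ])
  expect_equal(m3$e, m2b$e)

  expect_error(estimate_error_model(p2, exclude = rep(TRUE, n)),
               "100 non-excluded")
})

test_that("binomial caller matches the closed-form tail", {
  cfg <- caller_config(alpha = 1e-6, min_depth = 10)
  m <- structure(list(e = 0.001, rho = 0), class = "error_model")

  # no alternate reads: no call
  expect_equal(nrow(call_binomial(make_pileup("A", A = 2000), m, cfg)), 0)

  # depth 10, alt 1: p = 1 - 0.999^10, above alpha, no call emitted
  p <- make_pileup("A", A = 9, G = 1)
  out <- call_binomial(p, m, cfg)
  expect_equal(nrow(out), 0)
  cfg_loose <- caller_config(alpha = 0.05, min_depth = 10)
  out2 <- call_binomial(p, m, cfg_loose)
  expect_equal(out2$p_value, 1 - 0.999^10, tolerance = 1e-12)

  # depth 2000, alt 100: called at any sane alpha
  out3 <- call_binomial(make_pileup("A", A = 1900, G = 100), m, cfg)
  expect_equal(nrow(out3), 1)
  expect_equal(out3$alt, "G")
  expect_lt(out3$p_value, 1e-50)
  expect_identical(out3$vaf, out3$alt_count / out3$depth)

  # below min_depth: untested, recorded
  p4 <- make_pileup("A", A = 5, G = 3)
  out4 <- call_binomial(p4, m, cfg)
  expect_equal(nrow(out4), 0)
  expect_equal(attr(out4, "n_untested"), 1)
})

test_that("beta-binomial tail reduces to binomial at rho = 0", {
  for (alt in c(1, 5, 40)) {
    bb <- pbetabinom_upper(alt, 2000, 0.001, 0)
    bi <- pbinom(alt - 1, 2000, 0.001, lower.tail = FALSE)
    expect_equal(bb, bi, tolerance = 1e-10)
  }
  # and the caller agrees with the binomial caller on a fixed pileup
  p <- make_pileup(rep("A", 5), A = c(2000, 1990, 1960, 1900, 1500),
                   G = c(0, 10, 40, 100, 500))
  m0 <- structure(list(e = 0.001, rho = 0), class = "error_model")
  cfg <- caller_config(alpha = 1e-6, min_depth = 100)
  cb <- call_binomial(p, m0, cfg)
  cbb <- call_betabinom(p, m0, cfg)
  expect_equal(cbb$p_value, cb$p_value, tolerance = 1e-10)

  # overdispersion widens the tail: p-values are never smaller
  m1 <- structure(list(e = 0.001, rho = 0.01), class = "error_model")
  cbb1 <- call_betabinom(p, m1, caller_config(alpha = 0.999,
                                              min_depth = 100))
  cb1 <- call_binomial(p, m0, caller_config(alpha = 0.999,
                                            min_depth = 100))
  common <- intersect(paste(cb1$pos), paste(cbb1$pos))
  expect_true(all(cbb1$p_value[match(common, paste(cbb1$pos))] >=
                    cb1$p_value[match(common, paste(cb1$pos))] - 1e-12))
})

test_that("beta-binomial caller detects a 5% variant at depth 2000", {
  # exact tail oracle: at the expected alternate count (100 of 2000) the
  # overdispersed null with rho 0.01 gives p ~ 1.6e-4, so detection under
  # that much overdispersion needs alpha at the 1e-3 level
  expect_equal(pbetabinom_upper(100, 2000, 0.001, 0.01), 1.59037e-4,
               tolerance = 1e-4)
  set.seed(31)
  m <- structure(list(e = 0.001, rho = 0.01), class = "error_model")
  cfg <- caller_config(alpha = 1e-3, min_depth = 500)
  alt <- rbinom(200, 2000, 0.05)
  p <- make_pileup(rep("A", 200), A = 2000 - alt, G = alt)
  out <- call_betabinom(p, m, cfg)
  expect_gte(nrow(out), 198)   # >= 99% recall

  # with the overdispersion actually estimated from binomial null data
  # (rho ~ 0) the default alpha of 1e-6 retains full power
  m0 <- structure(list(e = 0.001, rho = 1e-4), class = "error_model")
  out0 <- call_betabinom(p, m0, caller_config(alpha = 1e-6,
                                              min_depth = 500))
  expect_gte(nrow(out0), 198)
})

test_that("integration rules behave as set operations", {
  a <- data.frame(chrom = "c", pos = c(1L, 2L), ref = "A", alt = "G",
                  alt_count = 10L, depth = 100L, vaf = 0.1,
                  p_value = 1e-9, caller = "binomial",
                  stringsAsFactors = FALSE)
  b <- a[1, ]; b$caller <- "betabinom"
  cfg_i <- caller_config(rule = "intersection")
  cfg_u <- caller_config(rule = "union")
  both <- integrate_calls(list(a, b), cfg_i)
  expect_equal(both$pos, 1)
  expect_equal(both$callers, "betabinom,binomial")
  expect_equal(nrow(integrate_calls(list(a, b), cfg_u)), 2)

  # at_least_k sweeps between union and intersection (brute-force check)
  for (seed in 1:5) {
    set.seed(seed)
    mk <- function(caller) {
      pos <- sort(sample(1:20, sample(3:8, 1)))
      data.frame(chrom = "c", pos = pos, ref = "A", alt = "G",
                 alt_count = 5L, depth = 50L, vaf = 0.1, p_value = 1e-8,
                 caller = caller, stringsAsFactors = FALSE)
    }
    cands <- list(mk("binomial"), mk("betabinom"))
    uni <- sort(unique(c(cands[[1]]$pos, cands[[2]]$pos)))
    int <- sort(intersect(cands[[1]]$pos, cands[[2]]$pos))
    k1 <- integrate_calls(cands, caller_config(rule = "at_least_k", k = 1))
    k2 <- integrate_calls(cands, caller_config(rule = "at_least_k", k = 2))
    expect_equal(sort(k1$pos), uni)
    expect_equal(sort(k2$pos), int)
  }
  expect_error(caller_config(rule = "majority"), "unknown integration")
})

test_that("AF window classification uses open intervals", {
  cfg <- caller_config()
  cls <- function(v) classify_call(data.frame(vaf = v), cfg)$classification
  expect_equal(cls(0.07), "somatic")    # a mosaic hotspot-level VAF
  expect_equal(cls(0.50), "germline")
  expect_equal(cls(0.01), "filtered")
  expect_equal(cls(0.015), "filtered")  # boundary excluded
  expect_equal(cls(0.35), "germline")   # boundary excluded
  expect_equal(cls(c(0.0151, 0.3499)), c("somatic", "somatic"))
})

test_that("region annotation applies feature precedence", {
  panel <- tiny_panel("FUS")
  gm <- panel$gene_model
  exon <- gm[gm$feature == "exon", ][1, ]
  utr3 <- gm[gm$feature == "3UTR", ][1, ]
  calls <- data.frame(chrom = exon$chrom,
                      pos = c(exon$start, utr3$start, 2L),
                      stringsAsFactors = FALSE)
  ann <- annotate_region(calls, gm)
  expect_equal(ann$region, c("exonic", "3UTR", "intergenic"))
  expect_equal(ann$gene_symbol, c("FUS", "FUS", NA))

  expect_warning(annotate_region(data.frame(chrom = "nope", pos = 1L), gm),
                 "absent from gene model")
})

test_that("end-to-end somatic recovery on one synthetic sample", {
  panel <- tiny_panel()
  cfg <- sim_config(seed = 41)
  meta <- simulate_metadata(cfg)[1, ]
  sim <- simulate_sample(panel, meta, cfg)
  calls <- call_variants(sim$pileup, caller_config(), panel$gene_model)
  expect_identical(calls$vaf, calls$alt_count / calls$depth)
  som_t <- sim$truth[sim$truth$origin == "somatic", ]
  som_c <- calls[calls$classification == "somatic", ]
  kt <- paste(som_t$chrom, som_t$pos, som_t$alt)
  kc <- paste(som_c$chrom, som_c$pos, som_c$alt)
  expect_gte(mean(kt %in% kc), 0.9)
  expect_gte(mean(kc %in% kt), 0.9)
  # union can only add calls relative to intersection
  cfg_u <- caller_config(rule = "union")
  calls_u <- call_variants(sim$pileup, cfg_u, panel$gene_model)
  expect_gte(nrow(calls_u), nrow(calls))
})
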