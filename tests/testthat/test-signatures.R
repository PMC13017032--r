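test_that("channel mapping is the pyrimidine-centred convention", {
  expect_equal(sbs_channel_of("A", "C", "T", "A"), "A[C>T]A")
  # purine reference reverse-complements, flanks swap
  expect_equal(sbs_channel_of("T", "G", "A", "T"), "A[C>T]A")
  expect_length(sbs_channels(), 96)
  expect_false(anyDuplicated(sbs_channels()) > 0)
})

test_that("all 192 stranded contexts map 2-to-1 onto the 96 channels", {
  # independent oracle: reverse-complement the full trinucleotide with
  # Biostrings and require the two strands to land in the same channel
  chan <- sbs_channels()
  hits <- setNames(integer(96), chan)
  for (ref in c("A", "C", "G", "T")) for (alt in setdiff(c("A", "C", "G",
                                                           "T"), ref))
    for (l in c("A", "C", "G", "T")) for (r in c("A", "C", "G", "T")) {
      ch <- sbs_channel_of(l, ref, alt, r)
      expect_true(ch %in% chan)
      hits[ch] <- hits[ch] + 1L
      rc <- function(s) as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(s)))
      tri_rc <- rc(paste0(l, ref, r))
      ch2 <- sbs_channel_of(substr(tri_rc, 1, 1), substr(tri_rc, 2, 2),
                            rc(alt), substr(tri_rc, 3, 3))
      expect_equal(ch2, ch)
    }
  expect_true(all(hits == 2))
})

test_that("context spectra conserve counts and skip contig edges", {
  ref <- c(c1 = "AACGT")
  snvs <- data.frame(chrom = "c1", pos = c(2L, 3L, 0L, 4L),
                     ref = c("C", "G", "A", "T"),
                     alt = c("T", "A", "G", "A"), stringsAsFactors = FALSE)
  sp <- context_spectrum(snvs, ref)
  expect_equal(sum(sp), 2)                   # edge SNVs skipped
  expect_equal(attr(sp, "n_skipped"), 2)
  # pos 2 is A[C>T]G directly; pos 3 (G>A, flanks C/T) lands there too
  # after reverse complementing onto the pyrimidine strand
  expect_equal(unname(sp["A[C>T]G"]), 2)
  expect_equal(sum(sp > 0), 1)

  expect_error(context_spectrum(
    data.frame(chrom = "c1", pos = 2L, ref = "G", alt = "A"), ref),
    "mismatch")
})

test_that("NNLS refitting recovers exact mixtures", {
  cat <- synthetic_signature_catalog(3)
  # identity catalog returns the spectrum itself
  ident <- diag(96); rownames(ident) <- paste0("u", 1:96)
  colnames(ident) <- sbs_channels()
  spec <- setNames(rpois(96, 5), sbs_channels())
  fit <- fit_signatures(spec, ident)
  expect_equal(unname(fit$weights), as.numeric(spec), tolerance = 1e-8)

  # noiseless 0.7 / 0.3 mixture
  mix <- 1000 * (0.7 * cat[1, ] + 0.3 * cat[2, ])
  fit2 <- fit_signatures(mix, cat)
  expect_equal(unname(fit2$fractions), c(0.7, 0.3, 0), tolerance = 1e-6)
  expect_lt(fit2$residual, 1e-6)

  # scaling invariance of fractions
  fit3 <- fit_signatures(mix * 37, cat)
  expect_equal(fit3$fractions, fit2$fractions, tolerance = 1e-8)

  # zero spectrum flagged degenerate
  fit0 <- fit_signatures(rep(0, 96), cat)
  expect_true(fit0$degenerate)
  expect_true(all(is.na(fit0$fractions)))
})

test_that("condition comparison ranks a signature-heavy condition first", {
  cat <- synthetic_signature_catalog(3)
  set.seed(70)
  ref <- c(ctg = paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
                       collapse = ""))
  # build SNV sets by sampling channels from two different mixtures and
  # materialising each channel at a matching reference position
  chan_at <- function(pos) {
    tri <- substr(ref[["ctg"]], pos, pos + 2)
    b <- strsplit(tri, "")[[1]]
    list(ref = b[2], left = b[1], right = b[3])
  }
  # positions whose centre base is C or T cover pyrimidine channels
  sample_snvs <- function(mixture, n, seed) {
    set.seed(seed)
    chans <- sample(sbs_channels(), n, replace = TRUE, prob = mixture)
    rows <- lapply(chans, function(ch) {
      m <- regmatches(ch, regexec("(.)\\[(.)>(.)\\](.)", ch))[[1]]
      # find a position in the reference with this trinucleotide
      tri <- paste0(m[2], m[3], m[5])
      hit <- regexpr(tri, ref[["ctg"]], fixed = TRUE)
      if (hit < 0) return(NULL)
      data.frame(chrom = "ctg", pos = as.integer(hit), ref = m[3],
                 alt = m[4], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  heavy <- 0.8 * cat["SBS26like", ] + 0.2 * cat["SBSflat", ]
  flat <- cat["SBSflat", ]
  snvs <- rbind(cbind(sample_snvs(heavy, 300, 71), condition = "sALS"),
                cbind(sample_snvs(flat, 300, 72), condition = "control"))
  res <- compare_condition_fractions(snvs, ref, cat, n_boot = 50, seed = 1)
  f26 <- res[res$signature == "SBS26like", ]
  expect_gt(f26$fraction[f26$condition == "sALS"],
            f26$fraction[f26$condition == "control"])
  res2 <- compare_condition_fractions(snvs, ref, cat, n_boot = 50, seed = 1)
  expect_identical(res, res2)   # seeded bootstrap

  # identical SNV sets give identical fractions
  snvs_same <- rbind(cbind(sample_snvs(flat, 100, 73), condition = "a"),
                     cbind(sample_snvs(flat, 100, 73), condition = "b"))
  res3 <- compare_condition_fractions(snvs_same, ref, cat, n_boot = 10,
                                      seed = 2)
  fa <- res3$fraction[res3$condition == "a"]
  fb <- res3$fraction[res3$condition == "b"]
  expect_equal(fa, fb, tolerance = 1e-12)
})

test_that("gene-set permutation test has the stated null behaviour", {
  w <- setNames(rep(1, 10), paste0("g", 1:10))
  snv_genes <- sample(names(w), 50, replace = TRUE)
  # a set holding the whole universe: null always equals observed, p = 1
  res <- geneset_burden_test(snv_genes, list(all = names(w)), w,
                             n_perm = 200, seed = 3)
  expect_equal(res$observed, 50)
  expect_equal(res$p_value, 1)

  # empty set warns and returns p = 1
  expect_warning(res0 <- geneset_burden_test(snv_genes,
                                             list(none = character(0)), w,
                                             n_perm = 50, seed = 3),
                 "empty gene set")
  expect_equal(res0$p_value, 1)

  # p-values are reproducible and never zero
  res1 <- geneset_burden_test(snv_genes, list(s = c("g1", "g2")), w,
                              n_perm = 200, seed = 4)
  res2 <- geneset_burden_test(snv_genes, list(s = c("g1", "g2")), w,
                              n_perm = 200, seed = 4)
  expect_identical(res1, res2)
  expect_gt(res1$p_value, 0)

  # planted 5x enrichment in one set is detected
  set.seed(81)
  enr_genes <- c(sample(paste0("g", 1:2), 50, replace = TRUE),
                 sample(paste0("g", 3:10), 40, replace = TRUE))
  res3 <- geneset_burden_test(enr_genes, list(hot = c("g1", "g2"),
                                              cold = c("g3", "g4")), w,
                              n_perm = 500, seed = 5)
  expect_lt(res3$q_value[res3$set == "hot"], 0.05)
})

test_that("permutation p-values are uniform under the null", {
  w <- setNames(rep(1, 20), paste0("g", 1:20))
  set.seed(91)
  ps <- vapply(1:100, function(i) {
    snv_genes <- sample(names(w), 200, replace = TRUE)
    geneset_burden_test(snv_genes, list(s = paste0("g", 1:5)), w,
                        n_perm = 999, seed = 1000 + i)$p_value
  }, numeric(1))
  expect_true(all(ps > 0))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
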