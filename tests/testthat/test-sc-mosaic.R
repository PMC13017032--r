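test_that("cell-type aggregation is exact summation with backtrace", {
  pile <- data.frame(
    cell_barcode = c("e1", "e2", "a1"),
    chrom = "c", pos = 0L, ref = "A",
    A = c(3L, 2L, 5L), C = 0L, G = c(0L, 1L, 0L), T = 0L,
    stringsAsFactors = FALSE)
  ann <- data.frame(cell_barcode = c("e1", "e2", "a1", "a2"),
                    cell_type = c("excitatory", "excitatory", "astrocyte",
                                  "astrocyte"), stringsAsFactors = FALSE)
  ctp <- aggregate_by_celltype(pile, ann)
  ex <- ctp[ctp$cell_type == "excitatory", ]
  expect_equal(ex$A, 5)
  expect_equal(ex$G, 1)
  expect_equal(ex$n_cells_covered, 2)
  # conservation against the backtrace
  bt <- attr(ctp, "backtrace")
  expect_equal(sum(ctp$A), sum(bt$A))
  expect_equal(sum(ctp$depth), sum(bt$A + bt$C + bt$G + bt$T))
  # zero-coverage type keeps a zero row
  expect_true("astrocyte" %in% ctp$cell_type)

  expect_error(aggregate_by_celltype(
    data.frame(cell_barcode = "zz", chrom = "c", pos = 0L, ref = "A",
               A = 1L, C = 0L, G = 0L, T = 0L), ann), "unannotated")
})

test_that("sc caller separates clonal, germline-like and untested sites", {
  # 30% alt in excitatory only, strong depth: somatic with that host
  ctp <- make_ctp(c("excitatory", "inhibitory", "astrocyte", "microglia"),
                  ref = "A", alt = "G",
                  alt_counts = c(30L, 0L, 0L, 0L),
                  depths = c(100L, 100L, 100L, 100L))
  v <- call_sc_variants(ctp)
  expect_equal(v$status, "somatic")
  expect_equal(v$host_cell_types, "excitatory")
  expect_equal(v$alt, "G")

  # ~50% everywhere: germline-like
  ctp2 <- make_ctp(c("excitatory", "inhibitory", "astrocyte"),
                   ref = "A", alt = "G", alt_counts = c(50L, 48L, 52L),
                   depths = c(100L, 100L, 100L))
  expect_equal(call_sc_variants(ctp2)$status, "germline_like")

  # depth below min_depth in every type: untested
  ctp3 <- make_ctp(c("excitatory", "inhibitory"), ref = "A", alt = "G",
                   alt_counts = c(2L, 0L), depths = c(5L, 5L))
  expect_equal(call_sc_variants(ctp3)$status, "untested")

  # widespread moderate alt fraction fails the germline screen -> artifact
  ctp4 <- make_ctp(c("excitatory", "inhibitory", "astrocyte"),
                   ref = "A", alt = "G", alt_counts = c(30L, 10L, 10L),
                   depths = c(100L, 100L, 100L))
  expect_true(call_sc_variants(ctp4)$status %in% c("artifact",
                                                   "germline_like"))
})

test_that("per-cell burden counts carrier cells by alt reads", {
  # 3 somatic sites; cell e1 carries alt at all three, a1 at none
  pile <- do.call(rbind, lapply(0:2, function(p) data.frame(
    cell_barcode = c("e1", "a1"), chrom = "c", pos = p, ref = "A",
    A = c(5L, 8L), C = 0L, G = c(3L, 0L), T = 0L,
    stringsAsFactors = FALSE)))
  ann <- data.frame(cell_barcode = c("e1", "a1"),
                    cell_type = c("excitatory", "astrocyte"),
                    cluster_id = 1L, condition = "sALS",
                    stringsAsFactors = FALSE)
  vars <- data.frame(chrom = "c", pos = 0:2, ref = "A", alt = "G",
                     status = "somatic", host_cell_types = "excitatory",
                     stringsAsFactors = FALSE)
  cb <- per_cell_burden(vars, pile, ann)
  expect_equal(cb$n_variants[cb$cell_barcode == "e1"], 3)
  expect_equal(cb$n_variants[cb$cell_barcode == "a1"], 0)
  expect_equal(cb$n_covered_sites, c(3, 3))
})

test_that("carrier counts match planted truth on a near-noiseless cohort", {
  cts <- data.frame(cell_type = c("excitatory", "astrocyte"),
                    n_cells = c(40, 30), mean_depth = 20, p_zero = 0)
  clones <- data.frame(cell_type = "excitatory", carrier_fraction = 0.3,
                       n_clones = 3)
  sc <- simulate_sc_cohort(cts, clones,
                           list(n_sites = 40, error_rate = 1e-9, seed = 6))
  for (i in seq_len(nrow(sc$truth))) {
    sel <- sc$pileup$pos == sc$truth$pos[i]
    altc <- sc$pileup[[sc$truth$alt[i]]][sel]
    carriers <- sc$pileup$cell_barcode[sel][altc > 0]
    # every observed carrier is a true carrier; counts agree up to
    # binomial dropout of het coverage (vanishing at depth 20)
    expect_true(all(carriers %in% sc$truth$carriers[[i]]))
    expect_equal(length(unique(carriers)), sc$truth$n_carriers[i],
                 tolerance = 0.1)
  }
})

test_that("pairwise cell-type contrasts flag a planted excess", {
  cts <- data.frame(cell_type = c("excitatory", "inhibitory", "astrocyte"),
                    n_cells = c(50, 40, 40))
  clones <- data.frame(cell_type = "excitatory", carrier_fraction = 0.3,
                       n_clones = 5)
  sc <- simulate_sc_cohort(cts, clones, list(n_sites = 100, seed = 8))
  ctp <- aggregate_by_celltype(sc$pileup, sc$annotations)
  v <- call_sc_variants(ctp)
  cb <- per_cell_burden(v, sc$pileup, sc$annotations)
  res <- compare_celltype_burden(cb)
  ex <- res[res$type_a == "excitatory" | res$type_b == "excitatory", ]
  expect_true(all(ex$q_value < 0.05))

  # a single cell type cannot be contrasted
  one <- cb[cb$cell_type == "excitatory", ]
  expect_error(compare_celltype_burden(one), ">= 2 cell types")
  # small cell types are excluded with a warning
  cb2 <- rbind(cb, transform(cb[1:3, ], cell_type = "rare",
                             cell_barcode = paste0("r", 1:3)))
  expect_warning(compare_celltype_burden(cb2), "rare")
})

test_that("cluster summaries rank by burden and close the composition", {
  cb <- data.frame(cell_barcode = sprintf("c%d", 1:4),
                   cell_type = "excitatory",
                   cluster_id = c(1, 1, 2, 2),
                   condition = c("sALS", "control", "sALS", "sALS"),
                   n_covered_sites = 10L, n_variants = c(1L, 1L, 5L, 7L),
                   stringsAsFactors = FALSE)
  res <- cluster_burden(cb)
  expect_equal(res$summary$cluster_id, c(2, 1))      # high burden first
  expect_equal(res$summary$mean_burden, c(6, 1))
  expect_true(all(abs(rowSums(res$composition) - 1) < 1e-12))
  expect_equal(unname(res$composition["1", "sALS"]), 0.5)
})
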