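#' Simulation configuration for the synthetic cohort
#'
#' Bundles every tunable of the synthetic cohort generator: group sizes,
#' sequencing depth, per-base error rate, UMI geometry, and the expected
#' number of planted somatic/germline variants per sample and group. All
#' randomness downstream is a pure function of `seed`.
#'
#' @param n_samples named integer vector of samples per disease group
#'   (default 9 sALS, 4 fALS, 6 control, the cohort scale of a deep
#'   targeted motor-cortex panel study).
#' @param target_depth target consensus coverage per site (default 2000).
#' @param error_rate per-base background error rate after consensus
#'   (default 1e-3).
#' @param umi_length length of the unique molecular identifier (default 8).
#' @param umi_family_size mean number of reads per UMI family (default 5).
#' @param somatic_rate named numeric vector: expected planted somatic
#'   variants per sample, per group. Default plants twice the control
#'   burden in sALS and control-level burden in fALS.
#' @param germline_rate expected germline variants per sample (default 10).
#' @param vaf_range range of true somatic variant allele fractions; VAFs
#'   are drawn log-uniformly inside the open interval (default 0.015-0.35).
#' @param seed integer seed fixing all randomness.
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$target_depth
#' @export
sim_config <- function(n_samples = c(sALS = 9L, fALS = 4L, control = 6L),
                       target_depth = 2000,
                       error_rate = 1e-3,
                       umi_length = 8L,
                       umi_family_size = 5,
                       somatic_rate = c(sALS = 40, fALS = 20, control = 20),
                       germline_rate = 10,
                       vaf_range = c(0.015, 0.35),
                       seed = 1L) {
  stopifnot(all(c("sALS", "fALS", "control") %in% names(n_samples)),
            all(n_samples >= 0))
  if (target_depth < 1) .stopf("target_depth must be >= 1")
  if (error_rate <= 0 || error_rate >= 1) .stopf("error_rate must be in (0,1)")
  if (umi_family_size < 1) .stopf("umi_family_size must be >= 1")
  stopifnot(length(vaf_range) == 2, vaf_range[1] > 0, vaf_range[2] < 0.5,
            vaf_range[1] < vaf_range[2])
  stopifnot(all(names(n_samples) %in% names(somatic_rate)))
  structure(list(n_samples = n_samples, target_depth = target_depth,
                 error_rate = error_rate, umi_length = as.integer(umi_length),
                 umi_family_size = umi_family_size,
                 somatic_rate = somatic_rate, germline_rate = germline_rate,
                 vaf_range = vaf_range, seed = as.integer(seed)),
            class = "sim_config")
}

DEFAULT_PANEL_GENES <- c("VAPB", "MAPT", "FUS", "NEFH", "CCNF", "NEK1", "TBK1")

#' Generate a synthetic targeted gene panel
#'
#' Builds, deterministically from `seed`, one random reference contig per
#' gene plus a toy gene model (5'UTR, exons, introns, 3'UTR, intergenic
#' flanks) and the corresponding target intervals. Coordinates are 0-based
#' half-open throughout.
#'
#' @param gene_names character vector of panel gene symbols; duplicates are
#'   rejected. Defaults to seven ALS-associated genes.
#' @param exon_model list controlling the toy gene geometry: `n_exons`,
#'   `exon_len`, `intron_len`, `utr5_len`, `utr3_len`, `flank`.
#' @param seed integer seed.
#' @return list with `reference` (named character vector of contig
#'   sequences), `targets` (BED-like data frame: chrom, start, end, name,
#'   score, strand), and `gene_model` (data frame: gene, chrom, start, end,
#'   feature, strand with feature in exon/intron/5UTR/3UTR).
#' @examples
#' panel <- generate_panel(c("FUS", "TBK1"), seed = 1)
#' head(panel$gene_model)
#' @export
generate_panel <- function(gene_names = DEFAULT_PANEL_GENES,
                           exon_model = list(n_exons = 3L, exon_len = 160L,
                                             intron_len = 300L, utr5_len = 100L,
                                             utr3_len = 150L, flank = 100L),
                           seed = 1L) {
  if (length(gene_names) == 0) .stopf("gene_names must be non-empty")
  if (anyDuplicated(gene_names)) .stopf("duplicate gene names: %s",
    paste(unique(gene_names[duplicated(gene_names)]), collapse = ", "))
  em <- modifyList(list(n_exons = 3L, exon_len = 160L, intron_len = 300L,
                        utr5_len = 100L, utr3_len = 150L, flank = 100L),
                   exon_model)
  with_seed(derive_seed(seed, "panel"), {
    ref <- character(0); targets <- NULL; gm <- NULL
    for (g in gene_names) {
      feats <- list(c("5UTR", em$utr5_len))
      for (i in seq_len(em$n_exons)) {
        feats <- c(feats, list(c("exon", em$exon_len)))
        if (i < em$n_exons) feats <- c(feats, list(c("intron", em$intron_len)))
      }
      feats <- c(feats, list(c("3UTR", em$utr3_len)))
      lens <- vapply(feats, function(f) as.integer(f[2]), integer(1))
      contig <- paste0("panel_", g)
      total <- em$flank + sum(lens) + em$flank
      ref[contig] <- .random_dna(1, total)
      pos <- em$flank
      for (f in feats) {
        gm <- rbind(gm, data.frame(gene = g, chrom = contig, start = pos,
                                   end = pos + as.integer(f[2]),
                                   feature = f[1], strand = "+",
                                   stringsAsFactors = FALSE))
        pos <- pos + as.integer(f[2])
      }
      targets <- rbind(targets, data.frame(chrom = contig, start = em$flank,
                                           end = pos, name = g, score = 0L,
                                           strand = "+",
                                           stringsAsFactors = FALSE))
    }
    rownames(gm) <- NULL
    list(reference = ref, targets = targets, gene_model = gm)
  })
}

#' Sample metadata table for a synthetic cohort
#'
#' Draws per-sample covariates (sex, age, collection-site origin, mean
#' coverage) for the configured group sizes.
#'
#' @param cfg a [sim_config()].
#' @return data frame with sample_id, group, sex, age, origin,
#'   total_coverage.
#' @export
simulate_metadata <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(derive_seed(cfg$seed, "metadata"), {
    groups <- rep(names(cfg$n_samples), cfg$n_samples)
    n <- length(groups)
    data.frame(
      sample_id = sprintf("S%02d", seq_len(n)),
      group = groups,
      sex = sample(c("M", "F"), n, replace = TRUE),
      age = as.integer(round(runif(n, 45, 85))),
      origin = sample(c("site1", "site2"), n, replace = TRUE),
      total_coverage = as.integer(round(cfg$target_depth * runif(n, 0.8, 1.2))),
      stringsAsFactors = FALSE)
  })
}

# draw somatic true VAFs log-uniformly inside cfg$vaf_range
.draw_somatic_vaf <- function(n, cfg) {
  exp(runif(n, log(cfg$vaf_range[1]), log(cfg$vaf_range[2])))
}

#' Simulate a consensus pileup for one sample with planted variants
#'
#' Generates a per-site consensus pileup over the panel targets at the
#' sample's coverage, planting somatic variants (log-uniform VAF inside the
#' configured window) and germline variants (VAF near 0.5 or 1.0). The
#' observed alternate count at a planted site is binomial with success
#' probability `vaf * (1 - e) + (1 - vaf) * e / 3`; non-variant sites carry
#' background errors at rate `e` split evenly over the three alternate
#' bases.
#'
#' @param panel output of [generate_panel()].
#' @param meta one row of [simulate_metadata()] (sample_id, group,
#'   total_coverage used).
#' @param cfg a [sim_config()].
#' @return list with `pileup` (data frame chrom, pos, ref, A, C, G, T,
#'   depth) and `truth` (data frame chrom, pos, ref, alt, true_vaf, origin,
#'   sample_id).
#' @examples
#' panel <- generate_panel(c("FUS"), seed = 1)
#' cfg <- sim_config(seed = 1)
#' meta <- simulate_metadata(cfg)[1, ]
#' sim <- simulate_sample(panel, meta, cfg)
#' head(sim$truth)
#' @export
simulate_sample <- function(panel, meta, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  depth_mean <- if (!is.null(meta$total_coverage)) meta$total_coverage else
    cfg$target_depth
  if (depth_mean < 1) .stopf("sample depth must be >= 1")
  with_seed(derive_seed(cfg$seed, paste0("sample_", meta$sample_id)), {
    sites <- do.call(rbind, lapply(seq_len(nrow(panel$targets)), function(i) {
      t <- panel$targets[i, ]
      pos <- seq.int(t$start, t$end - 1L)
      data.frame(chrom = t$chrom, pos = pos,
                 ref = strsplit(substr(panel$reference[[t$chrom]],
                                       t$start + 1L, t$end), "")[[1]],
                 stringsAsFactors = FALSE)
    }))
    n <- nrow(sites)
    e <- cfg$error_rate
    depth <- rpois(n, depth_mean)
    counts <- matrix(0L, n, 4, dimnames = list(NULL, DNA_BASES))
    # background errors: each non-reference base at rate e/3
    for (b in DNA_BASES) {
      idx <- sites$ref != b
      counts[idx, b] <- rbinom(sum(idx), depth[idx], e / 3)
    }

    # planted variants
    rate <- cfg$somatic_rate[[meta$group]]
    n_som <- rpois(1, rate)
    n_germ <- rpois(1, cfg$germline_rate)
    n_var <- min(n_som + n_germ, n)
    var_idx <- if (n_var > 0) sample.int(n, n_var) else integer(0)
    som_idx <- head(var_idx, min(n_som, n_var))
    germ_idx <- setdiff(var_idx, som_idx)
    truth <- NULL
    plant <- function(idx, vafs, origin) {
      for (k in seq_along(idx)) {
        i <- idx[k]
        alt <- sample(setdiff(DNA_BASES, sites$ref[i]), 1)
        p <- vafs[k] * (1 - e) + (1 - vafs[k]) * e / 3
        counts[i, alt] <<- rbinom(1, depth[i], p)
        truth <<- rbind(truth, data.frame(
          chrom = sites$chrom[i], pos = sites$pos[i], ref = sites$ref[i],
          alt = alt, true_vaf = vafs[k], origin = origin,
          sample_id = meta$sample_id, stringsAsFactors = FALSE))
      }
    }
    plant(som_idx, .draw_somatic_vaf(length(som_idx), cfg), "somatic")
    # germline: heterozygous 0.5 or homozygous 1.0 (2:1)
    if (length(germ_idx) > 0) {
      gv <- ifelse(runif(length(germ_idx)) < 2 / 3, 0.5, 1.0)
      plant(germ_idx, gv, "germline")
    }
    # reference base takes the remaining depth
    alt_total <- rowSums(counts)
    over <- alt_total > depth
    if (any(over)) { # rare collision of error draws; cap at depth
      for (i in which(over)) {
        counts[i, ] <- as.integer(counts[i, ] * depth[i] / alt_total[i])
      }
      alt_total <- rowSums(counts)
    }
    counts[cbind(seq_len(n), match(sites$ref, DNA_BASES))] <-
      depth - alt_total
    pileup <- cbind(sites, as.data.frame(counts), depth = depth)
    if (is.null(truth)) {
      truth <- data.frame(chrom = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          true_vaf = numeric(0), origin = character(0),
                          sample_id = character(0), stringsAsFactors = FALSE)
    } else {
      truth <- truth[order(truth$chrom, truth$pos), , drop = FALSE]
      rownames(truth) <- NULL
    }
    list(pileup = pileup, truth = truth)
  })
}

#' Simulate UMI-tagged reads over one locus
#'
#' Read-level simulator used to exercise UMI grouping and consensus: each
#' source molecule receives a random UMI and a mapping start, spawns a
#' family of reads (size 1 + Poisson(mean - 1)), and every read copies the
#' molecule sequence with independent per-base errors at rate
#' `error_rate`. Molecules carry a planted variant with probability equal
#' to its VAF.
#'
#' @param reference single reference sequence (character scalar).
#' @param chrom contig name of the locus.
#' @param n_molecules number of source molecules.
#' @param read_length read length (default 50).
#' @param variants optional data frame (pos, alt, vaf) of planted variants.
#' @param cfg a [sim_config()] (umi_length, umi_family_size, error_rate
#'   used; note read-level error is typically larger than the consensus
#'   rate, pass e.g. `error_rate = 0.01`).
#' @param seed integer seed.
#' @return data frame of reads: read_id, molecule_id, umi, chrom, start
#'   (0-based), bases; attribute `molecules` records per-molecule truth
#'   (umi, start, carries which variant).
#' @export
simulate_tagged_reads <- function(reference, chrom, n_molecules,
                                  read_length = 50L, variants = NULL,
                                  cfg = sim_config(), seed = 1L) {
  L <- nchar(reference)
  if (read_length > L) .stopf("read_length exceeds locus length")
  with_seed(derive_seed(seed, "reads"), {
    umis <- .random_dna(n_molecules, cfg$umi_length)
    starts <- sample.int(L - read_length + 1L, n_molecules,
                         replace = TRUE) - 1L
    carries <- matrix(FALSE, n_molecules,
                      if (is.null(variants)) 0 else nrow(variants))
    reads <- vector("list", n_molecules)
    for (m in seq_len(n_molecules)) {
      seq_m <- substr(reference, starts[m] + 1L, starts[m] + read_length)
      if (!is.null(variants) && nrow(variants) > 0) {
        for (v in seq_len(nrow(variants))) {
          off <- variants$pos[v] - starts[m]
          if (off >= 0 && off < read_length && runif(1) < variants$vaf[v]) {
            substr(seq_m, off + 1L, off + 1L) <- variants$alt[v]
            carries[m, v] <- TRUE
          }
        }
      }
      fam <- 1L + rpois(1, max(cfg$umi_family_size - 1, 0))
      bases <- vapply(seq_len(fam), function(r) {
        b <- strsplit(seq_m, "", fixed = TRUE)[[1]]
        err <- runif(read_length) < cfg$error_rate
        if (any(err)) {
          b[err] <- vapply(b[err], function(x)
            sample(setdiff(DNA_BASES, x), 1), character(1))
        }
        paste(b, collapse = "")
      }, character(1))
      reads[[m]] <- data.frame(molecule_id = m, umi = umis[m], chrom = chrom,
                               start = starts[m], bases = bases,
                               stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, reads)
    out$read_id <- sprintf("r%05d", seq_len(nrow(out)))
    out <- out[, c("read_id", "molecule_id", "umi", "chrom", "start", "bases")]
    attr(out, "molecules") <- data.frame(molecule_id = seq_len(n_molecules),
                                         umi = umis, start = starts)
    attr(out, "carries") <- carries
    out
  })
}

#' Simulate a single-cell cohort with planted clonal variants
#'
#' Emulates sparse scRNA pileups: per-cell per-site coverage follows a
#' zero-inflated Poisson with a cell-type-specific mean; planted clonal
#' somatic variants are carried by a stated fraction of the cells of one
#' host cell type (heterozygous, so carrier cells emit alternate reads at
#' ~50% of their site coverage); all other reads err at `error_rate`.
#'
#' @param cell_type_spec data frame with columns cell_type, n_cells, and
#'   optionally mean_depth (per covered site, default 8), p_zero (dropout
#'   probability, default 0.7), condition, cluster_id.
#' @param clone_spec data frame with columns cell_type (host),
#'   carrier_fraction in (0, 1], n_clones (variant sites per row); NULL
#'   for no clones.
#' @param cfg list with n_sites (default 200), error_rate (default 1e-3),
#'   seed.
#' @return list with `pileup` (long data frame: cell_barcode, cell_type,
#'   chrom, pos, ref, A, C, G, T; zero-coverage cell/site pairs omitted),
#'   `annotations` (cell_barcode, cell_type, cluster_id, condition) and
#'   `truth` (one row per clone: chrom, pos, ref, alt, cell_type,
#'   carrier_fraction, n_carriers plus carrier barcodes as a list column).
#' @examples
#' cts <- data.frame(cell_type = c("excitatory", "astrocyte"),
#'                   n_cells = c(30, 30))
#' clones <- data.frame(cell_type = "excitatory", carrier_fraction = 0.2,
#'                      n_clones = 2)
#' sc <- simulate_sc_cohort(cts, clones, list(n_sites = 50, seed = 1))
#' sc$truth$n_carriers
#' @export
simulate_sc_cohort <- function(cell_type_spec, clone_spec = NULL,
                               cfg = list()) {
  cfg <- modifyList(list(n_sites = 200L, error_rate = 1e-3, seed = 1L), cfg)
  if (nrow(cell_type_spec) < 2) .stopf("need at least 2 cell types")
  if (!is.null(clone_spec) && nrow(clone_spec) > 0) {
    if (any(clone_spec$carrier_fraction > 1 | clone_spec$carrier_fraction <= 0))
      .stopf("carrier_fraction must lie in (0, 1]")
    if (!all(clone_spec$cell_type %in% cell_type_spec$cell_type))
      .stopf("clone host cell type not in cell_type_spec")
  }
  cts <- cell_type_spec
  if (is.null(cts$mean_depth)) cts$mean_depth <- 8
  if (is.null(cts$p_zero)) cts$p_zero <- 0.7
  if (is.null(cts$condition)) cts$condition <- "sALS"
  if (is.null(cts$cluster_id)) cts$cluster_id <- seq_len(nrow(cts))
  with_seed(derive_seed(cfg$seed, "sc_cohort"), {
    n_sites <- cfg$n_sites
    ref <- sample(DNA_BASES, n_sites, replace = TRUE)
    sites <- data.frame(chrom = "sc_panel", pos = seq_len(n_sites) - 1L,
                        ref = ref, stringsAsFactors = FALSE)
    ann <- do.call(rbind, lapply(seq_len(nrow(cts)), function(i) {
      data.frame(cell_barcode = sprintf("%s_%03d", cts$cell_type[i],
                                        seq_len(cts$n_cells[i])),
                 cell_type = cts$cell_type[i],
                 cluster_id = cts$cluster_id[i],
                 condition = cts$condition[i], stringsAsFactors = FALSE)
    }))
    # assign clone sites and carriers
    truth <- NULL
    carrier_list <- list()
    carrier_of <- list()  # site index -> carrier barcodes, alt base
    if (!is.null(clone_spec) && nrow(clone_spec) > 0) {
      free_sites <- sample.int(n_sites)
      k <- 0
      for (r in seq_len(nrow(clone_spec))) {
        for (j in seq_len(clone_spec$n_clones[r])) {
          k <- k + 1
          if (k > n_sites) .stopf("more clones than sites")
          s <- free_sites[k]
          host <- clone_spec$cell_type[r]
          cells <- ann$cell_barcode[ann$cell_type == host]
          n_car <- round(clone_spec$carrier_fraction[r] * length(cells))
          carriers <- sample(cells, n_car)
          alt <- sample(setdiff(DNA_BASES, sites$ref[s]), 1)
          carrier_of[[as.character(s)]] <- list(carriers = carriers,
                                                alt = alt)
          truth <- rbind(truth, data.frame(
            chrom = "sc_panel", pos = sites$pos[s], ref = sites$ref[s],
            alt = alt, cell_type = host,
            carrier_fraction = clone_spec$carrier_fraction[r],
            n_carriers = n_car, stringsAsFactors = FALSE))
          carrier_list[[length(carrier_list) + 1L]] <- carriers
        }
      }
    }
    # per-cell coverage and counts
    n_cells <- nrow(ann)
    md <- cts$mean_depth[match(ann$cell_type, cts$cell_type)]
    pz <- cts$p_zero[match(ann$cell_type, cts$cell_type)]
    rows <- vector("list", n_cells)
    e <- cfg$error_rate
    for (ci in seq_len(n_cells)) {
      dep <- rpois(n_sites, md[ci]) * (runif(n_sites) >= pz[ci])
      cov <- which(dep > 0)
      if (length(cov) == 0) next
      cnt <- matrix(0L, length(cov), 4, dimnames = list(NULL, DNA_BASES))
      for (k in seq_along(cov)) {
        s <- cov[k]
        d <- dep[s]
        info <- carrier_of[[as.character(s)]]
        vaf <- if (!is.null(info) &&
                   ann$cell_barcode[ci] %in% info$carriers) 0.5 else 0
        alt_b <- if (!is.null(info)) info$alt else
          setdiff(DNA_BASES, sites$ref[s])[1]
        a <- rbinom(1, d, vaf * (1 - e) + (1 - vaf) * e)
        cnt[k, alt_b] <- a
        cnt[k, sites$ref[s]] <- cnt[k, sites$ref[s]] + d - a
      }
      rows[[ci]] <- data.frame(cell_barcode = ann$cell_barcode[ci],
                               cell_type = ann$cell_type[ci],
                               chrom = "sc_panel", pos = sites$pos[cov] ,
                               ref = sites$ref[cov],
                               as.data.frame(cnt), stringsAsFactors = FALSE)
    }
    pileup <- do.call(rbind, rows)
    rownames(pileup) <- NULL
    if (is.null(truth)) {
      truth <- data.frame(chrom = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          cell_type = character(0),
                          carrier_fraction = numeric(0),
                          n_carriers = integer(0), stringsAsFactors = FALSE)
      truth$carriers <- list()
    } else {
      truth$carriers <- carrier_list
    }
    list(pileup = pileup, annotations = ann, truth = truth, sites = sites)
  })
}
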