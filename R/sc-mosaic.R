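#' Aggregate per-cell pileups by annotated cell type
#'
#' Sums per-cell base counts into per-cell-type counts at every covered
#' site, keeping the per-cell backtrace. Cells with zero coverage at a
#' site do not count towards `n_cells_covered`; cell types with no covered
#' cell at a site are retained as zero rows.
#'
#' @param pileup long per-cell pileup data frame (cell_barcode, cell_type
#'   optional, chrom, pos, ref, A, C, G, T), e.g. from
#'   [simulate_sc_cohort()] or [read_sc_pileup()].
#' @param annotations data frame (cell_barcode, cell_type, ...); every
#'   barcode in the pileup must be annotated.
#' @return data frame with chrom, pos, ref, cell_type, A, C, G, T, depth,
#'   n_cells_covered, one row per site x cell type; attribute `backtrace`
#'   keeps the input per-cell rows (with cell_type filled from the
#'   annotations).
#' @export
aggregate_by_celltype <- function(pileup, annotations) {
  missing <- setdiff(unique(pileup$cell_barcode), annotations$cell_barcode)
  if (length(missing) > 0)
    .stopf("unannotated cell barcode(s): %s",
           paste(head(missing, 5), collapse = ", "))
  pileup$cell_type <- annotations$cell_type[match(pileup$cell_barcode,
                                                  annotations$cell_barcode)]
  types <- sort(unique(annotations$cell_type))
  pileup$depth_cell <- pileup$A + pileup$C + pileup$G + pileup$T
  sites <- unique(pileup[, c("chrom", "pos", "ref")])
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  key_site <- paste(pileup$chrom, pileup$pos)
  out <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
    sel <- key_site == paste(sites$chrom[i], sites$pos[i])
    sub <- pileup[sel, , drop = FALSE]
    do.call(rbind, lapply(types, function(ct) {
      s2 <- sub[sub$cell_type == ct & sub$depth_cell > 0, , drop = FALSE]
      data.frame(chrom = sites$chrom[i], pos = sites$pos[i],
                 ref = sites$ref[i], cell_type = ct,
                 A = sum(s2$A), C = sum(s2$C), G = sum(s2$G),
                 T = sum(s2$T),
                 depth = sum(s2$depth_cell), n_cells_covered = nrow(s2),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  attr(out, "backtrace") <- pileup
  out
}

#' Single-cell caller filter settings
#'
#' @param min_cells minimum covered cells per cell type for the type to be
#'   testable at a site (default 5).
#' @param min_depth minimum aggregated depth per cell type (default 20).
#' @param alpha significance threshold on BH-adjusted per-type p-values
#'   (default 0.01).
#' @param max_host_types maximum number of passing cell types for a
#'   somatic call; more passing types suggests a germline variant or
#'   artifact (default 2).
#' @param germline_screen pooled non-host alternate fraction above which a
#'   candidate is rejected (default 0.05).
#' @param germline_af,germline_types a variant with alternate fraction at
#'   least `germline_af` (default 0.2) in at least `germline_types`
#'   (default 3) testable types is labelled germline_like.
#' @param rho beta-binomial overdispersion of the cross-cell-type error
#'   null (default 0.01).
#' @param error_floor lower clamp on the cross-type error estimate
#'   (default 1e-4).
#' @return list of class `sc_filters`.
#' @export
sc_filters <- function(min_cells = 5L, min_depth = 20L, alpha = 0.01,
                       max_host_types = 2L, germline_screen = 0.05,
                       germline_af = 0.2, germline_types = 3L,
                       rho = 0.01, error_floor = 1e-4) {
  structure(list(min_cells = min_cells, min_depth = min_depth,
                 alpha = alpha, max_host_types = max_host_types,
                 germline_screen = germline_screen,
                 germline_af = germline_af,
                 germline_types = germline_types, rho = rho,
                 error_floor = error_floor), class = "sc_filters")
}

#' Call cell-type-restricted somatic variants from aggregated pileups
#'
#' SComatic-style contrast: at each site and for each sufficiently covered
#' cell type, the alternate count is tested against a beta-binomial error
#' null whose rate is estimated from all *other* cell types at that site.
#' Per-type p-values are BH-adjusted across types; a site is somatic when
#' at least one type passes, at most `max_host_types` types pass, and the
#' pooled alternate fraction outside the host types stays below the
#' germline screen. Sites with high alternate fraction in three or more
#' types are labelled germline_like; sites with no testable type are
#' untested.
#'
#' @param ctp output of [aggregate_by_celltype()].
#' @param filters an [sc_filters()] list.
#' @return data frame, one row per site with a non-reference observation:
#'   chrom, pos, ref, alt, status (somatic/germline_like/artifact/
#'   untested), host_cell_types (comma-joined), plus per-type alt
#'   fractions and q-values in the `per_type` attribute.
#' @export
call_sc_variants <- function(ctp, filters = sc_filters()) {
  cm <- as.matrix(ctp[, DNA_BASES])
  ridx <- match(ctp$ref, DNA_BASES)
  ref_count <- cm[cbind(seq_len(nrow(cm)), ridx)]
  alt_total <- ctp$depth - ref_count
  key <- paste(ctp$chrom, ctp$pos)
  out <- NULL
  per_type <- list()
  for (k in unique(key)) {
    sel <- which(key == k)
    sub <- ctp[sel, , drop = FALSE]
    # top alternate base pooled over types
    pooled <- colSums(cm[sel, , drop = FALSE])
    pooled[match(sub$ref[1], DNA_BASES)] <- -1
    alt_b <- DNA_BASES[which.max(pooled)]
    alt_counts <- cm[sel, alt_b]
    testable <- sub$n_cells_covered >= filters$min_cells &
      sub$depth >= filters$min_depth
    rec <- data.frame(chrom = sub$chrom[1], pos = sub$pos[1],
                      ref = sub$ref[1], alt = alt_b,
                      stringsAsFactors = FALSE)
    if (!any(testable)) {
      rec$status <- "untested"; rec$host_cell_types <- ""
      out <- rbind(out, rec); next
    }
    if (max(pooled) <= 0) next  # no alternate observation anywhere
    af <- ifelse(sub$depth > 0, alt_counts / sub$depth, 0)
    # germline screen: widespread high AF
    if (sum(af[testable] >= filters$germline_af) >=
        filters$germline_types) {
      rec$status <- "germline_like"; rec$host_cell_types <- ""
      out <- rbind(out, rec)
      next
    }
    p <- rep(NA_real_, nrow(sub))
    for (i in which(testable)) {
      others <- setdiff(which(testable), i)
      if (length(others) == 0) next
      e_bg <- sum(alt_counts[others]) / max(sum(sub$depth[others]), 1)
      e_bg <- min(max(e_bg, filters$error_floor), 0.499)
      p[i] <- pbetabinom_upper(alt_counts[i], sub$depth[i], e_bg,
                               filters$rho)
    }
    q <- rep(NA_real_, length(p))
    q[!is.na(p)] <- fdr_adjust(p[!is.na(p)])
    pass <- which(!is.na(q) & q <= filters$alpha)
    status <- "artifact"
    hosts <- character(0)
    if (length(pass) >= 1 && length(pass) <= filters$max_host_types) {
      non_host <- setdiff(which(testable), pass)
      pooled_af <- if (length(non_host) == 0) 0 else
        sum(alt_counts[non_host]) / max(sum(sub$depth[non_host]), 1)
      if (pooled_af < filters$germline_screen) {
        status <- "somatic"
        hosts <- sub$cell_type[pass]
      }
    } else if (length(pass) == 0) {
      next  # background noise only; no record emitted
    }
    rec$status <- status
    rec$host_cell_types <- paste(hosts, collapse = ",")
    out <- rbind(out, rec)
    per_type[[k]] <- data.frame(cell_type = sub$cell_type, alt_count =
                                  alt_counts, depth = sub$depth, af = af,
                                p = p, q = q, stringsAsFactors = FALSE)
  }
  if (is.null(out))
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      status = character(0), host_cell_types = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "per_type") <- per_type
  out
}

#' Per-cell somatic variant burden
#'
#' A cell's burden is the number of somatic variant sites at which it
#' carries at least one alternate read.
#'
#' @param variants output of [call_sc_variants()] (only status == somatic
#'   rows are used).
#' @param pileup the per-cell pileup the variants were called from.
#' @param annotations cell annotations (cell_barcode, cell_type,
#'   cluster_id, condition as available).
#' @return data frame: cell_barcode, cell_type, cluster_id, condition (as
#'   available), n_covered_sites, n_variants.
#' @export
per_cell_burden <- function(variants, pileup, annotations) {
  som <- variants[variants$status == "somatic", , drop = FALSE]
  pileup$depth_cell <- pileup$A + pileup$C + pileup$G + pileup$T
  cov_sites <- tapply(pileup$depth_cell > 0, pileup$cell_barcode, sum)
  n_var <- setNames(integer(nrow(annotations)), annotations$cell_barcode)
  if (nrow(som) > 0) {
    key_p <- paste(pileup$chrom, pileup$pos)
    for (i in seq_len(nrow(som))) {
      sel <- key_p == paste(som$chrom[i], som$pos[i])
      altc <- pileup[[som$alt[i]]][sel]
      carriers <- unique(pileup$cell_barcode[sel][altc > 0])
      carriers <- intersect(carriers, names(n_var))
      n_var[carriers] <- n_var[carriers] + 1L
    }
  }
  out <- annotations
  out$n_covered_sites <- as.integer(cov_sites[out$cell_barcode])
  out$n_covered_sites[is.na(out$n_covered_sites)] <- 0L
  out$n_variants <- as.integer(n_var[out$cell_barcode])
  rownames(out) <- NULL
  out
}

#' Pairwise cell-type burden comparison (NB GLM)
#'
#' Models per-cell somatic burden with cell type as predictor in an
#' [nb_glm()], adjusting for per-cell coverage, then tests all pairwise
#' cell-type contrasts by Wald tests on coefficient differences with BH
#' adjustment across contrasts. Cell types with fewer than `min_cells`
#' cells are excluded with a warning.
#'
#' @param burdens output of [per_cell_burden()].
#' @param min_cells minimum cells per included type (default 10).
#' @param cells_covariate "covered_sites" (default; per-cell
#'   log1p(covered sites) as covariate) or "per_type_offset" (log cells
#'   per type as offset).
#' @param test "lrt" (default) compares, per pair, the full model against
#'   one merging the two types (chi-squared, 1 df) — well behaved even
#'   when one type has all-zero burden; "wald" uses coefficient-difference
#'   z-tests.
#' @return data frame of contrasts: type_a, type_b, log_ratio, se, z,
#'   p_value, q_value; the fitted model in attribute `fit`.
#' @export
compare_celltype_burden <- function(burdens, min_cells = 10L,
                                    cells_covariate = "covered_sites",
                                    test = c("lrt", "wald")) {
  test <- match.arg(test)
  tab <- table(burdens$cell_type)
  small <- names(tab)[tab < min_cells]
  if (length(small) > 0) {
    .warnf("excluding cell type(s) with < %d cells: %s", min_cells,
           paste(small, collapse = ", "))
    burdens <- burdens[!burdens$cell_type %in% small, , drop = FALSE]
  }
  types <- sort(unique(burdens$cell_type))
  if (length(types) < 2) .stopf("need >= 2 cell types for contrasts")
  burdens$cell_type <- factor(burdens$cell_type, levels = types)
  make_fit <- function(d) {
    if (cells_covariate == "covered_sites") {
      nb_glm(n_variants ~ cell_type + log1p(n_covered_sites), d)
    } else {
      d$off <- log(as.numeric(table(d$cell_type)[as.character(d$cell_type)]))
      nb_glm(n_variants ~ cell_type + offset(off), d)
    }
  }
  fit <- make_fit(burdens)
  cf <- coef(fit); vc <- vcov(fit)
  coef_of <- function(ct) if (ct == types[1]) NULL else
    paste0("cell_type", ct)
  rows <- list()
  for (i in seq_along(types)) for (j in seq_along(types)) {
    if (i >= j) next
    ca <- coef_of(types[i]); cb <- coef_of(types[j])
    v <- setNames(numeric(length(cf)), names(cf))
    if (!is.null(ca)) v[ca] <- 1
    if (!is.null(cb)) v[cb] <- v[cb] - 1
    est <- sum(v * cf)
    se <- sqrt(drop(t(v) %*% vc %*% v))
    z <- est / se
    p <- if (test == "wald") 2 * pnorm(-abs(z)) else {
      # refit with the pair merged; theta fixed at the full-model value so
      # the two likelihoods are comparable
      d2 <- burdens
      lv <- as.character(d2$cell_type)
      lv[lv %in% c(types[i], types[j])] <- paste0(types[i], "+", types[j])
      d2$cell_type <- factor(lv)
      fit0 <- make_fit0 <- tryCatch({
        if (cells_covariate == "covered_sites") {
          nb_glm(n_variants ~ cell_type + log1p(n_covered_sites), d2,
                 theta = fit$theta)
        } else {
          d2$off <- log(as.numeric(table(d2$cell_type)[
            as.character(d2$cell_type)]))
          nb_glm(n_variants ~ cell_type + offset(off), d2,
                 theta = fit$theta)
        }
      }, error = function(e) NULL)
      if (is.null(fit0)) NA_real_ else {
        lr <- 2 * (fit$loglik - fit0$loglik)
        stats::pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
      }
    }
    rows[[length(rows) + 1]] <- data.frame(
      type_a = types[i], type_b = types[j], log_ratio = est, se = se,
      z = z, p_value = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q_value <- fdr_adjust(out$p_value)
  attr(out, "fit") <- fit
  out
}

#' Per-cluster burden summary
#'
#' Mean and median burden per externally provided cluster, plus the
#' cluster's condition composition (fractions summing to one).
#'
#' @param burdens output of [per_cell_burden()] with a cluster_id column.
#' @return list with `summary` (cluster_id, n_cells, mean_burden,
#'   median_burden, ranked by mean) and `composition` (cluster_id x
#'   condition fraction table).
#' @export
cluster_burden <- function(burdens) {
  stopifnot("cluster_id" %in% names(burdens))
  ids <- sort(unique(burdens$cluster_id))
  summ <- do.call(rbind, lapply(ids, function(cl) {
    b <- burdens$n_variants[burdens$cluster_id == cl]
    data.frame(cluster_id = cl, n_cells = length(b), mean_burden = mean(b),
               median_burden = median(b), stringsAsFactors = FALSE)
  }))
  summ <- summ[order(-summ$mean_burden), , drop = FALSE]
  rownames(summ) <- NULL
  comp <- NULL
  if ("condition" %in% names(burdens)) {
    comp <- prop.table(table(cluster_id = burdens$cluster_id,
                             condition = burdens$condition), margin = 1)
  }
  list(summary = summ, composition = comp)
}
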