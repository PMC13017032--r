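#' The 96 pyrimidine-centred substitution channels
#'
#' Standard single-base-substitution channel names in COSMIC order:
#' six substitution types (C>A, C>G, C>T, T>A, T>C, T>G) times 16 flanking
#' base pairs, written as e.g. `A[C>A]A`.
#'
#' @return character vector of 96 channel names.
#' @export
sbs_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (s in subs) for (l in DNA_BASES) for (r in DNA_BASES)
    out <- c(out, paste0(l, "[", s, "]", r))
  out
}

#' Map one stranded substitution-with-context to its channel
#'
#' Substitutions with a purine reference (A or G) are reverse-complemented
#' onto the pyrimidine strand, so all 192 stranded (left, ref, alt, right)
#' combinations map onto the 96 channels.
#'
#' @param left,ref,alt,right single bases.
#' @return a channel name, e.g. `"A[C>T]A"`.
#' @examples
#' sbs_channel_of("T", "G", "A", "T")  # reverse-complements to A[C>T]A
#' @export
sbs_channel_of <- function(left, ref, alt, right) {
  if (ref %in% c("A", "G")) {
    new_left <- .COMPLEMENT[[right]]
    new_right <- .COMPLEMENT[[left]]
    ref <- .COMPLEMENT[[ref]]
    alt <- .COMPLEMENT[[alt]]
    left <- new_left
    right <- new_right
  }
  paste0(left, "[", ref, ">", alt, "]", right)
}

#' Trinucleotide context spectrum of a set of SNVs
#'
#' Counts each SNV into its pyrimidine-centred 96-channel class using the
#' flanking bases from the reference. SNVs at a contig edge (no flank) are
#' skipped and counted in the `n_skipped` attribute.
#'
#' @param snvs data frame with chrom, pos (0-based), ref, alt.
#' @param reference named character vector of contig sequences.
#' @return named integer vector of length 96 (class `context_spectrum`);
#'   its sum equals the number of non-skipped SNVs.
#' @export
context_spectrum <- function(snvs, reference) {
  chan <- sbs_channels()
  spec <- setNames(integer(96), chan)
  n_skipped <- 0L
  for (i in seq_len(nrow(snvs))) {
    chrom <- snvs$chrom[i]; pos <- snvs$pos[i]
    if (!chrom %in% names(reference)) .stopf("contig '%s' not in reference",
                                             chrom)
    L <- nchar(reference[[chrom]])
    if (pos < 1 || pos > L - 2) { n_skipped <- n_skipped + 1L; next }
    tri <- substr(reference[[chrom]], pos, pos + 2)  # pos is 0-based
    b <- strsplit(tri, "", fixed = TRUE)[[1]]
    if (b[2] != snvs$ref[i])
      .stopf("reference mismatch at %s:%d (%s vs %s)", chrom, pos, b[2],
             snvs$ref[i])
    ch <- sbs_channel_of(b[1], b[2], snvs$alt[i], b[3])
    spec[ch] <- spec[ch] + 1L
  }
  attr(spec, "n_skipped") <- n_skipped
  class(spec) <- "context_spectrum"
  spec
}

#' A small synthetic SBS signature catalog
#'
#' Deterministic synthetic stand-in for a COSMIC-style catalog, for tests
#' and demos: a clock-like C>T-at-CpG-heavy signature, an indel-repair
#' (SBS26-like, T>C-heavy) signature, and a flat signature. Each row sums
#' to 1. It is synthetic: the channel weights are generated, not COSMIC
#' estimates.
#'
#' @param k number of signatures (2 or 3, default 3).
#' @return matrix of k signatures x 96 channels with rownames
#'   ("SBS1like", "SBS26like", "SBSflat").
#' @export
synthetic_signature_catalog <- function(k = 3L) {
  chan <- sbs_channels()
  w1 <- rep(0.2, 96)
  w1[grepl("\\[C>T\\]G", chan)] <- 8     # C>T at CpG
  w2 <- rep(0.2, 96)
  w2[grepl("\\[T>C\\]", chan)] <- 6      # T>C heavy, SBS26-like
  w3 <- rep(1, 96)
  m <- rbind(SBS1like = w1 / sum(w1), SBS26like = w2 / sum(w2),
             SBSflat = w3 / sum(w3))
  colnames(m) <- chan
  m[seq_len(k), , drop = FALSE]
}

#' Refit signature exposures by non-negative least squares
#'
#' Finds non-negative weights minimising the Euclidean distance between
#' the observed spectrum and a weighted mixture of catalog signatures
#' (active-set NNLS; deterministic). Relative fractions are the weights
#' normalised to sum one.
#'
#' @param spectrum a [context_spectrum()] (or any length-96 non-negative
#'   vector).
#' @param catalog signatures x 96 matrix with rows summing to 1, e.g.
#'   [synthetic_signature_catalog()] or [read_signature_catalog()].
#' @return list of class `signature_exposure`: weights, fractions (NA and
#'   flagged degenerate for an all-zero spectrum), residual (Euclidean).
#' @export
fit_signatures <- function(spectrum, catalog) {
  stopifnot(length(spectrum) == ncol(catalog))
  if (any(abs(rowSums(catalog) - 1) > 1e-6))
    .stopf("catalog rows must sum to 1")
  y <- as.numeric(spectrum)
  if (all(y == 0)) {
    return(structure(list(weights = setNames(rep(0, nrow(catalog)),
                                             rownames(catalog)),
                          fractions = setNames(rep(NA_real_, nrow(catalog)),
                                               rownames(catalog)),
                          residual = 0, degenerate = TRUE),
                     class = "signature_exposure"))
  }
  # solve on the unit-scale spectrum (NNLS iteration counts are scale
  # sensitive); weights scale back linearly
  ysum <- sum(y)
  fit <- pracma::lsqnonneg(t(catalog), y / ysum)
  w <- setNames(fit$x * ysum, rownames(catalog))
  structure(list(weights = w, fractions = w / sum(w),
                 residual = sqrt(sum((y - drop(t(catalog) %*% (fit$x * ysum)))^2)),
                 degenerate = FALSE),
            class = "signature_exposure")
}

#' @export
print.signature_exposure <- function(x, ...) {
  cat("signature exposures (NNLS refit)\n")
  print(round(rbind(weight = x$weights, fraction = x$fractions), 4))
  cat(sprintf("residual = %.4g\n", x$residual))
  invisible(x)
}

#' Compare signature fractions across conditions
#'
#' Computes per-condition context spectra, refits the catalog per
#' condition, and reports relative fractions side by side with bootstrap
#' confidence intervals obtained by resampling SNVs within condition.
#' Conditions contributing fewer than `min_snvs` SNVs are flagged
#' low-confidence.
#'
#' @param snvs data frame with chrom, pos, ref, alt, condition.
#' @param reference named character vector of contigs.
#' @param catalog signature catalog matrix.
#' @param n_boot bootstrap draws (default 1000).
#' @param min_snvs low-confidence threshold (default 50).
#' @param seed integer seed.
#' @return data frame: condition, signature, fraction, ci_lo, ci_hi,
#'   n_snvs, low_confidence.
#' @export
compare_condition_fractions <- function(snvs, reference, catalog,
                                        n_boot = 1000L, min_snvs = 50L,
                                        seed = 1L) {
  conds <- unique(snvs$condition)
  if (length(conds) < 2) .stopf("need >= 2 conditions")
  with_seed(derive_seed(seed, "sig_boot"), {
    out <- NULL
    for (cond in conds) {
      sub <- snvs[snvs$condition == cond, , drop = FALSE]
      fr <- fit_signatures(context_spectrum(sub, reference),
                           catalog)$fractions
      boots <- replicate(n_boot, {
        idx <- sample.int(nrow(sub), replace = TRUE)
        fit_signatures(context_spectrum(sub[idx, , drop = FALSE],
                                        reference), catalog)$fractions
      })
      ci <- apply(boots, 1, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
      out <- rbind(out, data.frame(
        condition = cond, signature = rownames(catalog),
        fraction = unname(fr), ci_lo = ci[1, ], ci_hi = ci[2, ],
        n_snvs = nrow(sub), low_confidence = nrow(sub) < min_snvs,
        stringsAsFactors = FALSE))
    }
    rownames(out) <- NULL
    out
  })
}

#' Weighted permutation gene-set burden enrichment
#'
#' Tests whether the observed number of SNVs falling in each gene set
#' exceeds a weighted null in which the same number of SNVs is reassigned
#' to genes with probability proportional to the gene weights (e.g.
#' covered panel length). Empirical p-values use the standard
#' pseudo-count `(1 + #{null >= obs}) / (n_perm + 1)`, so they are never
#' zero; q-values are BH across sets.
#'
#' @param snv_genes character vector: the gene of each SNV.
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param gene_weights named numeric vector of null sampling weights over
#'   the gene universe; names define the universe.
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @return data frame: set, size, observed, null_mean, p_value, q_value.
#' @export
geneset_burden_test <- function(snv_genes, gene_sets, gene_weights,
                                n_perm = 1000L, seed = 1L) {
  genes <- names(gene_weights)
  stopifnot(length(genes) > 0)
  n_snv <- length(snv_genes)
  with_seed(derive_seed(seed, "geneset_perm"), {
    null_genes <- matrix(sample(genes, n_snv * n_perm, replace = TRUE,
                                prob = gene_weights), nrow = n_perm)
    rows <- lapply(names(gene_sets), function(nm) {
      set <- gene_sets[[nm]]
      if (length(set) == 0) {
        .warnf("empty gene set '%s'", nm)
        return(data.frame(set = nm, size = 0L, observed = 0L,
                          null_mean = 0, p_value = 1,
                          stringsAsFactors = FALSE))
      }
      obs <- sum(snv_genes %in% set)
      null <- rowSums(matrix(null_genes %in% set, nrow = n_perm))
      data.frame(set = nm, size = length(set), observed = obs,
                 null_mean = mean(null),
                 p_value = (1 + sum(null >= obs)) / (n_perm + 1),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$q_value <- fdr_adjust(out$p_value)
    out
  })
}
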