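#' Caller configuration
#'
#' @param alpha per-caller significance threshold on the upper-tail
#'   p-value (default 1e-6).
#' @param min_depth minimum consensus depth for a site to be tested
#'   (default 500, a quarter of the 2000x design coverage).
#' @param af_low,af_high open allele-frequency window for somatic
#'   classification (defaults 0.015 and 0.35): calls with
#'   `af_low < VAF < af_high` are somatic, `VAF >= af_high` germline,
#'   `VAF <= af_low` filtered.
#' @param rule call-integration rule across callers: "intersection"
#'   (default), "union", or "at_least_k".
#' @param k number of supporting callers required under "at_least_k".
#' @return object of class `caller_config`.
#' @export
caller_config <- function(alpha = 1e-6, min_depth = 500L, af_low = 0.015,
                          af_high = 0.35, rule = "intersection", k = 1L) {
  if (!(af_low > 0 && af_low < af_high && af_high < 0.5))
    .stopf("require 0 < af_low < af_high < 0.5")
  if (!rule %in% c("intersection", "union", "at_least_k"))
    .stopf("unknown integration rule '%s'", rule)
  structure(list(alpha = alpha, min_depth = as.integer(min_depth),
                 af_low = af_low, af_high = af_high, rule = rule,
                 k = as.integer(k)),
            class = "caller_config")
}

#' Estimate the background error model from a pileup
#'
#' Pools the non-reference fraction over non-excluded sites into a global
#' per-base error rate `e`, and estimates the beta-binomial overdispersion
#' `rho` by method of moments on per-site alternate fractions:
#' for counts x_i ~ BetaBin(n_i, e, rho), Var(x_i/n_i) =
#' e(1-e)(1 + (n_i - 1) rho)/n_i. Both are clamped to their valid ranges
#' (`e` to [1e-6, 0.499], `rho` to [0, 0.999]).
#'
#' @param pileup consensus pileup data frame (chrom, pos, ref, A, C, G, T,
#'   depth).
#' @param exclude logical vector (length nrow(pileup)) masking candidate
#'   variant sites out of the estimate; NULL excludes nothing.
#' @return object of class `error_model`: list(e, rho, n_sites).
#' @export
estimate_error_model <- function(pileup, exclude = NULL) {
  if (!is.null(exclude)) pileup <- pileup[!exclude, , drop = FALSE]
  pileup <- pileup[pileup$depth > 0, , drop = FALSE]
  if (nrow(pileup) < 100)
    .stopf("need >= 100 non-excluded covered sites to estimate errors")
  cm <- as.matrix(pileup[, DNA_BASES])
  ref_count <- cm[cbind(seq_len(nrow(cm)), match(pileup$ref, DNA_BASES))]
  alt <- pileup$depth - ref_count
  e <- sum(alt) / sum(pileup$depth)
  e <- min(max(e, 1e-6), 0.499)
  # method of moments for rho on per-site alt fractions
  p_hat <- alt / pileup$depth
  s2 <- stats::var(p_hat)
  denom <- e * (1 - e) * mean((pileup$depth - 1) / pileup$depth)
  rho <- if (denom > 0) {
    (s2 - e * (1 - e) * mean(1 / pileup$depth)) / denom
  } else 0
  rho <- min(max(rho, 0), 0.999)
  structure(list(e = e, rho = rho, n_sites = nrow(pileup)),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf("error model: e = %.3g, rho = %.3g (from %d sites)\n",
              x$e, x$rho, x$n_sites))
  invisible(x)
}

# upper tail P(X >= q) for X ~ Binomial(size, prob), vectorised
.binom_upper <- function(q, size, prob) {
  pbinom(q - 1, size, prob, lower.tail = FALSE)
}

# log pmf of the beta-binomial with mean prob and overdispersion rho
.dbetabinom_log <- function(x, size, prob, rho) {
  s <- 1 / rho - 1
  a <- prob * s
  b <- (1 - prob) * s
  lchoose(size, x) + lbeta(x + a, size - x + b) - lbeta(a, b)
}

#' Beta-binomial upper-tail probability
#'
#' P(X >= q) for X ~ BetaBinomial(size, prob, rho); at rho = 0 this is the
#' binomial tail. Computed by summing the pmf below q (alternate counts at
#' error-dominated sites are small, so the lower sum is short).
#'
#' @param q observed count (vector).
#' @param size number of trials (vector).
#' @param prob mean success probability.
#' @param rho overdispersion in [0, 1).
#' @return vector of upper-tail probabilities.
#' @export
pbetabinom_upper <- function(q, size, prob, rho) {
  if (rho < 1e-12) return(.binom_upper(q, size, prob))
  s <- 1 / rho - 1
  a <- prob * s
  b <- (1 - prob) * s
  # lower-tail sum via the pmf ratio recurrence
  #   d(j+1)/d(j) = (size - j)/(j + 1) * (j + a)/(size - j - 1 + b),
  # advanced jointly for all sites and stopped early once every still-
  # active pmf term is negligible against the alpha scale
  lower <- numeric(length(q))
  d <- exp(lbeta(a, size + b) - lbeta(a, b))   # pmf at 0
  jmax <- max(q) - 1L
  j <- 0L
  while (j <= jmax) {
    act <- q > j
    if (!any(act)) break
    lower[act] <- lower[act] + d[act]
    if (max(d[act]) < 1e-18) break
    d <- d * ((size - j) / (j + 1)) * ((j + a) / (size - j - 1 + b))
    j <- j + 1L
  }
  out <- pmax(1 - lower, 0)
  out[q <= 0] <- 1
  out
}

# shared site-preparation: top non-reference base and its count
.site_candidates <- function(pileup) {
  cm <- as.matrix(pileup[, DNA_BASES])
  ridx <- match(pileup$ref, DNA_BASES)
  cm_alt <- cm
  cm_alt[cbind(seq_len(nrow(cm)), ridx)] <- -1L
  top <- max.col(cm_alt, ties.method = "first")
  data.frame(chrom = pileup$chrom, pos = pileup$pos, ref = pileup$ref,
             alt = DNA_BASES[top],
             alt_count = cm[cbind(seq_len(nrow(cm)), top)],
             depth = pileup$depth, stringsAsFactors = FALSE)
}

.call_with_tail <- function(pileup, model, cfg, tail_fun, caller) {
  cand <- .site_candidates(pileup)
  tested <- cand$depth >= cfg$min_depth
  cand <- cand[tested, , drop = FALSE]
  p <- tail_fun(cand$alt_count, cand$depth)
  keep <- p <= cfg$alpha & cand$alt_count > 0
  out <- cand[keep, , drop = FALSE]
  out$vaf <- out$alt_count / out$depth
  out$p_value <- p[keep]
  out$caller <- rep(caller, nrow(out))
  rownames(out) <- NULL
  attr(out, "n_untested") <- sum(!tested)
  out
}

#' Binomial low-VAF caller
#'
#' Tests, at every site of sufficient depth, the upper tail of
#' Binomial(depth, e) at the top non-reference count; a candidate is
#' emitted when the p-value is at most `cfg$alpha`.
#'
#' @param pileup consensus pileup data frame.
#' @param model an [estimate_error_model()] fit.
#' @param cfg a [caller_config()].
#' @return data frame of candidate calls (chrom, pos, ref, alt, alt_count,
#'   depth, vaf, p_value, caller) with attribute `n_untested`.
#' @export
call_binomial <- function(pileup, model, cfg = caller_config()) {
  .call_with_tail(pileup, model, cfg,
                  function(q, n) .binom_upper(q, n, model$e), "binomial")
}

#' Beta-binomial low-VAF caller
#'
#' As [call_binomial()] but with an overdispersed
#' BetaBinomial(depth, e, rho) null, robust to site-to-site error-rate
#' variation; converges to the binomial caller as rho tends to 0.
#'
#' @inheritParams call_binomial
#' @return data frame of candidate calls (see [call_binomial()]).
#' @export
call_betabinom <- function(pileup, model, cfg = caller_config()) {
  .call_with_tail(pileup, model, cfg,
                  function(q, n) pbetabinom_upper(q, n, model$e, model$rho),
                  "betabinom")
}

#' Integrate candidate calls across callers
#'
#' @param candidates list of per-caller candidate data frames.
#' @param cfg a [caller_config()]; `cfg$rule` selects intersection (all
#'   callers), union (any caller), or at_least_k (`cfg$k` callers).
#' @return data frame of integrated calls with a comma-separated `callers`
#'   provenance column and per-caller p-values (`p_<caller>`).
#' @export
integrate_calls <- function(candidates, cfg = caller_config()) {
  n_callers <- length(candidates)
  all_rows <- do.call(rbind, lapply(candidates, function(d)
    d[, c("chrom", "pos", "ref", "alt", "alt_count", "depth", "vaf",
          "p_value", "caller")]))
  if (is.null(all_rows) || nrow(all_rows) == 0) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      alt_count = integer(0), depth = integer(0),
                      vaf = numeric(0), callers = character(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  key <- paste(all_rows$chrom, all_rows$pos, all_rows$alt)
  need <- switch(cfg$rule, intersection = n_callers, union = 1L,
                 at_least_k = cfg$k)
  out <- NULL
  for (k in unique(key)) {
    sub <- all_rows[key == k, , drop = FALSE]
    if (length(unique(sub$caller)) < need) next
    row <- sub[1, c("chrom", "pos", "ref", "alt", "alt_count", "depth",
                    "vaf")]
    row$callers <- paste(sort(unique(sub$caller)), collapse = ",")
    for (i in seq_len(nrow(sub)))
      row[[paste0("p_", sub$caller[i])]] <- sub$p_value[i]
    out <- if (is.null(out)) row else {
      miss <- setdiff(names(row), names(out)); for (m in miss) out[[m]] <- NA
      miss2 <- setdiff(names(out), names(row)); for (m in miss2) row[[m]] <- NA
      rbind(out, row[names(out)])
    }
  }
  if (is.null(out))
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      alt_count = integer(0), depth = integer(0),
                      vaf = numeric(0), callers = character(0),
                      stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify calls by the somatic allele-frequency window
#'
#' Somatic if `af_low < VAF < af_high` (open interval), germline if
#' `VAF >= af_high`, filtered if `VAF <= af_low`.
#'
#' @param calls integrated call data frame with a `vaf` column.
#' @param cfg a [caller_config()].
#' @return `calls` with an added `classification` column.
#' @examples
#' cfg <- caller_config()
#' classify_call(data.frame(vaf = c(0.07, 0.5, 0.01)), cfg)$classification
#' @export
classify_call <- function(calls, cfg = caller_config()) {
  calls$classification <- ifelse(
    calls$vaf > cfg$af_low & calls$vaf < cfg$af_high, "somatic",
    ifelse(calls$vaf >= cfg$af_high, "germline", "filtered"))
  calls
}

#' Annotate calls with genomic region and gene
#'
#' Region precedence when intervals overlap: exonic > 5'UTR/3'UTR >
#' intronic > intergenic. A gene symbol is assigned whenever the position
#' falls within the gene's span. Positions on contigs absent from the gene
#' model are intergenic, with a warning.
#'
#' @param calls call data frame with chrom and pos columns.
#' @param gene_model data frame (gene, chrom, start, end, feature) from
#'   [generate_panel()] or [read_gene_model()].
#' @return `calls` with added `region` (exonic/5UTR/3UTR/intronic/
#'   intergenic) and `gene_symbol` (NA outside genes) columns.
#' @export
annotate_region <- function(calls, gene_model) {
  prec <- c(exon = 1, `5UTR` = 2, `3UTR` = 2, intron = 3)
  region_name <- c(exon = "exonic", `5UTR` = "5UTR", `3UTR` = "3UTR",
                   intron = "intronic")
  calls$region <- "intergenic"
  calls$gene_symbol <- NA_character_
  missing_chrom <- setdiff(unique(calls$chrom), unique(gene_model$chrom))
  if (length(missing_chrom) > 0)
    .warnf("chromosome(s) absent from gene model: %s",
           paste(missing_chrom, collapse = ", "))
  for (i in seq_len(nrow(calls))) {
    hits <- gene_model[gene_model$chrom == calls$chrom[i] &
                       gene_model$start <= calls$pos[i] &
                       gene_model$end > calls$pos[i], , drop = FALSE]
    if (nrow(hits) == 0) next
    best <- hits[which.min(prec[hits$feature]), ]
    calls$region[i] <- region_name[[best$feature]]
    calls$gene_symbol[i] <- best$gene
  }
  calls
}

#' Call, integrate, classify and annotate somatic variants from a pileup
#'
#' Pipeline driver for one sample: estimates the error model (masking
#' likely variant sites whose alternate fraction exceeds
#' `candidate_altfrac`), runs the binomial and beta-binomial callers,
#' integrates them under the configured rule, classifies calls by the
#' somatic AF window, and (optionally) annotates genomic regions.
#'
#' @param pileup consensus pileup data frame.
#' @param cfg a [caller_config()].
#' @param gene_model optional gene model for [annotate_region()].
#' @param model optional pre-estimated [estimate_error_model()]; estimated
#'   from the pileup when NULL.
#' @param candidate_altfrac alternate-fraction threshold above which a site
#'   is masked out of the error-model estimate (default 0.005).
#' @return data frame of classified (and annotated) variant calls.
#' @export
call_variants <- function(pileup, cfg = caller_config(), gene_model = NULL,
                          model = NULL, candidate_altfrac = 0.005) {
  if (is.null(model)) {
    cm <- as.matrix(pileup[, DNA_BASES])
    ref_count <- cm[cbind(seq_len(nrow(cm)), match(pileup$ref, DNA_BASES))]
    altfrac <- ifelse(pileup$depth > 0,
                      (pileup$depth - ref_count) / pileup$depth, 0)
    model <- estimate_error_model(pileup, exclude = altfrac >
                                    candidate_altfrac)
  }
  cands <- list(call_binomial(pileup, model, cfg),
                call_betabinom(pileup, model, cfg))
  calls <- integrate_calls(cands, cfg)
  calls <- classify_call(calls, cfg)
  if (!is.null(gene_model)) calls <- annotate_region(calls, gene_model)
  attr(calls, "error_model") <- model
  calls
}
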