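# shared fixtures, built in code

tiny_panel <- function(genes = c("FUS", "TBK1"), seed = 7) {
  generate_panel(genes, exon_model = list(n_exons = 2L, exon_len = 80L,
                                          intron_len = 60L, utr5_len = 40L,
                                          utr3_len = 40L, flank = 50L),
                 seed = seed)
}

# a minimal consensus pileup data frame from explicit counts
make_pileup <- function(ref, A = 0, C = 0, G = 0, T = 0, chrom = "c",
                        pos = seq_along(ref) - 1L) {
  d <- data.frame(chrom = chrom, pos = pos, ref = ref, A = A, C = C,
                  G = G, T = T, stringsAsFactors = FALSE)
  d$depth <- d$A + d$C + d$G + d$T
  d
}

# a per-cell-type aggregated pileup row set for one site
make_ctp <- function(cell_types, ref, alt, alt_counts, depths,
                     n_cells = 10L, pos = 0L) {
  cm <- matrix(0L, length(cell_types), 4,
               dimnames = list(NULL, c("A", "C", "G", "T")))
  cm[, alt] <- alt_counts
  cm[, ref] <- cm[, ref] + depths - alt_counts
  data.frame(chrom = "c", pos = pos, ref = ref, cell_type = cell_types,
             as.data.frame(cm), depth = depths,
             n_cells_covered = rep(n_cells, length(cell_types)),
             stringsAsFactors = FALSE)
}

# brute-force BH step-up, written straight from the definition
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    # q_i = min over j >= rank(i) of n * p_(j) / j, capped at 1
    r <- match(i, o)
    q[i] <- min(1, min(n * p[o][r:n] / (r:n)))
  }
  q
}
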