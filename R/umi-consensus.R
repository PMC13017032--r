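#' Group UMI-tagged reads into families
#'
#' Partitions reads sharing a mapping start coordinate into UMI families by
#' greedy directional merging: UMIs are visited in order of decreasing read
#' count (ties broken lexicographically) and each UMI joins the first
#' already-accepted family whose representative UMI lies within
#' `max_umi_edit_distance` (Hamming), so larger families absorb smaller
#' ones. Reads with malformed (non-ACGT) UMIs are rejected and counted.
#'
#' @param reads data frame with columns read_id, umi, chrom, start, bases
#'   (as produced by [simulate_tagged_reads()]).
#' @param max_umi_edit_distance maximum Hamming distance for merging
#'   (default 1).
#' @return the accepted reads with an added `family_id` column; attributes
#'   `families` (family_id, chrom, start, umi of the representative,
#'   family_size) and `n_rejected`.
#' @examples
#' reads <- data.frame(read_id = paste0("r", 1:4),
#'                     umi = c("AAAA", "AAAA", "AAAA", "AAAT"),
#'                     chrom = "c", start = 0,
#'                     bases = "ACGT", stringsAsFactors = FALSE)
#' fams <- attr(group_by_umi(reads, 1), "families")
#' fams$family_size
#' @export
group_by_umi <- function(reads, max_umi_edit_distance = 1L) {
  ok <- grepl("^[ACGT]+$", reads$umi)
  n_rejected <- sum(!ok)
  reads <- reads[ok, , drop = FALSE]
  reads$family_id <- NA_character_
  fam_rows <- list()
  for (key in unique(paste(reads$chrom, reads$start))) {
    idx <- which(paste(reads$chrom, reads$start) == key)
    tab <- table(reads$umi[idx])
    # descending count, then lexicographic: deterministic greedy order
    umis <- names(tab)[order(-as.integer(tab), names(tab))]
    reps <- character(0)           # representative UMI per family
    assign_to <- character(length(umis))
    for (j in seq_along(umis)) {
      hit <- NA_integer_
      if (max_umi_edit_distance > 0 && length(reps) > 0) {
        d <- vapply(reps, .hamming, numeric(1), b = umis[j])
        if (any(d <= max_umi_edit_distance)) hit <-
            which(d <= max_umi_edit_distance)[1]
      } else if (length(reps) > 0 && umis[j] %in% reps) {
        hit <- match(umis[j], reps)
      }
      if (is.na(hit)) {
        reps <- c(reps, umis[j])
        hit <- length(reps)
      }
      assign_to[j] <- reps[hit]
    }
    names(assign_to) <- umis
    fid <- paste0(reads$chrom[idx][1], ":", reads$start[idx][1], ":",
                  assign_to[reads$umi[idx]])
    reads$family_id[idx] <- fid
    for (r in unique(assign_to)) {
      fam_rows[[paste0(key, ":", r)]] <- data.frame(
        family_id = paste0(reads$chrom[idx][1], ":", reads$start[idx][1],
                           ":", r),
        chrom = reads$chrom[idx][1], start = reads$start[idx][1], umi = r,
        family_size = sum(fid == paste0(reads$chrom[idx][1], ":",
                                        reads$start[idx][1], ":", r)),
        stringsAsFactors = FALSE)
    }
  }
  families <- do.call(rbind, unname(fam_rows))
  if (is.null(families))
    families <- data.frame(family_id = character(0), chrom = character(0),
                           start = integer(0), umi = character(0),
                           family_size = integer(0), stringsAsFactors = FALSE)
  attr(reads, "families") <- families
  attr(reads, "n_rejected") <- n_rejected
  reads
}

#' Call a consensus sequence for one UMI family
#'
#' At each read offset the modal base is emitted if its fraction among the
#' family's reads is at least `min_agreement`; otherwise (including exact
#' ties) the offset is masked with `N`. Families smaller than
#' `min_family_size` are dropped.
#'
#' @param bases character vector of equal-length read sequences from one
#'   family.
#' @param min_family_size minimum reads per family (default 3).
#' @param min_agreement required modal-base fraction, must exceed 0.5
#'   (default 0.75).
#' @return the consensus string (with `N` at masked offsets), or `NULL` if
#'   the family is dropped.
#' @examples
#' consensus_call(c("AAC", "AAC", "AAT"), min_family_size = 3,
#'                min_agreement = 0.6)
#' @export
consensus_call <- function(bases, min_family_size = 3L,
                           min_agreement = 0.75) {
  if (min_agreement <= 0.5) .stopf("min_agreement must exceed 0.5")
  if (length(bases) < min_family_size) return(NULL)
  m <- do.call(rbind, strsplit(bases, "", fixed = TRUE))
  cons <- apply(m, 2, function(col) {
    tab <- table(col)
    top <- max(tab)
    if (top / length(col) < min_agreement) return("N")
    winners <- names(tab)[tab == top]
    if (length(winners) > 1) return("N")
    winners
  })
  paste(cons, collapse = "")
}

#' Collapse grouped reads into consensus reads
#'
#' Applies [consensus_call()] to every UMI family of a grouped read set.
#'
#' @param grouped output of [group_by_umi()].
#' @inheritParams consensus_call
#' @return data frame of consensus reads: family_id, chrom, start, bases,
#'   family_size (dropped families omitted).
#' @export
collapse_families <- function(grouped, min_family_size = 3L,
                              min_agreement = 0.75) {
  fams <- attr(grouped, "families")
  out <- lapply(seq_len(nrow(fams)), function(i) {
    sel <- grouped$family_id == fams$family_id[i]
    cons <- consensus_call(grouped$bases[sel], min_family_size,
                           min_agreement)
    if (is.null(cons)) return(NULL)
    data.frame(family_id = fams$family_id[i], chrom = fams$chrom[i],
               start = fams$start[i], bases = cons,
               family_size = fams$family_size[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(family_id = character(0), chrom = character(0),
                      start = integer(0), bases = character(0),
                      family_size = integer(0), stringsAsFactors = FALSE)
  out
}

#' Build a consensus pileup from consensus reads
#'
#' Tallies consensus base calls per reference position. Masked (`N`)
#' offsets contribute to `n_masked` rather than depth, so at every site
#' depth + n_masked equals the number of consensus families covering it.
#'
#' @param consensus data frame of consensus reads (chrom, start, bases),
#'   e.g. from [collapse_families()].
#' @param reference named character vector of contig sequences.
#' @param targets optional BED-like data frame restricting the pileup;
#'   defaults to the full span of each covered contig.
#' @return data frame with chrom, pos (0-based), ref, A, C, G, T, depth,
#'   n_masked; zero-coverage target sites are retained with zero counts.
#' @export
build_pileup <- function(consensus, reference, targets = NULL) {
  if (is.null(targets)) {
    targets <- data.frame(chrom = names(reference), start = 0L,
                          end = nchar(reference), stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, lapply(seq_len(nrow(targets)), function(i) {
    t <- targets[i, ]
    if (!t$chrom %in% names(reference))
      .stopf("target chrom '%s' absent from reference", t$chrom)
    if (t$end > nchar(reference[[t$chrom]]))
      .stopf("target [%d,%d) outside reference '%s'", t$start, t$end, t$chrom)
    data.frame(chrom = t$chrom, pos = seq.int(t$start, t$end - 1L),
               ref = strsplit(substr(reference[[t$chrom]], t$start + 1L,
                                     t$end), "")[[1]],
               stringsAsFactors = FALSE)
  }))
  counts <- matrix(0L, nrow(sites), 4, dimnames = list(NULL, DNA_BASES))
  n_masked <- integer(nrow(sites))
  key <- paste(sites$chrom, sites$pos)
  lookup <- setNames(seq_len(nrow(sites)), key)
  for (i in seq_len(nrow(consensus))) {
    b <- strsplit(consensus$bases[i], "", fixed = TRUE)[[1]]
    pos <- consensus$start[i] + seq_along(b) - 1L
    rows <- lookup[paste(consensus$chrom[i], pos)]
    keep <- !is.na(rows)
    for (k in which(keep)) {
      if (b[k] == "N") n_masked[rows[k]] <- n_masked[rows[k]] + 1L
      else counts[rows[k], b[k]] <- counts[rows[k], b[k]] + 1L
    }
    out_of_ref <- pos >= nchar(reference[[consensus$chrom[i]]])
    if (any(out_of_ref))
      .stopf("consensus read extends beyond reference '%s'",
             consensus$chrom[i])
  }
  cbind(sites, as.data.frame(counts), depth = rowSums(counts),
        n_masked = n_masked)
}

#' UMI consensus error correction in one step
#'
#' Convenience wrapper chaining [group_by_umi()], [collapse_families()] and
#' [build_pileup()].
#'
#' @inheritParams group_by_umi
#' @inheritParams build_pileup
#' @inheritParams consensus_call
#' @return consensus pileup data frame (see [build_pileup()]).
#' @export
umi_consensus_pileup <- function(reads, reference, targets = NULL,
                                 max_umi_edit_distance = 1L,
                                 min_family_size = 3L, min_agreement = 0.75) {
  grouped <- group_by_umi(reads, max_umi_edit_distance)
  cons <- collapse_families(grouped, min_family_size, min_agreement)
  build_pileup(cons, reference, targets)
}
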