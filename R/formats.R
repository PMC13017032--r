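# Plain-text readers and writers. All genomic coordinates are 0-based
# half-open internally; conversion to 1-based happens only at the VCF
# boundary.

#' Read / write FASTA
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param sequences named character vector of sequences.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read / write 6-column BED
#'
#' BED is natively 0-based half-open, matching the internal convention,
#' so coordinates pass through unchanged.
#'
#' @param path file path.
#' @return data frame chrom, start, end, name, score, strand.
#' @export
read_bed <- function(path) {
  d <- read.table(path, sep = "\t", header = FALSE,
                  stringsAsFactors = FALSE)
  if (ncol(d) < 3) .stopf("malformed BED: fewer than 3 columns")
  names(d)[1:min(6, ncol(d))] <- c("chrom", "start", "end", "name",
                                   "score", "strand")[1:min(6, ncol(d))]
  d
}

#' @rdname read_bed
#' @param bed BED-like data frame.
#' @export
write_bed <- function(bed, path) {
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read / write the gene-model TSV
#'
#' Tab-separated with header: gene, chrom, start, end, feature, strand;
#' 0-based half-open.
#'
#' @param path file path.
#' @return gene-model data frame.
#' @export
read_gene_model <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "start", "end", "feature", "strand")
  if (!all(need %in% names(d)))
    .stopf("malformed gene model: need columns %s", paste(need,
                                                          collapse = ", "))
  d
}

#' @rdname read_gene_model
#' @param gene_model gene-model data frame.
#' @export
write_gene_model <- function(gene_model, path) {
  write.table(gene_model, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write variant calls or planted truth as VCF
#'
#' Minimal VCFv4.2 writer. Internal 0-based positions are emitted as
#' 1-based POS. Truth tables carry INFO keys TRUE_VAF and ORIGIN; call
#' tables carry DP, AD, VAF, CALLERS, CLASS, REGION, GENE as available.
#'
#' @param variants data frame with chrom, pos, ref, alt plus optional
#'   columns (true_vaf, origin, depth, alt_count, vaf, callers,
#'   classification, region, gene_symbol).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_vcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=TRUE_VAF,Number=1,Type=Float,Description=\"Planted allele fraction\">",
               "##INFO=<ID=ORIGIN,Number=1,Type=String,Description=\"somatic or germline\">",
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Consensus depth\">",
               "##INFO=<ID=AD,Number=1,Type=Integer,Description=\"Alternate count\">",
               "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
               "##INFO=<ID=CALLERS,Number=1,Type=String,Description=\"Supporting callers\">",
               "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"somatic, germline or filtered\">",
               "##INFO=<ID=REGION,Number=1,Type=String,Description=\"Genomic region\">",
               "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  info_of <- function(i) {
    kv <- c()
    add <- function(key, val) {
      if (!is.null(val) && length(val) == 1 && !is.na(val))
        kv <<- c(kv, paste0(key, "=", val))
    }
    add("TRUE_VAF", variants$true_vaf[i])
    add("ORIGIN", variants$origin[i])
    add("DP", variants$depth[i])
    add("AD", variants$alt_count[i])
    if (!is.null(variants$vaf))
      add("VAF", formatC(variants$vaf[i], format = "g", digits = 6))
    add("CALLERS", variants$callers[i])
    add("CLASS", variants$classification[i])
    add("REGION", variants$region[i])
    add("GENE", variants$gene_symbol[i])
    if (length(kv) == 0) "." else paste(kv, collapse = ";")
  }
  for (i in seq_len(nrow(variants))) {
    writeLines(paste(variants$chrom[i], variants$pos[i] + 1L, ".",
                     variants$ref[i], variants$alt[i], ".", "PASS",
                     info_of(i), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF written by [write_vcf()]
#'
#' POS is converted back to the internal 0-based convention; INFO keys
#' become columns.
#'
#' @param path VCF path.
#' @return data frame with chrom, pos (0-based), ref, alt and one column
#'   per INFO key seen.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 8)
  if (length(bad) > 0)
    .stopf("malformed VCF line %d: fewer than 8 fields",
           which(!startsWith(lines, "#"))[bad[1]])
  out <- data.frame(chrom = vapply(parts, `[`, "", 1),
                    pos = as.integer(vapply(parts, `[`, "", 2)) - 1L,
                    ref = vapply(parts, `[`, "", 4),
                    alt = vapply(parts, `[`, "", 5),
                    stringsAsFactors = FALSE)
  infos <- vapply(parts, `[`, "", 8)
  keys <- unique(unlist(lapply(strsplit(infos, ";", fixed = TRUE),
                               function(kv) sub("=.*", "", kv))))
  keys <- setdiff(keys, ".")
  for (k in keys) {
    v <- vapply(strsplit(infos, ";", fixed = TRUE), function(kv) {
      hit <- grep(paste0("^", k, "="), kv, value = TRUE)
      if (length(hit) == 0) NA_character_ else sub("^[^=]*=", "", hit[1])
    }, character(1))
    col <- switch(k, TRUE_VAF = , VAF = as.numeric(v),
                  DP = , AD = as.integer(v), v)
    nm <- switch(k, TRUE_VAF = "true_vaf", ORIGIN = "origin", DP = "depth",
                 AD = "alt_count", VAF = "vaf", CALLERS = "callers",
                 CLASS = "classification", REGION = "region",
                 GENE = "gene_symbol", tolower(k))
    out[[nm]] <- col
  }
  out
}

#' Read / write sample metadata TSV
#'
#' Columns: sample_id, group, sex, age, origin, total_coverage.
#'
#' @param path file path.
#' @return metadata data frame.
#' @export
read_metadata <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "sex", "age", "origin", "total_coverage")
  if (!all(need %in% names(d)))
    .stopf("malformed metadata: need columns %s",
           paste(need, collapse = ", "))
  d
}

#' @rdname read_metadata
#' @param meta metadata data frame.
#' @export
write_metadata <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write single-cell pileup TSV
#'
#' Long format: cell_barcode, cell_type, chrom, pos (0-based), ref, A, C,
#' G, T.
#'
#' @param path file path.
#' @return pileup data frame.
#' @export
read_sc_pileup <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("cell_barcode", "chrom", "pos", "ref", "A", "C", "G", "T")
  if (!all(need %in% names(d)))
    .stopf("malformed sc pileup: need columns %s",
           paste(need, collapse = ", "))
  d
}

#' @rdname read_sc_pileup
#' @param pileup single-cell pileup data frame.
#' @export
write_sc_pileup <- function(pileup, path) {
  write.table(pileup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read GMT gene-set files
#'
#' @param path GMT path (set name, description, then genes, tab-separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) .stopf("malformed GMT line: '%s'", l)
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' @rdname read_gmt
#' @param gene_sets named list of character vectors.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm)
    paste(c(nm, "na", gene_sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a COSMIC-layout signature catalog TSV
#'
#' First column `Type` holds channel names like `A[C>A]A`; remaining
#' columns are signatures. Rows are reordered to [sbs_channels()] order
#' and each signature is checked to sum to 1.
#'
#' @param path TSV path.
#' @return signatures x 96 matrix.
#' @export
read_signature_catalog <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                  stringsAsFactors = FALSE)
  chan <- sbs_channels()
  if (!all(chan %in% d[[1]])) .stopf("catalog is missing channels")
  m <- t(as.matrix(d[match(chan, d[[1]]), -1, drop = FALSE]))
  colnames(m) <- chan
  if (any(abs(rowSums(m) - 1) > 1e-6))
    .stopf("catalog signatures must each sum to 1")
  m
}

#' @rdname read_signature_catalog
#' @param catalog signatures x 96 matrix.
#' @export
write_signature_catalog <- function(catalog, path) {
  d <- data.frame(Type = colnames(catalog), t(catalog),
                  check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
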