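#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom rpois runif rnbinom rnorm coef vcov pnorm pbinom
#'   dbinom p.adjust t.test optimize model.matrix model.frame model.response
#'   terms quantile median sd setNames rmultinom simulate qnorm delete.response
#'   na.fail
#' @importFrom utils read.table write.table head modifyList
NULL

DNA_BASES <- c("A", "C", "G", "T")

# complement lookup usable on character vectors of single bases
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @examples
#' revcomp("ACGT")
#' @export
revcomp <- function(x) {
  vapply(strsplit(toupper(x), "", fixed = TRUE), function(b) {
    paste(rev(unname(.COMPLEMENT[b])), collapse = "")
  }, character(1))
}

# Hamming distance between two equal-length strings
.hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

# random DNA string(s); relies on the caller having set the RNG state
.random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

# Stable 32-bit child seed derived from a global seed and a stage label, so
# each pipeline stage is reproducible independently of execution order.
derive_seed <- function(seed, label) {
  h <- 0
  for (cp in utf8ToInt(label)) h <- (h * 131 + cp) %% 2147480009
  as.integer((as.numeric(seed) * 7919 + h) %% 2147480009)
}

# run expr with a locally-scoped RNG seeded at `seed`, restoring global state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# rbind data frames, filling columns absent from some frames with NA
.rbind_fill <- function(dfs) {
  dfs <- dfs[!vapply(dfs, is.null, logical(1))]
  if (length(dfs) == 0) return(NULL)
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, c(lapply(dfs, function(d) {
    for (m in setdiff(cols, names(d))) d[[m]] <- rep(NA, nrow(d))
    d[cols]
  }), list(make.row.names = FALSE)))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
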