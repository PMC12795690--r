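#' Sequence record
#'
#' A protein sequence over the 20 canonical amino-acid letters plus `X`.
#' Non-standard residues are mapped to `X`; lower-case input is
#' canonicalised to upper case.
#'
#' @param id Record identifier.
#' @param sequence Amino-acid string, length >= 1.
#' @return Object of class `sequence_record`.
#' @export
sequence_record <- function(id, sequence) {
  sequence <- toupper(gsub("\\s", "", as.character(sequence)))
  if (nchar(sequence) < 1) stop("empty sequence")
  letters20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  chars <- strsplit(sequence, "")[[1]]
  chars[!chars %in% letters20] <- "X"
  structure(list(id = as.character(id),
                 sequence = paste(chars, collapse = "")),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<sequence_record> %s (%d aa)\n", x$id, nchar(x$sequence)))
  invisible(x)
}

# fixed per-letter base vectors of the mock provider; internal seed is a
# constant so the mock is reproducible across sessions and independent of
# the user's RNG
mock_letter_table <- local({
  tab <- NULL
  function(dim = 1024L) {
    if (is.null(tab) || ncol(tab) != dim) {
      letters21 <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
      tab <<- with_seed(77003917L, {
        m <- matrix(rnorm(length(letters21) * dim), length(letters21), dim)
        rownames(m) <- letters21
        m
      })
    }
    tab
  }
})

mock_positional <- function(L, dim) {
  pos <- seq_len(L)
  k <- seq_len(dim)
  freq <- 1 / (10000^((k - 1) / dim))
  phase <- outer(pos, freq)
  0.05 * ifelse(outer(rep(TRUE, L), k %% 2 == 0), cos(phase), sin(phase))
}

#' Embed a protein sequence
#'
#' Providers: `"mock"` (default) computes a deterministic hash-style
#' embedding per (residue letter, position) with no external model — each
#' per-residue row is a fixed letter vector plus a small sinusoidal
#' positional term — so identical sequences always embed identically.
#' `"prostt5"` is an adapter slot for a pretrained protein language model;
#' it requires external weights and an inference runtime that this package
#' does not ship, and raises a provider-unavailable error pointing at the
#' mock otherwise.
#'
#' @param record A [sequence_record()].
#' @param provider `"mock"` or `"prostt5"`.
#' @param dim Embedding width (1024 to match the language-model interface).
#' @return Object of class `embedding_matrix`: list with `per_residue`
#'   (L x dim) and `pooled` (length-dim column-wise mean).
#' @export
embed <- function(record, provider = c("mock", "prostt5"), dim = 1024L) {
  provider <- match.arg(provider)
  if (provider == "prostt5")
    stop_ptppi("ptppi_provider_unavailable",
               paste("the 'prostt5' provider needs external pretrained",
                     "weights and an inference runtime; use provider =",
                     "'mock' for a deterministic stand-in"))
  chars <- strsplit(record$sequence, "")[[1]]
  L <- length(chars)
  tab <- mock_letter_table(dim)
  per_res <- tab[chars, , drop = FALSE] + mock_positional(L, dim)
  rownames(per_res) <- NULL
  pooled <- colMeans(per_res)
  structure(list(per_residue = per_res, pooled = pooled, id = record$id),
            class = "embedding_matrix")
}

#' Embed a list of sequence records in batches
#'
#' Order-preserving; results are independent of `batch_size`.
#'
#' @param records List of [sequence_record()]s.
#' @param provider Embedding provider (see [embed()]).
#' @param batch_size Records per batch (>= 1).
#' @param cache_dir Optional directory caching pooled embeddings on disk,
#'   keyed by provider and sequence hash.
#' @param dim Embedding width.
#' @return List of `embedding_matrix` objects, same order as `records`.
#' @export
batch_embed <- function(records, provider = "mock", batch_size = 8L,
                        cache_dir = NULL, dim = 1024L) {
  stopifnot(batch_size >= 1)
  out <- vector("list", length(records))
  idx <- seq_along(records)
  for (start in seq(1, length.out = ceiling(length(records) / batch_size),
                    by = batch_size)) {
    batch <- idx[start:min(start + batch_size - 1, length(records))]
    for (i in batch) {
      rec <- records[[i]]
      key <- NULL
      if (!is.null(cache_dir)) {
        dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
        key <- file.path(cache_dir, paste0(provider, "_",
                                           seq_hash(rec$sequence), ".rds"))
        if (file.exists(key)) { out[[i]] <- readRDS(key); next }
      }
      out[[i]] <- embed(rec, provider, dim = dim)
      if (!is.null(key)) saveRDS(out[[i]], key)
    }
  }
  out
}

seq_hash <- function(s) {
  # small deterministic string hash (FNV-style), adequate as a cache key
  v <- utf8ToInt(s)
  h <- 2166136261
  for (x in v) h <- (xor(h, x) * 16777619) %% 2^32
  sprintf("%08x_%d", h, nchar(s))
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return List of [sequence_record()]s.
#' @export
read_fasta_records <- function(path) {
  fa <- bio3d::read.fasta(path)
  lapply(seq_len(nrow(fa$ali)), function(i) {
    s <- paste(fa$ali[i, fa$ali[i, ] != "-"], collapse = "")
    sequence_record(rownames(fa$ali)[i], s)
  })
}
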