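# Independent oracles used across the suite. Each deliberately re-derives the
# quantity by the most direct route available (explicit loops, closed forms,
# exhaustive DP) rather than calling the package's own code paths.

# toy gene-count table builder
toy_counts <- function(mat, species = colnames(mat), ids = rownames(mat)) {
  if (is.null(ids)) ids <- paste0("OG", seq_len(nrow(mat)))
  if (is.null(species)) species <- paste0("sp", seq_len(ncol(mat)))
  dplyr::bind_cols(
    tibble::tibble(orthogroup = ids),
    tibble::as_tibble(matrix(as.integer(mat), nrow(mat), dimnames = list(NULL, species)))
  )
}

# brute-force evaluation of the conservation rule, row by row
oracle_conserved <- function(counts, reference, panel, min_present) {
  keep <- vapply(seq_len(nrow(counts)), function(i) {
    counts[[reference]][i] >= 1 &&
      sum(vapply(panel, function(p) counts[[p]][i] >= 1, logical(1))) >= min_present
  }, logical(1))
  counts$orthogroup[keep]
}

# brute-force per-gene, per-tissue PET rule
oracle_pets <- function(expr, fold) {
  tissues <- names(expr)[-1]
  out <- list()
  for (i in seq_len(nrow(expr))) {
    v <- unlist(expr[i, tissues], use.names = FALSE)
    if (sum(v) == 0) next
    for (j in seq_along(tissues)) {
      if (v[j] >= fold * mean(v[-j])) {
        out[[length(out) + 1]] <- tibble::tibble(gene = expr$gene[i], tissue = tissues[j])
      }
    }
  }
  dplyr::bind_rows(out)
}

# affine-gap global alignment score by explicit three-state dynamic
# programming (gap of length L costs |open| + L * |extend|)
oracle_align_score <- function(a, b, match = 2, mismatch = -3,
                               gap_open = -5, gap_extend = -2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  go <- abs(gap_open); ge <- abs(gap_extend)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # ends in aligned pair
  X <- matrix(NEG, n + 1, m + 1)  # ends in gap consuming A (gap in b)
  Y <- matrix(NEG, n + 1, m + 1)  # ends in gap consuming B (gap in a)
  M[1, 1] <- 0
  for (i in 0:n) {
    for (j in 0:m) {
      if (i > 0 && j > 0) {
        s <- if (A[i] == B[j]) match else mismatch
        M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      }
      if (i > 0) {
        X[i + 1, j + 1] <- max(M[i, j + 1] - go - ge, X[i, j + 1] - ge,
                               Y[i, j + 1] - go - ge)
      }
      if (j > 0) {
        Y[i + 1, j + 1] <- max(M[i + 1, j] - go - ge, Y[i + 1, j] - ge,
                               X[i + 1, j] - go - ge)
      }
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# random intact ORF of the given codon length (including start and stop)
random_orf <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"), c("A","C","G","T")),
                  1, paste, collapse = "")
  sense <- setdiff(codons, stops)
  paste0("ATG", paste(sample(sense, n_codons - 2, replace = TRUE), collapse = ""),
         sample(stops, 1))
}

# classify each scanned pair by its dominant lesion kind
predicted_kind <- function(pairs_tbl) {
  ifelse(pairs_tbl$n_frameshift > 0, "frameshift",
         ifelse(pairs_tbl$n_premature_stop > 0, "premature_stop", "intact"))
}
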