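STOP_CODONS <- c("TAA", "TAG", "TGA")

validate_dna <- function(seq, what = "sequence") {
  seq <- toupper(as.character(seq))
  if (length(seq) != 1 || is.na(seq) || nchar(seq) == 0) {
    abort(sprintf("%s must be a single non-empty string", what))
  }
  if (grepl("[^ACGTN]", seq)) {
    abort(sprintf("%s contains characters outside the A/C/G/T/N alphabet", what))
  }
  seq
}

codons_of <- function(seq) {
  n <- nchar(seq) %/% 3
  if (n == 0) return(character(0))
  substring(seq, 3 * seq_len(n) - 2, 3 * seq_len(n))
}

validate_reference_cds <- function(ref) {
  ref <- validate_dna(ref, "reference CDS")
  if (nchar(ref) %% 3 != 0) abort("reference CDS length must be divisible by 3")
  cod <- codons_of(ref)
  internal <- cod[-length(cod)]
  if (any(internal %in% STOP_CODONS)) {
    abort("reference CDS contains an internal in-frame stop codon; it is not an intact ORF")
  }
  ref
}

#' Global alignment of a candidate sequence against a reference CDS
#'
#' Needleman-Wunsch global alignment with affine gap penalties, via
#' [Biostrings::pairwiseAlignment()]. Scores follow the usual convention:
#' positive match reward, negative mismatch and gap penalties; a gap of
#' length L costs `|gap_open| + L * |gap_extend|`.
#'
#' @param reference Reference CDS (intact ORF, sense strand).
#' @param candidate Candidate sequence (sense strand).
#' @param match,mismatch,gap_open,gap_extend Alignment scores (defaults
#'   +2 / -3 / -5 / -2).
#' @return A `cds_alignment` object: list with `ref_aligned` and
#'   `cand_aligned` (equal-length gapped strings), `score`, and the scoring
#'   parameters.
#' @export
align_cds_pair <- function(reference, candidate,
                           match = 2, mismatch = -3,
                           gap_open = -5, gap_extend = -2) {
  reference <- validate_dna(reference, "reference")
  candidate <- validate_dna(candidate, "candidate")
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE, type = "DNA"
  )
  aln <- Biostrings::pairwiseAlignment(
    pattern = candidate, subject = reference,
    type = "global",
    substitutionMatrix = sub_mat,
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend)
  )
  structure(
    list(
      ref_aligned = as.character(Biostrings::alignedSubject(aln)),
      cand_aligned = as.character(Biostrings::alignedPattern(aln)),
      score = Biostrings::score(aln),
      params = c(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend)
    ),
    class = "cds_alignment"
  )
}

#' Detect frameshift and premature-stop lesions in an aligned candidate
#'
#' Given a global alignment of a candidate sequence against an intact
#' reference CDS, reports two kinds of pseudogenising lesion:
#'
#' * **frameshift** — a maximal run of alignment gaps (an insertion or a
#'   deletion) whose length is not divisible by 3, located at the reference
#'   coordinate of the first affected base;
#' * **premature stop** — a stop codon (TAA/TAG/TGA) in the candidate's
#'   reading frame (its codons read consecutively from the start, so the
#'   frame tracks the cumulative indel offset), whose reference position
#'   precedes the reference's final codon.
#'
#' Coordinates are 1-based on the reference CDS. A frame-preserving indel
#' (length divisible by 3) is not a lesion.
#'
#' @param alignment A `cds_alignment` from [align_cds_pair()].
#' @param pair_id Identifier copied into the output.
#' @return A tibble ordered by `ref_position` with columns `pair_id`, `kind`
#'   (`"frameshift"` or `"premature_stop"`), `ref_position` and `detail`
#'   (indel length, or the stop triplet).
#' @export
detect_lesions <- function(alignment, pair_id = "pair") {
  stopifnot(inherits(alignment, "cds_alignment"))
  ref <- strsplit(alignment$ref_aligned, "", fixed = TRUE)[[1]]
  cand <- strsplit(alignment$cand_aligned, "", fixed = TRUE)[[1]]
  stopifnot(length(ref) == length(cand))
  ref_len <- sum(ref != "-")
  ref_pos <- cumsum(ref != "-") # reference coordinate consumed up to each column

  # indel events: maximal runs of gap columns in one of the two rows
  state <- ifelse(ref == "-", "ins", ifelse(cand == "-", "del", "aln"))
  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  empty <- tibble(kind = character(), ref_position = integer(), detail = character())
  lesions <- purrr::map_dfr(which(runs$values != "aln"), function(i) {
    len <- runs$lengths[i]
    pos <- if (runs$values[i] == "del") {
      ref_pos[starts[i]] # first deleted reference base
    } else {
      min(ref_pos[starts[i]] + 1L, ref_len) # insertion sits before this base
    }
    tibble(
      kind = if (len %% 3 != 0) "frameshift" else NA_character_,
      ref_position = as.integer(pos),
      detail = as.character(len)
    )
  })
  lesions <- dplyr::bind_rows(empty, lesions)
  lesions <- lesions[!is.na(lesions$kind), , drop = FALSE]

  # premature stops: candidate codons read consecutively from its start
  cand_idx <- which(cand != "-")
  cand_seq <- cand[cand_idx]
  # reference coordinate of each candidate base (inserted bases borrow the
  # coordinate of the next reference base)
  cand_ref <- ifelse(ref[cand_idx] != "-", ref_pos[cand_idx],
                     pmin(ref_pos[cand_idx] + 1L, ref_len))
  n_codon <- length(cand_seq) %/% 3
  if (n_codon > 0) {
    first <- 3 * seq_len(n_codon) - 2
    triplet <- paste0(cand_seq[first], cand_seq[first + 1], cand_seq[first + 2])
    hit <- which(triplet %in% STOP_CODONS & cand_ref[first] < ref_len - 2L)
    if (length(hit) > 0) {
      lesions <- dplyr::bind_rows(lesions, tibble(
        kind = "premature_stop",
        ref_position = as.integer(cand_ref[first[hit]]),
        detail = triplet[hit]
      ))
    }
  }
  lesions |>
    dplyr::mutate(pair_id = pair_id, .before = 1) |>
    dplyr::arrange(.data$ref_position)
}

#' Read paired reference/candidate CDS FASTA files
#'
#' Records are paired by shared id (the first whitespace-delimited token of
#' each FASTA header).
#'
#' @param ref_fasta,cand_fasta Paths to FASTA files.
#' @return Tibble with columns `pair_id`, `reference`, `candidate`.
#' @export
read_cds_pairs <- function(ref_fasta, cand_fasta) {
  refs <- Biostrings::readDNAStringSet(ref_fasta)
  cands <- Biostrings::readDNAStringSet(cand_fasta)
  names(refs) <- sub("\\s.*$", "", names(refs))
  names(cands) <- sub("\\s.*$", "", names(cands))
  shared <- intersect(names(refs), names(cands))
  if (length(shared) == 0) abort("no shared record ids between the two FASTA files")
  tibble(
    pair_id = shared,
    reference = as.character(refs[shared]),
    candidate = as.character(cands[shared])
  )
}

#' Scan candidate sequences for pseudogenising lesions
#'
#' Aligns each candidate against its reference CDS and classifies it as a
#' pseudogene when it carries at least one frameshift or premature stop
#' codon.
#'
#' @param pairs Tibble with columns `pair_id`, `reference`, `candidate`
#'   (see [read_cds_pairs()] or [simulate_cds_pairs()]).
#' @inheritParams align_cds_pair
#' @return A `lesion_report` object: list with `lesions` (tibble of all
#'   lesions, see [detect_lesions()]), `pairs` (tibble of `pair_id`,
#'   `n_frameshift`, `n_premature_stop`, `is_pseudogene`) and the scoring
#'   `params`. [tidy()] returns the lesion tibble, [glance()] a one-row
#'   summary.
#' @export
scan_pseudogenes <- function(pairs, match = 2, mismatch = -3,
                             gap_open = -5, gap_extend = -2) {
  stopifnot(is.data.frame(pairs),
            all(c("pair_id", "reference", "candidate") %in% names(pairs)))
  if (anyDuplicated(pairs$pair_id)) abort("pair_id values must be unique")
  purrr::walk(pairs$reference, validate_reference_cds)
  lesions <- purrr::pmap_dfr(
    pairs[c("pair_id", "reference", "candidate")],
    function(pair_id, reference, candidate) {
      aln <- align_cds_pair(reference, candidate,
                            match = match, mismatch = mismatch,
                            gap_open = gap_open, gap_extend = gap_extend)
      detect_lesions(aln, pair_id = pair_id)
    }
  )
  per_pair <- tibble(pair_id = pairs$pair_id) |>
    dplyr::left_join(
      lesions |>
        dplyr::count(.data$pair_id, .data$kind) |>
        tidyr::pivot_wider(names_from = "kind", values_from = "n", values_fill = 0L),
      by = "pair_id"
    )
  for (col in c("frameshift", "premature_stop")) {
    if (!col %in% names(per_pair)) per_pair[[col]] <- 0L
    per_pair[[col]][is.na(per_pair[[col]])] <- 0L
  }
  per_pair <- per_pair |>
    dplyr::transmute(
      pair_id = .data$pair_id,
      n_frameshift = as.integer(.data$frameshift),
      n_premature_stop = as.integer(.data$premature_stop),
      is_pseudogene = .data$n_frameshift + .data$n_premature_stop > 0
    )
  structure(
    list(
      lesions = lesions,
      pairs = per_pair,
      params = c(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend)
    ),
    class = "lesion_report"
  )
}

#' @export
print.lesion_report <- function(x, ...) {
  cat(sprintf(
    "Pseudogene scan of %d pairs: %d pseudogenes (%d frameshift lesions, %d premature stops)\n",
    nrow(x$pairs), sum(x$pairs$is_pseudogene),
    sum(x$pairs$n_frameshift), sum(x$pairs$n_premature_stop)
  ))
  invisible(x)
}

#' @rdname scan_pseudogenes
#' @param x A `lesion_report`.
#' @param ... Unused.
#' @export
tidy.lesion_report <- function(x, ...) x$lesions

#' @rdname scan_pseudogenes
#' @export
glance.lesion_report <- function(x, ...) {
  tibble(
    n_pairs = nrow(x$pairs),
    n_pseudogenes = sum(x$pairs$is_pseudogene),
    n_frameshift = sum(x$pairs$n_frameshift),
    n_premature_stop = sum(x$pairs$n_premature_stop)
  )
}
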