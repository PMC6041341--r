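run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

write_kv <- function(x, path) {
  writeLines(sprintf("%s\t%s", names(x), vapply(x, paste, "", collapse = ",")), path)
}

#' Run the full simulated analysis pipeline
#'
#' Generates every synthetic input with planted ground truth (gene-count
#' matrix, expression matrix, CDS pairs, k-mer histogram), runs each analysis
#' stage — conserved-orthogroup identification, per-target loss calling and
#' partitioning, F-index summaries, PET/PEG classification, the lost-PET
#' tabulation against a proxy expression atlas, the pseudogene scan, and the
#' k-mer genome survey — and writes every result as TSV into `out_dir`
#' together with a `manifest.tsv` recording package version, seed and
#' parameters, and a `summary.tsv` of headline numbers. A given seed and
#' configuration reproduce the run exactly.
#'
#' The global seed is expanded into fixed per-generator substreams
#' (`seed + 1` for the count matrix, `+2` expression, `+3` CDS pairs,
#' `+4` k-mer histogram), so individual stages can be regenerated
#' independently.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for all randomness.
#' @param n_orthogroups,n_genes,n_pairs Problem sizes handed to the
#'   generators.
#' @param min_present Conservation threshold (default 5 of a 6-species
#'   panel).
#' @param fold_threshold PET/PEG fold threshold (default 2).
#' @param repeat_multiplier Repeat cutoff for the k-mer survey (default 2).
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with each stage's result objects and the
#'   summary tibble.
#' @export
run_pipeline <- function(out_dir, seed = 1,
                         n_orthogroups = 2000, n_genes = 500, n_pairs = 100,
                         min_present = 5L, fold_threshold = 2,
                         repeat_multiplier = 2, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  say("[simulate] generating planted-truth inputs (seed %d)", seed)
  fam <- run_stage("simulate", simulate_family_matrix(
    n_orthogroups = n_orthogroups, min_present = min_present, seed = seed + 1
  ))
  expr_sim <- run_stage("simulate", simulate_expression(n_genes = n_genes, seed = seed + 2))
  cds <- run_stage("simulate", simulate_cds_pairs(n_pairs = n_pairs, seed = seed + 3))
  km <- run_stage("simulate", simulate_kmer_histogram(seed = seed + 4))

  counts <- fam$counts
  reference <- fam$truth$reference
  panel <- fam$truth$panel
  targets <- fam$truth$targets
  readr::write_tsv(counts, file.path(out_dir, "gene_counts.tsv"))
  readr::write_tsv(expr_sim$expression, file.path(out_dir, "expression.tsv"))
  readr::write_tsv(km$histogram, file.path(out_dir, "kmer_histogram.tsv"), col_names = FALSE)

  say("[conserved] reference %s, panel of %d, min_present %d", reference, length(panel), min_present)
  conserved <- run_stage("conserved", conserved_orthogroups(
    counts, reference = reference, panel = panel, min_present = min_present
  ))
  readr::write_tsv(conserved, file.path(out_dir, "conserved.tsv"))

  say("[losses] calling losses in %s and %s", targets[1], targets[2])
  loss_a <- run_stage("losses", call_losses(counts, conserved, targets[1]))
  loss_b <- run_stage("losses", call_losses(counts, conserved, targets[2]))
  readr::write_tsv(tidy(loss_a), file.path(out_dir, paste0("losses_", targets[1], ".tsv")))
  readr::write_tsv(tidy(loss_b), file.path(out_dir, paste0("losses_", targets[2], ".tsv")))

  part <- run_stage("partition", partition_losses(loss_a, loss_b))
  readr::write_tsv(tidy(part), file.path(out_dir, "loss_partition.tsv"))

  say("[findex] Tukey summaries over %d conserved orthogroups", nrow(conserved))
  fs_a <- run_stage("fsummary", f_summary(counts, conserved, targets[1]))
  fs_b <- run_stage("fsummary", f_summary(counts, conserved, targets[2]))
  readr::write_tsv(dplyr::bind_rows(tidy(fs_a), tidy(fs_b)),
                   file.path(out_dir, "f_summary.tsv"))

  say("[pet] classifying principally expressed tissues/genes")
  pets <- run_stage("pet", principal_tissues(expr_sim$expression, fold_threshold = fold_threshold))
  readr::write_tsv(pets, file.path(out_dir, "pets.tsv"))
  pegs <- run_stage("peg", principal_genes(
    expr_sim$expression, focal_tissues = c("prehaustoria", "haustoria"),
    fold_threshold = fold_threshold
  ))
  readr::write_tsv(pegs, file.path(out_dir, "pegs.tsv"))

  # proxy ortholog map: conserved orthogroups linked round-robin to the
  # simulated proxy-species genes
  genes <- expr_sim$expression$gene
  og_map <- tibble(
    orthogroup = conserved$orthogroup,
    gene = genes[(seq_len(nrow(conserved)) - 1) %% length(genes) + 1]
  )
  tissue_classes <- tibble(
    tissue = tissue_cols(expr_sim$expression),
    class = dplyr::case_match(tissue_cols(expr_sim$expression),
      "leaves" ~ "leaves", "roots" ~ "roots", "flowers" ~ "flowers",
      .default = "other"
    )
  )
  tab <- run_stage("tabulate", tabulate_lost_pets(loss_a, og_map, pets, tissue_classes))
  readr::write_tsv(tidy(tab), file.path(out_dir, "lost_pet_tabulation.tsv"))

  say("[pseudo] scanning %d CDS pairs", nrow(cds$pairs))
  refs <- Biostrings::DNAStringSet(setNames(cds$pairs$reference, cds$pairs$pair_id))
  cands <- Biostrings::DNAStringSet(setNames(cds$pairs$candidate, cds$pairs$pair_id))
  Biostrings::writeXStringSet(refs, file.path(out_dir, "cds_reference.fasta"))
  Biostrings::writeXStringSet(cands, file.path(out_dir, "cds_candidate.fasta"))
  scan <- run_stage("pseudo", scan_pseudogenes(cds$pairs))
  readr::write_tsv(
    dplyr::left_join(scan$lesions, scan$pairs[c("pair_id", "is_pseudogene")], by = "pair_id"),
    file.path(out_dir, "lesions.tsv")
  )

  say("[kmer-survey] estimating genome size")
  survey <- run_stage("kmer-survey", estimate_genome_size(
    km$histogram, repeat_multiplier = repeat_multiplier
  ))
  readr::write_tsv(tidy(survey), file.path(out_dir, "survey.tsv"))

  summary_tbl <- dplyr::bind_rows(
    tibble(stage = "conserved", key = "n_conserved", value = nrow(conserved)),
    tibble(stage = "losses", key = paste0("n_lost_", c(targets[1], targets[2])),
           value = c(loss_a$n_lost, loss_b$n_lost)),
    tibble(stage = "losses", key = paste0("loss_fraction_", c(targets[1], targets[2])),
           value = c(loss_a$loss_fraction, loss_b$loss_fraction)),
    tibble(stage = "partition", key = c("n_joint", "n_specific_a", "n_specific_b"),
           value = c(length(part$joint), length(part$specific_a), length(part$specific_b))),
    tibble(stage = "fsummary",
           key = paste0("fraction_below_half_", c(targets[1], targets[2])),
           value = c(fs_a$fraction_below_half, fs_b$fraction_below_half)),
    tibble(stage = "pet", key = "n_pet_genes", value = length(unique(pets$gene))),
    tibble(stage = "peg", key = "n_pegs", value = sum(pegs$is_peg)),
    tibble(stage = "pseudo", key = "n_pseudogenes", value = sum(scan$pairs$is_pseudogene)),
    tibble(stage = "kmer-survey", key = c("genome_size", "repeat_fraction", "peak_depth"),
           value = c(survey$genome_size, survey$repeat_fraction, survey$peak_depth))
  )
  readr::write_tsv(summary_tbl, file.path(out_dir, "summary.tsv"))

  write_kv(list(
    package = "genelossr",
    version = as.character(utils::packageVersion("genelossr")),
    seed = seed,
    n_orthogroups = n_orthogroups,
    n_genes = n_genes,
    n_pairs = n_pairs,
    reference = reference,
    panel = panel,
    targets = targets,
    min_present = min_present,
    fold_threshold = fold_threshold,
    repeat_multiplier = repeat_multiplier
  ), file.path(out_dir, "manifest.tsv"))

  invisible(list(
    counts = counts, truth = fam$truth, conserved = conserved,
    loss_a = loss_a, loss_b = loss_b, partition = part,
    f_summary_a = fs_a, f_summary_b = fs_b,
    pets = pets, pegs = pegs, pet_tabulation = tab,
    pseudogenes = scan, survey = survey, summary = summary_tbl
  ))
}
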