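ALL_CODONS <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"), paste0),
                              c("T", "C", "A", "G"), paste0))
SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("%s must be a single number in [0, 1]", name))
  }
  x
}

shifted_pois <- function(n, mean_size) 1L + rpois(n, max(mean_size - 1, 0))

#' Simulate an orthogroup-by-species gene-count matrix with planted losses
#'
#' Emulates a nine-species comparative table: one reference species, a panel
#' of autotrophs, and two heterotrophic target species whose gene losses are
#' planted. Conserved rows satisfy the conservation rule (present in the
#' reference and in at least `min_present` panel species) by construction;
#' non-conserved rows violate it by construction. Each conserved row is then
#' independently assigned to joint loss (zero count in both targets),
#' target-specific loss, or retention, at the stated rates. Family sizes are
#' drawn from a shifted Poisson (minimum 1 where presence is planted). A
#' fraction of retained target entries is planted as contracted (count 1) or
#' expanded (count drawn around three times the baseline mean).
#'
#' Defaults echo the study conditions of a parasitic-plant comparative
#' analysis: loss rates 0.117 and 0.130 with joint rate 0.047 against a
#' reference-plus-six-autotroph panel at `min_present = 5`.
#'
#' @param n_orthogroups Number of orthogroup rows.
#' @param species Ordered species ids (columns).
#' @param reference Reference species id.
#' @param panel Panel species ids (autotrophs other than the reference).
#' @param targets Two target species ids whose losses are planted.
#' @param conserved_fraction Fraction of rows planted as conserved.
#' @param loss_rate_a,loss_rate_b Marginal planted loss rates of the two
#'   targets among conserved rows.
#' @param joint_rate Planted rate of joint losses; must not exceed either
#'   marginal rate (`joint_rate` above the product of the marginals encodes
#'   a joint-loss excess).
#' @param mean_size Mean family size for present entries (shifted Poisson).
#' @param min_present Conservation threshold on the panel.
#' @param panel_presence Per-species presence probability in the panel for
#'   conserved rows (before topping up to `min_present`).
#' @param contracted_rate,expanded_rate Per-target planting rates of
#'   contractions/expansions among retained conserved entries.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @return List with `counts` (gene-count tibble) and `truth`, a list holding
#'   the planted `conserved`, `lost_a`, `lost_b`, `joint`, `specific_a`,
#'   `specific_b`, `contracted`/`expanded` per target, and the rule
#'   parameters.
#' @export
simulate_family_matrix <- function(n_orthogroups = 2000,
                                   species = c("C_australis", "A_thaliana", "I_nil",
                                               "S_lycopersicum", "S_tuberosum", "C_annuum",
                                               "C_canephora", "M_guttatus", "U_gibba"),
                                   reference = "A_thaliana",
                                   panel = c("I_nil", "S_lycopersicum", "S_tuberosum",
                                             "C_annuum", "C_canephora", "M_guttatus"),
                                   targets = c("C_australis", "U_gibba"),
                                   conserved_fraction = 0.56,
                                   loss_rate_a = 0.117,
                                   loss_rate_b = 0.130,
                                   joint_rate = 0.047,
                                   mean_size = 3,
                                   min_present = 5L,
                                   panel_presence = 0.9,
                                   contracted_rate = 0.05,
                                   expanded_rate = 0.05,
                                   seed) {
  if (missing(seed)) abort("seed is required")
  check_fraction(conserved_fraction, "conserved_fraction")
  check_fraction(loss_rate_a, "loss_rate_a")
  check_fraction(loss_rate_b, "loss_rate_b")
  check_fraction(joint_rate, "joint_rate")
  check_fraction(panel_presence, "panel_presence")
  if (joint_rate > min(loss_rate_a, loss_rate_b)) {
    abort("joint_rate cannot exceed either marginal loss rate")
  }
  if (loss_rate_a + loss_rate_b - joint_rate > 1) {
    abort("loss rates are inconsistent: categories sum above 1")
  }
  stopifnot(length(targets) == 2, !reference %in% panel,
            !any(targets %in% c(reference, panel)),
            all(c(reference, panel, targets) %in% species))
  min_present <- as.integer(min_present)
  stopifnot(min_present >= 0, min_present <= length(panel))

  withr::with_seed(seed, {
    n <- as.integer(n_orthogroups)
    ids <- sprintf("OG%07d", seq_len(n))
    m <- matrix(0L, nrow = n, ncol = length(species),
                dimnames = list(ids, species))
    n_cons <- round(conserved_fraction * n)
    cons_idx <- sort(sample.int(n, n_cons))
    is_cons <- seq_len(n) %in% cons_idx

    # conserved rows: reference present, >= min_present panel species present
    m[cons_idx, reference] <- shifted_pois(n_cons, mean_size)
    pres <- matrix(rbinom(n_cons * length(panel), 1, panel_presence) == 1,
                   nrow = n_cons)
    deficit <- which(rowSums(pres) < min_present)
    for (i in deficit) {
      absent <- which(!pres[i, ])
      topup <- absent[sample.int(length(absent), min_present - sum(pres[i, ]))]
      pres[i, topup] <- TRUE
    }
    m[cons_idx, panel][pres] <- shifted_pois(sum(pres), mean_size)

    # non-conserved rows: either reference-absent, or panel presence below threshold
    nc_idx <- which(!is_cons)
    flavor_ref0 <- rbinom(length(nc_idx), 1, 0.5) == 1
    for (j in seq_along(nc_idx)) {
      i <- nc_idx[j]
      if (flavor_ref0[j]) {
        present <- panel[rbinom(length(panel), 1, 0.5) == 1]
      } else {
        m[i, reference] <- shifted_pois(1, mean_size)
        present <- sample(panel, sample.int(min_present, 1) - 1L)
      }
      if (length(present) > 0) m[i, present] <- shifted_pois(length(present), mean_size)
    }

    # plant losses in the targets among conserved rows
    cat_probs <- c(joint = joint_rate,
                   a = loss_rate_a - joint_rate,
                   b = loss_rate_b - joint_rate,
                   none = 1 - loss_rate_a - loss_rate_b + joint_rate)
    category <- sample(names(cat_probs), n_cons, replace = TRUE, prob = cat_probs)
    a_present <- !category %in% c("joint", "a")
    b_present <- !category %in% c("joint", "b")
    m[cons_idx[a_present], targets[1]] <- shifted_pois(sum(a_present), mean_size)
    m[cons_idx[b_present], targets[2]] <- shifted_pois(sum(b_present), mean_size)

    # plant contractions/expansions among retained target entries
    size_class <- function(present_mask) {
      cls <- rep("baseline", n_cons)
      cls[present_mask] <- sample(c("contracted", "expanded", "baseline"),
                                  sum(present_mask), replace = TRUE,
                                  prob = c(contracted_rate, expanded_rate,
                                           1 - contracted_rate - expanded_rate))
      cls
    }
    cls_a <- size_class(a_present)
    cls_b <- size_class(b_present)
    m[cons_idx[cls_a == "contracted"], targets[1]] <- 1L
    m[cons_idx[cls_a == "expanded"], targets[1]] <- shifted_pois(sum(cls_a == "expanded"), 3 * mean_size)
    m[cons_idx[cls_b == "contracted"], targets[2]] <- 1L
    m[cons_idx[cls_b == "expanded"], targets[2]] <- shifted_pois(sum(cls_b == "expanded"), 3 * mean_size)

    # targets in non-conserved rows: unconstrained presence
    nc_a <- rbinom(length(nc_idx), 1, 0.7) == 1
    nc_b <- rbinom(length(nc_idx), 1, 0.7) == 1
    m[nc_idx[nc_a], targets[1]] <- shifted_pois(sum(nc_a), mean_size)
    m[nc_idx[nc_b], targets[2]] <- shifted_pois(sum(nc_b), mean_size)

    cons_ids <- ids[cons_idx]
    counts <- dplyr::bind_cols(tibble(orthogroup = ids), as_tibble(m))
    truth <- list(
      conserved = cons_ids,
      joint = cons_ids[category == "joint"],
      specific_a = cons_ids[category == "a"],
      specific_b = cons_ids[category == "b"],
      lost_a = cons_ids[category %in% c("joint", "a")],
      lost_b = cons_ids[category %in% c("joint", "b")],
      contracted_a = cons_ids[cls_a == "contracted"],
      expanded_a = cons_ids[cls_a == "expanded"],
      contracted_b = cons_ids[cls_b == "contracted"],
      expanded_b = cons_ids[cls_b == "expanded"],
      reference = reference, panel = panel, targets = targets,
      min_present = min_present
    )
    list(counts = counts, truth = truth)
  })
}

#' Simulate a gene-by-tissue expression matrix with planted PETs
#'
#' A fraction of genes is planted with one principally expressed tissue:
#' baseline expression `base_level` in every tissue except `fold` times that
#' in the planted tissue. All values then receive multiplicative lognormal
#' noise with the stated coefficient of variation (mean 1), so planted
#' signal is preserved in expectation.
#'
#' @param n_genes Number of genes.
#' @param tissues Tissue ids (at least 2).
#' @param pet_fraction Fraction of genes planted with a PET.
#' @param fold Planted fold elevation of the PET tissue; should exceed the
#'   classifier threshold you intend to use.
#' @param base_level Baseline expression level (TPM-like).
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   noise (0 = noiseless).
#' @param seed Integer seed.
#' @return List with `expression` (tibble, first column `gene`) and `truth`
#'   (tibble of `gene`, `pet_tissue`; `NA` where no PET is planted).
#' @export
simulate_expression <- function(n_genes = 500,
                                tissues = c("leaves", "roots", "flowers", "stems",
                                            "seeds", "prehaustoria", "haustoria"),
                                pet_fraction = 0.3,
                                fold = 10,
                                base_level = 10,
                                noise_cv = 0.2,
                                seed) {
  if (missing(seed)) abort("seed is required")
  check_fraction(pet_fraction, "pet_fraction")
  if (length(tissues) < 2) abort("need at least two tissues")
  if (!is.numeric(fold) || fold <= 0) abort("fold must be positive")
  if (!is.numeric(noise_cv) || noise_cv < 0) abort("noise_cv must be non-negative")

  withr::with_seed(seed, {
    genes <- sprintf("g%05d", seq_len(n_genes))
    n_pet <- round(pet_fraction * n_genes)
    pet_idx <- sort(sample.int(n_genes, n_pet))
    pet_tissue <- rep(NA_character_, n_genes)
    pet_tissue[pet_idx] <- sample(tissues, n_pet, replace = TRUE)

    m <- matrix(base_level, nrow = n_genes, ncol = length(tissues),
                dimnames = list(genes, tissues))
    m[cbind(pet_idx, match(pet_tissue[pet_idx], tissues))] <- fold * base_level
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      m <- m * matrix(stats::rlnorm(length(m), meanlog = -sdlog^2 / 2, sdlog = sdlog),
                      nrow = n_genes)
    }
    list(
      expression = dplyr::bind_cols(tibble(gene = genes), as_tibble(m)),
      truth = tibble(gene = genes, pet_tissue = pet_tissue)
    )
  })
}

#' Simulate reference/candidate CDS pairs with planted lesions
#'
#' References are random intact ORFs (ATG start, random sense codons, single
#' terminal stop). Each candidate starts as a copy of its reference, receives
#' background substitutions that are rejection-sampled so they never create
#' an in-frame stop codon, and then one planted lesion according to
#' `lesion_mix`: a frameshift (1- or 2-bp insertion or deletion), a
#' premature stop codon, or nothing (intact).
#'
#' @param n_pairs Number of pairs.
#' @param cds_length_codons Reference length in codons (including start and
#'   stop); at least 25.
#' @param lesion_mix Named numeric vector of mixture weights over
#'   `frameshift`, `premature_stop`, `intact` (normalised internally).
#' @param background_sub_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return List with `pairs` (tibble of `pair_id`, `reference`, `candidate`)
#'   and `truth` (list of `lesions`, a tibble of planted lesions with
#'   `pair_id`, `kind`, `ref_position`, `detail`; and `pairs`, a tibble of
#'   `pair_id`, `planted` kind).
#' @export
simulate_cds_pairs <- function(n_pairs = 200,
                               cds_length_codons = 200,
                               lesion_mix = c(frameshift = 0.3,
                                              premature_stop = 0.3,
                                              intact = 0.4),
                               background_sub_rate = 0.01,
                               seed) {
  if (missing(seed)) abort("seed is required")
  check_fraction(background_sub_rate, "background_sub_rate")
  if (!all(names(lesion_mix) %in% c("frameshift", "premature_stop", "intact")) ||
      is.null(names(lesion_mix)) || any(lesion_mix < 0) || sum(lesion_mix) == 0) {
    abort("lesion_mix must be non-negative weights named frameshift/premature_stop/intact")
  }
  L <- as.integer(cds_length_codons)
  if (L < 25) abort("cds_length_codons must be at least 25 so lesions fit in the interior")
  bases <- c("A", "C", "G", "T")

  withr::with_seed(seed, {
    kinds <- sample(names(lesion_mix), n_pairs, replace = TRUE,
                    prob = lesion_mix / sum(lesion_mix))
    out <- purrr::map(seq_len(n_pairs), function(i) {
      ref_codons <- c("ATG", sample(SENSE_CODONS, L - 2, replace = TRUE),
                      sample(STOP_CODONS, 1))
      ref <- strsplit(paste(ref_codons, collapse = ""), "")[[1]]
      cand <- ref

      # stop-free background substitutions in the interior
      elig <- 4:(3 * L - 3)
      n_sub <- rbinom(1, length(elig), background_sub_rate)
      for (pos in sample(elig, n_sub)) {
        codon_i <- (pos - 1) %/% 3
        for (attempt in 1:10) {
          new <- sample(setdiff(bases, cand[pos]), 1)
          trial <- cand
          trial[pos] <- new
          if (!paste(trial[3 * codon_i + 1:3], collapse = "") %in% STOP_CODONS) {
            cand <- trial
            break
          }
        }
      }

      kind <- kinds[i]
      lesion <- NULL
      if (kind == "frameshift") {
        len <- sample(1:2, 1)
        pos <- 3 * (sample(10:(L - 10), 1) - 1) + sample(0:2, 1) + 1
        if (runif(1) < 0.5) {
          cand <- cand[-(pos:(pos + len - 1))]
          detail <- -len
        } else {
          cand <- append(cand, sample(bases, len, replace = TRUE), after = pos - 1)
          detail <- len
        }
        lesion <- tibble(kind = "frameshift", ref_position = as.integer(pos),
                         detail = as.character(detail))
      } else if (kind == "premature_stop") {
        codon <- sample(10:(L - 10), 1)
        stop_cod <- sample(STOP_CODONS, 1)
        cand[3 * (codon - 1) + 1:3] <- strsplit(stop_cod, "")[[1]]
        lesion <- tibble(kind = "premature_stop",
                         ref_position = as.integer(3 * (codon - 1) + 1),
                         detail = stop_cod)
      }
      list(reference = paste(ref, collapse = ""),
           candidate = paste(cand, collapse = ""),
           lesion = lesion)
    })
    pair_ids <- sprintf("pair%04d", seq_len(n_pairs))
    lesions <- purrr::map2_dfr(out, pair_ids, function(o, id) {
      if (is.null(o$lesion)) return(NULL)
      dplyr::mutate(o$lesion, pair_id = id, .before = 1)
    })
    list(
      pairs = tibble(
        pair_id = pair_ids,
        reference = purrr::map_chr(out, "reference"),
        candidate = purrr::map_chr(out, "candidate")
      ),
      truth = list(lesions = lesions,
                   pairs = tibble(pair_id = pair_ids, planted = kinds))
    )
  })
}

#' Simulate a k-mer depth histogram from a unique/repeat/error mixture
#'
#' Unique genomic k-mers draw their depth from Poisson(`coverage`); k-mers
#' from repeats of copy number `repeat_copy` draw from
#' Poisson(`repeat_copy * coverage`) and contribute a fraction
#' `repeat_fraction` of the genomic k-mer mass; sequencing-error k-mers are
#' concentrated at depths 1-2 with total count proportional to
#' `error_rate * k * coverage * genome_size`.
#'
#' @param genome_size True genome size in bases (= number of genomic k-mer
#'   positions, to k-mer edge effects).
#' @param coverage Mean sequencing depth of unique sequence.
#' @param repeat_fraction Fraction of the genome in repeats.
#' @param repeat_copy Copy number of the repeats (> 1).
#' @param error_rate Per-base sequencing error rate.
#' @param k K-mer length (default 17).
#' @param seed Integer seed.
#' @return List with `histogram` (tibble `depth`, `count`) and `truth`
#'   (list echoing the parameters).
#' @export
simulate_kmer_histogram <- function(genome_size = 1e6,
                                    coverage = 42,
                                    repeat_fraction = 0.2,
                                    repeat_copy = 2,
                                    error_rate = 0.01,
                                    k = 17,
                                    seed) {
  if (missing(seed)) abort("seed is required")
  check_fraction(repeat_fraction, "repeat_fraction")
  check_fraction(error_rate, "error_rate")
  if (!is.numeric(coverage) || coverage <= 0) abort("coverage must be positive")
  if (!is.numeric(repeat_copy) || repeat_copy <= 1) abort("repeat_copy must exceed 1")
  if (genome_size < 1) abort("genome_size must be at least 1")

  withr::with_seed(seed, {
    n_unique <- round(genome_size * (1 - repeat_fraction))
    n_repeat <- round(genome_size * repeat_fraction / repeat_copy)
    depths <- c(rpois(n_unique, coverage), rpois(n_repeat, repeat_copy * coverage))
    depths <- depths[depths > 0]
    counts <- tabulate(depths)
    n_err <- round(genome_size * coverage * error_rate * k)
    if (n_err > 0) {
      counts[1] <- counts[1] + round(0.9 * n_err)
      counts[2] <- counts[2] + (n_err - round(0.9 * n_err))
    }
    keep <- which(counts > 0)
    list(
      histogram = tibble(depth = keep, count = as.numeric(counts[keep])),
      truth = list(genome_size = genome_size, coverage = coverage,
                   repeat_fraction = repeat_fraction, repeat_copy = repeat_copy,
                   error_rate = error_rate, k = k)
    )
  })
}
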