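toy_expr <- function(mat, tissues = colnames(mat), genes = rownames(mat)) {
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(mat)))
  dplyr::bind_cols(
    tibble::tibble(gene = genes),
    tibble::as_tibble(matrix(as.numeric(mat), nrow(mat), dimnames = list(NULL, tissues)))
  )
}

test_that("PET rule: tissue must reach fold x the mean of the other tissues", {
  e <- toy_expr(rbind(c(10, 1, 1, 1, 1, 1),  # leaf is 10x the others' mean of 1
                      c(5, 5, 5, 5, 5, 5),   # flat positive: v >= 2v is false
                      c(0, 0, 0, 0, 0, 0)),  # all-zero: no PET
                tissues = c("leaf", paste0("t", 1:5)))
  pets <- principal_tissues(e, fold_threshold = 2)
  expect_equal(pets$gene, "g1")
  expect_equal(pets$tissue, "leaf")

  # the weaker >= 1x reading makes every tissue of a flat gene a PET
  pets1 <- principal_tissues(e, fold_threshold = 1)
  expect_equal(sum(pets1$gene == "g2"), 6)

  single <- toy_expr(matrix(1, 2, 1), tissues = "only")
  expect_error(principal_tissues(single), "at least two tissues")
  expect_error(principal_tissues(e, fold_threshold = 0), "positive")
})

test_that("PET calls equal the brute-force rule and are scale-invariant", {
  withr::with_seed(13, {
    mat <- matrix(stats::rexp(60 * 6, rate = 0.2), 60, 6)
    mat[sample(length(mat), 40)] <- 0
    mat[1:3, ] <- 0
  })
  e <- toy_expr(mat, tissues = paste0("t", 1:6))
  for (fold in c(1, 2, 3)) {
    got <- principal_tissues(e, fold_threshold = fold)
    want <- oracle_pets(e, fold)
    expect_setequal(paste(got$gene, got$tissue), paste(want$gene, want$tissue))
  }
  # multiplying a gene's row by a positive scalar changes nothing
  scaled <- e
  scl <- withr::with_seed(14, runif(nrow(e), 0.1, 50))
  scaled[-1] <- e[-1] * scl
  g1 <- principal_tissues(e)
  g2 <- principal_tissues(scaled)
  expect_equal(paste(g1$gene, g1$tissue), paste(g2$gene, g2$tissue))
})

test_that("PEG rule agrees with hand arithmetic and with single-tissue PET calls", {
  e <- toy_expr(rbind(c(8, 8, 3, 3, 3),   # focal mean 8 vs other mean 3: 8 >= 6
                      c(4, 4, 4, 4, 4),   # equal means: not a PEG at fold 2
                      c(0, 0, 0, 0, 0)),
                tissues = c("prehaustoria", "haustoria", "leaf", "root", "stem"))
  pegs <- principal_genes(e, c("prehaustoria", "haustoria"), fold_threshold = 2)
  expect_equal(pegs$is_peg, c(TRUE, FALSE, FALSE))
  expect_error(principal_genes(e, character(0)), "empty")
  expect_error(principal_genes(e, names(e)[-1]), "proper subset")
  expect_error(principal_genes(e, "nope"), "unknown")

  withr::with_seed(23, mat <- matrix(stats::rexp(50 * 5, 0.3), 50, 5))
  em <- toy_expr(mat, tissues = paste0("t", 1:5))
  pet <- principal_tissues(em)
  for (t in paste0("t", 1:5)) {
    via_peg <- principal_genes(em, t)$gene[principal_genes(em, t)$is_peg]
    via_pet <- pet$gene[pet$tissue == t]
    expect_setequal(via_peg, via_pet)
  }
})

test_that("planted PEGs are recovered exactly in a noiseless matrix", {
  sim <- simulate_expression(n_genes = 500, pet_fraction = 0.1, fold = 10,
                             noise_cv = 0, seed = 31)
  # plant the PEG signal on one focal tissue and classify against the rest
  truth <- sim$truth
  focal <- "haustoria"
  planted <- truth$gene[!is.na(truth$pet_tissue) & truth$pet_tissue == focal]
  pegs <- principal_genes(sim$expression, focal)
  expect_setequal(pegs$gene[pegs$is_peg], planted)
})

test_that("lost-PET tabulation counts classes, multi-class members and unmapped orthogroups", {
  pets <- tibble::tibble(gene = c("gr", "gl", "gb", "gb"),
                         tissue = c("root", "leaf", "leaf", "root"),
                         value = 1, other_mean = 0)
  map <- tibble::tibble(orthogroup = c("O1", "O2", "O3", "O4"),
                        gene = c("gr", "gl", "gnopet", "gb"))
  classes <- tibble::tibble(tissue = c("leaf", "root", "flower", "stem"),
                            class = c("leaves", "roots", "flowers", "other"))
  tab <- tabulate_lost_pets(c("O1", "O2", "O3"), map, pets, classes)
  cls <- tidy(tab)
  expect_equal(cls$n_lost[match(c("leaves", "roots", "flowers", "other"), cls$class)],
               c(1L, 1L, 0L, 0L))
  expect_equal(tab$n_no_pet, 1L)    # O3 maps to a gene with no PET
  expect_equal(tab$n_unmapped, 0L)

  # an orthogroup whose proxy gene has PETs in leaf and root counts in both
  tab2 <- tabulate_lost_pets("O4", map, pets, classes)
  cls2 <- tidy(tab2)
  expect_equal(cls2$n_lost[match(c("leaves", "roots"), cls2$class)], c(1L, 1L))

  # orthogroup missing from the map lands in the unmapped tally, not an error
  tab3 <- tabulate_lost_pets(c("O1", "OX"), map, pets, classes)
  expect_equal(tab3$n_unmapped, 1L)

  expect_error(
    tabulate_lost_pets("O1", map, dplyr::mutate(pets, tissue = "mystery"), classes),
    "does not cover"
  )
})

test_that("tabulation is invariant to orthogroup relabeling and recovers planted proportions", {
  withr::with_seed(41, {
    n <- 200
    cls_truth <- sample(c("leaves", "roots", "flowers", "other"), n,
                        replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  })
  tissue_of <- c(leaves = "leaf", roots = "root", flowers = "flower", other = "stem")
  pets <- tibble::tibble(gene = paste0("g", 1:n), tissue = unname(tissue_of[cls_truth]),
                         value = 1, other_mean = 0)
  map <- tibble::tibble(orthogroup = paste0("O", 1:n), gene = paste0("g", 1:n))
  classes <- tibble::tibble(tissue = c("leaf", "root", "flower", "stem"),
                            class = c("leaves", "roots", "flowers", "other"))
  tab <- tabulate_lost_pets(paste0("O", 1:n), map, pets, classes)
  got <- tidy(tab)
  expect_equal(setNames(got$n_lost, got$class)[names(table(cls_truth))],
               table(cls_truth) |> as.vector() |> setNames(names(table(cls_truth))))

  # relabel orthogroups with a fixed permutation: counts unchanged
  perm <- withr::with_seed(5, sample(n))
  map2 <- dplyr::mutate(map, orthogroup = paste0("Z", perm))
  tab2 <- tabulate_lost_pets(paste0("Z", 1:n), map2, pets, classes)
  expect_equal(tidy(tab2)$n_lost, got$n_lost)
})
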