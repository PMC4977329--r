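test_that("pedigree generation follows the crossing arithmetic", {
  ped <- sim_pedigree(sim_config(n_founders = 2, n_generations = 1,
                                 offspring_per_cross = 3))
  expect_equal(nrow(ped), 5L)                    # 2 founders + 1 cross x 3
  expect_equal(sum(is.na(ped$mother) & is.na(ped$father)), 2L)
  kids <- ped[!is.na(ped$mother), ]
  expect_length(unique(paste(kids$mother, kids$father)), 1L)

  ped0 <- sim_pedigree(sim_config(n_founders = 3, n_generations = 0))
  expect_equal(nrow(ped0), 3L)
  expect_true(all(is.na(ped0$mother)))
})

test_that("large runs include a selfing and a single-known-parent individual", {
  ped <- sim_pedigree(sim_config(n_founders = 5, n_generations = 2))
  self <- ped[!is.na(ped$mother) & !is.na(ped$father) &
                ped$mother == ped$father, ]
  expect_gte(nrow(self), 1L)
  half <- ped[!is.na(ped$mother) & is.na(ped$father), ]
  expect_gte(nrow(half), 1L)
})

test_that("the simulator is deterministic under its seed", {
  cfg <- sim_config(n_founders = 4, n_generations = 2, n_blocks = 2, seed = 77)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$data$haplo, s2$data$haplo)
  expect_identical(s1$truth$haplo, s2$truth$haplo)
  expect_identical(s1$truth$transmissions, s2$truth$transmissions)
})

test_that("without final-generation recombination every haplotype is parental", {
  cfg <- sim_config(n_founders = 4, n_generations = 2, n_blocks = 3,
                    final_gen_recomb_rate = 0, seed = 9)
  truth <- simulate_dataset(cfg)$truth
  ped <- truth$pedigree
  for (i in seq_len(nrow(ped))) {
    for (s in 1:2) {
      parent <- if (s == 1L) ped$mother[i] else ped$father[i]
      if (is.na(parent)) next
      child_row <- paste0(ped$id[i], if (s == 1L) "|M" else "|P")
      for (b in names(truth$blocks)) {
        bm <- truth$blocks[[b]]
        child <- truth$haplo[child_row, bm]
        p1 <- truth$haplo[paste0(parent, "|M"), bm]
        p2 <- truth$haplo[paste0(parent, "|P"), bm]
        expect_true(identical(child, p1) || identical(child, p2))
      }
    }
  }
  expect_false(any(truth$transmissions$recombinant))
})

test_that("a homozygous parent always transmits its haplotype", {
  markers <- paste0("m", 1:3)
  ped <- data.frame(id = c("A", "B", "C"), mother = c(NA, NA, "A"),
                    father = c(NA, NA, "B"))
  cfg <- sim_config(n_founders = 2, n_generations = 1, n_blocks = 1,
                    markers_per_block = 3, founder_allele_freq = 1, seed = 1)
  truth <- gene_drop(ped, cfg)
  # founder_allele_freq = 1 makes every founder homozygous "A" everywhere
  expect_true(all(truth$haplo == "A"))
})

test_that("final-generation recombination splices the two parental haplotypes", {
  cfg <- sim_config(n_founders = 4, n_generations = 2, n_blocks = 4,
                    markers_per_block = 6, final_gen_recomb_rate = 1, seed = 6)
  truth <- simulate_dataset(cfg)$truth
  tr <- truth$transmissions
  ped <- truth$pedigree
  rec <- tr[tr$recombinant, ]
  expect_gt(nrow(rec), 0)
  # a recombinant block is a prefix of one parental haplotype followed by a
  # suffix of the other
  r <- rec[1, ]
  i <- match(r$individual, ped$id)
  parent <- if (r$slot == "M") ped$mother[i] else ped$father[i]
  bm <- truth$blocks[[r$block]]
  child <- truth$haplo[paste0(r$individual, "|", r$slot), bm]
  p1 <- truth$haplo[paste0(parent, "|M"), bm]
  p2 <- truth$haplo[paste0(parent, "|P"), bm]
  K <- length(bm)
  ok <- FALSE
  for (bp in 1:(K - 1)) {
    s1 <- c(p1[1:bp], p2[(bp + 1):K]); s2 <- c(p2[1:bp], p1[(bp + 1):K])
    if (identical(unname(child), unname(s1)) ||
        identical(unname(child), unname(s2))) ok <- TRUE
  }
  expect_true(ok)
})

test_that("corruption respects its rates", {
  cfg <- sim_config(n_founders = 6, n_generations = 2, n_blocks = 20, seed = 10)
  truth <- simulate_dataset(cfg)$truth
  expect_identical(corrupt_calls(truth$haplo, 0, 0, seed = 1), truth$haplo)
  allmiss <- corrupt_calls(truth$haplo, 1, 0, seed = 1)
  expect_true(all(is.na(allmiss)))
  # observed missing fraction within 3 binomial standard deviations
  n_calls <- length(truth$haplo)
  expect_gte(n_calls, 10000)
  p <- 0.1
  got <- mean(is.na(corrupt_calls(truth$haplo, p, 0, seed = 2)))
  tol <- 3 * sqrt(p * (1 - p) / n_calls)
  expect_lt(abs(got - p), tol)
  # errors flip to a different symbol of the same marker
  err <- corrupt_calls(truth$haplo, 0, 1, seed = 3)
  polymorphic <- vapply(seq_len(ncol(truth$haplo)), function(k)
    length(unique(truth$haplo[, k])) > 1L, logical(1))
  expect_true(all(err[, polymorphic] != truth$haplo[, polymorphic]))
  expect_identical(err[, !polymorphic], truth$haplo[, !polymorphic])
  expect_error(corrupt_calls(truth$haplo, 1.1, 0, seed = 1), "probabilities")
})
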