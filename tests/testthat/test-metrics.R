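# minimal hand-built fit-like object for informativeness checks
mini_fit <- function(p_hap1, p_hap2, markers = paste0("m", seq_along(p_hap1))) {
  ped <- validate_pedigree(data.frame(id = c("P", "C"), mother = c(NA, "P"),
                                      father = c(NA, NA)))
  haplo <- make_haplo(list(P = list(p_hap1, p_hap2),
                           C = list(p_hap1, rep(NA_character_, length(p_hap1)))),
                      markers)
  cat <- catalog_alleles(haplo)
  genotypes <- data.frame(
    individual = c("P", "C"), block = "B1",
    allele_mat = cat$assignment[c(1L, 3L)],
    allele_pat = cat$assignment[c(2L, 4L)], stringsAsFactors = FALSE)
  structure(list(blocks = list(B1 = markers), haplo = haplo,
                 genotypes = genotypes, pedigree = ped),
            class = "hb_fit")
}

test_that("informative fractions follow parental heterozygosity", {
  # parent heterozygous at 1 of 4 markers
  f <- mini_fit(c("1", "0", "0", "0"), c("0", "0", "0", "0"))
  expect_equal(informative_fraction(f, "marker"), 0.25)
  expect_equal(informative_fraction(f, "block"), 1)
  # fully homozygous parent
  f0 <- mini_fit(c("1", "0", "1"), c("1", "0", "1"))
  expect_equal(informative_fraction(f0, "marker"), 0)
  expect_equal(informative_fraction(f0, "block"), 0)
})

test_that("informative fraction is undefined without genotyped transmissions", {
  ped <- validate_pedigree(data.frame(id = "X", mother = NA, father = NA))
  f <- structure(list(blocks = list(), haplo = matrix(NA_character_, 2, 0),
                      genotypes = data.frame(), pedigree = ped),
                 class = "hb_fit")
  expect_true(is.na(informative_fraction(f, "block")))
})

test_that("the block-level fraction dominates the mean marker-level fraction", {
  for (seed in c(6, 28)) {
    sim <- simulate_dataset(sim_config(n_founders = 5, n_generations = 2,
                                       n_blocks = 6, seed = seed))
    fit <- assign_haploblocks(sim$data)
    fb <- informative_fraction(fit, "block")
    fm <- informative_fraction(fit, "marker")
    expect_gte(fb, fm)
  }
})

test_that("imputation classification distinguishes correct, wrong and missing", {
  truth <- matrix(c("A", "B", "A", "B"), 2, 2,
                  dimnames = list(c("i|M", "i|P"), c("m1", "m2")))
  observed <- truth
  observed[1, 1] <- NA          # missing call
  observed[2, 2] <- "A"         # erroneous call
  # engine recovered everything
  expect_equal(imputation_accuracy(truth, observed, truth),
               list(imputed_correct = 2L, imputed_wrong = 0L, still_missing = 0L))
  # engine did nothing
  expect_equal(imputation_accuracy(truth, observed, observed),
               list(imputed_correct = 0L, imputed_wrong = 1L, still_missing = 1L))
  bad <- truth; bad[1, 1] <- "B"
  expect_equal(imputation_accuracy(truth, observed, bad)$imputed_wrong, 1L)
  expect_error(imputation_accuracy(truth[, 1, drop = FALSE], observed, truth),
               "aligned")
})

test_that("the consistency audit counts children matching neither parental allele", {
  ped <- data.frame(id = c("P", "Q", "C"), mother = c(NA, NA, "P"),
                    father = c(NA, NA, "Q"))
  g <- data.frame(individual = c("P", "Q", "C"), block = "B1",
                  allele_mat = c(1L, 4L, 3L), allele_pat = c(2L, 4L, 4L))
  expect_equal(consistency_audit(g, ped), 1L)
  # all-missing genotypes: vacuous
  g2 <- g; g2$allele_mat <- NA_integer_; g2$allele_pat <- NA_integer_
  expect_equal(consistency_audit(g2, ped), 0L)
  # a not-fully-genotyped parent is not audited
  g3 <- g; g3$allele_pat[1] <- NA_integer_
  expect_equal(consistency_audit(g3, ped), 0L)
})

test_that("the catalog-based audit only counts conflicting alleles", {
  ped <- data.frame(id = c("P", "C"), mother = c(NA, "P"), father = c(NA, NA))
  g <- data.frame(individual = c("P", "C"), block = "B1",
                  allele_mat = c(1L, 3L), allele_pat = c(2L, NA))
  # allele 3 differs from allele 1 only in missing data: no conflict
  catalogs <- list(B1 = data.frame(allele = 1:3,
                                   m1 = c("A", "B", "A"),
                                   m2 = c("A", "B", NA)))
  expect_equal(consistency_audit(g, ped), 1L)
  expect_equal(consistency_audit(g, ped, catalogs), 0L)
  # an allele conflicting with both parental alleles is counted either way
  catalogs$B1$m1[3] <- "B"; catalogs$B1$m2[3] <- "A"
  expect_equal(consistency_audit(g, ped, catalogs), 1L)
})

test_that("evaluating a converged error-free run finds no wrong imputations", {
  sim <- simulate_dataset(sim_config(n_founders = 5, n_generations = 2,
                                     n_blocks = 4, error_rate = 0, seed = 44))
  fit <- assign_haploblocks(sim$data)
  ev <- evaluate_assignment(fit, sim)
  expect_equal(ev$imputed_wrong, 0L)
  expect_equal(ev$violations, 0L)
  expect_gt(ev$imputed_correct, 0L)
})
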