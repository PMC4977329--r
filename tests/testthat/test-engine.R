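params_default <- hb_params()

test_that("a large one-group family imputes the consensus into a missing parent", {
  C <- c("1","0","1","1","0","0")
  st <- family_state(rep(NA_character_, 6), rep(NA_character_, 6),
                     rep(list(C), 16))
  res <- resolve_family(st, single_family(16), params_default)
  expect_true(res$changed)
  expect_equal(unname(res$state[1, ]), C)
  expect_equal(unname(res$state[2, ]), C)
  expect_true(all(res$state[3:18, ] == matrix(C, 16, 6, byrow = TRUE)))
})

test_that("parental alleles conflicting only with each other are cut to the progeny consensus", {
  C <- c("1","0","1","1","0",NA)
  st <- family_state(c("1","0","1","1","0","0"), c("1","0","1","1","0","1"),
                     rep(list(C), 16))
  res <- resolve_family(st, single_family(16), params_default)
  expect_equal(unname(res$state[1, ]), C)
  expect_equal(unname(res$state[2, ]), C)
  expect_true("MARKER_DATA_DELETED" %in% res$diagnostics$event)
})

test_that("a parental allele conflicting with a large one-group consensus is rejected", {
  C <- c("1","0","1","1","0","0")
  st <- family_state(c("0","1","0","0","1","1"), rep(NA_character_, 6),
                     rep(list(C), 16))
  res <- resolve_family(st, single_family(16), params_default)
  expect_true("ALLELE_REJECTED" %in% res$diagnostics$event)
  expect_equal(unname(res$state[1, ]), C)
  expect_equal(unname(res$state[2, ]), C)
})

test_that("small families do not presume parental homozygosity", {
  # two children in one group; the parent's other allele is untouched
  C <- c("1","0","1","1","0","0")
  st <- family_state(c("1","0","1",NA,NA,NA), c("0","1","0","0","1","1"),
                     list(C, C))
  res <- resolve_family(st, single_family(2), params_default)
  # children conflict with parent allele 2 -> proven to carry allele 1
  expect_equal(unname(res$state[1, ]), C)
  expect_equal(unname(res$state[2, ]), c("0","1","0","0","1","1"))
  expect_equal(unname(res$state[3, ]), C)
})

test_that("a fully known homozygous parent forces its allele on the progeny", {
  P <- c("1","0","1","1")
  st <- family_state(P, P, list(c("1",NA,NA,NA), c("0","1",NA,NA)),
                     markers = paste0("m", 1:4))
  res <- resolve_family(st, single_family(2), params_default)
  expect_equal(unname(res$state[3, ]), P)             # compatible: completed
  expect_true(all(is.na(res$state[4, ])))             # conflicting: removed
  expect_true("SET_MISSING" %in% res$diagnostics$event)
  # over full iteration the removed slot is re-imputed with the obligate allele
  fin <- assign_block(st, list(single_family(2)), params_default)
  expect_equal(fin$status, "CONVERGED")
  expect_equal(unname(fin$state[4, ]), P)
})

test_that("a heterozygous parent is matched to its two progeny groups", {
  P1 <- c("1","0","1","1","0","0"); P2 <- c("0","1","0","0","1","1")
  st <- family_state(P1, P2,
                     list(c("1","0",NA,NA,NA,NA), c("1",NA,"1",NA,NA,NA),
                          c("0","1",NA,NA,NA,NA), c("0",NA,"0",NA,NA,NA)))
  res <- resolve_family(st, single_family(4), params_default)
  expect_equal(unname(res$state[3, ]), P1)
  expect_equal(unname(res$state[4, ]), P1)
  expect_equal(unname(res$state[5, ]), P2)
  expect_equal(unname(res$state[6, ]), P2)
})

test_that("an unmatched progeny group with support is promoted to a missing parental allele", {
  P1 <- c("1","0","1","1","0","0")
  st <- family_state(P1, rep(NA_character_, 6),
                     list(c("1","0",NA,NA,NA,NA),
                          c("0","1","0",NA,NA,NA), c("0","1",NA,"0",NA,NA)))
  res <- resolve_family(st, single_family(3), params_default)
  # the two children conflicting P1 prove the second parental allele
  expect_equal(unname(res$state[2, ]), c("0","1","0","0",NA,NA))
})

test_that("a progeny slot conflicting with both parental alleles is blanked", {
  P1 <- c("1","0","1","1"); P2 <- c("1","0","1","0")
  st <- family_state(P1, P2, list(c("0","1",NA,NA)),
                     markers = paste0("m", 1:4))
  res <- resolve_family(st, single_family(1), params_default)
  expect_true("SET_MISSING" %in% res$diagnostics$event)
  # obligate positions (parents agree) are refilled
  expect_equal(unname(res$state[3, ]), c("1","0","1",NA))
})

test_that("resolve_family logs every mutation exactly once", {
  C <- c("1","0","1","1","0","0")
  st <- family_state(rep(NA_character_, 6), rep(NA_character_, 6),
                     rep(list(C), 16))
  res <- resolve_family(st, single_family(16), params_default)
  moved <- sum(vapply(seq_len(nrow(st)), function(r)
    !identical(st[r, ], res$state[r, ]), logical(1)))
  expect_equal(nrow(res$diagnostics), moved)
})

test_that("a trio with homozygous genotyped parents imputes the obligate child alleles", {
  fit <- assign_haploblocks(trio_data(), hb_params(min_allele_count = 1))
  expect_equal(unname(fit$status["B1"]), "CONVERGED")
  g <- fit$genotypes
  child <- g[g$individual == "C", ]
  expect_false(is.na(child$allele_mat))
  expect_false(is.na(child$allele_pat))
  expect_equal(unname(fit$haplo["C|M", ]), c("1","0","1","1"))
  expect_equal(unname(fit$haplo["C|P", ]), c("0","1","0","0"))
  expect_true(all(fit$diagnostics$event %in%
                    c("IMPUTED", "UPDATED", "MARKER_DATA_DELETED")))
})

test_that("assign_block is idempotent on converged output", {
  sim <- simulate_dataset(sim_config(n_founders = 5, n_generations = 2,
                                     n_blocks = 3, error_rate = 0, seed = 17))
  fit <- assign_haploblocks(sim$data)
  fams <- family_descriptors(fit$pedigree)
  for (b in names(fit$blocks)) {
    st <- fit$haplo[, fit$blocks[[b]], drop = FALSE]
    again <- assign_block(st, fams, fit$params)
    expect_identical(again$state, st)
    if (fit$status[b] == "CONVERGED") expect_equal(nrow(again$diagnostics), 0L)
  }
})

test_that("max_iter = 0 reports non-convergence with all genotypes missing", {
  sim <- simulate_dataset(sim_config(n_founders = 4, n_generations = 1,
                                     n_blocks = 2, seed = 5))
  fit <- assign_haploblocks(sim$data, hb_params(max_iter = 0))
  expect_true(all(fit$status == "MAX_ITER"))
  expect_true(all(is.na(fit$genotypes$allele_mat)))
  expect_true(all(is.na(fit$genotypes$allele_pat)))
  expect_true("NON_CONVERGENCE" %in% fit$diagnostics$event)
})

test_that("marker data deleted in one family are re-imputed in a later pass", {
  markers <- paste0("m", 1:4)
  map <- data.frame(marker = markers, group = "LG1", position = 1:4)
  ped <- data.frame(id = c("M", "F", "X"), mother = c(NA, NA, "M"),
                    father = c(NA, NA, "F"))
  A <- c("1","1","1","1"); B <- c("0","0","0","0")
  haplo <- make_haplo(list(
    M = list(A, A),                       # homozygous, fully known
    F = list(B, B),
    X = list(c("0","1","1","1"), rep(NA_character_, 4))), markers)
  fit <- assign_haploblocks(haplo_data(map, list(B1 = markers), ped, haplo),
                            hb_params(min_allele_count = 1))
  ev <- fit$diagnostics[fit$diagnostics$subject == "X|M", ]
  expect_true("SET_MISSING" %in% ev$event)           # conflicting data removed
  expect_equal(unname(fit$haplo["X|M", ]), A)        # and re-imputed from M
  expect_equal(unname(fit$haplo["X|P", ]), B)
  expect_equal(unname(fit$status["B1"]), "CONVERGED")
})
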