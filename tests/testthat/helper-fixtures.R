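# Shared fixtures and brute-force oracles, all built in code.

# Seven haploblock alleles over six bi-allelic markers mirroring the worked
# grouping illustration: two groups (three alleles + one allele) and three
# alleles compatible with both groups.
h7_alleles <- function() {
  list(a1 = c("1", "0", "1", "1", "0", "0"),
       a2 = c("1", "0", "1", NA, NA, NA),
       a3 = c(NA, "0", "1", "1", "0", "0"),
       a4 = c("0", "1", "1", "0", NA, NA),
       a5 = c(NA, NA, "1", NA, NA, NA),
       a6 = c(NA, NA, "1", NA, "0", NA),
       a7 = c(NA, NA, "1", NA, NA, "0"))
}

# random haploblock alleles (members x markers), bi-allelic with missing data
random_members <- function(n, K, p_miss = 0.35) {
  m <- matrix(sample(c("0", "1"), n * K, replace = TRUE), n, K)
  m[matrix(stats::runif(n * K) < p_miss, n, K)] <- NA_character_
  m
}

# Brute-force check of a grouping result. Returns character(0) when all
# properties hold, else descriptions of the failures.
oracle_group_check <- function(mat, res) {
  fails <- character(0)
  n <- nrow(mat)
  seen <- c(unlist(lapply(res$groups, `[[`, "members")), res$ungrouped,
            res$all_missing)
  if (!setequal(seen, seq_len(n)) || length(seen) != n)
    fails <- c(fails, "members not partitioned")
  for (i in seq_len(n)) {
    obs <- sum(!is.na(mat[i, ]))
    if ((obs == 0L) != (i %in% res$all_missing))
      fails <- c(fails, paste("all_missing wrong for member", i))
  }
  cons <- lapply(res$groups, `[[`, "consensus")
  for (g in seq_along(res$groups)) {
    mem <- res$groups[[g]]$members
    for (a in mem) for (b in mem) if (a < b &&
        allele_compare(mat[a, ], mat[b, ]) == "incompatible")
      fails <- c(fails, paste("conflict inside group", g))
    # consensus = positionwise union of the members
    u <- apply(mat[mem, , drop = FALSE], 2, function(col) {
      v <- unique(col[!is.na(col)])
      if (length(v) == 1L) v else NA_character_
    })
    if (!identical(unname(u), unname(cons[[g]])))
      fails <- c(fails, paste("consensus not the union in group", g))
    for (a in mem) if (allele_compare(mat[a, ], cons[[g]]) != "compatible")
      fails <- c(fails, paste("member not compatible with consensus, group", g))
  }
  if (length(cons) > 1L)
    for (g in seq_along(cons)) for (h in seq_along(cons)) if (g < h &&
        allele_compare(cons[[g]], cons[[h]]) != "incompatible")
      fails <- c(fails, paste("consensuses", g, h, "not incompatible"))
  for (i in res$ungrouped) {
    rel <- vapply(cons, function(cv) allele_compare(mat[i, ], cv), character(1))
    n_comp <- sum(rel == "compatible")
    if (!(n_comp >= 2L || n_comp == 0L))
      fails <- c(fails, paste("member", i, "ungrouped but matches one group"))
    if (length(cons) && all(rel == "incompatible"))
      fails <- c(fails, paste("member", i, "ungrouped but conflicts all groups"))
  }
  fails
}

# haplotype matrix from a named list: list(A = list(mat, pat), ...)
make_haplo <- function(x, markers) {
  m <- matrix(NA_character_, 2L * length(x), length(markers),
              dimnames = list(paste0(rep(names(x), each = 2L), c("|M", "|P")),
                              markers))
  for (i in seq_along(x)) {
    m[2L * i - 1L, ] <- x[[i]][[1L]]
    m[2L * i, ] <- x[[i]][[2L]]
  }
  m
}

# a trio dataset: two fully genotyped homozygous founders, child all missing
trio_data <- function() {
  markers <- paste0("m", 1:4)
  map <- data.frame(marker = markers, group = "LG1", position = 1:4)
  blocks <- list(B1 = markers)
  ped <- data.frame(id = c("A", "B", "C"),
                    mother = c(NA, NA, "A"),
                    father = c(NA, NA, "B"))
  haplo <- make_haplo(list(
    A = list(c("1", "0", "1", "1"), c("1", "0", "1", "1")),
    B = list(c("0", "1", "0", "0"), c("0", "1", "0", "0")),
    C = list(rep(NA_character_, 4), rep(NA_character_, 4))), markers)
  haplo_data(map, blocks, ped, haplo)
}

# family descriptor for a synthetic single-family state matrix in which the
# parent occupies rows 1:2 and the n members rows 3:(n + 2)
single_family <- function(n_members, block_id = "B1") {
  list(parent_rows = c(1L, 2L), member_rows = 2L + seq_len(n_members),
       member_labels = sprintf("child%02d|M", seq_len(n_members)),
       member_keys = sprintf("child%02d|0", seq_len(n_members)),
       parent_id = "parent", block_id = block_id)
}

# state matrix for single_family(): parent alleles + list of member alleles
family_state <- function(p1, p2, members, markers = paste0("m", seq_along(p1))) {
  rows <- c(list(p1, p2), members)
  m <- do.call(rbind, rows)
  dimnames(m) <- list(c("parent|M", "parent|P",
                        sprintf("child%02d|M", seq_along(members))), markers)
  m
}
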