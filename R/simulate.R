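#' Configuration for the gene-drop simulator
#'
#' The simulator emulates the data the assignment engine is designed for:
#' a multi-generation pedigree genotyped for map-contiguous haploblocks of
#' bi-allelic markers, phased, with block-wise transmission (no recombination
#' within a block except, optionally, in the final generation) plus
#' missing-data and genotyping-error corruption.
#'
#' @param n_founders Number of founders (>= 1).
#' @param n_generations Number of crossing generations after the founders.
#' @param offspring_per_cross Offspring per cross. Crosses are a deterministic
#'   round-robin over the previous generation (parent j x parent j+1,
#'   wrapping; two parents form a single cross, a single parent selfs), so
#'   each generation is about `offspring_per_cross` times larger than the
#'   previous one. When the last parental generation has at least four
#'   members, the final generation additionally contains one selfed offspring
#'   and one offspring with unknown father, to exercise those pedigree
#'   structures.
#' @param n_blocks,markers_per_block Haploblock layout; all blocks on one
#'   linkage group, markers contiguous.
#' @param founder_allele_freq Per-marker probability of allele `"A"` (vs
#'   `"B"`) when drawing founder haplotypes.
#' @param missing_rate,error_rate Per-call corruption probabilities applied to
#'   the observed (not the truth) data.
#' @param final_gen_recomb_rate Probability that a transmission into the final
#'   generation splices the two parental block haplotypes at a uniform
#'   internal breakpoint instead of copying one of them.
#' @param seed Integer; fixes all randomness of the simulation.
#' @return An object of class `hb_sim_config`.
#' @export
sim_config <- function(n_founders = 6, n_generations = 3, offspring_per_cross = 2,
                       n_blocks = 20, markers_per_block = 6,
                       founder_allele_freq = 0.5, missing_rate = 0.1,
                       error_rate = 0.01, final_gen_recomb_rate = 0,
                       seed = 1L) {
  counts <- c(n_founders = n_founders, n_generations = n_generations + 1,
              offspring_per_cross = offspring_per_cross,
              n_blocks = n_blocks, markers_per_block = markers_per_block)
  for (nm in names(counts))
    if (!is.numeric(counts[[nm]]) || counts[[nm]] < 1 || counts[[nm]] != round(counts[[nm]]))
      stop(sprintf("invalid count for %s", nm), call. = FALSE)
  probs <- c(founder_allele_freq = founder_allele_freq,
             missing_rate = missing_rate, error_rate = error_rate,
             final_gen_recomb_rate = final_gen_recomb_rate)
  for (nm in names(probs))
    if (!is.numeric(probs[[nm]]) || is.na(probs[[nm]]) ||
        probs[[nm]] < 0 || probs[[nm]] > 1)
      stop(sprintf("'%s' must be a probability in [0, 1]", nm), call. = FALSE)
  structure(list(n_founders = as.integer(n_founders),
                 n_generations = as.integer(n_generations),
                 offspring_per_cross = as.integer(offspring_per_cross),
                 n_blocks = as.integer(n_blocks),
                 markers_per_block = as.integer(markers_per_block),
                 founder_allele_freq = founder_allele_freq,
                 missing_rate = missing_rate, error_rate = error_rate,
                 final_gen_recomb_rate = final_gen_recomb_rate,
                 seed = as.integer(seed)),
            class = "hb_sim_config")
}

#' Generate a deterministic multi-generation pedigree
#'
#' Founders `F01..`, then `n_generations` of round-robin crosses among the
#' previous generation. The final generation includes one selfed offspring
#' and one offspring with unknown father whenever the previous generation has
#' at least two members. The structure depends only on the size parameters.
#'
#' @param config An [sim_config()] object.
#' @return A pedigree data.frame (`id`, `mother`, `father`).
#' @export
sim_pedigree <- function(config) {
  id <- sprintf("F%02d", seq_len(config$n_founders))
  mother <- father <- rep(NA_character_, config$n_founders)
  prev <- id
  for (g in seq_len(config$n_generations)) {
    np <- length(prev)
    n_crosses <- if (np <= 2L) 1L else np
    gen_ids <- character(0)
    for (j in seq_len(n_crosses)) {
      mo <- prev[j]
      fa <- if (np == 1L) prev[j] else prev[if (j == np) 1L else j + 1L]
      for (k in seq_len(config$offspring_per_cross)) {
        cid <- sprintf("G%d_%03d", g, length(gen_ids) + 1L)
        gen_ids <- c(gen_ids, cid)
        id <- c(id, cid); mother <- c(mother, mo); father <- c(father, fa)
      }
    }
    if (g == config$n_generations && np >= 4L) {
      id <- c(id, sprintf("G%d_self", g))
      mother <- c(mother, prev[1L]); father <- c(father, prev[1L])
      id <- c(id, sprintf("G%d_half", g))
      mother <- c(mother, prev[2L]); father <- c(father, NA_character_)
    }
    prev <- gen_ids
  }
  data.frame(id = id, mother = mother, father = father, stringsAsFactors = FALSE)
}

#' Drop founder haplotypes through a pedigree
#'
#' Draws founder block haplotypes marker-wise (`"A"` with probability
#' `founder_allele_freq`) and copies, for every transmission, one whole
#' parental block haplotype chosen uniformly — the haploblock assumption.
#' With probability `final_gen_recomb_rate` a transmission into the final
#' generation instead splices the two parental haplotypes at a uniform
#' internal breakpoint and is flagged recombinant. A slot with unknown parent
#' receives a fresh founder-style haplotype.
#'
#' @param pedigree A pedigree data.frame (validated or not; it is validated).
#' @param config An [sim_config()] object (`seed` fixes all randomness).
#' @return A list of class `hb_truth`: `haplo` (complete truth matrix, two
#'   rows per individual), `transmissions` (data.frame `individual`, `slot`,
#'   `block`, `source_hap` (1, 2 or `NA` for founder draws), `recombinant`),
#'   and `blocks`/`map` describing the marker layout.
#' @export
gene_drop <- function(pedigree, config) {
  ped <- validate_pedigree(pedigree)
  set.seed(config$seed)
  nb <- config$n_blocks; K <- config$markers_per_block
  markers <- as.vector(vapply(seq_len(nb), function(b)
    sprintf("B%02dM%d", b, seq_len(K)), character(K)))
  map <- data.frame(marker = markers, group = "LG1",
                    position = round(seq_along(markers) * 0.5, 3),
                    stringsAsFactors = FALSE)
  blocks <- lapply(seq_len(nb), function(b) markers[((b - 1L) * K + 1L):(b * K)])
  names(blocks) <- sprintf("B%02d", seq_len(nb))

  ids <- ped$id
  n <- length(ids)
  M <- nb * K
  haplo <- matrix(NA_character_, 2L * n, M,
                  dimnames = list(paste0(rep(ids, each = 2L), c("|M", "|P")),
                                  markers))
  # final generation = individuals whose offspring count is zero and that are
  # not founders, identified structurally as the maximum depth layer
  depth <- integer(n); names(depth) <- ids
  for (i in seq_len(n)) {
    ps <- c(ped$mother[i], ped$father[i])
    ps <- ps[!is.na(ps)]
    depth[i] <- if (length(ps)) max(depth[ps]) + 1L else 0L
  }
  final_gen <- depth == max(depth) & max(depth) > 0L

  draw_founder_hap <- function()
    ifelse(stats::runif(M) < config$founder_allele_freq, "A", "B")

  nt_max <- 2L * n * nb
  t_ind <- character(nt_max); t_slot <- character(nt_max)
  t_blk <- character(nt_max); t_src <- integer(nt_max); t_rec <- logical(nt_max)
  ti <- 0L
  for (i in seq_len(n)) {
    for (s in 1:2) {
      row <- 2L * i - 2L + s
      parent <- if (s == 1L) ped$mother[i] else ped$father[i]
      if (is.na(parent)) {
        haplo[row, ] <- draw_founder_hap()
        next
      }
      pi <- match(parent, ids)
      h1 <- haplo[2L * pi - 1L, ]; h2 <- haplo[2L * pi, ]
      for (b in seq_len(nb)) {
        cols <- ((b - 1L) * K + 1L):(b * K)
        recomb <- final_gen[i] && K > 1L &&
          stats::runif(1) < config$final_gen_recomb_rate
        if (recomb) {
          bp <- sample.int(K - 1L, 1L)
          first <- if (stats::runif(1) < 0.5) 1L else 2L
          a <- if (first == 1L) h1[cols] else h2[cols]
          z <- if (first == 1L) h2[cols] else h1[cols]
          haplo[row, cols] <- c(a[seq_len(bp)], z[(bp + 1L):K])
          src <- NA_integer_
        } else {
          src <- if (stats::runif(1) < 0.5) 1L else 2L
          haplo[row, cols] <- if (src == 1L) h1[cols] else h2[cols]
        }
        ti <- ti + 1L
        t_ind[ti] <- ids[i]
        t_slot[ti] <- if (s == 1L) "M" else "P"
        t_blk[ti] <- names(blocks)[b]
        t_src[ti] <- src
        t_rec[ti] <- recomb
      }
    }
  }
  keep <- seq_len(ti)
  transmissions <- data.frame(individual = t_ind[keep], slot = t_slot[keep],
                              block = t_blk[keep], source_hap = t_src[keep],
                              recombinant = t_rec[keep],
                              stringsAsFactors = FALSE)
  structure(list(haplo = haplo, transmissions = transmissions,
                 map = map, blocks = blocks, pedigree = ped),
            class = "hb_truth")
}

#' Corrupt phased marker calls with missing data and genotyping errors
#'
#' Each call is independently set missing with probability `missing_rate`;
#' otherwise it is flipped to a different allele symbol of its marker with
#' probability `error_rate` (for a bi-allelic marker, the other symbol; for a
#' multi-allelic marker, a uniform draw among the other observed symbols; a
#' monomorphic marker cannot be flipped). The input is not modified.
#'
#' @param haplo Truth haplotype matrix.
#' @param missing_rate,error_rate Probabilities in `[0, 1]`.
#' @param seed Integer seed.
#' @return A corrupted copy of `haplo`.
#' @export
corrupt_calls <- function(haplo, missing_rate, error_rate, seed) {
  for (r in c(missing_rate, error_rate))
    if (!is.numeric(r) || is.na(r) || r < 0 || r > 1)
      stop("rates must be probabilities in [0, 1]", call. = FALSE)
  set.seed(seed)
  out <- haplo
  miss <- matrix(stats::runif(length(out)) < missing_rate, nrow(out))
  err <- matrix(stats::runif(length(out)) < error_rate, nrow(out)) & !miss
  for (k in seq_len(ncol(out))) {
    syms <- sort(unique(out[, k][!is.na(out[, k])]))
    if (length(syms) < 2L) next
    ek <- which(err[, k] & !is.na(out[, k]))
    for (i in ek) {
      others <- setdiff(syms, out[i, k])
      out[i, k] <- if (length(others) == 1L) others else
        others[sample.int(length(others), 1L)]
    }
  }
  out[miss] <- NA_character_
  out
}

#' Simulate a complete haploblock dataset with hidden truth
#'
#' Runs [sim_pedigree()], [gene_drop()] and [corrupt_calls()] under one seed
#' and packages the observed data as an [haplo_data()] object ready for
#' [assign_haploblocks()], keeping the uncorrupted truth alongside.
#'
#' @param config An [sim_config()] object.
#' @return A list of class `hb_sim`: `data` (observed, an `hb_data`),
#'   `truth` (an `hb_truth`), `config`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_founders = 4, n_generations = 2, seed = 3))
#' sim$data
#' @export
simulate_dataset <- function(config) {
  ped <- sim_pedigree(config)
  truth <- gene_drop(ped, config)
  observed <- corrupt_calls(truth$haplo, config$missing_rate,
                            config$error_rate, config$seed + 1L)
  data <- haplo_data(map = truth$map, blocks = truth$blocks,
                     pedigree = ped, haplo = observed)
  structure(list(data = data, truth = truth, config = config),
            class = "hb_sim")
}

#' Write a simulated dataset as the standard input files
#'
#' Writes `map.txt`, `blocks.txt`, `pedigree.txt`, `genotypes.txt` (observed)
#' and `truth_genotypes.txt` (uncorrupted) into `dir`. The first four
#' round-trip through [read_haplo_data()].
#'
#' @param sim An `hb_sim` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sim_data <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- sim$data
  p <- c(map = file.path(dir, "map.txt"),
         blocks = file.path(dir, "blocks.txt"),
         pedigree = file.path(dir, "pedigree.txt"),
         genotypes = file.path(dir, "genotypes.txt"),
         truth = file.path(dir, "truth_genotypes.txt"))
  .write_tsv(d$map, p[["map"]])
  .write_tsv(data.frame(block = rep(names(d$blocks), lengths(d$blocks)),
                        marker = unlist(d$blocks, use.names = FALSE),
                        stringsAsFactors = FALSE), p[["blocks"]])
  ped_out <- d$pedigree
  ped_out$mother[is.na(ped_out$mother)] <- "0"
  ped_out$father[is.na(ped_out$father)] <- "0"
  .write_tsv(ped_out, p[["pedigree"]])
  write_genotype_file(d$haplo, p[["genotypes"]])
  write_genotype_file(sim$truth$haplo, p[["truth"]])
  invisible(p)
}

#' Standard simulation battery configurations
#'
#' A fixed battery of seeded simulation scenarios used to validate the engine:
#' 50 configurations spanning two to four generations (up to about 200
#' individuals), 20 blocks of 6 markers, missing rates up to 0.2 and error
#' rates up to 0.02; half the configurations are error-free so that
#' imputation against the hidden truth can be audited under pure missingness.
#'
#' @param n Number of configurations (default 50).
#' @param seed_base Offset added to each configuration's index to form its
#'   seed.
#' @return A list of [sim_config()] objects.
#' @export
sim_battery_configs <- function(n = 50, seed_base = 1000L) {
  shapes <- list(
    list(n_founders = 6, n_generations = 3, offspring_per_cross = 2),  # 90 + 2
    list(n_founders = 4, n_generations = 4, offspring_per_cross = 2),  # 124 + 2
    list(n_founders = 8, n_generations = 3, offspring_per_cross = 2),  # 120 + 2
    list(n_founders = 5, n_generations = 2, offspring_per_cross = 3),  # 65 + 2
    list(n_founders = 6, n_generations = 4, offspring_per_cross = 2))  # 186 + 2
  miss <- c(0.05, 0.1, 0.2)
  errs <- c(0.01, 0.02)
  lapply(seq_len(n), function(i) {
    sh <- shapes[[(i - 1L) %% length(shapes) + 1L]]
    e <- if (i %% 2L == 0L) 0 else errs[[(i - 1L) %/% 2L %% length(errs) + 1L]]
    sim_config(n_founders = sh$n_founders, n_generations = sh$n_generations,
               offspring_per_cross = sh$offspring_per_cross,
               n_blocks = 20, markers_per_block = 6,
               missing_rate = miss[[(i - 1L) %% length(miss) + 1L]],
               error_rate = e,
               final_gen_recomb_rate = 0,
               seed = seed_base + i)
  })
}
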