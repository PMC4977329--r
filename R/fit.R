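#' Assign consistent phased haploblock genotypes to a pedigree
#'
#' The main entry point. For each haploblock, the phased marker data are
#' condensed into haploblock alleles (one allele per distinct marker-haplotype
#' sequence), and an iterative process over the pedigree's half-sib families
#' imputes missing marker data, updates partially observed alleles and rejects
#' conflicting data until every transmitted allele is consistent between
#' parent and offspring. Blocks are processed independently. Low-frequency
#' markers are rejected beforehand (see [filter_markers()]); a block losing
#' all its markers is dropped with a diagnostic. Haploblock genotypes are only
#' assigned for blocks that reached convergence; a block hitting the iteration
#' cap has all its genotypes set missing.
#'
#' @param data An [haplo_data()] object.
#' @param params An [hb_params()] object.
#'
#' @return An object of class `hb_fit` with components:
#' \describe{
#'   \item{genotypes}{data.frame `individual`, `block`, `allele_mat`,
#'     `allele_pat` (integer allele numbers, `NA` missing).}
#'   \item{catalogs}{named list (per block) of allele composition tables.}
#'   \item{haplo}{final phased marker matrix (retained markers only).}
#'   \item{status}{named character: `"CONVERGED"`, `"CYCLE_CONVERGED"` or
#'     `"MAX_ITER"` per block.}
#'   \item{iterations}{named integer, passes used per block.}
#'   \item{diagnostics}{data.frame of all logged events, chronological.}
#'   \item{blocks, map, pedigree, params, observed}{inputs as used (blocks
#'     after marker filtering; `observed` is the input marker matrix restricted
#'     to retained markers).}
#' }
#' @examples
#' sim <- simulate_dataset(sim_config(n_founders = 4, n_generations = 2,
#'                                    n_blocks = 2, seed = 7))
#' fit <- assign_haploblocks(sim$data)
#' fit
#' @export
assign_haploblocks <- function(data, params = hb_params()) {
  if (!inherits(data, "hb_data"))
    stop("data must be an 'hb_data' object (see haplo_data())", call. = FALSE)
  diag_list <- list()

  flt <- filter_markers(data$haplo, params$min_allele_count)
  marker_block <- rep(names(data$blocks), lengths(data$blocks))
  names(marker_block) <- unlist(data$blocks, use.names = FALSE)
  if (nrow(flt$diagnostics)) {
    d <- flt$diagnostics
    d$block_id <- unname(marker_block[d$subject])
    diag_list[[length(diag_list) + 1L]] <- d
  }
  blocks <- lapply(data$blocks, function(mk) mk[mk %in% flt$retained])
  dropped <- names(blocks)[lengths(blocks) == 0L]
  for (b in dropped)
    diag_list[[length(diag_list) + 1L]] <- data.frame(
      block_id = b, subject = b, event = "MARKER_FILTERED",
      detail = "block dropped: no markers retained", stringsAsFactors = FALSE)
  blocks <- blocks[lengths(blocks) > 0L]

  ped <- data$pedigree
  ids <- ped$id
  fam_desc <- family_descriptors(ped)

  retained <- unlist(blocks, use.names = FALSE)
  haplo <- data$haplo[, retained, drop = FALSE]
  genos <- list()
  catalogs <- list()
  status <- character(0)
  iters <- integer(0)
  for (b in names(blocks)) {
    bm <- blocks[[b]]
    st <- data$haplo[, bm, drop = FALSE]
    fd <- lapply(fam_desc, function(f) { f$block_id <- b; f })
    res <- assign_block(st, fd, params)
    status[b] <- res$status
    iters[b] <- res$iterations
    if (nrow(res$diagnostics))
      diag_list[[length(diag_list) + 1L]] <- res$diagnostics
    haplo[, bm] <- res$state
    cat_b <- catalog_alleles(res$state)
    catalogs[[b]] <- cat_b$composition
    genos[[b]] <- data.frame(
      individual = ids, block = b,
      allele_mat = cat_b$assignment[seq(1L, length(ids) * 2L, by = 2L)],
      allele_pat = cat_b$assignment[seq(2L, length(ids) * 2L, by = 2L)],
      stringsAsFactors = FALSE)
  }
  genotypes <- if (length(genos)) do.call(rbind, genos) else
    data.frame(individual = character(0), block = character(0),
               allele_mat = integer(0), allele_pat = integer(0))
  rownames(genotypes) <- NULL
  diagnostics <- if (length(diag_list)) do.call(rbind, diag_list) else .empty_diag()
  rownames(diagnostics) <- NULL

  structure(list(
    genotypes = genotypes, catalogs = catalogs, haplo = haplo,
    status = status, iterations = iters, diagnostics = diagnostics,
    blocks = blocks, map = data$map, pedigree = ped, params = params,
    observed = data$haplo[, retained, drop = FALSE]
  ), class = "hb_fit")
}

#' @export
print.hb_fit <- function(x, ...) {
  st <- table(factor(x$status, levels = c("CONVERGED", "CYCLE_CONVERGED", "MAX_ITER")))
  cat(sprintf("Haploblock assignment: %d block(s), %d individuals\n",
              length(x$blocks), nrow(x$pedigree)))
  cat(sprintf("  converged: %d  cycle-converged: %d  not converged: %d\n",
              st[["CONVERGED"]], st[["CYCLE_CONVERGED"]], st[["MAX_ITER"]]))
  cat(sprintf("  missing haploblock alleles: %.1f%%\n",
              100 * mean(is.na(c(x$genotypes$allele_mat, x$genotypes$allele_pat)))))
  cat(sprintf("  diagnostics logged: %d event(s)\n", nrow(x$diagnostics)))
  invisible(x)
}

#' Per-block summary of a haploblock assignment
#'
#' @param object An `hb_fit` object.
#' @param ... Unused.
#' @return A data.frame with one row per block: marker count, number of
#'   distinct alleles, convergence status, iterations, and the fraction of
#'   missing haploblock alleles.
#' @export
summary.hb_fit <- function(object, ...) {
  out <- data.frame(
    block = names(object$blocks),
    n_markers = lengths(object$blocks),
    n_alleles = vapply(object$catalogs, nrow, integer(1))[names(object$blocks)],
    status = object$status[names(object$blocks)],
    iterations = object$iterations[names(object$blocks)],
    stringsAsFactors = FALSE)
  miss <- vapply(names(object$blocks), function(b) {
    g <- object$genotypes[object$genotypes$block == b, ]
    mean(is.na(c(g$allele_mat, g$allele_pat)))
  }, numeric(1))
  out$frac_missing <- miss
  rownames(out) <- NULL
  class(out) <- c("summary.hb_fit", "data.frame")
  out
}
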