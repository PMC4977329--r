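# Evaluation of engine output: informativeness, imputation accuracy against a
# simulator truth set, and a Mendelian consistency audit.

# transmissions per block: data.frame(child_row, parent_row1, parent_row2)
.block_transmissions <- function(pedigree) {
  ids <- pedigree$id
  out <- list()
  for (i in seq_along(ids)) {
    for (s in 1:2) {
      parent <- if (s == 1L) pedigree$mother[i] else pedigree$father[i]
      if (is.na(parent)) next
      pi <- match(parent, ids)
      out[[length(out) + 1L]] <- c(child_row = 2L * i - 2L + s,
                                   p1 = 2L * pi - 1L, p2 = 2L * pi)
    }
  }
  if (!length(out)) return(data.frame(child_row = integer(0), p1 = integer(0),
                                      p2 = integer(0)))
  as.data.frame(do.call(rbind, out))
}

#' Fraction of informative meioses
#'
#' A meiosis (one parent-to-offspring transmission, i.e. one child slot with a
#' known parent) is *informative* at a locus when the transmitting parent is
#' heterozygous there. At block level a parent is heterozygous when its two
#' haploblock alleles differ; at marker level when its two haplotypes carry
#' different observed codes at that marker. Both levels use the same
#' denominator — transmissions whose parent has two not-entirely-missing block
#' haplotypes — so that within every block the per-marker fraction can never
#' exceed the block fraction. The marker-level result is the unweighted mean
#' over markers, the block-level result the unweighted mean over blocks.
#'
#' @param fit An `hb_fit` object.
#' @param level `"block"` or `"marker"`.
#' @return A single proportion, or `NA` if there are no transmissions with a
#'   genotyped parent.
#' @export
informative_fraction <- function(fit, level = c("block", "marker")) {
  level <- match.arg(level)
  tr <- .block_transmissions(fit$pedigree)
  if (!nrow(tr)) return(NA_real_)
  block_fracs <- numeric(0)
  marker_fracs <- numeric(0)
  for (b in names(fit$blocks)) {
    bm <- fit$blocks[[b]]
    st <- fit$haplo[, bm, drop = FALSE]
    p1m <- st[tr$p1, , drop = FALSE]
    p2m <- st[tr$p2, , drop = FALSE]
    genotyped <- rowSums(!is.na(p1m)) > 0L & rowSums(!is.na(p2m)) > 0L
    D <- sum(genotyped)
    if (D == 0L) next
    g <- fit$genotypes[fit$genotypes$block == b, ]
    a_mat <- g$allele_mat[match(fit$pedigree$id, g$individual)]
    a_pat <- g$allele_pat[match(fit$pedigree$id, g$individual)]
    allele_of_row <- function(rows) ifelse(rows %% 2L == 1L,
                                           a_mat[(rows + 1L) %/% 2L],
                                           a_pat[rows %/% 2L])
    pa1 <- allele_of_row(tr$p1)[genotyped]
    pa2 <- allele_of_row(tr$p2)[genotyped]
    het_block <- !is.na(pa1) & !is.na(pa2) & pa1 != pa2
    block_fracs <- c(block_fracs, sum(het_block) / D)
    for (k in seq_along(bm)) {
      v1 <- p1m[genotyped, k]; v2 <- p2m[genotyped, k]
      het_k <- !is.na(v1) & !is.na(v2) & v1 != v2
      marker_fracs <- c(marker_fracs, sum(het_k) / D)
    }
  }
  if (level == "block") {
    if (!length(block_fracs)) return(NA_real_)
    mean(block_fracs)
  } else {
    if (!length(marker_fracs)) return(NA_real_)
    mean(marker_fracs)
  }
}

#' Classify imputations against the simulator truth
#'
#' Considers every marker call that was missing or erroneous in the observed
#' data and classifies its final (post-engine) value: `imputed_correct` if it
#' now equals the truth, `imputed_wrong` if it is non-missing and differs,
#' `still_missing` otherwise.
#'
#' @param truth,observed,final Haplotype matrices with identical row and
#'   column names (`final`'s columns — the retained markers — select the
#'   columns compared).
#' @return A list with counts `imputed_correct`, `imputed_wrong`,
#'   `still_missing`.
#' @export
imputation_accuracy <- function(truth, observed, final) {
  cols <- colnames(final)
  rows <- rownames(final)
  if (!all(cols %in% colnames(truth)) || !all(rows %in% rownames(truth)) ||
      !all(cols %in% colnames(observed)) || !all(rows %in% rownames(observed)))
    stop("truth/observed/final are not aligned", call. = FALSE)
  tt <- truth[rows, cols, drop = FALSE]
  oo <- observed[rows, cols, drop = FALSE]
  needs <- is.na(oo) | (!is.na(oo) & oo != tt)
  f <- final[needs]; t0 <- tt[needs]
  list(imputed_correct = sum(!is.na(f) & f == t0),
       imputed_wrong = sum(!is.na(f) & f != t0),
       still_missing = sum(is.na(f)))
}

#' Audit Mendelian consistency of haploblock genotypes
#'
#' Counts (child, slot, block) combinations in which the child carries a
#' non-missing haploblock allele, the transmitting parent is fully genotyped
#' (two non-missing alleles), and the child's allele matches neither parental
#' allele. Without a catalog, "matches" is identity of allele numbers (the
#' strict view, under which alleles differing only in missing marker data
#' count as different). With the fit's allele catalogs, a violation requires
#' the child's allele to carry an observed marker code conflicting with both
#' parental alleles — the consistency the engine guarantees on converged
#' blocks.
#'
#' @param genotypes data.frame `individual`, `block`, `allele_mat`,
#'   `allele_pat` (allele numbers, `NA` missing).
#' @param pedigree Pedigree data.frame.
#' @param catalogs Optional named list of per-block allele composition tables
#'   (as in `fit$catalogs`).
#' @return Integer count of violations.
#' @export
consistency_audit <- function(genotypes, pedigree, catalogs = NULL) {
  ped <- validate_pedigree(pedigree)
  viol <- 0L
  for (b in unique(genotypes$block)) {
    g <- genotypes[genotypes$block == b, ]
    am <- g$allele_mat[match(ped$id, g$individual)]
    ap <- g$allele_pat[match(ped$id, g$individual)]
    comp <- if (!is.null(catalogs)) catalogs[[b]] else NULL
    vec_of <- function(num) unlist(comp[comp$allele == num, -1, drop = TRUE])
    for (i in seq_along(ped$id)) {
      for (s in 1:2) {
        parent <- if (s == 1L) ped$mother[i] else ped$father[i]
        if (is.na(parent)) next
        child_allele <- if (s == 1L) am[i] else ap[i]
        if (is.na(child_allele)) next
        pi <- match(parent, ped$id)
        pa <- c(am[pi], ap[pi])
        if (any(is.na(pa))) next
        if (child_allele %in% pa) next
        if (is.null(comp)) {
          viol <- viol + 1L
        } else {
          cv <- vec_of(child_allele)
          if (.conflicts(cv, vec_of(pa[1L])) && .conflicts(cv, vec_of(pa[2L])))
            viol <- viol + 1L
        }
      }
    }
  }
  viol
}

#' Evaluate a haploblock assignment against the simulator truth
#'
#' @param fit An `hb_fit` object.
#' @param sim The `hb_sim` object the fit was computed from.
#' @return A list of class `hb_eval`: imputation counts (see
#'   [imputation_accuracy()]), `violations` (consistency audit over converged
#'   blocks, catalog-based), `informative_fraction_marker`,
#'   `informative_fraction_block`, and the per-block `status`.
#' @export
evaluate_assignment <- function(fit, sim) {
  acc <- imputation_accuracy(sim$truth$haplo, fit$observed, fit$haplo)
  converged <- names(fit$status)[fit$status != "MAX_ITER"]
  gt <- fit$genotypes[fit$genotypes$block %in% converged, , drop = FALSE]
  viol <- consistency_audit(gt, fit$pedigree, fit$catalogs)
  structure(c(acc, list(
    violations = viol,
    informative_fraction_marker = informative_fraction(fit, "marker"),
    informative_fraction_block = informative_fraction(fit, "block"),
    status = fit$status)), class = "hb_eval")
}

#' @export
print.hb_eval <- function(x, ...) {
  cat("Assignment evaluation against truth:\n")
  cat(sprintf("  imputed correct : %d\n", x$imputed_correct))
  cat(sprintf("  imputed wrong   : %d\n", x$imputed_wrong))
  cat(sprintf("  still missing   : %d\n", x$still_missing))
  cat(sprintf("  consistency violations (converged blocks): %d\n", x$violations))
  cat(sprintf("  informative meioses: %.1f%% per marker, %.1f%% per block\n",
              100 * x$informative_fraction_marker,
              100 * x$informative_fraction_block))
  invisible(x)
}
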