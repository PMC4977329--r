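#' Engine parameters for haploblock assignment
#'
#' Collects the tunable parameters of the half-sib-family resolution engine.
#' The algorithm itself is deterministic; none of these interact with the
#' random number generator.
#'
#' @param homozygous_family_min Minimum number of half-sib family members
#'   required before a single allele group in the progeny is taken as evidence
#'   that the shared parent is homozygous. Default 15.
#' @param min_allele_count Marker frequency threshold: for polymorphic markers,
#'   every observed marker allele must occur at least this many times over all
#'   haplotypes (two per diploid individual) or the marker is rejected from its
#'   block. Default 3.
#' @param max_iter Maximum number of passes over the half-sib families for one
#'   block before the block is declared non-converged. Default 100.
#' @param min_group_support Minimum number of members an allele group without a
#'   matching parental allele needs before its consensus may be promoted to a
#'   parental allele. Default 2.
#' @param include_missing_count_in_names If `TRUE`, haploblock allele names
#'   carry a `_m<k>` suffix giving the number of markers with missing values in
#'   the allele (e.g. `"5_m2"`). Default `FALSE`.
#'
#' @return An object of class `hb_params` (a named list).
#' @examples
#' hb_params(max_iter = 50)
#' @export
hb_params <- function(homozygous_family_min = 15,
                      min_allele_count = 3,
                      max_iter = 100,
                      min_group_support = 2,
                      include_missing_count_in_names = FALSE) {
  counts <- c(homozygous_family_min = homozygous_family_min,
              min_allele_count = min_allele_count,
              min_group_support = min_group_support)
  for (nm in names(counts)) {
    v <- counts[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 || v != round(v))
      stop(sprintf("'%s' must be a single integer >= 1", nm), call. = FALSE)
  }
  if (!is.numeric(max_iter) || length(max_iter) != 1L || is.na(max_iter) ||
      max_iter < 0 || max_iter != round(max_iter))
    stop("'max_iter' must be a single non-negative integer", call. = FALSE)
  structure(list(
    homozygous_family_min = as.integer(homozygous_family_min),
    min_allele_count = as.integer(min_allele_count),
    max_iter = as.integer(max_iter),
    min_group_support = as.integer(min_group_support),
    include_missing_count_in_names = isTRUE(include_missing_count_in_names)
  ), class = "hb_params")
}

#' @export
print.hb_params <- function(x, ...) {
  cat("Haploblock engine parameters:\n")
  cat(sprintf("  homozygous family threshold : %d members\n", x$homozygous_family_min))
  cat(sprintf("  marker allele count minimum : %d\n", x$min_allele_count))
  cat(sprintf("  maximum iterations per block: %d\n", x$max_iter))
  cat(sprintf("  group support for promotion : %d\n", x$min_group_support))
  cat(sprintf("  missing-count allele names  : %s\n",
              if (x$include_missing_count_in_names) "on" else "off"))
  invisible(x)
}
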