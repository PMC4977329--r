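#' Assemble and cross-validate a haploblock dataset
#'
#' Bundles the four inputs of the assignment engine — linkage map, haploblock
#' definitions, pedigree and phased marker genotypes — into a single validated
#' object. Checks that individuals and markers are consistent between the
#' components and that every haploblock is composed of contiguous markers of
#' one linkage group, in map order.
#'
#' @param map data.frame with columns `marker`, `group`, `position` (cM);
#'   marker ids unique, positions non-decreasing within a linkage group.
#' @param blocks Named list mapping block id to an ordered character vector of
#'   marker ids, or a data.frame with columns `block`, `marker` (one row per
#'   marker, in block order).
#' @param pedigree data.frame with columns `id`, `mother`, `father`
#'   (`NA`, `"0"` or empty = unknown parent).
#' @param haplo Phased marker genotypes: a character matrix with two rows per
#'   genotyped individual named `"<id>|M"` (allele inherited from the mother)
#'   and `"<id>|P"` (from the father), one column per marker, `NA` = missing.
#'   Pedigree individuals without rows are retained with all-missing data;
#'   rows for individuals absent from the pedigree are an error.
#'
#' @return An object of class `hb_data`: a list with the validated `map`,
#'   `blocks` (named list), `pedigree` (topologically ordered) and `haplo`
#'   (two rows per pedigree individual, pedigree order).
#' @seealso [read_haplo_data()], [simulate_dataset()]
#' @export
haplo_data <- function(map, blocks, pedigree, haplo) {
  # --- map ---
  if (!is.data.frame(map) || !all(c("marker", "group", "position") %in% names(map)))
    stop("map must have columns marker, group, position", call. = FALSE)
  map <- data.frame(marker = as.character(map$marker),
                    group = as.character(map$group),
                    position = as.numeric(map$position),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(map$marker))
    stop("duplicated marker in map: ", map$marker[duplicated(map$marker)][1L],
         call. = FALSE)
  for (g in unique(map$group)) {
    pos <- map$position[map$group == g]
    if (is.unsorted(pos))
      stop("positions not non-decreasing within linkage group ", g, call. = FALSE)
  }

  # --- blocks ---
  if (is.data.frame(blocks)) {
    if (!all(c("block", "marker") %in% names(blocks)))
      stop("blocks data.frame must have columns block, marker", call. = FALSE)
    blocks <- split(as.character(blocks$marker), as.character(blocks$block))
  }
  if (!is.list(blocks) || is.null(names(blocks)) || any(names(blocks) == ""))
    stop("blocks must be a named list of marker id vectors", call. = FALSE)
  blocks <- blocks[order(names(blocks))]
  for (b in names(blocks)) {
    mk <- as.character(blocks[[b]])
    if (!length(mk)) stop("haploblock ", b, " is empty", call. = FALSE)
    absent <- setdiff(mk, map$marker)
    if (length(absent))
      stop("haploblock ", b, " contains marker absent from map: ", absent[1L],
           call. = FALSE)
    idx <- match(mk, map$marker)
    grp <- unique(map$group[idx])
    if (length(grp) > 1L)
      stop("haploblock ", b, " spans linkage groups ",
           paste(grp, collapse = ", "), call. = FALSE)
    span <- seq(min(idx), max(idx))
    if (!identical(idx, span)) {
      if (is.unsorted(idx, strictly = TRUE))
        stop("haploblock ", b, " markers are not in map order", call. = FALSE)
      interloper <- map$marker[setdiff(span, idx)][1L]
      stop("haploblock ", b, " is not contiguous: map marker ", interloper,
           " lies between its markers", call. = FALSE)
    }
    blocks[[b]] <- mk
  }

  # --- pedigree ---
  pedigree <- validate_pedigree(pedigree)
  ids <- pedigree$id

  # --- phased genotypes ---
  if (!is.matrix(haplo) || (nrow(haplo) > 0L && is.null(rownames(haplo))) ||
      (ncol(haplo) > 0L && is.null(colnames(haplo))))
    stop("haplo must be a character matrix with row and column names", call. = FALSE)
  if (is.null(colnames(haplo))) colnames(haplo) <- character(0)
  if (is.null(rownames(haplo))) rownames(haplo) <- character(0)
  unknown_mk <- setdiff(colnames(haplo), map$marker)
  if (length(unknown_mk))
    stop("genotyped marker absent from map: ", unknown_mk[1L], call. = FALSE)
  rn <- rownames(haplo)
  if (anyDuplicated(rn))
    stop("duplicated haplotype row: ", rn[duplicated(rn)][1L], call. = FALSE)
  slot_ok <- grepl("\\|[MP]$", rn)
  if (any(!slot_ok))
    stop("haplotype row names must end in '|M' or '|P': ", rn[!slot_ok][1L],
         call. = FALSE)
  geno_ids <- unique(sub("\\|[MP]$", "", rn))
  alien <- setdiff(geno_ids, ids)
  if (length(alien))
    stop("genotyped individual not in pedigree: ", alien[1L], call. = FALSE)

  full <- matrix(NA_character_, nrow = 2L * length(ids), ncol = nrow(map),
                 dimnames = list(
                   if (length(ids)) paste0(rep(ids, each = 2L), c("|M", "|P"))
                   else character(0),
                   map$marker))
  have <- intersect(rownames(full), rn)
  full[have, colnames(haplo)] <- haplo[have, , drop = FALSE]
  full[full %in% c("-", "")] <- NA_character_

  structure(list(map = map, blocks = blocks, pedigree = pedigree, haplo = full),
            class = "hb_data")
}

#' @export
print.hb_data <- function(x, ...) {
  n_geno <- sum(rowSums(!is.na(x$haplo)) > 0L) / 2
  cat(sprintf("Haploblock dataset: %d individuals (%.0f with marker data),\n",
              nrow(x$pedigree), n_geno))
  cat(sprintf("  %d markers on %d linkage group(s), %d haploblocks\n",
              nrow(x$map), length(unique(x$map$group)), length(x$blocks)))
  cat(sprintf("  missing marker calls: %.1f%%\n", 100 * mean(is.na(x$haplo))))
  invisible(x)
}
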