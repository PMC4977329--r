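# Tab-delimited input and output. All files are UTF-8, one header line,
# "-" = missing allele call, "0" or empty field = unknown parent.

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    colClasses = "character", check.names = FALSE,
                    na.strings = NULL, stringsAsFactors = FALSE)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "-", eol = "\n")
}

#' Read the four input tables of a haploblock dataset
#'
#' Reads the linkage map, haploblock definitions, pedigree and phased marker
#' genotypes from tab-delimited text files and cross-validates them (see
#' [haplo_data()] for the checks performed).
#'
#' File layouts (one header line each):
#' \describe{
#'   \item{map}{`marker`, `group`, `position` (cM).}
#'   \item{blocks}{`block`, `marker`; one row per marker, in within-block
#'     order.}
#'   \item{pedigree}{`id`, `mother`, `father`; `"0"` or empty = unknown.}
#'   \item{genotypes}{`individual`, then two columns per marker named
#'     `<marker>_mat` and `<marker>_pat` holding the allele inherited from
#'     the mother and father respectively; `"-"` = missing.}
#' }
#'
#' @param map_file,blocks_file,pedigree_file,genotypes_file Paths.
#' @return An [haplo_data()] object.
#' @export
read_haplo_data <- function(map_file, blocks_file, pedigree_file, genotypes_file) {
  map <- .read_tsv(map_file)
  if (!all(c("marker", "group", "position") %in% names(map)))
    stop("map file must have columns marker, group, position", call. = FALSE)
  blocks <- .read_tsv(blocks_file)
  ped <- .read_tsv(pedigree_file)
  gt <- .read_tsv(genotypes_file)
  if (!"individual" %in% names(gt))
    stop("genotypes file must have an 'individual' column", call. = FALSE)
  if (anyDuplicated(gt$individual))
    stop("duplicated individual row in genotypes file: ",
         gt$individual[duplicated(gt$individual)][1L], call. = FALSE)
  cols <- setdiff(names(gt), "individual")
  bad <- cols[!grepl("_(mat|pat)$", cols)]
  if (length(bad))
    stop("genotype column not of the form <marker>_mat/<marker>_pat: ", bad[1L],
         call. = FALSE)
  markers <- unique(sub("_(mat|pat)$", "", cols))
  need <- c(paste0(markers, "_mat"), paste0(markers, "_pat"))
  absent <- setdiff(need, cols)
  if (length(absent))
    stop("genotypes file missing column ", absent[1L], call. = FALSE)
  haplo <- matrix(NA_character_, nrow = 2L * nrow(gt), ncol = length(markers),
                  dimnames = list(paste0(rep(gt$individual, each = 2L), c("|M", "|P")),
                                  markers))
  for (m in markers) {
    haplo[seq(1L, 2L * nrow(gt), by = 2L), m] <- gt[[paste0(m, "_mat")]]
    haplo[seq(2L, 2L * nrow(gt), by = 2L), m] <- gt[[paste0(m, "_pat")]]
  }
  haplo[haplo %in% c("-", "")] <- NA_character_
  haplo_data(map = map, blocks = blocks, pedigree = ped, haplo = haplo)
}

# haplotype matrix -> wide genotype data.frame (one row per individual)
.haplo_to_table <- function(haplo) {
  ids <- sub("\\|[MP]$", "", rownames(haplo)[seq(1L, nrow(haplo), by = 2L)])
  markers <- colnames(haplo)
  out <- data.frame(individual = ids, stringsAsFactors = FALSE)
  for (m in markers) {
    out[[paste0(m, "_mat")]] <- haplo[seq(1L, nrow(haplo), by = 2L), m]
    out[[paste0(m, "_pat")]] <- haplo[seq(2L, nrow(haplo), by = 2L), m]
  }
  out
}

#' Write phased marker genotypes to a tab-delimited file
#'
#' Inverse of the genotype reader: one row per individual, two columns per
#' marker (`<marker>_mat`, `<marker>_pat`), `"-"` for missing.
#'
#' @param haplo Haplotype matrix (two rows per individual).
#' @param path Output path.
#' @export
write_genotype_file <- function(haplo, path) {
  .write_tsv(.haplo_to_table(haplo), path)
  invisible(path)
}

#' Write the result files of a haploblock assignment
#'
#' Writes, into `dir`:
#' \describe{
#'   \item{`haploblock_genotypes.txt`}{`individual`, `block`, `allele_mat`,
#'     `allele_pat` — haploblock allele names (`"-"` missing; non-converged
#'     blocks all missing).}
#'   \item{`allele_composition.txt`}{`block`, `allele`, `name`, then one
#'     column per map marker with the allele's marker code; `"-"` = missing
#'     within the allele, `"."` = marker not part of that block.}
#'   \item{`imputed_genotypes.txt`}{the final phased marker genotypes (same
#'     layout as the genotype input, retained markers only).}
#'   \item{`pedimap.txt`}{pedigree plus phased haploblock genotypes in a
#'     Pedimap-style layout: `Name`, `Mother`, `Father`, then two columns
#'     per block (`<block>_1`, `<block>_2`).}
#' }
#' Content is byte-stable given identical inputs.
#'
#' @param fit An `hb_fit` object from [assign_haploblocks()].
#' @param dir Output directory (created if needed).
#' @param flexqtl_names Use FlexQTL-style column headers (`Genotype`,
#'   `<block>m`, `<block>p`) in the haploblock genotype table.
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(fit, dir, flexqtl_names = FALSE) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir, call. = FALSE)
  }
  inc <- fit$params$include_missing_count_in_names
  name_of <- function(block, num) {
    if (is.na(num)) return(NA_character_)
    comp <- fit$catalogs[[block]]
    allele_name(num, unlist(comp[comp$allele == num, -1, drop = TRUE]), inc)
  }
  gt <- fit$genotypes
  gt_out <- data.frame(
    individual = gt$individual, block = gt$block,
    allele_mat = mapply(name_of, gt$block, gt$allele_mat, USE.NAMES = FALSE),
    allele_pat = mapply(name_of, gt$block, gt$allele_pat, USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  if (flexqtl_names)
    names(gt_out) <- c("Genotype", "block", "allele_m", "allele_p")
  p1 <- file.path(dir, "haploblock_genotypes.txt")
  .write_tsv(gt_out, p1)

  all_markers <- unlist(fit$blocks, use.names = FALSE)
  comp_rows <- lapply(names(fit$catalogs), function(b) {
    comp <- fit$catalogs[[b]]
    if (!nrow(comp)) return(NULL)
    wide <- matrix(".", nrow = nrow(comp), ncol = length(all_markers),
                   dimnames = list(NULL, all_markers))
    bm <- fit$blocks[[b]]
    for (m in bm) wide[, m] <- ifelse(is.na(comp[[m]]), "-", comp[[m]])
    nm <- vapply(seq_len(nrow(comp)), function(i)
      allele_name(comp$allele[i], unlist(comp[i, bm, drop = TRUE]), inc),
      character(1))
    cbind(data.frame(block = b, allele = comp$allele, name = nm,
                     stringsAsFactors = FALSE),
          as.data.frame(wide, stringsAsFactors = FALSE))
  })
  comp_rows <- comp_rows[!vapply(comp_rows, is.null, logical(1))]
  comp_out <- if (length(comp_rows)) do.call(rbind, comp_rows) else
    cbind(data.frame(block = character(0), allele = integer(0),
                     name = character(0)),
          as.data.frame(matrix(character(0), 0, length(all_markers),
                               dimnames = list(NULL, all_markers))))
  p2 <- file.path(dir, "allele_composition.txt")
  .write_tsv(comp_out, p2)

  p3 <- file.path(dir, "imputed_genotypes.txt")
  write_genotype_file(fit$haplo, p3)

  ped <- fit$pedigree
  pm <- data.frame(Name = ped$id,
                   Mother = ifelse(is.na(ped$mother), "0", ped$mother),
                   Father = ifelse(is.na(ped$father), "0", ped$father),
                   stringsAsFactors = FALSE)
  for (b in names(fit$blocks)) {
    sel <- gt$block == b
    sub <- gt[sel, , drop = FALSE]
    ord <- match(ped$id, sub$individual)
    pm[[paste0(b, "_1")]] <- mapply(name_of, b, sub$allele_mat[ord], USE.NAMES = FALSE)
    pm[[paste0(b, "_2")]] <- mapply(name_of, b, sub$allele_pat[ord], USE.NAMES = FALSE)
  }
  p4 <- file.path(dir, "pedimap.txt")
  .write_tsv(pm, p4)

  invisible(c(p1, p2, p3, p4))
}

#' Write engine diagnostics
#'
#' One tab-delimited row per logged event, in chronological order. Events:
#' `IMPUTED`, `UPDATED`, `MARKER_DATA_DELETED`, `ALLELE_REJECTED`,
#' `SET_MISSING`, `MARKER_FILTERED`, `NON_CONVERGENCE`.
#'
#' @param diagnostics Diagnostics data.frame (e.g. `fit$diagnostics`).
#' @param path Output path.
#' @export
write_diagnostics <- function(diagnostics, path) {
  .write_tsv(diagnostics, path)
  invisible(path)
}
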